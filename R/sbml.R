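# SBML Level 3 Version 1 + fbc version 2 input/output, covering the
# COBRA-style subset genome-scale models use: species with
# boundaryCondition, flux bound parameters, gene product associations,
# and an active maximization objective.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

# attribute lookup tolerant of namespace prefixes ("fbc:reaction" etc.)
attr_any <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- which(names(at) == name | grepl(paste0(":", name, "$"), names(at)))
  if (length(hit)) at[[hit[1L]]] else NA_character_
}

local_nodes <- function(x, name) {
  xml2::xml_find_all(x, paste0(".//*[local-name()='", name, "']"))
}

#' Read a metabolic model from SBML
#'
#' Parses SBML Level 3 with the fbc extension: stoichiometry from
#' reactant/product lists, flux bounds from fbc bound parameters (or
#' kinetic-law defaults), gene associations from
#' `fbc:geneProductAssociation` trees, the boundary flag from species
#' `boundaryCondition`, and the objective from the active fbc objective.
#'
#' @param path SBML file path.
#' @return a [metabolic_model()].
#' @export
read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e) {
    stop("malformed SBML in '", path, "': ", conditionMessage(e))
  })
  mnode <- local_nodes(doc, "model")
  if (!length(mnode)) stop("malformed SBML: no <model> element in '", path, "'")

  # species
  sp <- xml2::xml_find_all(doc,
    ".//*[local-name()='listOfSpecies']/*[local-name()='species']")
  met_ids <- vapply(sp, attr_any, "", name = "id")
  boundary <- vapply(sp, function(s) {
    isTRUE(tolower(attr_any(s, "boundaryCondition")) == "true")
  }, logical(1))

  # gene product id -> label
  gps <- local_nodes(doc, "geneProduct")
  gp_label <- stats::setNames(
    vapply(gps, function(g) {
      lab <- attr_any(g, "label")
      if (is.na(lab)) attr_any(g, "id") else lab
    }, ""),
    vapply(gps, attr_any, "", name = "id")
  )

  # flux bound parameters
  pars <- xml2::xml_find_all(doc,
    ".//*[local-name()='listOfParameters']/*[local-name()='parameter']")
  par_val <- stats::setNames(
    as.numeric(vapply(pars, attr_any, "", name = "value")),
    vapply(pars, attr_any, "", name = "id")
  )

  gpr_from_node <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- attr_any(node, "geneProduct")
      lab <- gp_label[ref]
      return(if (is.na(lab)) ref else unname(lab))
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpr_from_node, "")
    op <- if (nm == "and") " and " else " or "
    paste0("(", paste(parts, collapse = op), ")")
  }

  rx <- xml2::xml_find_all(doc,
    ".//*[local-name()='listOfReactions']/*[local-name()='reaction']")
  if (!length(rx)) stop("malformed SBML: model has no reactions")
  n <- length(rx)
  rxn_ids <- vapply(rx, attr_any, "", name = "id")
  S <- matrix(0, length(met_ids), n, dimnames = list(met_ids, rxn_ids))
  lb <- numeric(n); ub <- numeric(n)
  gpr <- character(n); subsystems <- rep(NA_character_, n)
  for (j in seq_len(n)) {
    node <- rx[[j]]
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(node, paste0(
        "./*[local-name()='", side, "']/*[local-name()='speciesReference']"))
      for (ref in refs) {
        sid <- attr_any(ref, "species")
        st <- attr_any(ref, "stoichiometry")
        st <- if (is.na(st)) 1 else as.numeric(st)
        if (!sid %in% met_ids) {
          stop("malformed SBML: reaction '", rxn_ids[j],
               "' references unknown species '", sid, "'")
        }
        S[sid, j] <- S[sid, j] + sgn * st
      }
    }
    lref <- attr_any(node, "lowerFluxBound")
    uref <- attr_any(node, "upperFluxBound")
    lb[j] <- if (!is.na(lref) && lref %in% names(par_val)) par_val[[lref]]
             else if (isTRUE(tolower(attr_any(node, "reversible")) == "true")) -1000
             else 0
    ub[j] <- if (!is.na(uref) && uref %in% names(par_val)) par_val[[uref]] else 1000
    ga <- xml2::xml_find_first(node,
      "./*[local-name()='geneProductAssociation']")
    if (!inherits(ga, "xml_missing")) {
      kids <- xml2::xml_children(ga)
      if (length(kids)) gpr[j] <- gpr_from_node(kids[[1L]])
    }
    note <- xml2::xml_find_first(node, ".//*[local-name()='p']")
    if (!inherits(note, "xml_missing")) {
      txt <- xml2::xml_text(note)
      if (grepl("^SUBSYSTEM:", txt)) {
        subsystems[j] <- trimws(sub("^SUBSYSTEM:", "", txt))
      }
    }
  }

  # active objective
  fobj <- local_nodes(doc, "fluxObjective")
  if (!length(fobj)) {
    stop("configuration error: SBML file '", path,
         "' declares no flux objective")
  }
  objective_id <- attr_any(fobj[[1L]], "reaction")

  metabolic_model(S, rxn_ids, met_ids, lb, ub, gpr, objective_id,
                  boundary = boundary, subsystems = subsystems)
}

gpr_to_fbc <- function(node, tree) {
  if (!is.null(tree$gene)) {
    ref <- xml2::xml_add_child(node, "fbc:geneProductRef")
    xml2::xml_set_attr(ref, "fbc:geneProduct", tree$gene)
    return(invisible())
  }
  inner <- xml2::xml_add_child(node, paste0("fbc:", tree$op))
  for (a in tree$args) gpr_to_fbc(inner, a)
  invisible()
}

#' Write a metabolic model to SBML
#'
#' Emits SBML Level 3 Version 1 with fbc version 2: shared bound
#' parameters, `boundaryCondition` species flags, gene product
#' associations rebuilt from the model's GPR strings, and a maximization
#' objective on the model's objective reaction. [read_sbml()] of the
#' written file reproduces the model exactly.
#'
#' @param model a [metabolic_model()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sbml <- function(model, path) {
  doc <- xml2::xml_new_root(
    "sbml",
    xmlns = SBML_NS, "xmlns:fbc" = FBC_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mnode <- xml2::xml_add_child(doc, "model", id = "model",
                               "fbc:strict" = "true")

  comp <- xml2::xml_add_child(mnode, "listOfCompartments")
  xml2::xml_add_child(comp, "compartment", id = "c", constant = "true")

  spl <- xml2::xml_add_child(mnode, "listOfSpecies")
  for (i in seq_along(model$metabolite_ids)) {
    xml2::xml_add_child(
      spl, "species",
      id = model$metabolite_ids[i], compartment = "c",
      hasOnlySubstanceUnits = "false", constant = "false",
      boundaryCondition = if (model$boundary[i]) "true" else "false"
    )
  }

  bounds <- sort(unique(c(model$lb, model$ub)))
  fmt1 <- function(v) vapply(v, function(b) format(b, digits = 17), "")
  par_id <- stats::setNames(paste0("bnd_", seq_along(bounds)), fmt1(bounds))
  parl <- xml2::xml_add_child(mnode, "listOfParameters")
  for (i in seq_along(bounds)) {
    xml2::xml_add_child(parl, "parameter",
                        id = par_id[[i]],
                        value = format(bounds[i], digits = 17),
                        constant = "true")
  }

  rxl <- xml2::xml_add_child(mnode, "listOfReactions")
  for (j in seq_along(model$reaction_ids)) {
    rn <- xml2::xml_add_child(
      rxl, "reaction",
      id = model$reaction_ids[j],
      reversible = if (model$lb[j] < 0) "true" else "false",
      fast = "false",
      "fbc:lowerFluxBound" = par_id[[format(model$lb[j], digits = 17)]],
      "fbc:upperFluxBound" = par_id[[format(model$ub[j], digits = 17)]]
    )
    if (!is.na(model$subsystems[j])) {
      notes <- xml2::xml_add_child(rn, "notes")
      body <- xml2::xml_add_child(notes, "body",
                                  xmlns = "http://www.w3.org/1999/xhtml")
      xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", model$subsystems[j]))
    }
    col <- model$S[, j]
    rt <- which(col < 0); pd <- which(col > 0)
    if (length(rt)) {
      lr <- xml2::xml_add_child(rn, "listOfReactants")
      for (i in rt) {
        xml2::xml_add_child(lr, "speciesReference",
                            species = model$metabolite_ids[i],
                            stoichiometry = format(-col[i], digits = 17),
                            constant = "true")
      }
    }
    if (length(pd)) {
      lp <- xml2::xml_add_child(rn, "listOfProducts")
      for (i in pd) {
        xml2::xml_add_child(lp, "speciesReference",
                            species = model$metabolite_ids[i],
                            stoichiometry = format(col[i], digits = 17),
                            constant = "true")
      }
    }
    rule <- parse_gpr(model$gpr_rules[j])
    if (!is.null(rule)) {
      ga <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      gpr_to_fbc(ga, rule$tree)
    }
  }

  objs <- xml2::xml_add_child(mnode, "fbc:listOfObjectives",
                              "fbc:activeObjective" = "obj")
  ob <- xml2::xml_add_child(objs, "fbc:objective", "fbc:id" = "obj",
                            "fbc:type" = "maximize")
  fol <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
  xml2::xml_add_child(fol, "fbc:fluxObjective",
                      "fbc:reaction" = model$objective_id,
                      "fbc:coefficient" = "1")

  genes <- model_genes(model)
  if (length(genes)) {
    gl <- xml2::xml_add_child(mnode, "fbc:listOfGeneProducts")
    for (g in genes) {
      xml2::xml_add_child(gl, "fbc:geneProduct", "fbc:id" = g,
                          "fbc:label" = g)
    }
  }

  xml2::write_xml(doc, path)
  invisible(path)
}
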