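test_that("fastcc equals the per-reaction LP oracle on all fixtures", {
  for (top in c("chain", "dead_end", "diamond", "isozyme",
                "parallel_paths", "minimal_medium")) {
    m <- make_toy_model(top)
    want <- setdiff(m$reaction_ids, naive_blocked(m, tol = 1e-9))
    expect_setequal(fastcc(m), want)
  }
  for (s in 1:6) {
    m <- random_toy_model(s)
    expect_setequal(fastcc(m), setdiff(m$reaction_ids, naive_blocked(m)))
  }
})

test_that("fastcore returns the minimal consistent superset on designed fixtures", {
  # single core reaction in a chain pulls in the whole chain
  ch <- make_toy_model("chain", chain_len = 4)
  r <- fastcore(ch, core = "R1")
  expect_setequal(names(r)[r == 1], ch$reaction_ids)
  oracle <- brute_force_min_consistent_superset(ch, "R1")
  expect_equal(sum(r), length(oracle[[1]]))
  # diamond: core on the short path excludes the long path
  dm <- make_toy_model("diamond")
  r2 <- fastcore(dm, core = "S1")
  expect_setequal(names(r2)[r2 == 1], c("R_src", "S1", "S2", "biomass"))
  o2 <- brute_force_min_consistent_superset(dm, "S1")
  expect_true(any(vapply(o2, function(s)
    setequal(s, names(r2)[r2 == 1]), logical(1))))
  # core = everything consistent returns everything consistent
  r3 <- fastcore(dm, core = dm$reaction_ids)
  expect_equal(sum(r3), length(dm$reaction_ids))
})

test_that("fastcore output always contains its core and is flux-consistent", {
  set.seed(13)
  for (s in 1:6) {
    m <- random_toy_model(s)
    cons <- fastcc(m)
    core <- sample(cons, min(3, length(cons)))
    r <- suppressWarnings(fastcore(m, core))
    kept <- names(r)[r == 1]
    expect_true(all(intersect(core, cons) %in% kept))
    sub <- set_bounds(m, setdiff(m$reaction_ids, kept), lb = 0, ub = 0)
    expect_setequal(fastcc(sub), kept)
  }
})

test_that("fastcore drops inconsistent core members with a warning", {
  de <- make_toy_model("dead_end")
  expect_warning(r <- fastcore(de, core = c("R1", "R_dead")),
                 "inconsistent core")
  expect_equal(unname(r["R_dead"]), 0L)
  expect_error(suppressWarnings(fastcore(de, core = "R_dead")),
               "empty")
})

test_that("tinit matches exhaustive subnetwork enumeration", {
  pp <- make_toy_model("parallel_paths")
  ras <- c(R_src = 0, P1 = 1, P2 = 1, N1 = -1, N2 = -1, biomass = 0)
  r <- tinit(pp, ras)
  oracle <- brute_force_tinit(pp, ras, "biomass")
  expect_equal(attr(r, "objective"), oracle$objective, tolerance = 1e-6)
  expect_setequal(names(r)[r == 1], oracle$subnetwork)
  # all-positive scores keep the whole consistent model
  dm <- make_toy_model("diamond")
  rp <- tinit(dm, stats::setNames(rep(1, 7), dm$reaction_ids))
  expect_equal(sum(rp), 7)
  # all-negative scores leave a minimal biomass-sustaining subnetwork
  rn <- tinit(dm, stats::setNames(rep(-1, 7), dm$reaction_ids))
  on <- brute_force_tinit(dm, stats::setNames(rep(-1, 7), dm$reaction_ids),
                          "biomass")
  expect_equal(attr(rn, "objective"), on$objective, tolerance = 1e-6)
  # protected reaction must be activatable
  cut <- set_bounds(dm, "R_src", lb = 0, ub = 0)
  expect_error(tinit(cut, stats::setNames(rep(1, 7), dm$reaction_ids)),
               "cannot carry flux")
})

test_that("tinit is deterministic across repeated runs", {
  pp <- make_toy_model("parallel_paths")
  ras <- c(R_src = 0.5, P1 = 1, P2 = -0.3, N1 = 0.2, N2 = -1, biomass = 0)
  r1 <- tinit(pp, ras)
  r2 <- tinit(pp, ras)
  expect_identical(as.integer(r1), as.integer(r2))
})

test_that("apply_presence knocks out without deleting and is idempotent", {
  dm <- make_toy_model("diamond")
  r <- reaction_presence(dm, setdiff(dm$reaction_ids, c("S1", "L1")))
  ctx <- apply_presence(dm, r)
  expect_length(ctx$reaction_ids, length(dm$reaction_ids))
  expect_equal(fba(ctx)$objective_value, 0)  # both routes severed
  expect_identical(apply_presence(ctx, r), ctx)
  # all-ones presence is the identity
  expect_identical(apply_presence(dm, reaction_presence(dm, dm$reaction_ids)),
                   dm)
})

test_that("check_model reports growth with and without a medium", {
  mm <- make_toy_model("minimal_medium")
  chk <- check_model(mm, medium = "Y")
  expect_true(chk$grows)
  expect_false(chk$grows_on_medium)
  chk2 <- check_model(mm, medium = "X")
  expect_true(chk2$grows_on_medium)
  dead <- apply_presence(mm, reaction_presence(mm, setdiff(mm$reaction_ids, "R1")))
  expect_false(check_model(dead)$grows)
})

test_that("parameter_grid applies the validity predicate deterministically", {
  g <- parameter_grid()
  # localT2 requires p_gmin < p_gmax
  t2 <- g[g$strategy == "localT2", ]
  expect_true(all(t2$p_gmin < t2$p_gmax))
  # global ignores p_gmin and p_local: no duplicates
  expect_false(any(duplicated(g)))
  gl <- g[g$strategy == "global", ]
  expect_true(all(is.na(gl$p_gmin)) && all(is.na(gl$p_local)))
  # reduced grid size by hand: 2 algorithms x 2 gmax x 1 or_fn, global only
  small <- parameter_grid(strategies = "global", p_gmax = c(50, 75),
                          or_fns = "max")
  expect_equal(nrow(small), 4)
  # deterministic ordering
  expect_identical(g, parameter_grid())
})
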