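test_that("gapfill problems expose the documented candidate sets", {
  ch <- make_toy_model("chain", chain_len = 4)
  r_all <- reaction_presence(ch, ch$reaction_ids)
  p0 <- build_gapfill_problem(ch, r_all, "biomass")
  expect_length(p0$K, 0)
  r1 <- reaction_presence(ch, setdiff(ch$reaction_ids, "R1"))
  expect_identical(build_gapfill_problem(ch, r1, "biomass")$K, "R1")
  mm <- make_toy_model("minimal_medium")
  pm <- build_gapfill_problem(mm, reaction_presence(mm, mm$reaction_ids),
                              "biomass", scenario = "medium")
  expect_setequal(pm$K, c("EX_X", "EX_Y", "EX_W", "biomass"))
})

test_that("efm_gapfill restores a severed chain with the single missing link", {
  ch <- make_toy_model("chain", chain_len = 4)
  r <- reaction_presence(ch, setdiff(ch$reaction_ids, "R1"))
  s <- efm_gapfill(build_gapfill_problem(ch, r, "biomass"))
  expect_identical(s$selected, "R1")
  expect_equal(s$cardinality, 1)
  # already-growing model needs nothing
  s0 <- efm_gapfill(build_gapfill_problem(
    ch, reaction_presence(ch, ch$reaction_ids), "biomass"))
  expect_equal(s0$cardinality, 0)
})

test_that("efm_gapfill prefers the cheaper of two alternative repairs", {
  dm <- make_toy_model("diamond")
  # short path needs 2 insertions, long path only 1
  r <- reaction_presence(dm, setdiff(dm$reaction_ids, c("S1", "S2", "L1")))
  s <- efm_gapfill(build_gapfill_problem(dm, r, "biomass"))
  expect_identical(s$selected, "L1")
})

test_that("gapfill optimality, soundness and indicators hold on random problems", {
  set.seed(11)
  for (i in 1:12) {
    m <- random_toy_model(i, n_extra = 3)
    cand <- m$reaction_ids[!exchange_reactions(m)]
    dropped <- sample(cand, min(sample(1:3, 1), length(cand)))
    r <- reaction_presence(m, setdiff(m$reaction_ids, dropped))
    pb <- build_gapfill_problem(m, r, "biomass")
    sol <- efm_gapfill(pb)
    oracle <- brute_force_min_gapfill(m, r, "biomass", pb$K,
                                      delta = pb$delta)
    if (sol$status == "optimal") {
      expect_equal(sol$cardinality, oracle$cardinality)
      # soundness: applying the solution restores biomass flux
      keep <- union(names(r)[r == 1], sol$selected)
      shut <- setdiff(setdiff(m$reaction_ids, keep),
                      m$reaction_ids[exchange_reactions(m)])
      f <- fba(set_bounds(m, shut, lb = 0, ub = 0), "biomass")
      expect_gte(f$objective_value, pb$delta - 1e-9)
      # indicator correctness in the witness
      off <- setdiff(pb$K, sol$selected)
      if (length(off)) expect_lt(max(abs(sol$witness[off])), 1e-6)
    } else {
      expect_length(oracle$solutions, 0)
    }
  }
})

test_that("medium-scenario gapfill recovers the minimal growth medium", {
  mm <- make_toy_model("minimal_medium")
  pb <- build_gapfill_problem(mm, reaction_presence(mm, mm$reaction_ids),
                              "biomass", scenario = "medium")
  s <- efm_gapfill(pb)
  expect_identical(s$selected, "EX_X")
  oracle <- brute_force_min_gapfill(mm, reaction_presence(mm, mm$reaction_ids),
                                    "biomass", pb$K, delta = pb$delta,
                                    medium_scenario = TRUE)
  expect_equal(s$cardinality, oracle$cardinality)
})

test_that("a gap that cannot be closed is a result, not an error", {
  ch <- make_toy_model("chain", chain_len = 4)
  r <- reaction_presence(ch, setdiff(ch$reaction_ids, "R1"))
  # medium scenario cannot re-enable a missing enzyme
  s <- efm_gapfill(build_gapfill_problem(ch, r, "biomass",
                                         scenario = "medium"))
  expect_equal(s$status, "no_gapfill")
})

test_that("enumerate_gapfill_solutions yields distinct ordered solutions", {
  dm <- make_toy_model("diamond")
  r <- reaction_presence(dm, setdiff(dm$reaction_ids, c("S1", "L1")))
  pb <- build_gapfill_problem(dm, r, "biomass")
  sols <- enumerate_gapfill_solutions(pb, 5)
  expect_length(sols, 2)
  expect_setequal(vapply(sols, function(s) s$selected, ""), c("S1", "L1"))
  cards <- vapply(sols, function(s) s$cardinality, numeric(1))
  expect_true(all(diff(cards) >= 0))
  # k = 1 equals the single solve
  one <- enumerate_gapfill_solutions(pb, 1)
  expect_identical(one[[1]]$selected, efm_gapfill(pb)$selected)
})

test_that("enlarging K never increases optimal cardinality", {
  ch <- make_toy_model("chain", chain_len = 5)
  r <- reaction_presence(ch, setdiff(ch$reaction_ids, c("R1", "R2")))
  pb <- build_gapfill_problem(ch, r, "biomass")
  base <- efm_gapfill(pb)$cardinality
  # adding an irrelevant extra candidate by also dropping a parallel rxn
  m2 <- make_toy_model("diamond")
  r2 <- reaction_presence(m2, setdiff(m2$reaction_ids, "S1"))
  r3 <- reaction_presence(m2, setdiff(m2$reaction_ids, c("S1", "L1")))
  c2 <- efm_gapfill(build_gapfill_problem(m2, r2, "biomass"))$cardinality
  c3 <- efm_gapfill(build_gapfill_problem(m2, r3, "biomass"))$cardinality
  expect_lte(c3, c2 + 1)
  expect_equal(base, 2)
})
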