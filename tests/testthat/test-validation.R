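test_that("essentiality_screen recovers planted GPR patterns exactly", {
  # sole-path genes (chain), isozyme backup and complex subunits
  iso <- make_toy_model("isozyme")
  rep_ <- essentiality_screen(iso, c("g1", "g2", "g3", "g4", "gAbsent"))
  got <- rep_$gene[rep_$essential]
  expect_setequal(got, attr(iso, "ground_truth")$essential_genes)
  expect_false(any(c("g1", "g2", "gAbsent") %in% got))
  ch <- make_toy_model("chain", chain_len = 5)
  rep2 <- essentiality_screen(ch, model_genes(ch))
  expect_setequal(rep2$gene[rep2$essential],
                  attr(ch, "ground_truth")$essential_genes)
})

test_that("essentiality uses the 0.1 percent rule and restores bounds", {
  iso <- make_toy_model("isozyme")
  before <- list(iso$lb, iso$ub)
  out <- essentiality_screen(iso, c("g3", "g1"))
  expect_identical(list(iso$lb, iso$ub), before)
  expect_equal(out$growth_ratio[out$gene == "g1"], 1)
  expect_equal(out$mutant_growth[out$gene == "g3"], 0)
  # a knockout reducing growth to 0.05% of wild type is lethal, 5% is not
  m <- make_toy_model("parallel_paths")
  m$ub[match(c("N1", "N2"), m$reaction_ids)] <- 10 * 0.0005
  scr <- essentiality_screen(m, "gP1")  # forces flux through tiny N path
  expect_true(scr$essential)
  m$ub[match(c("N1", "N2"), m$reaction_ids)] <- 10 * 0.05
  scr2 <- essentiality_screen(m, "gP1")
  expect_false(scr2$essential)
  # non-growing wild type refuses to screen
  dead <- set_bounds(iso, "R_src", lb = 0, ub = 0)
  expect_error(essentiality_screen(dead, "g1"), "does not grow")
})

test_that("discretize_ceres thresholds and grid behave as specified", {
  expect_equal(ceres_threshold_grid(), c(-1.5, -1.25, -1, -0.75, -0.5))
  sc <- c(a = -2, b = 0, c = -0.8, d = NA)
  expect_message(out <- discretize_ceres(sc, -0.75), "dropping 1")
  expect_identical(out, c(a = TRUE, b = FALSE, c = TRUE))  # -0.8 <= -0.75
})

test_that("mcc reproduces the multiclass formula and its edge values", {
  expect_equal(mcc(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(mcc(c(1, 0, 1, 0), c(0, 1, 0, 1)), -1)
  expect_equal(mcc(rep("x", 6), c("x", "y", "x", "y", "x", "y")), 0)
  expect_error(mcc(1:3, 1:4), "equal length")
  # equals the covariance (Gorodkin) formulation on random 2- and 3-class data
  gorodkin <- function(pred, act) {
    cls <- union(pred, act)
    X <- outer(pred, cls, "==") * 1
    Y <- outer(act, cls, "==") * 1
    cv <- function(A, B) sum(vapply(seq_along(cls), function(k)
      stats::cov(A[, k], B[, k]), numeric(1)))
    d <- sqrt(cv(X, X) * cv(Y, Y))
    if (d == 0) 0 else cv(X, Y) / d
  }
  set.seed(3)
  for (i in 1:30) {
    k <- sample(2:3, 1)
    pred <- sample(letters[1:k], 40, TRUE)
    act <- sample(letters[1:k], 40, TRUE)
    expect_equal(mcc(pred, act), gorodkin(pred, act), tolerance = 1e-12)
  }
  # symmetric under simultaneous class relabeling
  pred <- sample(c("a", "b", "c"), 30, TRUE)
  act <- sample(c("a", "b", "c"), 30, TRUE)
  relab <- c(a = "z1", b = "z2", c = "z3")
  expect_equal(mcc(pred, act), mcc(relab[pred], relab[act]))
})

test_that("discretize_flux is tolerance-symmetric around zero", {
  expect_identical(unname(discretize_flux(c(5, -2, 0))),
                   c("forward_active", "reverse_active", "null"))
  expect_identical(unname(discretize_flux(5e-7)), "null")
  v <- c(3, -0.2, 0, 1e-8)
  flip <- discretize_flux(-v)
  orig <- discretize_flux(v)
  expect_identical(flip[orig == "forward_active"] == "reverse_active",
                   rep(TRUE, sum(orig == "forward_active")))
  expect_identical(flip[orig == "null"], orig[orig == "null"])
})

test_that("compare_flux_activity matches hand-computed MCC on overlaps", {
  pred <- c(r1 = "forward_active", r2 = "forward_active", r3 = "null",
            r4 = "reverse_active")
  meas <- c(r2 = "forward_active", r3 = "forward_active",
            r4 = "reverse_active", r9 = "null")
  got <- compare_flux_activity(pred, meas)
  expect_equal(got, mcc(c("forward_active", "null", "reverse_active"),
                        c("forward_active", "forward_active",
                          "reverse_active")))
  expect_equal(compare_flux_activity(pred, pred), 1)
  expect_error(compare_flux_activity(pred, c(zz = "null")), "no overlapping")
  # sign map flips direction conventions
  flipped <- compare_flux_activity(pred, meas, sign_map = c(r4 = -1))
  expect_lt(flipped, got)
})

test_that("parameter_importance recovers a planted one-hot effect", {
  set.seed(21)
  hits <- 0
  for (s in 1:20) {
    cfg <- parameter_grid(strategies = "localT2", p_gmin = c(10, 25),
                          p_gmax = c(50, 75), p_local = c(50, 75))
    cfg <- cfg[sample(nrow(cfg), 100, TRUE), ]
    sc <- 0.1 * (cfg$algorithm == "tINIT") + stats::rnorm(100, 0, 0.01)
    pi_ <- parameter_importance(cfg, sc)
    row <- pi_[pi_$parameter == "algorithm" & pi_$option == "tINIT", ]
    if (abs(row$coefficient - 0.1) <= 3 * row$std_error) hits <- hits + 1
  }
  expect_gte(hits, 19)  # 3-sigma coverage
})

test_that("parameter_importance handles degenerate designs", {
  cfg <- parameter_grid(strategies = "localT2", p_gmin = c(10, 25),
                        p_gmax = 75, p_local = 50)
  # constant scores: zero coefficients, intercept = the constant
  pi0 <- suppressWarnings(parameter_importance(cfg, rep(0.4, nrow(cfg))))  # perfect fit
  expect_equal(pi0$coefficient[pi0$parameter == "(Intercept)"], 0.4)
  expect_true(all(abs(pi0$coefficient[pi0$parameter != "(Intercept)"]) < 1e-10))
  # single-valued parameters are excluded, others still fit
  expect_false("p_gmax" %in% pi0$parameter)
  # fully constant design errors
  one <- cfg[rep(1, 5), ]
  expect_error(parameter_importance(one, stats::rnorm(5)), "no parameter varies")
})
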