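test_that("sigmoid scaling with a = -2 is tanh(x/2)", {
  set.seed(19)
  x <- stats::runif(1000, -30, 30)
  expect_lt(max(abs(scale_fluxes(x) - tanh(x / 2))), 1e-12)
  expect_equal(scale_fluxes(0), 0)
  expect_equal(scale_fluxes(1e4), 1, tolerance = 1e-12)
  expect_equal(scale_fluxes(-1e4), -1, tolerance = 1e-12)
  # sign preservation, bound, strict monotonicity
  xs <- sort(x)
  s <- scale_fluxes(xs)
  expect_true(all(sign(s) == sign(xs)))
  expect_true(all(abs(s) < 1))
  expect_true(all(diff(s) > 0))
  expect_error(scale_fluxes(x, a = 0), "constant map")
})

test_that("select_flux_features filters variance then ranks by ANOVA", {
  set.seed(4)
  lab <- rep(c("A", "B"), each = 15)
  X <- cbind(matrix(stats::rnorm(30 * 50), 30, 50), const = 5)
  colnames(X) <- c(paste0("f", 1:50), "const")
  X <- cbind(X, planted = stats::rnorm(30) + 3 * (lab == "B"))
  sel <- select_flux_features(X, lab, n_top = 10)
  rk <- attr(sel, "ranking")
  expect_identical(rk$feature[1], "planted")
  expect_false("const" %in% colnames(sel))
  # n_top = everything: only the variance filter acts
  all_feats <- suppressWarnings(select_flux_features(X, lab, n_top = ncol(X)))
  expect_equal(ncol(all_feats), ncol(X) - 1)  # constant column dropped
  expect_warning(select_flux_features(X, lab, n_top = 1000), "survive")
  expect_error(select_flux_features(X, rep("A", 30), n_top = 5),
               "two classes")
})

test_that("planted effects rank first in repeated seeded draws", {
  set.seed(77)
  wins <- 0
  for (i in 1:50) {
    lab <- rep(c("A", "B"), each = 10)
    X <- matrix(stats::rnorm(20 * 51), 20, 51)
    X[, 51] <- stats::rnorm(20) + 3 * (lab == "B")
    colnames(X) <- paste0("f", 1:51)
    sel <- select_flux_features(X, lab, n_top = 5)
    if (attr(sel, "ranking")$feature[1] == "f51") wins <- wins + 1
  }
  expect_gte(wins, 48)
})

test_that("pathway_loading_summary computes normalized mean ratios", {
  L <- matrix(c(2, -1, 0, 0.5), 4, 1,
              dimnames = list(c("r1", "r2", "r3", "r4"), "PC1"))
  pm <- c(r1 = "P1", r2 = "P2", r3 = "P2", r4 = "P3")
  ps <- pathway_loading_summary(L, pm)
  expect_equal(ps["P1", 1], 1)       # pathway of the max-loading flux
  expect_equal(ps["P2", 1], 0.25)    # mean(1/2, 0)
  expect_equal(ps["P3", 1], 0.25)
  # all-zero pathway scores zero; unmapped goes to "unassigned"
  L2 <- matrix(c(1, 0, 0), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  ps2 <- pathway_loading_summary(L2, c(a = "P1", b = "P2"))
  expect_equal(unname(ps2["P2", 1]), 0)
  expect_true("unassigned" %in% rownames(ps2))
  # invariance to rescaling a component
  expect_equal(pathway_loading_summary(L * 13.7, pm), ps)
  # all-zero component is an error
  expect_error(pathway_loading_summary(matrix(0, 2, 1,
    dimnames = list(c("a", "b"), NULL)), c(a = "P", b = "P")), "all-zero")
})

test_that("grouped_kfold never leaks a group across a split", {
  g <- rep(paste0("cl", 1:6), each = 3)
  folds <- grouped_kfold(g, 3, shuffle = FALSE)
  expect_length(folds, 3)
  for (f in folds) {
    expect_length(f$test, 6)  # 2 whole cell lines x 3 rows
    expect_length(intersect(g[f$train], g[f$test]), 0)
  }
  expect_identical(sort(unlist(lapply(folds, `[[`, "test"))),
                   seq_along(g))
  # leave-one-group-out
  loo <- grouped_kfold(g, 6, shuffle = FALSE)
  expect_true(all(vapply(loo, function(f)
    length(unique(g[f$test])) == 1, logical(1))))
  expect_error(grouped_kfold(g, 7), "exceeds")
})

test_that("grouped splits stay leak-free over many random assignments", {
  set.seed(23)
  for (i in 1:300) {
    n <- sample(8:25, 1)
    g <- sample(paste0("cl", 1:sample(3:7, 1)), n, TRUE)
    k <- min(3, length(unique(g)))
    folds <- grouped_kfold(g, k)
    test_all <- sort(unlist(lapply(folds, `[[`, "test")))
    expect_identical(test_all, seq_len(n))
    for (f in folds) {
      expect_length(intersect(g[f$train], g[f$test]), 0)
    }
  }
})
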