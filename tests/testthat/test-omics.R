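test_that("local thresholds are per-transcript quantiles", {
  expr <- rbind(t1 = c(1, 2, 3, 4, 5), t2 = c(4, 4, 4, 4, 4))
  expect_equal(unname(local_thresholds(expr, 50)), c(3, 4))
  expect_equal(unname(local_thresholds(rbind(a = c(0, 10)), 25)), 2.5)
  expect_error(local_thresholds(rbind(a = 1), 50), "at least 2 samples")
  expect_error(local_thresholds(rbind(a = c(-1, 2)), 50), "non-negative")
})

test_that("global threshold is the mean of the local set", {
  expect_equal(global_threshold(c(1, 3)), 2)
  expect_equal(global_threshold(rep(7, 10)), 7)
  set.seed(1)
  v <- stats::runif(100)
  expect_equal(global_threshold(v), sum(v) / 100)
})

test_that("compute_tas hits the documented branch values", {
  ts2 <- structure(list(strategy = "localT2", g_max = 8, g_min = 2,
                        local = c(a = 4)), class = "threshold_set")
  expect_equal(as.numeric(compute_tas(c(a = 8), ts2)), 1)     # x = g_max
  expect_equal(as.numeric(compute_tas(c(a = 16), ts2)), 2)    # 1 + log2(2)
  expect_equal(as.numeric(compute_tas(c(a = 2), ts2)), 0)     # x = g_min, low branch
  expect_equal(as.numeric(compute_tas(c(a = 0), ts2)), -10)   # zero floor
  wide <- structure(list(strategy = "localT2", g_max = 100, g_min = 2,
                         local = c(a = 4)), class = "threshold_set")
  expect_equal(as.numeric(compute_tas(c(a = 16), wide)), 1)   # log2(4)=2 clipped
  tg <- structure(list(strategy = "global", g_max = 8),
                  class = "threshold_set")
  expect_equal(as.numeric(compute_tas(c(a = 8), tg)), 0)
  t1 <- structure(list(strategy = "localT1", g_max = 8, local = c(a = 2)),
                  class = "threshold_set")
  expect_equal(as.numeric(compute_tas(c(a = 8), t1)), 0)      # boundary: global branch
  expect_equal(as.numeric(compute_tas(c(a = 4), t1)), 1)      # log2(4/2)
})

test_that("TAS ranges conform per strategy over random threshold sets", {
  set.seed(11)
  for (i in 1:40) {
    gmin <- stats::runif(1, 0.5, 5)
    gmax <- gmin + stats::runif(1, 0.5, 5)
    l <- stats::runif(1, 0.1, 8)
    tt <- structure(list(strategy = "localT2", g_max = gmax, g_min = gmin,
                         local = c(a = l)), class = "threshold_set")
    xs <- sort(c(gmin, gmax, stats::runif(150, 0, 3 * gmax)))
    v <- vapply(xs, function(z) as.numeric(compute_tas(c(a = z), tt)), 0)
    mid <- xs > gmin & xs < gmax
    expect_true(all(v[mid] >= -1 - 1e-12 & v[mid] <= 1 + 1e-12))
    expect_true(all(v[xs >= gmax] >= 1 - 1e-12))
    expect_true(all(v[xs <= gmin] <= 1e-12))
    t1 <- structure(list(strategy = "localT1", g_max = gmax, local = c(a = l)),
                    class = "threshold_set")
    v1 <- vapply(xs, function(z) as.numeric(compute_tas(c(a = z), t1)), 0)
    expect_true(all(v1[xs >= gmax] >= -1e-12))
    # within-branch monotonicity (the branch switch may jump by design)
    for (br in list(xs <= gmin, mid, xs >= gmax)) {
      if (sum(br) > 1) expect_true(all(diff(v[br]) >= -1e-12))
    }
    # the global strategy is fully monotone
    tg <- structure(list(strategy = "global", g_max = gmax),
                    class = "threshold_set")
    vg <- vapply(xs, function(z) as.numeric(compute_tas(c(a = z), tg)), 0)
    expect_true(all(diff(vg) >= -1e-12))
  }
})

test_that("degenerate thresholds make localT2's high branch global + 1", {
  g <- 5
  t2 <- structure(list(strategy = "localT2", g_max = g, g_min = g,
                       local = c(a = g)), class = "threshold_set")
  tg <- structure(list(strategy = "global", g_max = g),
                  class = "threshold_set")
  for (x in c(5, 7, 20, 100)) {
    expect_equal(as.numeric(compute_tas(c(a = x), t2)),
                 as.numeric(compute_tas(c(a = x), tg)) + 1)
  }
})

test_that("threshold_set wires strategy-specific requirements", {
  X <- synth_expression(100, 8, seed = 3)
  ts <- threshold_set(X, "localT2", p_gmax = 75, p_gmin = 25, p_local = 50)
  expect_lte(ts$g_min, ts$g_max)
  expect_length(ts$local, nrow(X))
  expect_error(threshold_set(X, "localT2", p_gmax = 25, p_gmin = 90),
               "p_gmin < p_gmax")
  tg <- threshold_set(X, "global", p_gmax = 50)
  expect_null(tg$local)
  tm <- compute_tas_matrix(X, ts)
  expect_identical(dim(tm), dim(X))
})
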