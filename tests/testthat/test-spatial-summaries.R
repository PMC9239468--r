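test_that("intensities are counts over area, pooled over the requested pair", {
  set.seed(3)
  p <- mpp(runif(50, 0, 100), runif(50, 0, 100), rep("a", 50),
           window = obs_window(0, 100, 0, 100))
  expect_equal(unname(estimate_intensities(p)["a"]), 0.005)

  q <- mpp(c(runif(30), runif(20)) * 50, runif(50) * 20,
           rep(c("a", "b"), c(30, 20)), window = obs_window(0, 50, 0, 20))
  lam <- estimate_intensities(q, pair = c("a", "b"))
  expect_equal(unname(lam["a"]), 0.03)
  expect_equal(unname(lam["b"]), 0.02)
  expect_equal(unname(lam["lambda_dot"]), 0.05)
})

test_that("K and cross-K match the direct pair-enumeration oracle on toy4", {
  p <- toy4()
  g <- r_grid(0.8, 17)   # includes r = 0.15 and r = 0.6 exactly? 0.8/16 = 0.05
  k <- k_function(p, g)
  expect_equal(k$values[1], 0)   # r = 0 exactly
  for (r in c(0.15, 0.6, 0.75)) {
    idx <- which(abs(as.numeric(g) - r) < 1e-12)
    expect_equal(k$values[idx], oracle_k(p, r), tolerance = 1e-12)
  }
  kc <- k_function(p, g, types = c("t1", "t2"))
  for (r in c(0.6, 0.75)) {
    idx <- which(abs(as.numeric(g) - r) < 1e-12)
    expect_equal(kc$values[idx], oracle_cross_k(p, "t1", "t2", r),
                 tolerance = 1e-12)
  }
})

test_that("estimators match the O(n^2) oracle on random patterns", {
  grid <- r_grid(0.3, 7)
  rs <- as.numeric(grid)[-1]
  for (seed in 1:6) {
    p <- random_test_pattern(n = 10 + 5 * seed, seed = seed)
    h <- 0.08
    kv <- k_function(p, grid)$values
    gv <- pair_correlation(p, grid, bandwidth = h)$values
    cg <- pair_correlation(p, grid, types = c("t1", "t2"), bandwidth = h)$values
    mc <- mark_connection(p, "t1", "t2", grid, bandwidth = h)$values
    mo <- morans_i_profile(p, "t1", "t2", "marker", grid,
                           band_halfwidth = 0.04)$values
    for (t in seq_along(rs)) {
      r <- rs[t]
      expect_equal(kv[t + 1], oracle_k(p, r), tolerance = 1e-10)
      expect_equal(gv[t + 1], oracle_g(p, r, h), tolerance = 1e-10)
      expect_equal(cg[t + 1], oracle_cross_g(p, "t1", "t2", r, h),
                   tolerance = 1e-10)
      om <- oracle_mcf(p, "t1", "t2", r, h)
      if (is.finite(om)) expect_equal(mc[t + 1], om, tolerance = 1e-10)
      expect_equal(mo[t + 1], oracle_moran(p, "t1", "t2", "marker", r, 0.04),
                   tolerance = 1e-10)
    }
  }
})

test_that("K is near pi r^2 and g near 1 under complete spatial randomness", {
  set.seed(101)
  n <- 500
  p <- mpp(runif(n), runif(n), rep("a", n), window = obs_window(0, 1, 0, 1))
  grid <- r_grid(0.2, 21)
  k <- k_function(p, grid)
  # Monte Carlo envelope from 99 CSR simulations of the same size
  sims <- replicate(99, {
    q <- mpp(runif(n), runif(n), rep("a", n), window = obs_window(0, 1, 0, 1))
    k_function(q, grid)$values
  })
  lo <- apply(sims, 1, min); hi <- apply(sims, 1, max)
  inside <- k$values >= lo & k$values <= hi
  expect_gt(mean(inside[-1]), 0.9)
  expect_lt(max(abs(k$values - pi * as.numeric(grid)^2)), 0.02)

  set.seed(202)
  n2 <- 1000
  p2 <- mpp(runif(n2), runif(n2), rep("a", n2), window = obs_window(0, 1, 0, 1))
  g2 <- pair_correlation(p2, r_grid(0.3, 31))
  mid <- 11:20
  expect_true(all(g2$values[mid] > 0.85 & g2$values[mid] < 1.15))
})

test_that("clustered patterns show g > 1 at short range", {
  set.seed(7)
  cfg <- pattern_sim_config(window = obs_window(0, 500, 0, 500),
                            process = "two_type_thomas", kappa = 1e-4,
                            sigma = 10, mu_off = 15)
  p <- simulate_pattern(cfg)
  g <- pair_correlation(p, r_grid(50, 26))
  expect_gt(mean(g$values[2:6]), 1.5)  # below the cluster scale
})

test_that("normalised mcf sits at 1 under random labeling and below 1 for separated clusters", {
  set.seed(11)
  n <- 2000
  lab <- sample(c("a", "b"), n, replace = TRUE)
  p <- mpp(runif(n), runif(n), lab, window = obs_window(0, 1, 0, 1))
  m <- mark_connection(p, "a", "b", r_grid(0.25, 26))
  mid <- 9:18
  expect_true(all(m$values[mid] > 0.9 & m$values[mid] < 1.1))

  # two far-separated single-type clusters
  set.seed(12)
  xa <- rnorm(60, 0.2, 0.03); ya <- rnorm(60, 0.2, 0.03)
  xb <- rnorm(60, 0.8, 0.03); yb <- rnorm(60, 0.8, 0.03)
  q <- mpp(pmin(pmax(c(xa, xb), 0), 1), pmin(pmax(c(ya, yb), 0), 1),
           rep(c("a", "b"), each = 60), window = obs_window(0, 1, 0, 1))
  mq <- mark_connection(q, "a", "b", r_grid(0.2, 21), bandwidth = 0.03)
  expect_true(all(mq$values[2:10] < 1, na.rm = TRUE))
})

test_that("the literal mcf form has baseline lambda_i lambda_j / lambda_dot", {
  set.seed(13)
  n <- 2000
  lab <- sample(c("a", "b"), n, replace = TRUE, prob = c(0.6, 0.4))
  p <- mpp(runif(n), runif(n), lab, window = obs_window(0, 1, 0, 1))
  raw <- mark_connection(p, "a", "b", r_grid(0.25, 26), normalised = FALSE)
  lam <- estimate_intensities(p, pair = c("a", "b"))
  base <- lam["a"] * lam["b"] / lam["lambda_dot"]
  mid <- 9:18
  expect_true(all(abs(raw$values[mid] / base - 1) < 0.15))
})

test_that("normalised mcf is symmetric in the type pair and rotation invariant", {
  p <- random_test_pattern(40, seed = 21)
  g <- r_grid(0.3, 11)
  m12 <- mark_connection(p, "t1", "t2", g, bandwidth = 0.08)$values
  m21 <- mark_connection(p, "t2", "t1", g, bandwidth = 0.08)$values
  expect_equal(m12, m21, tolerance = 1e-14)

  # rotate by 90 degrees about the center of the square window
  rot <- mpp(0.5 - (p$y - 0.5), 0.5 + (p$x - 0.5), as.character(p$type),
             marks = p$marks, window = p$window, type_levels = levels(p$type))
  for (fn in list(
    function(q) k_function(q, g)$values,
    function(q) pair_correlation(q, g, bandwidth = 0.08)$values,
    function(q) mark_connection(q, "t1", "t2", g, bandwidth = 0.08)$values,
    function(q) morans_i_profile(q, "t1", "t2", "marker", g)$values)) {
    expect_equal(fn(rot), fn(p), tolerance = 1e-12)
  }
})

test_that("Moran's I profile reproduces the hand-worked two-pair example", {
  p <- mpp(c(0, 0, 0.1, 0.1), c(0, 1, 0, 1), c("a", "a", "b", "b"),
           marks = data.frame(m = c(1, 3, 2, 4)),
           window = obs_window(-0.5, 1.5, -0.5, 1.5))
  # band of half-width 0.06 around r = 0.1 captures exactly the two
  # horizontal pairs (1-2 and 3-4); numerator 2, denominator 5
  mi <- morans_i_profile(p, "a", "b", "m", r_grid(1.2, 25),
                         band_halfwidth = 0.06)
  idx <- which(abs(mi$r - 0.1) < 1e-9)
  expect_equal(mi$values[idx], 0.4, tolerance = 1e-15)
  expect_equal(mi$meta$pair_counts[idx], 2L)
  # a band with no cross pairs gives 0 with count 0
  idx0 <- which(abs(mi$r - 0.5) < 1e-9)
  expect_equal(mi$values[idx0], 0)
  expect_equal(mi$meta$pair_counts[idx0], 0L)
})

test_that("degenerate marks give a flagged NaN Moran curve", {
  p <- mpp(c(0, 0, 0.1, 0.1), c(0, 1, 0, 1), c("a", "a", "b", "b"),
           marks = data.frame(m = rep(2, 4)),
           window = obs_window(-0.5, 1.5, -0.5, 1.5))
  mi <- morans_i_profile(p, "a", "b", "m", r_grid(1, 11))
  expect_true(mi$meta$degenerate)
  expect_true(all(is.nan(mi$values)))
})

test_that("the common reference grid caps at a quarter of the densest image's short side", {
  set.seed(31)
  p1 <- mpp(runif(200, 0, 400), runif(200, 0, 2000), rep("a", 200),
            window = obs_window(0, 400, 0, 2000))
  p2 <- mpp(runif(50, 0, 1000), runif(50, 0, 1000), rep("a", 50),
            window = obs_window(0, 1000, 0, 1000))
  g <- common_reference_grid(list(p1, p2), n_points = 100)
  expect_equal(max(g), 100)                 # 400 / 4
  expect_equal(attr(g, "spacing"), 100 / 99)
  g1 <- common_reference_grid(list(p2), n_points = 50)
  expect_equal(max(g1), 250)
})

test_that("curves_to_matrix interpolates linearly and fills the leading NaN region", {
  g_target <- r_grid(1, 11)
  mk_curve <- function(r, v) structure(list(r = r, values = v, kind = "mcf",
                                            type_pair = NULL, mark = NULL,
                                            meta = list()),
                                       class = "summary_curve")
  # identity on the same grid
  v <- sin(as.numeric(g_target))
  m1 <- curves_to_matrix(list(s1 = mk_curve(as.numeric(g_target), v)), g_target)
  expect_equal(m1[1, ], v)
  # finer grid passes through the knots
  rf <- seq(0, 1, length.out = 21)
  m2 <- curves_to_matrix(list(s1 = mk_curve(rf, rf^2)), g_target)
  expect_equal(m2[1, ], as.numeric(g_target)^2, tolerance = 1e-12)
  # piecewise-linear hand check + leading NaN fill
  cv <- mk_curve(c(0, 0.5, 1), c(NaN, 2, 4))
  m3 <- curves_to_matrix(list(s1 = cv), g_target)
  expect_equal(unname(m3[1, 1]), 2)            # nearest defined value
  expect_equal(unname(m3[1, 8]), 2 + (0.7 - 0.5) / 0.5 * 2)
  # failure to cover the grid names the subject
  short <- mk_curve(c(0, 0.4), c(1, 1))
  expect_error(curves_to_matrix(list(bob = short), g_target), "bob")
})
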