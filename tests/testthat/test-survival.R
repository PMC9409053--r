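test_that("surviving_fraction arithmetic, flags and errors", {
  expect_equal(surviving_fraction(500, 1000, 0.5), 1.0)
  expect_equal(surviving_fraction(50, 1000, 0.5), 0.1)
  sf0 <- surviving_fraction(0, 1000, 0.5)
  expect_equal(as.numeric(sf0), 0)
  expect_identical(attr(sf0, "flag"), "zero")
  sf_hi <- surviving_fraction(700, 1000, 0.5)
  expect_identical(attr(sf_hi, "flag"), "gt1")
  expect_error(surviving_fraction(10, 1000, 0), "plating_efficiency")
})

test_that("noiseless curves are recovered exactly", {
  d_lin <- data.frame(dose_Gy = 0:5, sf = exp(-0.3 * (0:5)))
  f_lin <- fit_survival(d_lin, "linear")
  expect_equal(f_lin$alpha, 0.3, tolerance = 1e-8)
  expect_identical(f_lin$beta, 0)

  D <- c(0, 0.5, 1, 2, 3, 5)
  d_lq <- data.frame(dose_Gy = D, sf = exp(-0.1 * D - 0.02 * D^2))
  f_lq <- fit_survival(d_lq, "linear_quadratic")
  expect_equal(f_lq$alpha, 0.1, tolerance = 1e-6)
  expect_equal(f_lq$beta, 0.02, tolerance = 1e-6)
})

test_that("dose cutoff and zero-SF points are handled with bookkeeping", {
  D <- c(0.25, 0.5, 1, 2, 5)
  d <- data.frame(dose_Gy = D, sf = exp(-0.5 * D))
  d$sf[5] <- 0
  expect_warning(f <- fit_survival(d, "linear"), "zero-survival")
  expect_equal(f$n_points_used, 4L)
  f2 <- suppressWarnings(fit_survival(d, "linear", dose_cutoff = 1))
  expect_equal(f2$n_points_used, 3L)
  expect_equal(f2$n_points_total, 5L)
  expect_equal(f2$alpha, 0.5, tolerance = 1e-8)
  expect_error(fit_survival(d[1:2, ], "linear_quadratic"), "insufficient")
})

test_that("fit is invariant to row order and to half-weight duplication", {
  set.seed(3)
  D <- c(0.5, 1, 2, 3, 4)
  d <- data.frame(dose_Gy = D, sf = exp(-0.4 * D - 0.01 * D^2 + rnorm(5, 0, 0.05)))
  f1 <- fit_survival(d, "linear_quadratic")
  f2 <- fit_survival(d[sample(5), ], "linear_quadratic")
  expect_equal(f1$alpha, f2$alpha, tolerance = 1e-12)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-12)
  # duplicating a point with half weight leaves the estimate unchanged
  d3 <- rbind(d, d[3, ])
  w3 <- c(1, 1, 0.5, 1, 1, 0.5)
  f3 <- fit_survival(d3, "linear_quadratic", weights = w3)
  expect_equal(f3$alpha, f1$alpha, tolerance = 1e-12)
  expect_equal(f3$beta, f1$beta, tolerance = 1e-12)
})

test_that("binomial colony noise: estimate is deterministic and near truth", {
  # determinism and a wide sanity band for a single seed; the 95% CI
  # coverage proper is established over 100 replicates in the end-to-end
  # suite
  doses <- c(0, 0.25, 0.5, 1, 1.5, 2, 3, 4)
  df <- generate_colony_assay(0.8, 0, doses, 1000, 0.6, 3, seed = 77)
  prep <- prepare_survival_data(df)
  fit <- fit_survival(prep$data, "linear", weights = prep$weights,
                      shared_sd = prep$shared_sd)
  se <- sqrt(fit$covariance[1, 1])
  expect_gt(se, 0)
  expect_lt(abs(fit$alpha - 0.8), 4 * se)
  # identical generator spec reproduces the identical fit
  df2 <- generate_colony_assay(0.8, 0, doses, 1000, 0.6, 3, seed = 77)
  prep2 <- prepare_survival_data(df2)
  fit2 <- fit_survival(prep2$data, "linear", weights = prep2$weights,
                       shared_sd = prep2$shared_sd)
  expect_identical(fit$alpha, fit2$alpha)
})

test_that("iso-effect doses match closed forms and a root-finder oracle", {
  f_lin <- fit_survival(data.frame(dose_Gy = 0:4, sf = exp(-0.2303 * (0:4))),
                        "linear")
  expect_equal(dose_at_survival(f_lin, 0.10), -log(0.10) / 0.2303,
               tolerance = 1e-8)
  D <- c(0, 1, 2, 4, 6, 8)
  f_lq <- fit_survival(data.frame(dose_Gy = D, sf = exp(-0.1 * D - 0.02 * D^2)),
                       "linear_quadratic")
  d10 <- dose_at_survival(f_lq, 0.10)
  oracle <- stats::uniroot(function(x) exp(-0.1 * x - 0.02 * x^2) - 0.10,
                           c(0.1, 50), tol = 1e-12)$root
  expect_equal(d10, oracle, tolerance = 1e-8)
  expect_equal(oracle, 8.517, tolerance = 1e-3)
  expect_equal(dose_at_survival(f_lq, 1), 0)
  # strictly decreasing in level; beta -> 0 converges to the linear form
  lv <- c(0.8, 0.5, 0.2, 0.1, 0.01)
  ds <- vapply(lv, function(l) dose_at_survival(f_lq, l), numeric(1))
  expect_true(all(diff(ds) > 0))  # lower survival needs more dose
  f_small_b <- f_lq; f_small_b$beta <- 1e-12
  expect_equal(dose_at_survival(f_small_b, 0.1), -log(0.1) / f_lq$alpha,
               tolerance = 1e-6)
  f0 <- f_lq; f0$alpha <- 0; f0$beta <- 0
  expect_error(dose_at_survival(f0, 0.1), "no solution")
})

test_that("RBE at a survival level: identities and closed forms", {
  d <- data.frame(dose_Gy = 0:4, sf = exp(-0.3 * (0:4)))
  f <- fit_survival(d, "linear")
  expect_equal(rbe_at_level(f, f, 0.10)$rbe, 1.0)
  d2 <- data.frame(dose_Gy = 0:4, sf = exp(-0.6 * (0:4)))
  f2 <- fit_survival(d2, "linear")
  expect_equal(rbe_at_level(f, f2, 0.10)$rbe, 2.0, tolerance = 1e-9)
  r12 <- rbe_at_level(f, f2, 0.37)$rbe
  r21 <- rbe_at_level(f2, f, 0.37)$rbe
  expect_equal(r12 * r21, 1.0, tolerance = 1e-12)
})

test_that("noiseless alpha-like vs beta-like pair recovers an RBE of 1.6 within 5%", {
  # reference: linear-quadratic curve; test: linear curve built so that its
  # D10 is exactly D10_ref / 1.6
  D <- c(0, 0.5, 1, 2, 3, 4, 6, 8)
  a_ref <- 0.12; b_ref <- 0.015
  ref <- fit_survival(data.frame(dose_Gy = D, sf = exp(-a_ref * D - b_ref * D^2)),
                      "linear_quadratic")
  d10_ref <- dose_at_survival(ref, 0.10)
  a_test <- -log(0.10) / (d10_ref / 1.6)
  Dt <- c(0, 0.25, 0.5, 1, 1.5, 2, 3)
  tst <- fit_survival(data.frame(dose_Gy = Dt, sf = exp(-a_test * Dt)), "linear")
  r <- rbe_at_level(ref, tst, 0.10)
  expect_lt(abs(r$rbe - 1.6) / 1.6, 0.05)
})

test_that("bootstrap RBE interval covers the generating ratio", {
  set.seed(19)
  D <- c(0.5, 1, 1.5, 2, 3, 4, 5, 6)
  mk <- function(alpha) {
    data.frame(dose_Gy = rep(D, 2),
               sf = exp(-alpha * rep(D, 2) + rnorm(16, 0, 0.08)))
  }
  f_ref <- fit_survival(mk(0.25), "linear")
  f_test <- fit_survival(mk(0.40), "linear")   # true dose ratio 1.6
  r <- rbe_at_level(f_ref, f_test, 0.10, bootstrap = 400, seed = 99)
  expect_true(r$ci[1] <= 1.6 && 1.6 <= r$ci[2])
})

test_that("prepare_survival_data normalises and propagates uncertainty pieces", {
  df <- data.frame(dose_Gy = c(0, 0, 1, 1, 2), colonies = c(300, 310, 150, 0, 40),
                   cells_seeded = 1000)
  prep <- prepare_survival_data(df)
  expect_equal(prep$plating_efficiency, 0.305)
  expect_equal(prep$n_dropped_zero, 1L)
  expect_equal(nrow(prep$data), 2L)
  expect_equal(prep$data$sf[1], (150 / 1000) / 0.305)
  expect_gt(prep$shared_sd, 0)
  expect_error(prepare_survival_data(df[df$dose_Gy > 0, ]), "control")
})
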