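test_that("vst and inverse_vst are mutual inverses, monotone, with the stated zero value", {
  m <- 100
  for (x in c(0, m / 2, m)) {
    expect_equal(inverse_vst(vst(x, m), m), x, tolerance = 1e-9)
  }
  xs <- sort(stats::runif(50, 0, 200))
  ys <- vst(xs, 200)
  expect_true(all(diff(ys) > 0))
  expect_equal(vst(0, 100), log2(1 / 1100), tolerance = 1e-12)
  expect_equal(vst(0, 100), -10.1034, tolerance = 1e-4)
  expect_error(vst(-1, 100), "non-negative")
  expect_error(vst(1, 0), "positive")
})

test_that("the Matern 5/2 kernel evaluates correctly and decays", {
  h <- list(sigma_f = 2, tau = 3)
  expect_equal(matern52(1, 1, h), 4)
  h1 <- list(sigma_f = 1, tau = 2)
  expect_equal(matern52(0, 2, h1), (1 + sqrt(5) + 5 / 3) * exp(-sqrt(5)),
               tolerance = 1e-12)
  expect_equal(matern52(0, 2, h1), 0.52399, tolerance = 1e-4)
  r <- seq(0, 50, by = 0.5)
  v <- matern52(0, r, h1)
  expect_true(all(diff(v) < 0))
  expect_lt(v[length(v)], 1e-10)
  # PSD over a grid
  t <- seq(0, 10, by = 0.7)
  K <- outer(t, t, function(a, b) matern52(a, b, h1))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("the marginal log-likelihood matches closed forms and rejects duplicates", {
  h <- list(sigma_f = sqrt(0.5), tau = 1, sigma_n = sqrt(0.5))
  expect_equal(as.numeric(gp_marginal_loglik(0, 0, h)), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  expect_error(gp_marginal_loglik(c(1, 1), c(0, 0), h), "duplicates")
  expect_no_error(gp_marginal_loglik(c(1, 1), c(0, 0), h,
                                     allow_duplicate_times = TRUE))
  set.seed(5)
  for (i in 1:25) {
    n <- sample(1:5, 1)
    t <- sort(stats::runif(n, 0, 10))
    y <- stats::rnorm(n)
    hy <- list(sigma_f = stats::rexp(1) + 0.2, tau = stats::rexp(1) + 0.3,
               sigma_n = stats::rexp(1) + 0.1)
    K <- outer(t, t, function(a, b) matern52(a, b, hy)) + diag(hy$sigma_n^2, n)
    expect_equal(as.numeric(gp_marginal_loglik(t, y, hy)),
                 mvn_logdens_oracle(y, K), tolerance = 1e-8)
  }
})

test_that("MAP fits are deterministic and symmetric on constant data", {
  t <- seq(0, 9.5, by = 0.5)
  f1 <- fit_gp(t, rep(0, 20))
  f2 <- fit_gp(t, rep(0, 20))
  expect_identical(glance(f1), glance(f2))
  expect_true(all(abs(f1$median) < 1e-6))
  expect_equal(f1$median - f1$ci_low, f1$ci_high - f1$median)
  expect_true(all(f1$ci_low <= f1$median & f1$median <= f1$ci_high))
})

test_that("confidence band ordering survives the monotone back-transform", {
  t <- seq(0, 9.5, by = 0.5)
  x <- 100 * exp(-t / 3)
  m <- max(x)
  f <- fit_gp(t, vst(x, m), vst_params = list(m = m, alpha = 1, beta = 1000))
  expect_true(all(f$ci_low <= f$median & f$median <= f$ci_high))
  expect_true(all(f$ci_low >= -1))  # domain bound of the inverse transform
  td <- tidy(f)
  expect_named(td, c("time", "median", "ci_low", "ci_high"))
})

test_that("direction classification follows the average of the median difference", {
  t <- seq(0, 9.5, by = 0.5)
  base <- fit_gp(t, sin(t / 3))
  up <- base; up$median <- base$median + 1
  expect_equal(classify_direction(base, up), "increased")
  expect_equal(classify_direction(base, base), "decreased")  # tie rule
  mixed <- base
  mixed$median <- base$median + c(rep(0.5, 5), rep(-1, 15))  # net negative
  expect_equal(classify_direction(base, mixed), "decreased")
  other <- fit_gp(seq(0, 5, by = 0.5), sin(seq(0, 5, by = 0.5)))
  expect_error(classify_direction(base, other), "grid")
})

test_that("the LR statistic is the stated combination and is label-symmetric", {
  t <- seq(0, 9.5, by = 0.5)
  set.seed(8)
  uic <- 100 * exp(-t / 3) * exp(stats::rnorm(20, 0, 0.1))
  mo <- pmax(100 * exp(-t / 3), 25) * exp(stats::rnorm(20, 0, 0.1))
  r <- lr_test("g", t, uic, mo)
  expect_equal(r$LR, r$L_U + r$L_M - r$L_UM)
  flipped <- lr_test("g", t, mo, uic)
  expect_equal(flipped$LR, r$LR, tolerance = 1e-6)
  expect_equal(r$direction, "increased")
  expect_equal(flipped$direction, "decreased")
})

test_that("null threshold is a deterministic quantile with the stated boundary", {
  thr1 <- null_lr_threshold(n_sim = 100, rate = 1, rng_seed = 99, n_restarts = 2)
  lrs <- attr(thr1, "null_lr")
  expect_equal(as.numeric(thr1), min(lrs))
  thr2 <- null_lr_threshold(n_sim = 100, rate = 1, rng_seed = 99, n_restarts = 2)
  expect_equal(as.numeric(thr1), as.numeric(thr2))
  expect_error(null_lr_threshold(n_sim = 50), "at least 100")
})
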