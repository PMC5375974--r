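test_that("noise-free trajectories are recovered exactly with vanishing G", {
  d <- simulate_mmta(n_officers = 3, n_windows = 120,
                     beta = c(0.3, 0.5, 0, 0), sd_u0 = 0, sd_u1 = 0,
                     sigma = 0, seed = 1)
  d$y <- 0.3 + 0.5 * d$time  # exact, no residual at all
  fit <- suppressWarnings(suppressMessages(
    fit_mmta(y ~ time, d, random = ~ 1 + time)))
  expect_equal(unname(coef(fit)), c(0.3, 0.5), tolerance = 1e-6)
  expect_lt(max(abs(fit$G)), 1e-6)
  expect_equal(fit$method, "REML")
  expect_equal(fit$df_method, "satterthwaite")
})

test_that("without random effects the fit reduces to closed-form OLS", {
  d <- simulate_mmta(n_officers = 2, n_windows = 180, seed = 2)
  fit <- fit_mmta(y ~ time * intx, d, random = NULL)
  X <- cbind(1, d$time, d$intx, d$time * d$intx)
  beta_ols <- solve(crossprod(X), crossprod(X, d$y))
  expect_equal(unname(coef(fit)), as.numeric(beta_ols), tolerance = 1e-10)
  expect_equal(fit$engine, "lm")
})

test_that("REML and ML fixed effects converge at large n", {
  d <- simulate_mmta(n_officers = 4, n_windows = 12500,
                     beta = c(0.3, 0.05, 0.6, 0.02), sd_u0 = 0.1,
                     sigma = 0.3, seed = 3)
  reml <- suppressMessages(fit_mmta(y ~ time * intx, d, random = ~ 1))
  ml <- suppressMessages(fit_mmta(y ~ time * intx, d, random = ~ 1,
                                  method = "ML"))
  gap <- abs(coef(reml) - coef(ml)) / abs(coef(ml))
  expect_lt(max(gap), 0.01)
})

test_that("parameter estimates are unbiased at a modest simulation scale", {
  est <- matrix(NA_real_, 20, 4)
  for (r in 1:20) {
    d <- simulate_mmta(n_officers = 3, n_windows = 360, seed = 300 + r)
    fit <- suppressWarnings(suppressMessages(
      fit_mmta(y ~ time * intx, d, random = ~ 1)))
    est[r, ] <- unname(coef(fit))
  }
  bias <- colMeans(est) - c(0.3, 0, 0.6, 0)
  expect_lt(abs(bias[1]), 0.08)
  expect_lt(abs(bias[3]), 0.03)
})

test_that("the small-sample df correction never rejects more than the z test", {
  # null simulation: no intervention effect; compare rejection counts for
  # the intervention coefficient at alpha = 0.05
  rej_corrected <- 0L
  rej_z <- 0L
  for (r in 1:200) {
    d <- simulate_mmta(n_officers = 3, n_windows = 60,
                       beta = c(0.3, 0, 0, 0), sd_u0 = 0.1, sigma = 0.3,
                       seed = 5000 + r)
    fit <- suppressWarnings(suppressMessages(
      fit_mmta(y ~ time * intx, d, random = ~ 1)))
    ct <- fit$coefficients["intx", ]
    p_t <- 2 * pt(-abs(ct["t"]), ct["df"])
    p_z <- 2 * pnorm(-abs(ct["t"]))
    rej_corrected <- rej_corrected + (p_t < 0.05)
    rej_z <- rej_z + (p_z < 0.05)
    expect_gte(p_t, p_z)  # heavier tail with finite df, per replicate
  }
  expect_lte(rej_corrected, rej_z)
})

test_that("Kenward-Roger degrees of freedom are available on modest samples", {
  d <- simulate_mmta(n_officers = 3, n_windows = 100, seed = 6)
  kr <- suppressWarnings(suppressMessages(
    fit_mmta(y ~ time * intx, d, random = ~ 1, df = "kenward-roger")))
  expect_equal(kr$df_method, "kenward-roger")
  expect_true(all(is.finite(kr$coefficients[, "df"])))
  expect_true(all(kr$coefficients[, "df"] > 0))
})

test_that("AR(1) errors are estimated and preferred when truly present", {
  wins <- 0L
  n_rep <- 15L
  for (r in seq_len(n_rep)) {
    d <- simulate_mmta(n_officers = 2, n_windows = 240, rho = 0.5,
                       seed = 700 + r)
    fa <- suppressWarnings(suppressMessages(
      fit_mmta(y ~ time * intx, d, random = ~ 1, error = "ar1",
               method = "ML")))
    fi <- suppressWarnings(suppressMessages(
      fit_mmta(y ~ time * intx, d, random = ~ 1, method = "ML")))
    cmp <- compare_models(independent = fi, ar1 = fa)
    wins <- wins + (cmp$table$model[1] == "ar1")
    if (r == 1) {
      expect_equal(unname(fa$corr), 0.5, tolerance = 0.15)
      expect_false(is.null(cmp$lrt))
      expect_equal(cmp$lrt$df, 1L)
    }
  }
  expect_gte(wins / n_rep, 0.8)
})

test_that("a pure-noise covariate does not improve BIC on average", {
  dbic <- numeric(15)
  for (r in 1:15) {
    d <- simulate_mmta(n_officers = 3, n_windows = 120, seed = 900 + r)
    d$junk <- rnorm(nrow(d))
    base <- suppressWarnings(suppressMessages(
      fit_mmta(y ~ time * intx, d, random = ~ 1, method = "ML")))
    full <- suppressWarnings(suppressMessages(
      fit_mmta(y ~ time * intx + junk, d, random = ~ 1, method = "ML")))
    dbic[r] <- full$BIC - base$BIC
  }
  expect_gt(mean(dbic), 0)
})

test_that("model comparison demands ML and identical data", {
  d <- simulate_mmta(n_officers = 2, n_windows = 120, seed = 10)
  ml <- suppressWarnings(suppressMessages(
    fit_mmta(y ~ time, d, random = ~ 1, method = "ML")))
  reml <- suppressWarnings(suppressMessages(
    fit_mmta(y ~ time, d, random = ~ 1)))
  expect_error(compare_models(ml, reml), "ML")

  cmp <- compare_models(a = ml, b = ml)
  expect_equal(cmp$table$rank, c(1L, 1L))
  expect_equal(cmp$table$dAIC, c(0, 0))
})

test_that("toeplitz-banded errors fit and report their band parameters", {
  d <- simulate_mmta(n_officers = 2, n_windows = 150, rho = 0.4, seed = 11)
  ft <- suppressWarnings(suppressMessages(
    fit_mmta(y ~ time * intx, d, random = ~ 1, error = "toeplitz",
             bands = 2, method = "ML")))
  expect_length(ft$corr, 2L)
  expect_equal(ft$df_method, "residual")
})

test_that("phase contrasts report descriptives and a degenerate-safe test", {
  d <- data.frame(officer_id = rep(c("a", "b"), each = 20),
                  y = rep(1.5, 40),
                  lab = rep(c("low", "high"), 20))
  pc <- suppressWarnings(phase_contrast(d, "y", "lab", ref = "low"))
  expect_equal(pc$contrast[1, "estimate"], 0)
  expect_equal(pc$contrast[1, "p"], 1)
  expect_equal(pc$descriptives$mean, c(1.5, 1.5))

  set.seed(12)
  d2 <- data.frame(officer_id = "a",
                   y = c(rnorm(30, 1), rnorm(30, 3)),
                   lab = rep(c("low", "high"), each = 30))
  pc2 <- phase_contrast(d2, "y", "lab", ref = "low")
  expect_equal(pc2$engine, "lm")  # single officer: no random intercept
  expect_equal(pc2$contrast["high", "estimate"], 2, tolerance = 0.3)
  expect_lt(pc2$contrast["high", "p"], 1e-6)

  expect_error(phase_contrast(d2[d2$lab == "low", ], "y", "lab"),
               "single-class")
  d3 <- d2[c(1:30, 31), ]
  expect_error(phase_contrast(d3, "y", "lab"), "at least 2 windows")
})

test_that("per-officer BLUPs track the simulated random intercepts", {
  d <- simulate_mmta(n_officers = 6, n_windows = 600, sd_u0 = 0.3,
                     sigma = 0.2, seed = 13)
  fit <- suppressMessages(fit_mmta(y ~ time * intx, d, random = ~ 1))
  b <- blup(fit)
  expect_equal(nrow(b), 6L)
  # recompute the true u0 draws from the generator's seed path
  truth <- vapply(split(d$y - (0.3 + 0.6 * d$intx), d$officer_id), mean, 0)
  expect_gt(cor(b[[1]], truth[rownames(b)]), 0.95)
})
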