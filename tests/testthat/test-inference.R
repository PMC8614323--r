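simulate_one_factor <- function(a, nper, mu = 2, sd_b = 0.6, sd_e = 0.9,
                                beta = 0.5, seed = 1) {
  set.seed(seed)
  g <- factor(rep(seq_len(a), each = nper))
  x <- rnorm(a * nper)
  y <- mu + beta * x + rnorm(a, 0, sd_b)[g] + rnorm(a * nper, 0, sd_e)
  data.frame(y = y, x = x, g = g)
}

test_that("REML matches the closed-form ANOVA estimators when balanced", {
  a <- 30L; nper <- 8L
  d <- simulate_one_factor(a, nper, beta = 0, seed = 3)
  fit <- fit_lmm(d, "y", "x", "g")
  gm <- tapply(d$y, d$g, mean)
  msb <- nper * stats::var(gm)
  msw <- sum((d$y - gm[d$g])^2) / (a * (nper - 1L))
  # intercept-and-group-only ANOVA oracle; the x column is centered noise,
  # so the balanced decomposition still applies to high accuracy
  expect_equal(unname(fit$re_sd["g"]), sqrt((msb - msw) / nper),
               tolerance = 0.02)
  expect_equal(fit$residual_sd, sqrt(msw), tolerance = 0.02)
})

test_that("zero-variance random effects collapse the fit onto least squares", {
  d <- simulate_one_factor(20, 6, sd_b = 0, seed = 4)
  fit <- fit_lmm(d, "y", "x", "g")
  expect_lt(unname(fit$re_sd["g"]), 0.05)
  ols <- coef(lm(y ~ x, d))
  expect_equal(fit$coefficients$estimate, unname(ols), tolerance = 1e-2)
  expect_true(fit$singular || unname(fit$re_sd["g"]) < 0.05)
})

test_that("crossed random intercepts are supported and recovered", {
  set.seed(9)
  f1 <- factor(sample(1:40, 600, TRUE))
  f2 <- factor(sample(1:12, 600, TRUE))
  x <- rnorm(600)
  y <- 1 + 0.8 * x + rnorm(40, 0, 0.7)[f1] + rnorm(12, 0, 0.5)[f2] +
    rnorm(600, 0, 1)
  d <- data.frame(y, x, f1, f2)
  fit <- fit_lmm(d, "y", "x", c("f1", "f2"))
  expect_equal(unname(fit$re_sd[c("f1", "f2")]), c(0.7, 0.5),
               tolerance = 0.35)
  expect_equal(fit$coefficients$estimate[2], 0.8, tolerance = 0.15)
})

test_that("a singular design raises an error naming collinear columns", {
  d <- simulate_one_factor(10, 4, seed = 5)
  d$x2 <- 2 * d$x
  expect_error(fit_lmm(d, "y", c("x", "x2"), "g"), "x2")
})

test_that("the fit is invariant to row permutation", {
  d <- simulate_one_factor(15, 5, seed = 6)
  fit1 <- fit_lmm(d, "y", "x", "g")
  set.seed(1)
  fit2 <- fit_lmm(d[sample(nrow(d)), ], "y", "x", "g")
  expect_equal(fit1$coefficients$estimate, fit2$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(fit1$re_sd, fit2$re_sd, tolerance = 1e-6)
})

test_that("Satterthwaite df respects its balanced-design anchors", {
  a <- 24L; nper <- 6L
  d <- simulate_one_factor(a, nper, seed = 7)
  fit <- fit_lmm(d, "y", "x", "g")
  # grand-mean df in a balanced one-way layout is the between-group df
  df_int <- satterthwaite_df(fit, "(Intercept)")
  expect_equal(as.numeric(df_int), a - 1L, tolerance = 0.05)
  expect_identical(attr(df_int, "method"), "satterthwaite")
  # a unit-level covariate sits near the residual df
  df_x <- satterthwaite_df(fit, "x")
  expect_gt(as.numeric(df_x), a - 1L)
  expect_lt(as.numeric(df_x), a * nper)
  expect_error(satterthwaite_df(fit, "nope"), "unknown term")
})

test_that("Satterthwaite df approaches the residual df as RE variance -> 0", {
  d <- simulate_one_factor(20, 6, sd_b = 0, seed = 8)
  fit <- fit_lmm(d, "y", "x", "g")
  df_x <- as.numeric(satterthwaite_df(fit, "x"))
  expect_gt(df_x, 0.85 * (nrow(d) - 2L))
})

test_that("the Satterthwaite t reference is calibrated on a crossed design", {
  # parametric bootstrap: with the null coefficient simulated at truth, the
  # |t| > t_crit(df_satt) rate should sit near the nominal 5%
  set.seed(10)
  f1 <- factor(rep(1:10, each = 6))
  f2 <- factor(rep(1:6, times = 10))
  x <- rnorm(60)
  gen <- function() {
    1 + 0.5 * x + rnorm(10, 0, 0.5)[f1] + rnorm(6, 0, 0.4)[f2] +
      rnorm(60, 0, 0.8)
  }
  d0 <- data.frame(y = gen(), x = x, f1 = f1, f2 = f2)
  fit0 <- fit_lmm(d0, "y", "x", c("f1", "f2"))
  df0 <- as.numeric(satterthwaite_df(fit0, "x"))
  crit <- qt(0.975, df0)
  hits <- replicate(400, {
    d <- data.frame(y = gen(), x = x, f1 = f1, f2 = f2)
    f <- suppressMessages(fit_lmm(d, "y", "x", c("f1", "f2")))
    tab <- f$coefficients
    abs((tab$estimate[2] - 0.5) / tab$se[2]) > crit
  })
  expect_lt(abs(mean(hits) - 0.05), 0.035)
})

test_that("Nakagawa R2 recovers known variance shares", {
  # sigma_f^2 = 1, sigma_RE^2 = 1, sigma_e^2 = 2 -> (0.25, 0.50)
  set.seed(11)
  a <- 250L; nper <- 16L
  g <- factor(rep(seq_len(a), each = nper))
  x <- rnorm(a * nper)
  y <- 1 * x + rnorm(a)[g] + rnorm(a * nper, 0, sqrt(2))
  fit <- fit_lmm(data.frame(y, x, g), "y", "x", "g")
  r2 <- r2_nakagawa(fit)
  expect_equal(unname(r2["r2_marginal"]), 0.25, tolerance = 0.03)
  expect_equal(unname(r2["r2_conditional"]), 0.50, tolerance = 0.03)
  expect_true(r2["r2_marginal"] <= r2["r2_conditional"])
  expect_true(all(r2 >= 0 & r2 <= 1))
})

test_that("intercept-only models have zero marginal R2", {
  d <- simulate_one_factor(12, 5, beta = 0, seed = 12)
  d$ones <- 0 # no informative fixed effect beyond the intercept
  fit <- fit_lmm(d, "y", "x", "g") # x is pure noise here
  # refit with the intercept only via a zero column is rank-deficient, so
  # check the formula property instead: var_f from a constant predictor
  fit_int <- lmerTest::lmer(y ~ 1 + (1 | g), data = d)
  r2 <- r2_nakagawa(fit_int)
  expect_equal(unname(r2["r2_marginal"]), 0)
  # no random variance -> conditional approaches marginal
  fit_lm <- fit_lmm(simulate_one_factor(60, 12, sd_b = 0, seed = 13),
                    "y", "x", "g")
  r2b <- r2_nakagawa(fit_lm)
  expect_equal(unname(r2b["r2_marginal"]), unname(r2b["r2_conditional"]),
               tolerance = 0.05)
})

test_that("backward elimination prunes only removable interactions", {
  set.seed(14)
  n <- 1200L
  g <- factor(sample(1:60, n, TRUE))
  x <- rnorm(n); w <- rnorm(n); s <- rbinom(n, 1, 0.5)
  # x:s is real, w:s is exactly zero
  y <- 1 + x + 0.5 * w + 0.4 * s + 0.8 * x * s + 0 * w * s +
    rnorm(60, 0, 0.4)[g] + rnorm(n, 0, 1)
  d <- data.frame(y, x.1 = x, w.1 = w, s_m = s,
                  x.1_x_s = x * s, w.1_x_s = w * s, g = g)
  terms <- data.frame(
    term = c("x.1", "w.1", "s_m", "x.1_x_s", "w.1_x_s"),
    interaction = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    family = c("x", "w", "s", "x:s", "w:s"),
    degree = c(1L, 1L, 0L, 1L, 1L)
  )
  res <- backward_eliminate(d, "y", terms, "g")
  expect_true("x.1_x_s" %in% res$terms$term)     # real interaction kept
  expect_false("w.1_x_s" %in% res$terms$term)    # null interaction removed
  expect_true(all(c("x.1", "w.1", "s_m") %in% res$terms$term))
  expect_equal(res$log$removed, "w.1_x_s")
  expect_gt(res$log$p, 0.05)
})

test_that("marginality protects lower-degree terms of a live interaction", {
  set.seed(15)
  n <- 800L
  g <- factor(sample(1:40, n, TRUE))
  x <- rnorm(n); s <- rbinom(n, 1, 0.5)
  # degree-2 interaction is real; degree-1 interaction is null but shielded
  y <- 1 + x + 0.3 * s + 0.9 * (x^2 - 1) * s + rnorm(40, 0, 0.3)[g] +
    rnorm(n)
  d <- data.frame(y, x.1 = x, x.2 = x^2 - 1, s_m = s,
                  x.1_x_s = x * s, x.2_x_s = (x^2 - 1) * s, g = g)
  terms <- data.frame(
    term = c("x.1", "x.2", "s_m", "x.1_x_s", "x.2_x_s"),
    interaction = c(FALSE, FALSE, FALSE, TRUE, TRUE),
    family = c("x", "x", "s", "x:s", "x:s"),
    degree = c(1L, 2L, 0L, 1L, 2L)
  )
  res <- backward_eliminate(d, "y", terms, "g")
  # the degree-2 interaction is significant, so the degree-1 interaction
  # beneath it must never have been tested or removed
  expect_true(all(c("x.1_x_s", "x.2_x_s") %in% res$terms$term))
  expect_equal(nrow(res$log), 0L)
})
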