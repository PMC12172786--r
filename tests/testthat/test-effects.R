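# Effect sizes, coding, run standardization, REML mega-analysis.

test_that("cohens_d_within computes d, t, df and rejects degenerate input", {
  est <- cohens_d_within(c(1, 2, 3))
  expect_equal(est$estimate, 2.0)
  expect_equal(est$t, 2 * sqrt(3), tolerance = 1e-12)
  expect_equal(est$df, 2)
  expect_error(cohens_d_within(rep(1.5, 10)), "zero variance")
  expect_error(cohens_d_within(c(1, 2)), "at least 3")
})

test_that("cohens_d_within is invariant to positive rescaling", {
  set.seed(2)
  x <- rnorm(20, 0.6)
  e1 <- cohens_d_within(x)
  e2 <- cohens_d_within(x * 37.5)
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-12)
  expect_equal(e1$ci_low, e2$ci_low, tolerance = 1e-9)
})

test_that("noncentral-t CI reproduces a published confidence bound", {
  # d = -0.34, n = 95 is printed with 95% CI [-0.55, -0.13]
  d <- -0.34; n <- 95
  ci <- emosig:::nct_ci_d(d * sqrt(n), n - 1, n)
  expect_lt(abs(ci[1] - (-0.55)), 0.01)
  expect_lt(abs(ci[2] - (-0.13)), 0.01)
})

test_that("cohens_d_between pools variances and exposes both statistics", {
  e0 <- cohens_d_between(c(0, 1, 2), c(0, 1, 2))
  expect_equal(e0$estimate, 0)
  expect_equal(e0$t, 0)

  e2 <- cohens_d_between(c(2, 3, 4), c(0, 1, 2))
  expect_equal(e2$estimate, 2.0)

  # pooled t from d: d * sqrt(n1 n2 / (n1 + n2))
  set.seed(3)
  x <- rnorm(62, 0.3); y <- rnorm(33)
  e <- cohens_d_between(x, y)
  expect_equal(e$t_pooled, e$estimate * sqrt(62 * 33 / 95),
               tolerance = 1e-12)
  expect_equal(e$df_pooled, 93)

  # equal sizes and equal variances: Welch and pooled t coincide
  xx <- c(1, 2, 3, 4); yy <- c(2, 3, 4, 5)
  ee <- cohens_d_between(xx, yy)
  expect_equal(ee$t, ee$t_pooled, tolerance = 1e-12)
})

test_that("weighted effect codes satisfy their defining invariants", {
  wc <- weighted_effect_codes(20, 20)
  expect_equal(wc$code_ed, 0.5)
  expect_equal(wc$code_hc, -0.5)

  wc2 <- weighted_effect_codes(62, 33)
  expect_equal(wc2$code_ed, 33 / 95)
  expect_equal(wc2$code_hc, -62 / 95)
  expect_equal(wc2$code_ed - wc2$code_hc, 1)
  expect_equal(62 * wc2$code_ed + 33 * wc2$code_hc, 0, tolerance = 1e-12)
})

test_that("regression on weighted effect codes recovers the raw mean difference", {
  set.seed(13)
  for (rep in 1:5) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    y <- c(rnorm(n1, 1.3), rnorm(n2))
    wc <- weighted_effect_codes(n1, n2)
    x <- rep(c(wc$code_ed, wc$code_hc), c(n1, n2))
    slope <- coef(lm(y ~ x))[["x"]]
    diff <- mean(y[1:n1]) - mean(y[(n1 + 1):(n1 + n2)])
    expect_lt(abs(slope - diff), 1e-10)
  }
})

test_that("run_scale standardizes each run-within-study cell as specified", {
  rec <- data.frame(study = "s1", participant = paste0("p", 1:3),
                    run = "run1", group = NA_character_, signature = "sig",
                    delta = c(1, 2, 3))
  so <- run_scale(rec, "scale_only")
  expect_equal(so$delta, c(1, 2, 3))   # sd is already 1
  cs <- run_scale(rec, "center_and_scale")
  expect_equal(cs$delta, c(-1, 0, 1))

  # after center_and_scale every cell has mean ~ 0
  set.seed(17)
  rec2 <- expand.grid(participant = paste0("p", 1:12),
                      run = c("run1", "run2"), study = c("s1", "s2"),
                      stringsAsFactors = FALSE)
  rec2$group <- rep(c("ED", "HC"), length.out = nrow(rec2))
  rec2$delta <- rnorm(nrow(rec2), 1, 2)
  cs2 <- run_scale(rec2, "center_and_scale")
  cellmeans <- tapply(cs2$delta, paste(cs2$study, cs2$run), mean)
  expect_true(all(abs(cellmeans) < 1e-12))

  # scale_only makes per-run one-sample d values equal when runs differ
  # only by a multiplicative design effect
  base <- rnorm(30, 0.8)
  rec3 <- rbind(
    data.frame(study = "s", participant = paste0("p", 1:30), run = "r1",
               group = NA, signature = "sig", delta = 2 * base),
    data.frame(study = "s", participant = paste0("p", 1:30), run = "r2",
               group = NA, signature = "sig", delta = 4 * base))
  so3 <- run_scale(rec3, "scale_only")
  d1 <- cohens_d_within(so3$delta[so3$run == "r1"])$estimate
  d2 <- cohens_d_within(so3$delta[so3$run == "r2"])$estimate
  expect_equal(d1, d2, tolerance = 1e-12)

  rec$delta <- rep(2, 3)
  expect_error(run_scale(rec, "scale_only"), "zero SD")
})

test_that("REML fit collapses to OLS for singleton clusters", {
  set.seed(23)
  y <- rnorm(40); x <- rnorm(40)
  fit <- fit_random_intercept(y, cbind(intercept = 1, slope = x),
                              cluster = seq_along(y))
  ols <- summary(lm(y ~ x))
  expect_equal(unname(fit$gamma), unname(coef(ols)[, 1]), tolerance = 1e-9)
  expect_equal(unname(fit$se), unname(coef(ols)[, 2]), tolerance = 1e-9)
  expect_true(fit$boundary)
})

test_that("REML fit matches the balanced one-way closed form", {
  set.seed(29)
  k <- 40; m <- 2
  u <- rnorm(k, 0, sqrt(0.4))
  y <- 0.7 + rep(u, each = m) + rnorm(k * m, 0, sqrt(0.6))
  fit <- fit_random_intercept(y, rep(1, k * m), rep(1:k, each = m))
  oracle <- balanced_reml_oracle(y, k, m)
  expect_equal(unname(fit$gamma), oracle$gamma, tolerance = 1e-8)
  expect_equal(fit$var_participant, oracle$var_participant,
               tolerance = 1e-6)
  expect_equal(fit$var_residual, oracle$var_residual, tolerance = 1e-6)
  expect_equal(unname(fit$se), oracle$se, tolerance = 1e-6)
})

test_that("REML fit agrees with lme4 on unbalanced data", {
  skip_if_not_installed("lme4")
  set.seed(31)
  sizes <- sample(1:4, 60, replace = TRUE)
  cl <- rep(seq_along(sizes), sizes)
  x <- rnorm(length(cl))
  y <- 0.4 + 0.8 * x + rep(rnorm(60, 0, 0.6), sizes) + rnorm(length(cl))
  fit <- fit_random_intercept(y, cbind(`(Intercept)` = 1, x = x), cl)
  lf <- lme4::lmer(y ~ x + (1 | cl), REML = TRUE)
  expect_equal(unname(fit$gamma), unname(lme4::fixef(lf)),
               tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(sqrt(diag(as.matrix(vcov(lf))))), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit$var_participant, vc$vcov[1], tolerance = 1e-5)
  expect_equal(fit$var_residual, vc$vcov[2], tolerance = 1e-5)
})

test_that("no variance-ratio grid point beats the REML optimum", {
  set.seed(37)
  k <- 30; m <- 3
  y <- rep(rnorm(k, 0, 0.5), each = m) + rnorm(k * m)
  X <- matrix(1, k * m, 1)
  st <- emosig:::.cluster_stats(y, X, rep(1:k, each = m))
  fit <- fit_random_intercept(y, X, rep(1:k, each = m))
  crit_opt <- emosig:::.reml_crit(st, fit$lambda)
  grid <- exp(seq(-12, 12, length.out = 100))
  crit_grid <- vapply(grid, function(l) emosig:::.reml_crit(st, l),
                      numeric(1))
  expect_true(all(crit_opt <= crit_grid + 1e-8))
})

test_that("mega_within on one single-run study equals the one-sample d", {
  set.seed(41)
  rec <- data.frame(study = "s1", participant = paste0("p", 1:25),
                    run = "run1", group = NA, signature = "sig",
                    delta = rnorm(25, 0.7))
  mw <- mega_within(rec)
  d <- cohens_d_within(rec$delta)$estimate
  expect_equal(unname(mw$gamma[1]), d, tolerance = 1e-9)
})

test_that("mega_within recovers a common simulated condition effect", {
  set.seed(43)
  gammas <- replicate(30, {
    rec <- do.call(rbind, lapply(1:3, function(k)
      data.frame(study = paste0("s", k),
                 participant = paste0("s", k, "p", 1:50), run = "run1",
                 group = NA, signature = "sig",
                 delta = rnorm(50, 1.0, 1))))
    unname(mega_within(rec)$gamma[1])
  })
  expect_equal(mean(gammas), 1.0, tolerance = 0.1)
})

test_that("mega_group is unbiased and covered under a null group effect", {
  set.seed(47)
  res <- t(replicate(100, {
    rec <- do.call(rbind, lapply(1:3, function(k) {
      n1 <- 20; n2 <- 15
      data.frame(study = paste0("s", k),
                 participant = paste0("s", k, "p", 1:(n1 + n2)),
                 run = "run1",
                 group = rep(c("ED", "HC"), c(n1, n2)), signature = "sig",
                 delta = rnorm(n1 + n2, 0.5, 1))
    }))
    fit <- mega_group(rec)
    c(gamma = unname(fit$gamma[1]),
      covers = unname(fit$ci_low[1]) <= 0 & 0 <= unname(fit$ci_high[1]))
  }))
  expect_lt(abs(mean(res[, "gamma"])), 0.1)
  expect_gt(mean(res[, "covers"]), 0.88)
})
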