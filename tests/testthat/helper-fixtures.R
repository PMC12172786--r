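# Shared fixtures and independent oracles used across test files.

# small grid + pattern/beta builders --------------------------------------
tiny_grid <- function(dims = c(3, 1, 1), voxel_size = c(1, 1, 1)) {
  volume_grid(dims, voxel_size)
}

tiny_pattern <- function(w, name = "test") {
  g <- tiny_grid(c(length(w), 1, 1))
  signature_pattern(name, g, array(w, c(length(w), 1, 1)))
}

tiny_beta <- function(b, condition = "negative", participant = "p1",
                      run = "run1", study = "study1") {
  g <- tiny_grid(c(length(b), 1, 1))
  beta_map(study, participant, run, condition, g,
           array(b, c(length(b), 1, 1)))
}

# long-format expression records for metric tests
make_records <- function(neg, neu, participants = seq_along(neg),
                         run = "run1", study = "study1",
                         signature = "sig", group = NA_character_) {
  rbind(
    data.frame(study = study, participant = paste0("p", participants),
               run = run, group = group, signature = signature,
               condition = "negative", expression = neg,
               stringsAsFactors = FALSE),
    data.frame(study = study, participant = paste0("p", participants),
               run = run, group = group, signature = signature,
               condition = "neutral", expression = neu,
               stringsAsFactors = FALSE))
}

# brute-force JZS oracle: fixed-grid trapezoid over delta in
# [-40, 40] * scale at 1e6 points; independent of the quadrature path.
jzs_brute_force <- function(t, n1, n2 = NULL, scale = sqrt(2) / 2,
                            alternative = "two_sided", n_grid = 1e6) {
  if (is.null(n2)) { df <- n1 - 1; n_eff <- n1 }
  else { df <- n1 + n2 - 2; n_eff <- n1 * n2 / (n1 + n2) }
  delta <- seq(-40 * scale, 40 * scale, length.out = n_grid)
  w <- stats::dcauchy(delta, 0, scale)
  w <- switch(alternative,
              two_sided = w,
              greater = ifelse(delta > 0, 2 * w, 0),
              less = ifelse(delta < 0, 2 * w, 0))
  f <- suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(n_eff))) * w
  h <- delta[2] - delta[1]
  num <- sum((f[-1] + f[-n_grid]) / 2) * h
  num / stats::dt(t, df)
}

# closed-form REML for the balanced one-way random-effects model
# (k clusters of m observations, intercept only): ANOVA estimators.
balanced_reml_oracle <- function(y, k, m) {
  ybar_i <- colMeans(matrix(y, m, k))
  grand <- mean(y)
  msb <- m * sum((ybar_i - grand)^2) / (k - 1)
  msw <- sum((y - rep(ybar_i, each = m))^2) / (k * (m - 1))
  list(gamma = grand,
       var_participant = max((msb - msw) / m, 0),
       var_residual = if (msb > msw) msw else
         (sum((y - grand)^2)) / (k * m - 1),
       se = sqrt(msb / (k * m)))
}
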