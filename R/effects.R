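# Single-study effect sizes, run-specific standardization, weighted effect
# coding, and the mega-analytic random-intercept model.

# 95% CI on Cohen's d by inverting the noncentral-t distribution on the
# observed statistic, then converting the noncentrality bounds to d.
nct_ci_d <- function(t, df, n_eff, level = 0.95) {
  a <- (1 - level) / 2
  lim <- abs(t) + 20
  f_lo <- function(nc) suppressWarnings(stats::pt(t, df, ncp = nc)) - (1 - a)
  f_hi <- function(nc) suppressWarnings(stats::pt(t, df, ncp = nc)) - a
  lo <- tryCatch(stats::uniroot(f_lo, c(-lim, lim), tol = 1e-9)$root,
                 error = function(e) -lim)
  hi <- tryCatch(stats::uniroot(f_hi, c(-lim, lim), tol = 1e-9)$root,
                 error = function(e) lim)
  c(lo, hi) / sqrt(n_eff)
}

#' Within-person Cohen's d from difference scores
#'
#' One-sample t-test on reactivity difference scores; d is the mean
#' difference divided by the standard deviation of the differences
#' (denominator n-1), t = d*sqrt(n), df = n-1. The 95% CI on d is obtained
#' by noncentral-t inversion.
#'
#' @param deltas Numeric vector of difference scores (n >= 3, nonzero
#'   variance).
#' @param direction Hypothesized sign, `"greater"`, `"less"` or
#'   `"two_sided"`; carried through to Bayes-factor computation.
#' @return An `effect_estimate` list: `estimate` (d), `ci_low`, `ci_high`,
#'   `t`, `df`, `p` (two-sided), `n`, `direction`.
#' @export
cohens_d_within <- function(deltas, direction = "greater") {
  deltas <- deltas[is.finite(deltas)]
  n <- length(deltas)
  if (n < 3L) stop("need at least 3 difference scores")
  s <- stats::sd(deltas)
  if (s == 0) stop("zero variance in difference scores")
  d <- mean(deltas) / s
  t <- d * sqrt(n)
  df <- n - 1
  ci <- nct_ci_d(t, df, n)
  structure(list(estimate = d, ci_low = ci[1], ci_high = ci[2],
                 t = t, df = df, p = 2 * stats::pt(-abs(t), df),
                 n = n, direction = direction),
            class = "effect_estimate")
}

#' Between-group Cohen's d from reactivity scores
#'
#' d is the difference in group means divided by the pooled standard
#' deviation. The significance test is Welch's unequal-variance t with
#' Welch-Satterthwaite df; a separate pooled-variance statistic
#' t = d*sqrt(n1*n2/(n1+n2)) is exposed (`t_pooled`, `df_pooled`) because
#' default Bayes factors for two-sample designs are defined on it. The CI
#' on d uses the pooled statistic by noncentral-t inversion.
#'
#' @param deltas_ed,deltas_hc Numeric score vectors for the two groups
#'   (each n >= 3). Positive d means the first group (`ed`) scores higher.
#' @param direction Hypothesized sign of the effect.
#' @return An `effect_estimate` list with fields `estimate`, `ci_low`,
#'   `ci_high`, `t` (Welch), `df` (Welch-Satterthwaite), `t_pooled`,
#'   `df_pooled`, `p`, `n1`, `n2`, `direction`.
#' @export
cohens_d_between <- function(deltas_ed, deltas_hc, direction = "greater") {
  x <- deltas_ed[is.finite(deltas_ed)]
  y <- deltas_hc[is.finite(deltas_hc)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 3L || n2 < 3L) stop("need at least 3 scores per group")
  v1 <- stats::var(x); v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) stop("zero variance in both groups")
  sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
  d <- (mean(x) - mean(y)) / sp
  n_eff <- n1 * n2 / (n1 + n2)
  t_pooled <- d * sqrt(n_eff)
  df_pooled <- n1 + n2 - 2
  se_w <- sqrt(v1 / n1 + v2 / n2)
  t_welch <- (mean(x) - mean(y)) / se_w
  df_welch <- se_w^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  ci <- nct_ci_d(t_pooled, df_pooled, n_eff)
  structure(list(estimate = d, ci_low = ci[1], ci_high = ci[2],
                 t = t_welch, df = df_welch,
                 t_pooled = t_pooled, df_pooled = df_pooled,
                 p = 2 * stats::pt(-abs(t_welch), df_welch),
                 n1 = n1, n2 = n2, direction = direction),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("d = %.2f [%.2f, %.2f], t = %.2f, df = %.1f, p = %.3g\n",
              x$estimate, x$ci_low, x$ci_high, x$t, x$df, x$p))
  invisible(x)
}

#' Weighted effect codes for two groups
#'
#' Codes the clinical (`ed`) group as n_hc/(n_ed+n_hc) and the control
#' (`hc`) group as -n_ed/(n_ed+n_hc), so that the codes differ by 1, the
#' size-weighted mean code is zero, and the regression slope on the codes
#' equals the raw difference in group means. With equal sizes this reduces
#' to +/-0.5.
#'
#' @param n_ed,n_hc Group sizes (>= 1).
#' @return List with `code_ed`, `code_hc`, `n_ed`, `n_hc`.
#' @export
weighted_effect_codes <- function(n_ed, n_hc) {
  stopifnot(n_ed >= 1, n_hc >= 1)
  n <- n_ed + n_hc
  list(code_ed = n_hc / n, code_hc = -n_ed / n, n_ed = n_ed, n_hc = n_hc)
}

#' Run-specific scaling / standardization of reactivity scores
#'
#' Puts reactivity scores from different runs and designs on a common
#' Cohen's-d-compatible scale before mega-analysis. `scale_only` divides
#' each score by the standard deviation of its run-within-study cell
#' (within-person analysis: the fixed intercept is then in the d metric).
#' `center_and_scale` additionally subtracts the run mean and divides by
#' the run's pooled-across-groups standard deviation (group analysis: the
#' run intercepts vanish, and the group slope is in the d metric).
#'
#' @param records Reactivity data.frame with columns `study`, `run`,
#'   `delta`, and `group` (required for `center_and_scale` pooling when
#'   groups are present).
#' @param mode `"scale_only"` or `"center_and_scale"`.
#' @return `records` with `delta` replaced by the scaled score and columns
#'   `run_sd` (the divisor) added.
#' @export
run_scale <- function(records, mode = c("scale_only", "center_and_scale")) {
  mode <- match.arg(mode)
  cell <- interaction(records$study, records$run, drop = TRUE)
  out <- records
  out$run_sd <- NA_real_
  for (lv in levels(cell)) {
    i <- which(cell == lv)
    d <- records$delta[i]
    if (length(i) < 3L)
      stop("run cell '", lv, "' has fewer than 3 records")
    if (mode == "scale_only") {
      s <- stats::sd(d)
      if (s == 0) stop("zero SD in run cell '", lv, "'")
      out$delta[i] <- d / s
    } else {
      g <- records$group[i]
      if (length(unique(g[!is.na(g)])) == 2L) {
        # pooled across the two groups, weighted by group df
        sp2 <- 0; dfs <- 0
        for (gg in unique(g)) {
          dg <- d[g == gg]
          sp2 <- sp2 + (length(dg) - 1) * stats::var(dg)
          dfs <- dfs + length(dg) - 1
        }
        s <- sqrt(sp2 / dfs)
      } else {
        s <- stats::sd(d)
      }
      if (s == 0) stop("zero SD in run cell '", lv, "'")
      out$delta[i] <- (d - mean(d)) / s
    }
    out$run_sd[i] <- s
  }
  out
}

#' Mega-analysis of the within-person condition effect
#'
#' Pools run-wise reactivity scores across studies in a two-level
#' random-intercept model on individual participant data: each score,
#' scaled by its run-specific SD, is regressed on a fixed intercept with a
#' random intercept per study-participant. The fixed intercept is the
#' pooled condition effect in the Cohen's d metric. Study-level random
#' terms are intentionally absent (too few studies to estimate them).
#'
#' @param records Reactivity data.frame (`study`, `participant`, `run`,
#'   `delta`, optionally `group`).
#' @return A `mega_fit`; see [fit_random_intercept()].
#' @export
mega_within <- function(records) {
  scaled <- run_scale(records, "scale_only")
  cl <- paste(scaled$study, scaled$participant, sep = "\r")
  fit_random_intercept(scaled$delta, rep(1, nrow(scaled)), cl,
                       intercept = FALSE)
}

#' Mega-analysis of the group effect
#'
#' Reactivity scores are standardized within each run-within-study cell
#' (mean 0, pooled-across-groups SD 1) and regressed, without intercept, on
#' per-run weighted effect codes for group, with a random intercept per
#' study-participant. The slope is the clinical-minus-control difference in
#' the Cohen's d metric; positive values mean the clinical group reacts
#' more strongly.
#'
#' @param records Reactivity data.frame with a two-level `group` column
#'   (`"ED"` first level by convention: positive = ED > HC).
#' @param group_levels Length-2 character vector naming the (clinical,
#'   control) levels.
#' @return A `mega_fit`.
#' @export
mega_group <- function(records, group_levels = c("ED", "HC")) {
  if (!all(records$group %in% group_levels))
    stop("group labels outside ", paste(group_levels, collapse = "/"))
  scaled <- run_scale(records, "center_and_scale")
  cell <- interaction(scaled$study, scaled$run, drop = TRUE)
  code <- numeric(nrow(scaled))
  for (lv in levels(cell)) {
    i <- which(cell == lv)
    n_ed <- sum(scaled$group[i] == group_levels[1])
    n_hc <- sum(scaled$group[i] == group_levels[2])
    wc <- weighted_effect_codes(n_ed, n_hc)
    code[i] <- ifelse(scaled$group[i] == group_levels[1],
                      wc$code_ed, wc$code_hc)
  }
  cl <- paste(scaled$study, scaled$participant, sep = "\r")
  fit_random_intercept(scaled$delta, code, cl, intercept = FALSE)
}
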