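# REML estimation of the Gaussian random-intercept model
#   y = X beta + u[cluster] + e,  u ~ N(0, s2_u), e ~ N(0, s2_e)
# by one-dimensional profile optimization over the variance ratio
# lambda = s2_u / s2_e, with GLS fixed effects at each step.
#
# For a cluster of size n_i, (I + lambda J)^-1 = I - c_i J with
# c_i = lambda / (1 + n_i lambda)  (Sherman-Morrison), so all quadratic
# forms reduce to per-cluster sums, and the whole profile evaluation is
# O(number of clusters).

# per-cluster sufficient statistics for the profile likelihood
.cluster_stats <- function(y, X, cluster) {
  cl <- factor(cluster)
  p <- ncol(X)
  n_i <- as.numeric(table(cl))
  Sy <- rowsum(y, cl)                      # cluster sums of y
  Syy <- sum(y^2)
  SX <- rowsum(X, cl)                      # cluster sums of each column
  SXy_tot <- crossprod(X, y)               # p x 1
  SXX_tot <- crossprod(X)                  # p x p
  list(cl = cl, n_i = n_i, Sy = as.numeric(Sy), Syy = Syy,
       SX = SX, SXy_tot = SXy_tot, SXX_tot = SXX_tot,
       n = length(y), p = p, G = nlevels(cl))
}

# GLS pieces at a given lambda; returns quadratic forms and log-dets
.profile_pieces <- function(st, lambda) {
  c_i <- lambda / (1 + st$n_i * lambda)
  # X' W y = X'y - sum_i c_i (SX_i) (Sy_i),  W = (I + lambda ZZ')^-1
  XtWy <- st$SXy_tot - crossprod(st$SX, c_i * st$Sy)
  XtWX <- st$SXX_tot - crossprod(st$SX, c_i * st$SX)
  yWy <- st$Syy - sum(c_i * st$Sy^2)
  logdet_V <- sum(log1p(st$n_i * lambda))
  list(XtWy = XtWy, XtWX = XtWX, yWy = yWy, logdet_V = logdet_V)
}

# -2 * restricted log-likelihood, profiled over beta and s2_e
.reml_crit <- function(st, lambda) {
  pp <- .profile_pieces(st, lambda)
  beta <- solve(pp$XtWX, pp$XtWy)
  Q <- as.numeric(pp$yWy - crossprod(beta, pp$XtWy))
  npp <- st$n - st$p
  npp * (log(2 * pi * Q / npp) + 1) + pp$logdet_V +
    determinant(pp$XtWX, logarithm = TRUE)$modulus[1]
}

#' Fit a random-intercept model by REML
#'
#' Restricted maximum likelihood for the two-level Gaussian model with a
#' participant-level random intercept, as used by the mega-analyses. The
#' REML criterion is profiled down to the single variance ratio
#' s2_participant / s2_residual and optimized by Brent search on the log
#' ratio in \[-12, 12\]; fixed effects are generalized least squares at the
#' optimum, with Wald 95% confidence intervals. A boundary fit (zero
#' participant variance, where the model collapses to ordinary least
#' squares) is reported via the `boundary` flag, not as an error.
#'
#' @param y Numeric outcome vector (typically run-standardized reactivity).
#' @param x Fixed-effect covariate: a vector (all-ones for the pooled
#'   condition effect, group codes for the group effect) or a matrix of
#'   covariates.
#' @param cluster Participant labels, one per observation.
#' @param intercept Add an intercept column to `x`? (default `FALSE`; the
#'   mega-analytic models carry their design in `x` directly).
#' @return A `mega_fit` list: `gamma` (named fixed-effect estimates), `se`,
#'   `ci_low`, `ci_high`, `var_participant`, `var_residual`, `n_obs`,
#'   `n_participants`, `boundary`, `reml_loglik`, `lambda`.
#' @export
fit_random_intercept <- function(y, x, cluster, intercept = FALSE) {
  y <- as.numeric(y)
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1,
                                       dimnames = list(NULL, "gamma"))
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  if (length(y) != nrow(X) || length(cluster) != length(y))
    stop("y, x and cluster must have matching lengths")
  st <- .cluster_stats(y, X, cluster)
  if (st$G < 2L) stop("need at least 2 clusters")
  if (qr(X)$rank < ncol(X)) stop("collinear fixed-effect design")

  obj <- function(loglam) .reml_crit(st, exp(loglam))
  opt <- stats::optimize(obj, c(-12, 12), tol = 1e-10)
  lambda <- exp(opt$minimum)
  # boundary check: is lambda -> 0 at least as good?
  crit0 <- .reml_crit(st, 0)
  boundary <- crit0 <= opt$objective + 1e-8
  if (boundary) lambda <- 0

  pp <- .profile_pieces(st, lambda)
  beta <- solve(pp$XtWX, pp$XtWy)
  Q <- as.numeric(pp$yWy - crossprod(beta, pp$XtWy))
  s2e <- Q / (st$n - st$p)
  vcov_beta <- s2e * solve(pp$XtWX)
  se <- sqrt(diag(vcov_beta))
  z <- stats::qnorm(0.975)
  gamma <- as.numeric(beta); names(gamma) <- colnames(X)
  structure(list(gamma = gamma, se = se,
                 ci_low = gamma - z * se, ci_high = gamma + z * se,
                 var_participant = lambda * s2e, var_residual = s2e,
                 n_obs = st$n, n_participants = st$G,
                 boundary = boundary,
                 reml_loglik = -0.5 * (if (boundary) crit0 else opt$objective),
                 lambda = lambda),
            class = "mega_fit")
}

#' @export
print.mega_fit <- function(x, ...) {
  cat(sprintf(
    "gamma = %s, var_participant = %.4f, var_residual = %.4f (%d obs, %d participants)%s\n",
    paste(sprintf("%.3f [%.3f, %.3f]", x$gamma, x$ci_low, x$ci_high),
          collapse = "; "),
    x$var_participant, x$var_residual, x$n_obs, x$n_participants,
    if (x$boundary) " [boundary: zero participant variance]" else ""))
  invisible(x)
}

# Restricted log-likelihood on the original scale at given variance
# components; used by the grid property test and the Bayes module.
reml_loglik_at <- function(y, x, cluster, var_participant, var_residual,
                           intercept = FALSE) {
  X <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 1)
  if (intercept) X <- cbind(1, X)
  st <- .cluster_stats(as.numeric(y), X, cluster)
  lambda <- var_participant / var_residual
  pp <- .profile_pieces(st, lambda)
  beta <- solve(pp$XtWX, pp$XtWy)
  Q <- as.numeric(pp$yWy - crossprod(beta, pp$XtWy))
  npp <- st$n - st$p
  -0.5 * (npp * log(2 * pi * var_residual) + pp$logdet_V +
            determinant(pp$XtWX / var_residual, logarithm = TRUE)$modulus[1] +
            Q / var_residual) + 0.5 * st$p * log(2 * pi)
}
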