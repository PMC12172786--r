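# Reactivity scores, run aggregation, reliability, forced-choice accuracy.

#' Reactivity: negative-minus-neutral expression differences
#'
#' For each (study, participant, run, signature) with both conditions
#' scored, the neutral-condition expression is subtracted from the
#' negative-condition expression, yielding the reactivity score Delta used
#' by every downstream model. Incomplete pairs are skipped and reported.
#'
#' @param records Data.frame of expression records with columns `study`,
#'   `participant`, `run`, `signature`, `condition`, `expression`, and
#'   optionally `group`.
#' @param conditions Length-2 character vector `c(minuend, subtrahend)`;
#'   the default computes negative minus neutral.
#' @return Data.frame with columns `study`, `participant`, `run`, `group`,
#'   `signature`, `delta`; the skipped incomplete keys are attached as the
#'   `"skipped"` attribute (a data.frame, possibly empty).
#' @export
compute_reactivity <- function(records,
                               conditions = c("negative", "neutral")) {
  if (nrow(records) == 0L) stop("empty expression table")
  stopifnot(length(conditions) == 2L)
  if (!"group" %in% names(records)) records$group <- NA_character_
  key <- interaction(records$study, records$participant, records$run,
                     records$signature, records$condition, drop = TRUE)
  if (anyDuplicated(key))
    stop("duplicated (study, participant, run, signature, condition) keys")

  a <- records[records$condition == conditions[1], ]
  b <- records[records$condition == conditions[2], ]
  ka <- paste(a$study, a$participant, a$run, a$signature, sep = "\r")
  kb <- paste(b$study, b$participant, b$run, b$signature, sep = "\r")
  m <- match(ka, kb)
  ok <- !is.na(m)
  out <- data.frame(study = a$study[ok], participant = a$participant[ok],
                    run = a$run[ok], group = a$group[ok],
                    signature = a$signature[ok],
                    delta = a$expression[ok] - b$expression[m[ok]],
                    stringsAsFactors = FALSE)
  skipped <- rbind(
    a[!ok, c("study", "participant", "run", "signature")],
    b[!(kb %in% ka), c("study", "participant", "run", "signature")])
  if (nrow(skipped) > 0L)
    message(nrow(skipped), " incomplete condition pair(s) skipped")
  attr(out, "skipped") <- skipped
  out
}

#' Average reactivity over runs
#'
#' Replaces each participant's per-run reactivity scores by their unweighted
#' mean, as done for the three runs of a multi-run study before single-study
#' testing. Participants with fewer runs than the study's full run count are
#' averaged over the available runs and flagged as partial.
#'
#' @param records Reactivity data.frame from [compute_reactivity()].
#' @return Data.frame with one row per study x participant x signature and
#'   columns `study`, `participant`, `group`, `signature`, `delta`,
#'   `n_runs`, `partial`.
#' @export
average_runs <- function(records) {
  if (nrow(records) == 0L) stop("empty reactivity table")
  f <- interaction(records$study, records$participant, records$signature,
                   drop = TRUE)
  agg <- do.call(rbind, lapply(split(records, f), function(d) {
    data.frame(study = d$study[1], participant = d$participant[1],
               group = d$group[1], signature = d$signature[1],
               delta = mean(d$delta), n_runs = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  # a participant is partial relative to the run count of their own study
  full <- tapply(agg$n_runs, paste(agg$study, agg$signature, sep = "\r"), max)
  agg$partial <- agg$n_runs < full[paste(agg$study, agg$signature, sep = "\r")]
  agg
}

#' Cronbach's alpha across experimental runs
#'
#' Internal consistency of a brain measure over runs of the same session,
#' treating runs as parallel items: alpha = k/(k-1) * (1 - sum(var_i) /
#' var_total), where var_i is the per-run variance over participants and
#' var_total the variance of per-participant run sums (sample variances,
#' denominator n-1). Rows with missing cells are dropped (listwise) with a
#' message. Alpha is at most 1 and may be negative.
#'
#' @param mat Numeric matrix, participants x runs.
#' @return Scalar alpha with attributes `k` (runs) and `n` (participants
#'   after listwise deletion).
#' @export
cronbach_alpha <- function(mat) {
  mat <- as.matrix(mat)
  complete <- stats::complete.cases(mat)
  if (any(!complete))
    message(sum(!complete), " row(s) with missing cells dropped")
  mat <- mat[complete, , drop = FALSE]
  k <- ncol(mat)
  n <- nrow(mat)
  if (k < 2L) stop("alpha requires at least 2 runs")
  if (n < 3L) stop("alpha requires at least 3 complete participants")
  v_total <- stats::var(rowSums(mat))
  if (v_total <= 0) stop("zero total variance")
  alpha <- k / (k - 1) * (1 - sum(apply(mat, 2, stats::var)) / v_total)
  structure(alpha, k = k, n = n)
}

#' Correlation of pattern expression between two runs
#'
#' Pearson correlation over participants present in both runs, used to
#' compare e.g. an event-related run with a block-design run.
#'
#' @param records Reactivity (or expression) data.frame with columns
#'   `participant`, `run` and a score column.
#' @param run_a,run_b Run identifiers to correlate.
#' @param value Name of the score column (default `"delta"`).
#' @return Scalar correlation with attribute `n` (shared participants).
#' @export
inter_run_correlation <- function(records, run_a, run_b, value = "delta") {
  a <- records[records$run == run_a, ]
  b <- records[records$run == run_b, ]
  m <- match(a$participant, b$participant)
  ok <- !is.na(m)
  x <- a[[value]][ok]
  y <- b[[value]][m[ok]]
  if (length(x) < 3L) stop("fewer than 3 shared participants")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in a run")
  structure(stats::cor(x, y), n = length(x))
}

#' Forced-choice accuracy of a signature
#'
#' The fraction of participants whose expression is higher in the negative
#' than in the neutral condition — the two-alternative forced-choice
#' accuracy of the signature as a within-person classifier. Exact ties
#' count 0.5, keeping the measure symmetric under sign conventions.
#'
#' @param records Expression data.frame (as for [compute_reactivity()]).
#' @param signature Signature to evaluate (default: all rows as given).
#' @return Proportion correct in \[0, 1\], with attribute `n` (complete
#'   pairs).
#' @export
forced_choice_accuracy <- function(records, signature = NULL) {
  if (!is.null(signature)) records <- records[records$signature == signature, ]
  rx <- compute_reactivity(records)
  if (nrow(rx) == 0L) stop("no complete condition pairs")
  # one decision per participant-run, so the measure is invariant under any
  # strictly monotone transform of the expressions
  acc <- mean(ifelse(rx$delta > 0, 1, ifelse(rx$delta < 0, 0, 0.5)))
  structure(acc, n = nrow(rx))
}
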