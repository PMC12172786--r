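# Neural signature patterns and pattern-expression scoring.

#' Construct a neural signature pattern
#'
#' A signature is a fixed map of regression weights, one per in-mask voxel,
#' applied to new beta images by a voxelwise dot product ("pattern
#' expression"). Voxels outside the mask carry no weight.
#'
#' @param name Signature identifier, e.g. `"PINES"`, `"fear"`, `"anger"`.
#' @param grid A [volume_grid()].
#' @param weights 3-D array of weights on `grid` (values outside `mask`
#'   are ignored).
#' @param mask Logical 3-D array marking where weights are defined. Defaults
#'   to the finite, nonzero-support voxels of `weights`.
#' @return An object of class `signature_pattern`.
#' @export
signature_pattern <- function(name, grid, weights, mask = NULL) {
  stopifnot(inherits(grid, "volume_grid"))
  weights <- array(as.numeric(weights), dim = grid$dims)
  if (is.null(mask)) mask <- array(is.finite(weights), dim = grid$dims)
  mask <- array(as.logical(mask), dim = grid$dims)
  if (!any(mask)) stop("signature mask is empty")
  if (any(!is.finite(weights[mask]))) stop("non-finite weights inside mask")
  if (all(weights[mask] == 0)) stop("all in-mask weights are zero")
  structure(list(name = as.character(name), grid = grid,
                 weights = weights, mask = mask),
            class = "signature_pattern")
}

#' @export
print.signature_pattern <- function(x, ...) {
  cat(sprintf("<signature_pattern '%s': %d in-mask voxels on %dx%dx%d grid>\n",
              x$name, sum(x$mask), x$grid$dims[1], x$grid$dims[2],
              x$grid$dims[3]))
  invisible(x)
}

#' Construct a beta map
#'
#' A first-level beta image for one participant x run x condition, tagged
#' with the metadata needed downstream. Undefined voxels (outside individual
#' brain coverage) are `NA`/`NaN`.
#'
#' @param study,participant,run Identifiers.
#' @param condition One of `"negative"`, `"neutral"`,
#'   `"implicit_baseline_contrast"`.
#' @param grid A [volume_grid()].
#' @param values 3-D numeric array of beta values on `grid`.
#' @param group Optional group label (e.g. `"ED"`, `"HC"`).
#' @return An object of class `beta_map`.
#' @export
beta_map <- function(study, participant, run, condition, grid, values,
                     group = NA_character_) {
  condition <- match.arg(condition,
                         c("negative", "neutral", "implicit_baseline_contrast"))
  stopifnot(inherits(grid, "volume_grid"))
  values <- array(as.numeric(values), dim = grid$dims)
  if (!any(is.finite(values))) stop("beta map has no defined voxels")
  structure(list(study = study, participant = participant, run = run,
                 condition = condition, group = group,
                 grid = grid, values = values),
            class = "beta_map")
}

#' Construct a region-of-interest mask
#'
#' @param grid A [volume_grid()].
#' @param mask Logical 3-D array; at least one voxel must be `TRUE`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(grid, mask) {
  stopifnot(inherits(grid, "volume_grid"))
  mask <- array(as.logical(mask), dim = grid$dims)
  if (!any(mask)) stop("ROI mask is empty")
  structure(list(grid = grid, mask = mask), class = "roi_mask")
}

#' Pattern expression: signature dot-product score
#'
#' Computes the dot product between a signature's weight map and a beta
#' image, the signature's "predicted" response for that condition. The beta
#' image is resampled to the signature grid (trilinear) when the grids
#' differ. Undefined voxels inside the mask contribute 0 to the sum; their
#' count is returned and a warning is raised when more than 10% of the mask
#' is uncovered, making coverage loss visible without invalidating the
#' score.
#'
#' @param beta A [beta_map()] (or a bare list with `grid` and `values`).
#' @param pattern A [signature_pattern()].
#' @return The scalar expression value, with attributes `n_mask_voxels`
#'   (in-mask voxel count) and `n_undefined` (in-mask voxels with no beta
#'   coverage).
#' @export
pattern_expression <- function(beta, pattern) {
  stopifnot(inherits(pattern, "signature_pattern"))
  b <- align_to_grid(beta, pattern$grid, method = "trilinear")
  m <- pattern$mask
  bm <- b[m]
  n_mask <- sum(m)
  undef <- !is.finite(bm)
  if (all(undef)) stop("no overlap between beta coverage and signature mask")
  if (sum(undef) > 0.1 * n_mask)
    warning(sprintf("%d of %d in-mask voxels (%.1f%%) lack beta coverage",
                    sum(undef), n_mask, 100 * sum(undef) / n_mask))
  bm[undef] <- 0
  out <- sum(pattern$weights[m] * bm)
  attr(out, "n_mask_voxels") <- n_mask
  attr(out, "n_undefined") <- sum(undef)
  out
}

#' Mean beta response within a region of interest
#'
#' Arithmetic mean of the defined beta values inside the ROI; the ROI mask
#' is brought onto the beta grid with nearest-neighbour resampling when the
#' grids differ. Coverage below 50% of the ROI triggers a warning.
#'
#' @param beta A [beta_map()].
#' @param roi An [roi_mask()].
#' @return Scalar mean, with attribute `n_undefined`.
#' @export
roi_mean <- function(beta, roi) {
  stopifnot(inherits(roi, "roi_mask"))
  if (grids_equal(beta$grid, roi$grid)) {
    m <- roi$mask
    vals <- beta$values[m]
  } else {
    rm_on_beta <- align_to_grid(list(grid = roi$grid,
                                     values = array(as.numeric(roi$mask),
                                                    dim = roi$grid$dims)),
                                beta$grid, method = "nearest")
    m <- !is.na(rm_on_beta) & rm_on_beta > 0.5
    if (!any(m)) stop("ROI does not overlap the beta grid")
    vals <- beta$values[m]
  }
  def <- is.finite(vals)
  if (!any(def)) stop("no defined beta voxels inside the ROI")
  if (sum(def) < 0.5 * length(vals))
    warning(sprintf("ROI coverage %.1f%% (< 50%%)",
                    100 * sum(def) / length(vals)))
  out <- mean(vals[def])
  attr(out, "n_undefined") <- sum(!def)
  out
}

#' Score a set of beta maps against a set of signatures
#'
#' Applies [pattern_expression()] to every beta map x signature combination
#' and returns the long scoring table used by the downstream reactivity and
#' effect analyses.
#'
#' @param betas A list of [beta_map()] objects.
#' @param patterns A list of [signature_pattern()] objects.
#' @return A data.frame with columns `study`, `participant`, `run`, `group`,
#'   `condition`, `signature`, `expression`, `n_mask_voxels`, `n_undefined`.
#' @export
score_dataset <- function(betas, patterns) {
  if (inherits(patterns, "signature_pattern")) patterns <- list(patterns)
  rows <- vector("list", length(betas) * length(patterns))
  ix <- 0L
  for (b in betas) {
    for (p in patterns) {
      e <- pattern_expression(b, p)
      ix <- ix + 1L
      rows[[ix]] <- data.frame(
        study = b$study, participant = b$participant, run = b$run,
        group = b$group, condition = b$condition, signature = p$name,
        expression = as.numeric(e),
        n_mask_voxels = attr(e, "n_mask_voxels"),
        n_undefined = attr(e, "n_undefined"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
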