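# Synthetic beta-map generator with known ground truth.
#
# The generator emulates the statistical structure the pipeline assumes:
# participants nested in studies, 1-3 runs, two picture conditions, two
# groups, and beta maps whose dot product with a signature's weight map
# yields a controlled expression value. It makes no attempt at anatomical
# or hemodynamic realism; it exists so that every downstream stage can be
# validated against known truth without any data download.

# evaluate code under a temporary RNG state derived from `seed`
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  code
}

# deterministic 31-bit sub-seed from a root seed and a string tag
sub_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  as.integer((seed + h) %% 2147483647)
}

# separable Gaussian smoothing of a 3-D array (replicate padding)
smooth3d <- function(a, sd_vox = 1.5) {
  r <- ceiling(3 * sd_vox)
  kern <- stats::dnorm(-r:r, sd = sd_vox)
  kern <- kern / sum(kern)
  pad_filter <- function(v) {
    vp <- c(rep(v[1], r), v, rep(v[length(v)], r))
    as.numeric(stats::filter(vp, kern, sides = 2)[(r + 1):(r + length(v))])
  }
  along1 <- function(x) array(apply(x, c(2, 3), pad_filter), dim = dim(x))
  a <- along1(a)
  a <- aperm(along1(aperm(a, c(2, 1, 3))), c(2, 1, 3))
  a <- aperm(along1(aperm(a, c(3, 1, 2))), c(2, 3, 1))
  a
}

#' Generate a smooth pseudo-random signature pattern
#'
#' Produces a signature whose weights are a smoothed Gaussian random field
#' normalized to unit self-expression (sum of squared weights = 1), plus a
#' stored orthogonal nuisance map `q` (unit norm, exactly orthogonal to the
#' weights) used to inject structured noise that a correct scorer must
#' ignore.
#'
#' @param grid A [volume_grid()].
#' @param seed Integer seed; the same seed always yields the same maps.
#' @param name Signature name.
#' @return A [signature_pattern()] with an extra `nuisance` field.
#' @export
make_signature <- function(grid, seed, name = "synthetic") {
  stopifnot(inherits(grid, "volume_grid"))
  maps <- with_seed(seed, {
    w <- smooth3d(array(stats::rnorm(prod(grid$dims)), dim = grid$dims))
    q <- smooth3d(array(stats::rnorm(prod(grid$dims)), dim = grid$dims))
    list(w = w, q = q)
  })
  w <- maps$w / sqrt(sum(maps$w^2))
  q <- maps$q - sum(maps$q * w) * w
  q <- q / sqrt(sum(q^2))
  sig <- signature_pattern(name, grid, w,
                           mask = array(TRUE, dim = grid$dims))
  sig$nuisance <- q
  sig
}

#' Simulation configuration
#'
#' Describes a multi-study dataset: per-study sample sizes and run counts,
#' true standardized effects, and noise levels. The generative model per
#' participant j (group g), run i, signature s is
#' `Delta_ij = m_i * (d_within + d_between * code_g + u_j + e_ij)` with
#' `u_j ~ N(0, icc)`, `e_ij ~ N(0, 1 - icc)` so that Var(Delta) = 1 before
#' the run multiplier m_i (run multipliers emulate design effects: they
#' scale mean and SD jointly, leaving per-run Cohen's d unchanged), and
#' `code_g` the weighted effect code of the participant's group (so the
#' population mean of Delta is d_within and the ED - HC difference is
#' d_between). Neutral-condition expression is a unit-normal baseline;
#' negative-condition expression adds Delta.
#'
#' @param studies List of per-study lists with fields `n_ed`, `n_hc`,
#'   `n_runs`, and optionally `run_sd_multipliers` (defaults to all 1).
#' @param grid_dims Voxel grid dimensions (default 8x8x8).
#' @param n_signatures Number of signatures to simulate.
#' @param d_within True standardized condition effect, recycled per
#'   signature.
#' @param d_between True standardized group effect (ED - HC), recycled per
#'   signature.
#' @param icc Intraclass correlation of Delta across runs within
#'   participant, in \[0, 1).
#' @param noise_orthogonal_sd SD of the nuisance-map component added to
#'   each beta map (invisible to a correct scorer).
#' @param noise_iid_sd SD of voxelwise white noise (induces score error
#'   with variance `noise_iid_sd^2` for unit-norm signatures).
#' @param seed Root seed; all draws derive from it deterministically, with
#'   per-participant-and-signature substreams so adding a signature leaves
#'   existing draws untouched.
#' @return A `sim_config` list.
#' @export
sim_config <- function(studies, grid_dims = c(8, 8, 8), n_signatures = 1,
                       d_within = 1, d_between = 0, icc = 0.5,
                       noise_orthogonal_sd = 1, noise_iid_sd = 0.1,
                       seed = 1) {
  stopifnot(length(studies) >= 1, icc >= 0, icc < 1,
            noise_orthogonal_sd >= 0, noise_iid_sd >= 0)
  studies <- lapply(studies, function(s) {
    stopifnot(s$n_ed >= 1, s$n_hc >= 1, s$n_runs >= 1)
    if (is.null(s$run_sd_multipliers))
      s$run_sd_multipliers <- rep(1, s$n_runs)
    stopifnot(length(s$run_sd_multipliers) == s$n_runs,
              all(s$run_sd_multipliers > 0))
    s
  })
  structure(list(studies = studies, grid_dims = grid_dims,
                 n_signatures = n_signatures,
                 d_within = rep_len(d_within, n_signatures),
                 d_between = rep_len(d_between, n_signatures),
                 icc = icc, noise_orthogonal_sd = noise_orthogonal_sd,
                 noise_iid_sd = noise_iid_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Named simulation presets
#'
#' `"three_study"` mirrors the sample structure of the three source
#' studies: 29 + 28 participants with 3 runs, 20 + 20 with 3 runs, and
#' 62 + 33 with a single run.
#'
#' @param name Preset name.
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = "three_study", ...) {
  studies <- switch(name,
    three_study = list(
      list(n_ed = 29, n_hc = 28, n_runs = 3),
      list(n_ed = 20, n_hc = 20, n_runs = 3),
      list(n_ed = 62, n_hc = 33, n_runs = 1)),
    stop("unknown preset: ", name))
  sim_config(studies, ...)
}

#' Simulate true expression values (no voxel data)
#'
#' Draws the ground-truth expression table under the generative model of
#' [sim_config()], without constructing beta maps. This is the fast path
#' used by parameter-recovery simulations; [simulate_dataset()] layers the
#' voxel-level maps on top of it.
#'
#' @param config A `sim_config`.
#' @return A data.frame (the truth table) with one row per study x
#'   participant x run x condition x signature: columns `study`,
#'   `participant`, `run`, `group`, `signature`, `condition`,
#'   `expression` (true, noise-free), `u` (the participant's random
#'   intercept), `delta_true`.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- list()
  for (k in seq_along(config$studies)) {
    stu <- config$studies[[k]]
    n <- stu$n_ed + stu$n_hc
    groups <- rep(c("ED", "HC"), c(stu$n_ed, stu$n_hc))
    wc <- weighted_effect_codes(stu$n_ed, stu$n_hc)
    codes <- ifelse(groups == "ED", wc$code_ed, wc$code_hc)
    for (s in seq_len(config$n_signatures)) {
      sig <- paste0("sig", s)
      nr <- stu$n_runs
      u <- numeric(n)
      e <- base <- matrix(0, nr, n)
      for (j in seq_len(n)) {
        draws <- with_seed(
          sub_seed(config$seed, paste("expr", k, j, sig)), {
            list(u = stats::rnorm(1, 0, sqrt(config$icc)),
                 e = stats::rnorm(nr, 0, sqrt(1 - config$icc)),
                 base = stats::rnorm(nr, 0, 1))
          })
        u[j] <- draws$u; e[, j] <- draws$e; base[, j] <- draws$base
      }
      # runs x participants matrix of true reactivity
      delta <- stu$run_sd_multipliers *
        (rep(config$d_within[s] + config$d_between[s] * codes + u,
             each = nr) + e)
      rows[[length(rows) + 1L]] <- data.frame(
        study = paste0("study", k),
        participant = rep(sprintf("s%d_p%03d", k, seq_len(n)),
                          each = nr, times = 2L),
        run = rep(paste0("run", seq_len(nr)), n * 2L),
        group = rep(groups, each = nr, times = 2L), signature = sig,
        condition = rep(c("neutral", "negative"), each = nr * n),
        expression = c(as.numeric(base), as.numeric(base + delta)),
        u = rep(u, each = nr, times = 2L),
        delta_true = rep(as.numeric(delta), 2L),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a full beta-map dataset
#'
#' Generates signatures, the ground-truth expression table, and one beta
#' map per participant x run x condition x signature:
#' `b = e * w + z1 * q + white noise`, where `w` is the signature's
#' unit-norm weight map, `q` its stored orthogonal nuisance map,
#' `z1 ~ N(0, noise_orthogonal_sd)`, and the voxelwise white noise has SD
#' `noise_iid_sd`. Scoring `b` against `w` returns the true expression
#' `e` plus an error of known variance `noise_iid_sd^2` (the orthogonal
#' component contributes nothing).
#'
#' @param config A `sim_config`.
#' @param dir Optional directory: when given, every beta map is written as
#'   a NIfTI-1 file and a `manifest.csv` (paths + metadata) plus the
#'   metadata/truth tables are written alongside.
#' @return A list with `signatures` (list of [signature_pattern()]),
#'   `betas` (list of [beta_map()], with a `signature` field each),
#'   `truth` (the table from [simulate_expression()]), `config`, and
#'   `manifest` (data.frame of written paths, or `NULL`).
#' @export
simulate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  grid <- volume_grid(config$grid_dims)
  signatures <- lapply(seq_len(config$n_signatures), function(s)
    make_signature(grid, sub_seed(config$seed, paste("sig", s)),
                   name = paste0("sig", s)))
  names(signatures) <- vapply(signatures, `[[`, "", "name")
  truth <- simulate_expression(config)

  betas <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    sig <- signatures[[tr$signature]]
    noise <- with_seed(
      sub_seed(config$seed, paste("map", tr$study, tr$participant, tr$run,
                                  tr$condition, tr$signature)), {
        list(z1 = stats::rnorm(1, 0, 1),
             white = stats::rnorm(prod(config$grid_dims)))
      })
    vals <- tr$expression * sig$weights +
      config$noise_orthogonal_sd * noise$z1 * sig$nuisance +
      config$noise_iid_sd * array(noise$white, dim = config$grid_dims)
    bm <- beta_map(tr$study, tr$participant, tr$run, tr$condition,
                   grid, vals, group = tr$group)
    bm$signature <- tr$signature
    betas[[i]] <- bm
  }

  manifest <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(length(betas))
    for (i in seq_along(betas)) {
      b <- betas[[i]]
      paths[i] <- file.path(dir, sprintf("beta_%s_%s_%s_%s_%s.nii.gz",
                                         b$study, b$participant, b$run,
                                         b$condition, b$signature))
      write_volume(list(grid = b$grid, values = b$values), paths[i])
    }
    for (s in signatures)
      write_volume(list(grid = s$grid, values = s$weights),
                   file.path(dir, paste0("signature_", s$name, ".nii.gz")))
    manifest <- cbind(truth[, c("study", "participant", "run", "group",
                                "signature", "condition")],
                      path = paths)
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  }

  list(signatures = signatures, betas = betas, truth = truth,
       config = config, manifest = manifest)
}
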