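# End-to-end orchestration: score -> reactivity -> reliability ->
# single-study effects -> mega-analysis -> Bayes factors -> tables.

#' Default hypothesis directions per signature
#'
#' Directions of the one-sided alternatives for the canonical signatures:
#' negative-emotion signatures (and the general negative-affect signature)
#' are hypothesized to react positively to negative pictures and more
#' strongly in the clinical group; positive-emotion and neutral signatures
#' negatively; surprise is left two-sided.
#'
#' @return Named character vector of `"greater"`/`"less"`/`"two_sided"`.
#' @export
default_directions <- function() {
  c(negative_affect = "greater", PINES = "greater", fear = "greater",
    anger = "greater", sadness = "greater", amusement = "less",
    contentment = "less", surprise = "two_sided", neutral = "less")
}

# direction lookup with a fallback for unknown (e.g. simulated) signatures
.direction_for <- function(signature, directions, fallback = "greater") {
  if (signature %in% names(directions)) directions[[signature]] else fallback
}

#' Run the full analysis pipeline
#'
#' Orchestrates the complete analysis over a simulated (or pre-scored)
#' dataset: pattern-expression scoring, reactivity computation for the
#' configured contrast, reliability and forced-choice reports, per-study
#' condition and group effects with directional Bayes factors, and the two
#' mega-analyses. Identical config and seed give identical outputs.
#'
#' @param config A named list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{simulate}{List of arguments for [sim_preset()] /
#'       [sim_config()]; either `preset` plus overrides, or `studies` etc.}
#'     \item{expression_table}{Alternatively, a data.frame (or delimited
#'       file path) of already-scored expression records.}
#'     \item{contrast}{`"negative_minus_neutral"` (default),
#'       `"neutral_vs_implicit"` or `"negative_vs_implicit"`.}
#'     \item{directions}{Named vector of per-signature hypothesis
#'       directions; defaults to [default_directions()] with `"greater"`
#'       for unknown names.}
#'     \item{prior_scale}{Cauchy prior scale (default 0.707).}
#'     \item{average_runs_studies}{Character vector of studies whose runs
#'       are averaged for single-study tests (runs of other studies are
#'       tested separately); all studies enter the mega-analysis at run
#'       level regardless.}
#'     \item{out_dir}{Output directory for tables and the log (optional:
#'       when missing nothing is written).}
#'     \item{seed}{Integer seed for simulation.}
#'     \item{mixed_bf}{Compute mixed-model Bayes factors for the mega rows
#'       (default `TRUE`; the quadrature is the slowest step).}
#'   }
#' @return A list with `condition_table`, `group_table`, `reliability`,
#'   `forced_choice`, `expression` (the scored records), and `paths`
#'   (written files, if any).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  contrast <- config$contrast %||% "negative_minus_neutral"
  contrast <- match.arg(contrast, c("negative_minus_neutral",
                                    "neutral_vs_implicit",
                                    "negative_vs_implicit"))
  prior_scale <- config$prior_scale %||% (sqrt(2) / 2)
  directions <- config$directions %||% default_directions()
  mixed_bf <- config$mixed_bf %||% TRUE
  log_lines <- c(sprintf("emosig %s | %s",
                         as.character(utils::packageVersion("emosig")),
                         format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 sprintf("contrast: %s | prior scale: %.3f",
                         contrast, prior_scale))

  # --- obtain expression records -----------------------------------------
  if (!is.null(config$simulate)) {
    simargs <- config$simulate
    seed <- config$seed %||% simargs$seed %||% 1L
    simargs$seed <- seed
    cfg <- if (!is.null(simargs$preset)) {
      do.call(sim_preset, c(list(name = simargs$preset),
                            simargs[setdiff(names(simargs), "preset")]))
    } else {
      do.call(sim_config, simargs)
    }
    sim <- simulate_dataset(cfg)
    records <- score_dataset(sim$betas, sim$signatures)
    # each simulated map targets one signature; keep the matching scores
    target <- vapply(sim$betas, `[[`, "", "signature")
    records <- records[records$signature ==
                         target[rep(seq_along(sim$betas),
                                    each = length(sim$signatures))], ]
    log_lines <- c(log_lines, sprintf("simulated dataset, seed %d: %d maps",
                                      seed, length(sim$betas)))
  } else if (!is.null(config$expression_table)) {
    records <- config$expression_table
    if (is.character(records))
      records <- utils::read.delim(records, stringsAsFactors = FALSE)
  } else {
    stop("config must provide either `simulate` or `expression_table`")
  }

  # --- contrast ----------------------------------------------------------
  # the dependent variable fed to the models changes; the model path does not
  rx <- switch(contrast,
    negative_minus_neutral = compute_reactivity(records),
    neutral_vs_implicit = {
      r <- records[records$condition == "neutral", ]
      data.frame(study = r$study, participant = r$participant, run = r$run,
                 group = r$group, signature = r$signature,
                 delta = r$expression, stringsAsFactors = FALSE)
    },
    negative_vs_implicit = {
      r <- records[records$condition == "negative", ]
      data.frame(study = r$study, participant = r$participant, run = r$run,
                 group = r$group, signature = r$signature,
                 delta = r$expression, stringsAsFactors = FALSE)
    })
  n_skip <- nrow(attr(rx, "skipped") %||% data.frame())
  if (n_skip > 0)
    log_lines <- c(log_lines, sprintf("skipped %d incomplete pairs", n_skip))

  signatures <- unique(rx$signature)
  studies <- unique(rx$study)
  avg_studies <- config$average_runs_studies %||%
    studies[vapply(studies, function(s)
      length(unique(rx$run[rx$study == s])) > 1L, logical(1))][1]
  has_groups <- length(unique(rx$group[!is.na(rx$group)])) == 2L

  cond_rows <- list(); grp_rows <- list()
  for (sig in signatures) {
    dir_c <- .direction_for(sig, directions)
    rs <- rx[rx$signature == sig, ]

    # single-study tests: averaged runs or per-run, per configuration
    for (stu in studies) {
      d_stu <- rs[rs$study == stu, ]
      units <- if (stu %in% avg_studies || length(unique(d_stu$run)) == 1L) {
        av <- average_runs(d_stu)
        list(list(label = stu, data = av))
      } else {
        lapply(unique(d_stu$run), function(r)
          list(label = paste(stu, r, sep = ":"),
               data = d_stu[d_stu$run == r, ]))
      }
      for (u in units) {
        est <- cohens_d_within(u$data$delta, direction = dir_c)
        bf <- jzs_bf(est$t, est$n, scale = prior_scale,
                     alternative = if (dir_c == "two_sided") "two_sided"
                     else dir_c)
        cond_rows[[length(cond_rows) + 1L]] <- data.frame(
          unit = u$label, signature = sig, d = est$estimate,
          ci_low = est$ci_low, ci_high = est$ci_high,
          bf10 = bf$bf10, n = est$n, stringsAsFactors = FALSE)
        if (has_groups) {
          g1 <- u$data$delta[u$data$group == "ED"]
          g2 <- u$data$delta[u$data$group == "HC"]
          estg <- cohens_d_between(g1, g2, direction = dir_c)
          bfg <- jzs_bf(estg$t_pooled, estg$n1, estg$n2, scale = prior_scale,
                        alternative = if (dir_c == "two_sided") "two_sided"
                        else dir_c)
          grp_rows[[length(grp_rows) + 1L]] <- data.frame(
            unit = u$label, signature = sig, d = estg$estimate,
            ci_low = estg$ci_low, ci_high = estg$ci_high,
            bf01 = bfg$bf01, n_ed = estg$n1, n_hc = estg$n2,
            stringsAsFactors = FALSE)
        }
      }
    }

    # mega-analytic rows
    mw <- mega_within(rs)
    scaled <- run_scale(rs, "scale_only")
    bf_mw <- if (mixed_bf)
      mixed_model_bf(scaled$delta, rep(1, nrow(scaled)),
                     paste(scaled$study, scaled$participant, sep = "\r"),
                     direction = dir_c, prior_scale = prior_scale)$bf10
    else NA_real_
    cond_rows[[length(cond_rows) + 1L]] <- data.frame(
      unit = "mega", signature = sig, d = unname(mw$gamma[1]),
      ci_low = unname(mw$ci_low[1]), ci_high = unname(mw$ci_high[1]),
      bf10 = bf_mw, n = mw$n_participants, stringsAsFactors = FALSE)

    if (has_groups) {
      mg <- mega_group(rs)
      scaled_g <- run_scale(rs, "center_and_scale")
      bf_mg <- if (mixed_bf) {
        cell <- interaction(scaled_g$study, scaled_g$run, drop = TRUE)
        code <- numeric(nrow(scaled_g))
        for (lv in levels(cell)) {
          i <- which(cell == lv)
          wc <- weighted_effect_codes(sum(scaled_g$group[i] == "ED"),
                                      sum(scaled_g$group[i] == "HC"))
          code[i] <- ifelse(scaled_g$group[i] == "ED",
                            wc$code_ed, wc$code_hc)
        }
        mixed_model_bf(scaled_g$delta, code,
                       paste(scaled_g$study, scaled_g$participant,
                             sep = "\r"),
                       direction = dir_c, prior_scale = prior_scale)$bf01
      } else NA_real_
      grp_rows[[length(grp_rows) + 1L]] <- data.frame(
        unit = "mega", signature = sig, d = unname(mg$gamma[1]),
        ci_low = unname(mg$ci_low[1]), ci_high = unname(mg$ci_high[1]),
        bf01 = bf_mg, n_ed = sum(!duplicated(
          rs[rs$group == "ED", c("study", "participant")])),
        n_hc = sum(!duplicated(
          rs[rs$group == "HC", c("study", "participant")])),
        stringsAsFactors = FALSE)
    }
  }
  condition_table <- do.call(rbind, cond_rows)
  group_table <- if (length(grp_rows)) do.call(rbind, grp_rows) else NULL

  # --- reliability & forced choice ---------------------------------------
  rel_rows <- list(); fc_rows <- list()
  for (sig in signatures) {
    rs <- rx[rx$signature == sig, ]
    for (stu in studies) {
      d_stu <- rs[rs$study == stu, ]
      runs <- unique(d_stu$run)
      if (length(runs) >= 2L) {
        m <- stats::reshape(
          d_stu[, c("participant", "run", "delta")],
          idvar = "participant", timevar = "run", direction = "wide")
        a <- cronbach_alpha(as.matrix(m[, -1]))
        rel_rows[[length(rel_rows) + 1L]] <- data.frame(
          study = stu, signature = sig, alpha = as.numeric(a),
          k = attr(a, "k"), n = attr(a, "n"), stringsAsFactors = FALSE)
      }
    }
  }
  if (contrast == "negative_minus_neutral") {
    for (sig in signatures) {
      per <- records[records$signature == sig, ]
      for (stu in studies) {
        acc <- forced_choice_accuracy(per[per$study == stu, ])
        fc_rows[[length(fc_rows) + 1L]] <- data.frame(
          study = stu, signature = sig, accuracy = as.numeric(acc),
          n = attr(acc, "n"), stringsAsFactors = FALSE)
      }
    }
  }
  reliability <- if (length(rel_rows)) do.call(rbind, rel_rows) else NULL
  forced_choice <- if (length(fc_rows)) do.call(rbind, fc_rows) else NULL

  # --- write outputs ------------------------------------------------------
  paths <- character(0)
  if (!is.null(config$out_dir)) {
    out <- config$out_dir
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    wr <- function(tab, nm) {
      if (is.null(tab)) return()
      full <- file.path(out, paste0(nm, "_full.tsv"))
      utils::write.table(tab, full, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      rounded <- tab
      num <- vapply(rounded, is.numeric, logical(1))
      rounded[num] <- lapply(rounded[num], round, 2)
      disp <- file.path(out, paste0(nm, ".tsv"))
      utils::write.table(rounded, disp, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      paths <<- c(paths, full, disp)
    }
    wr(condition_table, "condition_effects")
    wr(group_table, "group_effects")
    wr(reliability, "reliability")
    wr(forced_choice, "forced_choice")
    cfg_file <- file.path(out, "config.yaml")
    yaml::write_yaml(config[setdiff(names(config), "expression_table")],
                     cfg_file)
    log_lines <- c(log_lines,
                   sprintf("config md5: %s",
                           unname(tools::md5sum(cfg_file))),
                   sprintf("wrote: %s", paste(basename(paths),
                                              collapse = ", ")))
    writeLines(log_lines, file.path(out, "pipeline.log"))
    paths <- c(paths, cfg_file, file.path(out, "pipeline.log"))
  }

  list(condition_table = condition_table, group_table = group_table,
       reliability = reliability, forced_choice = forced_choice,
       expression = records, paths = paths, log = log_lines)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
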