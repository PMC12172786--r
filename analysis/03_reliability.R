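#!/usr/bin/env Rscript
# Step 3: measurement properties of the signature scores. Cronbach's alpha
# across runs within each multi-run study, correlations between runs, and
# forced-choice accuracy (fraction of participant-runs with higher
# expression for negative than neutral pictures).

suppressPackageStartupMessages(library(emosig))

expr <- read.delim("results/expression.tsv", stringsAsFactors = FALSE)
rx <- compute_reactivity(expr)

rel_rows <- list(); cor_rows <- list(); fc_rows <- list()
for (sig in unique(rx$signature)) {
  for (stu in unique(rx$study)) {
    d <- rx[rx$signature == sig & rx$study == stu, ]
    runs <- sort(unique(d$run))
    if (length(runs) >= 2) {
      m <- reshape(d[, c("participant", "run", "delta")],
                   idvar = "participant", timevar = "run",
                   direction = "wide")
      a <- cronbach_alpha(as.matrix(m[, -1]))
      rel_rows[[length(rel_rows) + 1]] <- data.frame(
        study = stu, signature = sig, alpha = as.numeric(a),
        k = attr(a, "k"), n = attr(a, "n"))
      for (i in seq_len(length(runs) - 1)) for (j in (i + 1):length(runs)) {
        r <- inter_run_correlation(d, runs[i], runs[j])
        cor_rows[[length(cor_rows) + 1]] <- data.frame(
          study = stu, signature = sig, run_a = runs[i], run_b = runs[j],
          r = as.numeric(r), n = attr(r, "n"))
      }
    }
    acc <- forced_choice_accuracy(expr[expr$signature == sig &
                                         expr$study == stu, ])
    fc_rows[[length(fc_rows) + 1]] <- data.frame(
      study = stu, signature = sig, accuracy = as.numeric(acc),
      n = attr(acc, "n"))
  }
}

rel <- do.call(rbind, rel_rows)
cors <- do.call(rbind, cor_rows)
fc <- do.call(rbind, fc_rows)
write.table(rel, "results/reliability.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
write.table(cors, "results/inter_run_correlations.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(fc, "results/forced_choice.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

cat(sprintf("alpha range: %.2f - %.2f (Spearman-Brown prediction %.2f for icc .55, k = 3)\n",
            min(rel$alpha), max(rel$alpha), 3 * 0.55 / (1 + 2 * 0.55)))
cat(sprintf("forced-choice accuracy for the strong signature: %.2f - %.2f across studies\n",
            min(fc$accuracy[fc$signature == "sig1"]),
            max(fc$accuracy[fc$signature == "sig1"])))
cat("wrote results/reliability.tsv, inter_run_correlations.tsv, forced_choice.tsv\n")
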