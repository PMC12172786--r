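#!/usr/bin/env Rscript
# Step 4: single-study condition and group effects. Runs of the first
# study are averaged before testing (their designs are compatible); runs
# of the second are analyzed separately (they differ by design); the third
# has a single run. Each test reports Cohen's d with a noncentral-t 95% CI
# and a directional JZS Bayes factor (BF10 for condition effects, BF01 for
# group effects), mirroring the layout of the published effect tables.

suppressPackageStartupMessages(library(emosig))

expr <- read.delim("results/expression.tsv", stringsAsFactors = FALSE)

res <- run_pipeline(list(
  expression_table = expr,
  directions = c(sig1 = "greater", sig2 = "greater", sig3 = "greater"),
  average_runs_studies = "study1",
  mixed_bf = FALSE))          # mega-model Bayes factors come in step 5

cond <- res$condition_table[res$condition_table$unit != "mega", ]
grp <- res$group_table[res$group_table$unit != "mega", ]
write.table(cond, "results/condition_effects.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(grp, "results/group_effects.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("condition effects (per study/run):\n")
print(transform(cond, d = round(d, 2), ci_low = round(ci_low, 2),
                ci_high = round(ci_high, 2), bf10 = signif(bf10, 3)),
      row.names = FALSE)
cat("\nthe strong signature shows large positive effects everywhere;\n")
cat("the weak negative signature is reversed, with BF10 favoring the null.\n")
cat("group effects hover near zero by construction (no group effect simulated).\n")
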