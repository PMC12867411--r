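#!/usr/bin/env Rscript
# Inferential stage: three-way ANOVA (tissue x pathology x MW) of each
# kinetic metric, a t-test example, and a correlation example.

library(nucflux)

metrics <- read.csv("results/kinetic_metrics.csv", stringsAsFactors = FALSE)
metrics$flags <- ifelse(is.na(metrics$flags), "", as.character(metrics$flags))
clean <- metrics[metrics$flags == "", ]
clean$mw <- factor(clean$molecular_weight, levels = c(700, 3000, 10000),
                   labels = c("free_dye", "3kDa", "10kDa"))

tabs <- list()
for (metric in c("t_half_s", "y_half_normalized", "max_rate_per_s")) {
  rec <- data.frame(tissue = clean$tissue, pathology = clean$pathology,
                    mw = clean$mw, value = clean[[metric]])
  out <- three_way_anova(rec)
  out$metric <- metric
  tabs[[metric]] <- out
  sig <- out$term[!is.na(out$p.value) & out$p.value < 0.05]
  message(metric, ": significant terms (p < 0.05, uncorrected): ",
          if (length(sig)) paste(sig, collapse = ", ") else "none")
}
write.csv(do.call(rbind, tabs), "results/anova_tables.csv", row.names = FALSE)

# t-test: bright vs dim population plateaus (stain level should not bias cargo)
tt <- ttest_independent(clean$plateau[clean$population == "bright"],
                        clean$plateau[clean$population == "dim"])
# correlation: nucleus plateau vs max rate across cells
cr <- correlate(clean$plateau, clean$max_rate_per_s)
jsonlite::write_json(list(ttest_bright_vs_dim = tt,
                          correlation_plateau_rate = cr),
                     "results/stat_tests.json", auto_unbox = TRUE, digits = NA)
message(sprintf("bright-vs-dim plateau t-test p = %.3g; plateau~rate R2 = %.3f",
                tt$p, cr$r_squared))
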