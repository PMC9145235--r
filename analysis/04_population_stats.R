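#!/usr/bin/env Rscript
# Step 4 — population-level descriptive statistics on line BLUPs.
#
# Fold-variation summary per trait, Spearman correlation with
# average-linkage clustering of the traits into four groups, and one-way
# ANOVA with Duncan's multiple range test across the four maize
# subpopulations (SS / NSS / TST / Mixed, sized 25/67/51/59 as in a
# 202-line association panel).

suppressMessages(library(shankvb))

blups <- utils::read.csv("results/line_blups.csv", check.names = FALSE)
traits <- blups[, -1, drop = FALSE]

vs <- variation_summary(traits)
vs <- vs[order(-vs$fold), ]
cat("largest fold variation:\n")
print(utils::head(vs[, c("trait", "median", "min", "max", "fold")], 4),
      row.names = FALSE)
utils::write.csv(vs, "results/variation_summary.csv", row.names = FALSE)

cl <- spearman_cluster(traits, k = 4)
utils::write.csv(data.frame(trait = names(cl$groups), group = cl$groups),
                 "results/trait_clusters.csv", row.names = FALSE)
utils::write.csv(round(cl$rho, 4), "results/spearman_rho.csv")
cat("\ntrait groups (k = 4):\n")
print(split(names(cl$groups), cl$groups))

# subgroup labels planted by step 3 (SS 25, NSS 67, TST 51, Mixed 59)
sg <- utils::read.csv("results/subgroups.csv")
subgroup <- sg$subgroup[match(blups$line, sg$line)]
dunc <- lapply(names(traits), function(tr) {
  d <- anova_duncan(traits[[tr]], subgroup)
  data.frame(trait = tr, F = d$F, p = d$p,
             means = paste(sprintf("%s=%.3g%s", d$groups$subgroup,
                                   d$groups$mean, d$groups$letters),
                           collapse = " "))
})
dunc <- do.call(rbind, dunc)
utils::write.csv(dunc, "results/anova_duncan.csv", row.names = FALSE)
cat("\ntraits with subgroup differences at p <= 0.05:",
    sum(dunc$p <= 0.05), "of", nrow(dunc), "\n")
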