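#!/usr/bin/env Rscript

# Step 3 — in silico saturation mutagenesis and candidate ranking.
# (a) Rescore the published single/double/multiple ddG tables from their
#     printed one-decimal triples and the derived weights, and rank them.
# (b) Run the same screen on a synthetic ddG landscape over the 11
#     unfavorable interface positions, where the planted best design is
#     known, as an end-to-end control.

library(il18design)

dir.create("results", showWarnings = FALSE)
w <- derive_weights(c(-0.7019, -0.7443, -0.5770))

## (a) published tables
tab <- score_variants(il18_published_ddg(), w)
ranked <- rank_variants(tab[tab$group != "control", ])
write.table(ranked, "results/published_variants_rescored.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

dev <- abs(ranked$score - ranked$score_published)
message(nrow(ranked), " candidate rows rescored from printed ddG; ",
        "max |recomputed - printed| = ", round(max(dev), 3),
        "; ", round(100 * mean(dev <= 0.05)), "% within 0.05.")
message("Top three designs by recomputed score: ",
        paste(ranked$variant[1:3], collapse = ", "))
strict <- select_candidates(tab, "strict_all_negative")
message(nrow(strict), " variants satisfy the strict all-negative-ddG rule.")

## (b) synthetic landscape over the 11 unfavorable positions
sites <- data.frame(
  wt_res = c("E", "N", "R", "D", "Q", "D", "N", "M", "K", "R", "N"),
  position = c(6, 41, 44, 54, 56, 110, 111, 113, 129, 131, 155))
message(length(saturate(sites)), " single variants in the saturation scan (",
        nrow(sites), " sites x 19 substitutions).")

ls <- gen_ddg_landscape(sites, weights = w, epistasis_sd = 0.3, seed = 42)
syn_ranked <- rank_variants(score_variants(ls$table, w))
write.table(syn_ranked, "results/synthetic_screen_ranked.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("Synthetic screen: ", nrow(syn_ranked), " variants ranked; ",
        "planted additive-best design ", ls$truth$best_variant,
        if (syn_ranked$variant[1] == ls$truth$best_variant) {
          " recovered at rank 1"
        } else {
          paste0(" observed at rank ",
                 which(syn_ranked$variant == ls$truth$best_variant),
                 " under epistatic noise (sd 0.3 kcal/mol)")
        }, ".")
message("Wrote results/published_variants_rescored.tsv and ",
        "results/synthetic_screen_ranked.tsv")
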