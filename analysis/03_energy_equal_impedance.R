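#!/usr/bin/env Rscript

# Step 3: battery current draw in the equal-impedance scenario (3 kOhm).
#
# Uses the published ring-mode and single-electrode amplitude anchors
# plus the titrated fractionalization amplitudes from step 2 (run
# analysis/02_steering_grid.R first) and evaluates the current-draw
# model for MICC, Interleaving/MSS and coactivation. One-sided
# signed-rank tests check the expected orderings (MICC below
# Interleaving/MSS; coactivation below MICC for uniform splits).

suppressPackageStartupMessages(library(vtasteer))

params <- energy_params()
anchors <- anchor_amplitudes()

ref <- data.frame(
  target_radius = anchors$target_radius,
  ring_uA = round(vapply(anchors$ring_mA, function(a)
    current_draw_micc(a * c(0.34, 0.33, 0.33), rep(3, 3), params), numeric(1)), 1),
  single_uA = round(vapply(anchors$single_mA, function(a)
    current_draw_micc(a, 3, params), numeric(1)), 1)
)
message("Reference rows (3 kOhm), uA:")
print(ref, row.names = FALSE)
write.csv(ref, "results/current_reference_rows.csv", row.names = FALSE)

grid_file <- "results/grid_results.csv"
if (!file.exists(grid_file)) {
  message("\nresults/grid_results.csv not found; run analysis/02_steering_grid.R for the fractionalization comparison")
  quit(status = 0)
}
res <- read.csv(grid_file)
fracs <- c("-50/-50", "-60/-40", "-70/-30", "-80/-20", "-90/-10")
two <- res[res$setting %in% fracs, ]
m <- two[two$paradigm == "micc", c("setting", "target_radius", "current_uA")]
i <- two[two$paradigm == "interleaving", c("setting", "target_radius", "current_uA")]
mi <- merge(m, i, by = c("setting", "target_radius"), suffixes = c("_micc", "_il"))

w <- wilcoxon_signed_rank(mi$current_uA_micc, mi$current_uA_il, "less")
pct <- 100 * (mi$current_uA_il - mi$current_uA_micc) / mi$current_uA_il
q <- summarize_median_iqr(pct)
message(sprintf("\nMICC current draw %.1f (%.1f-%.1f)%% below Interleaving/MSS across %d cells (one-sided p = %.2g)",
                q$median, q$q25, q$q75, nrow(mi), w$p))
message(sprintf("MICC below Interleaving/MSS in every cell: %s",
                all(mi$current_uA_micc < mi$current_uA_il)))

co <- res[res$paradigm == "coactivation", ]
mc <- merge(res[res$paradigm == "micc", c("setting", "target_radius", "current_uA")],
            co[, c("setting", "target_radius", "current_uA")],
            by = c("setting", "target_radius"), suffixes = c("_micc", "_co"))
w <- wilcoxon_signed_rank(mc$current_uA_co, mc$current_uA_micc, "less")
message(sprintf("Coactivation at or below MICC for uniform settings (one-sided p = %.2g): %s",
                w$p, all(mc$current_uA_co <= mc$current_uA_micc + 1e-9)))
write.csv(mi, "results/current_fractionalizations.csv", row.names = FALSE)
message("wrote results/current_reference_rows.csv, results/current_fractionalizations.csv")
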