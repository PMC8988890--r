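#!/usr/bin/env Rscript
# Inter-laboratory agreement on the simulated two-lab phytic acid pairs
# (Pearson correlation + Bland-Altman) and core-collection representativeness
# from the packaged published trait ranges (coincidence rate).
# Run analysis/01_simulate_inputs.R first.

suppressPackageStartupMessages(library(phytofer))
pairs <- read.csv("results/sim/twolab.csv")

pc <- pearson_correlation(pairs$x, pairs$y)
ba <- bland_altman(pairs$x, pairs$y)
cat(sprintf("two-lab agreement (n = %d): r = %.3f (p = %.2g)\n",
            pc$n, pc$r, pc$p))
cat(sprintf("Bland-Altman: bias %.1f mg/100g, limits %.1f to %.1f (+/- %.0f)\n",
            ba$bias, ba$loa_low, ba$loa_high, 1.96 * ba$sd_diff))
cat(sprintf("difference vs magnitude: r = %.2f (p = %.2f)\n",
            ba$r_diff_mean, ba$p_diff_mean))
write.csv(data.frame(n = ba$n, r = pc$r, r2 = pc$r2, p = pc$p,
                     bias = ba$bias, sd_diff = ba$sd_diff,
                     loa_low = ba$loa_low, loa_high = ba$loa_high),
          "results/agreement.csv", row.names = FALSE)

tab <- millet_table("trait_ranges")
cr <- coincidence_rate(tab$max_core - tab$min_core,
                       tab$max_panel - tab$min_panel)
cat(sprintf("\ncoincidence rate of the diversity panel over %d traits: %.1f%%\n",
            nrow(tab), cr))
write.csv(data.frame(n_traits = nrow(tab), cr_pct = cr),
          "results/panel_coincidence.csv", row.names = FALSE)
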