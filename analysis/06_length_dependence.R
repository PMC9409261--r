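#!/usr/bin/env Rscript
# Helix-length dependence and method comparison. Tabulates the mean MM
# hydrogen-bond energy of each helix length against the pair count L and
# 1/L^2 (the cooperativity axes), and demonstrates the comparison
# statistics (Pearson r, least squares) used to relate quantum-chemical
# energies -- imported as plain tables when available -- to the MM values
# computed here. A pairwise force field shows no cooperativity: the length
# curve is essentially flat, unlike the published quantum-chemical trend.

library(helixhb)

dir.create("results", showWarnings = FALSE)

mm310 <- do.call(rbind, lapply(2:7, function(n) mm_hbond_energies(build_helix("310", n), 3)))
curve <- energy_vs_length(mm310)
write.csv(curve, "results/energy_vs_length_310.csv", row.names = FALSE)
cat("Mean MM H-bond energy vs helix length (3_10 series):\n")
print(transform(curve, mean_e = round(mean_e, 4), sd_e = round(sd_e, 4),
                inv_L2 = round(inv_L2, 4)))
cat(sprintf("Total spread of the means: %.3f kcal/mol (no cooperativity in a\n",
            diff(range(curve$mean_e))))
cat("pairwise force field; the published QM curves stabilize with length)\n")

# comparison-statistics demonstration on a designed fixture. The ideal-
# geometry models are screw-symmetric, so their MM energies carry no
# per-pair spread and a regression against them is meaningless; external
# quantum-chemical energies, when available, are imported as tables and
# compared exactly like this designed pair of tables (here: y = 1.2 x + 1
# plus small designed residuals, routed through the synthetic fragment-
# energy generator so the whole NFA path is exercised).
mm_designed <- seq(-6.2, -3.4, length.out = 8)
resid <- c(0.15, -0.1, 0.2, -0.2, 0.05, -0.15, 0.1, -0.05)
pairs <- sprintf("7-%d", seq_along(mm_designed))
mm_table <- data.frame(pair = pairs, e_mm = mm_designed)
qm_table <- data.frame(pair = pairs,
                       e_hb = nfa_combine(gen_fragment_energies(
                         1.2 * mm_designed + 1 + resid, seed = 40)))
st <- compare_qm_mm(qm_table, mm_table)
print(st)
write.csv(data.frame(n = st$n, r = st$r, slope = st$slope, intercept = st$intercept,
                     mean_qm = st$mean_qm, sd_qm = st$sd_qm,
                     mean_mm = st$mean_mm, sd_mm = st$sd_mm),
          "results/qm_mm_comparison_demo.csv", row.names = FALSE)
cat("Tables written under results/\n")
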