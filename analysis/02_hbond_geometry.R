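#!/usr/bin/env Rscript
# Hydrogen-bond geometry of the helix series: per-pair O...H distances and
# C-O...N-H torsions, and distance statistics by positional class
# (terminal / adjacent-to-terminal / inner), with the two-pair model's
# double-counting rule. The published reference values (measured on
# dihedral-constrained DFT-relaxed structures) are 2.05 +/- 0.04 A for the
# 3_10 series, 2.30 +/- 0.07 A for the alpha series, and 2.08 +/- 0.03 A
# for the 3_10 adjacent class; the ideal-geometry surrogates built here are
# systematically tighter (see the methods vignette).

library(helixhb)

dir.create("results", showWarnings = FALSE)

gs310 <- summarize_geometry(lapply(2:7, build_helix, helix = "310"), offset = 3)
gsa <- summarize_geometry(lapply(3:8, build_helix, helix = "alpha"), offset = 4)

write.csv(gs310$per_pair, "results/hbond_geometry_310.csv", row.names = FALSE)
write.csv(gsa$per_pair, "results/hbond_geometry_alpha.csv", row.names = FALSE)
both <- rbind(cbind(helix = "3_10", gs310$by_class),
              cbind(helix = "alpha", gsa$by_class))
write.csv(both, "results/hbond_distance_by_class.csv", row.names = FALSE)

cat("O...H distance statistics (mean +/- population sd, Angstrom):\n")
print(transform(both, mean_A = round(mean_A, 3), sd_A = round(sd_A, 3)))
cat(sprintf("\n3_10 overall: %.3f A (reference 2.05); alpha overall: %.3f A (reference 2.30)\n",
            gs310$by_class$mean_A[gs310$by_class$group == "all"],
            gsa$by_class$mean_A[gsa$by_class$group == "all"]))
cat("Ideal-geometry helices are perfectly screw-symmetric, so per-class spreads\n")
cat("are near zero and the adjacent-class lengthening seen on relaxed structures\n")
cat("does not appear; tables written under results/\n")
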