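#!/usr/bin/env Rscript

# Accuracy of the slopes versus iterative absolute-property recovery at
# correct distances, over the 3 x 3 optical-property grid and both distance
# sets. Writes results/table1_method_accuracy.csv.
#
# Findings: the slopes method carries a +2..+11% absorption bias (worst at
# low absorption) and a -1..-14% scattering bias; the iterative method
# recovers absorption to <0.05% while its scattering bias follows -mua/musp
# (the data-generating model's absorption-independent diffusion coefficient
# versus the inversion's mua+musp convention).

library(dsoptode)

dir.create("results", showWarnings = FALSE)
t1 <- run_table("T1", out_csv = "results/table1_method_accuracy.csv")
print(t1[, c("rho_set", "mua", "musp", "slopes_err_mua_printed",
             "slopes_err_musp_printed", "iterative_err_mua_printed",
             "iterative_err_musp_printed")], row.names = FALSE)

cat(sprintf(paste0(
  "\nGrand averages over all 18 cells (at printed cell precision):\n",
  "  slopes    mua %+0.1f%%  musp %+0.1f%%\n",
  "  iterative mua %+0.3f%%  musp %+0.1f%%\n"),
  mean(signif(t1$slopes_err_mua_pct, 2)),
  mean(signif(t1$slopes_err_musp_pct, 2)),
  mean(signif(t1$iterative_err_mua_pct, 2)),
  mean(signif(t1$iterative_err_musp_pct, 2))))
cat("wrote results/table1_method_accuracy.csv\n")
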