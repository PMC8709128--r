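#!/usr/bin/env Rscript
# End-to-end synthetic study: paired non-degraded/degraded WSS fields on the
# dome-on-vessel mesh -> TAWSS/OSI/ECAP -> relative changes, correlation
# product, digitization, regime classification and the inverse-correlation
# report. All artifacts land in results/pipeline/.

suppressPackageStartupMessages(library(aneuflow))
dir.create("results", showWarnings = FALSE)

res <- run_pipeline(list(seed = 1, resolution = 32), "results/pipeline")

cmp <- res$comparison
rep <- res$report
cat(sprintf("Aneurysm-region nodes compared: %d (masked: %d)\n",
            rep$n_nodes, rep$n_masked))
cat(sprintf("Overall inverse-correlation fraction: %.3f\n",
            rep$overall_inverse_fraction))
print(rep$by_regime)
cat(sprintf("Mean ECAP change in the low-TAWSS/high-OSI regime: %+.1f%%\n",
            rep$mean_dECAP_lowT_highO))
cat("\nRegime summary (see results/pipeline/regime_summary.csv):\n")
print(summarize_regimes(cmp))
cat("\nInterpretation: in the low-shear, oscillatory region degradation\n",
    "lowers TAWSS while raising OSI (digitized product -1), so ECAP rises\n",
    "exactly where the wall is already most vulnerable.\n", sep = "")
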