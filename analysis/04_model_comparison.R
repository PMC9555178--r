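#!/usr/bin/env Rscript
# Compare the two fitted models by DIC (conditional on frailties) and
# LPML, and record the selection.

library(scrAFT)

fits <- readRDS("results/fits.rds")
ds <- fits$dataset

rep_ln <- comparison_entry("lognormal", fits$lognormal, ds)
rep_dp <- comparison_entry("dpm", fits$dpm, ds)
sel <- select_model(list(rep_ln, rep_dp))

cat(sprintf("log-normal: DIC = %.1f (pD = %.1f), LPML = %.1f\n",
            rep_ln$DIC, rep_ln$pD, rep_ln$LPML))
cat(sprintf("DPM:        DIC = %.1f (pD = %.1f), LPML = %.1f\n",
            rep_dp$DIC, rep_dp$pD, rep_dp$LPML))
cat("selected:", sel$selected,
    if (sel$dic_lpml_disagree) "(DIC and LPML disagree; DIC governs)" else "",
    "\n")

jsonlite::write_json(
  list(table = sel$table, selected = sel$selected,
       dic_lpml_disagree = sel$dic_lpml_disagree),
  "results/model_comparison.json", auto_unbox = TRUE, digits = NA)
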