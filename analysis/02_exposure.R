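#!/usr/bin/env Rscript
# Stage 2: exposure fate. Measured diquat against nominal applications at
# 1 h, first-order dissipation per treatment, and detection-limit status
# three weeks after dosing.

suppressMessages(library(mesotox))

ds <- suppressWarnings(read_dataset("results/dataset"))
res <- run_pipeline(ds, stages = "chemistry", seed = 1)

s <- res$chemistry$summary
cat(sprintf("Measured diquat at 1 h: %.1f +/- %.1f%% of nominal (n = %d, range %.1f-%.1f%%)\n",
            s$mean_pct_nominal, s$se_pct_nominal, s$n, s$min_pct, s$max_pct))
print(res$chemistry$dissipation)
cat("Detection status at day 21 (tanks detected vs below 5 ug/L):\n")
print(res$chemistry$detection_day21)

write_results(list(fate_summary = s,
                   dissipation_fits = res$chemistry$dissipation,
                   detection_day21 = res$chemistry$detection_day21),
              "results/exposure", seed = 1)
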