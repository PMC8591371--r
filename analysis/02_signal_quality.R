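#!/usr/bin/env Rscript
# Signal quality of the simulated runs: temporal SNR per region and
# coherence at the stimulation frequency (one movie/darkness cycle = 1/60 s),
# thresholded at the study's 0.35 level.
#
# Reads results/data; writes results/signal_quality.tsv

library(fvconn)

design <- run_design()
spec <- coherence_spec(f0 = 1 / 60, threshold = 0.35)

rows <- list()
for (f in list.files("results/data", pattern = "bold_run1\\.tsv$",
                     full.names = TRUE)) {
  x <- read_timeseries(f)
  subj <- sub("_bold_run1\\.tsv$", "", basename(f))
  ts_tsnr <- apply(x, 2, tsnr)
  coh <- apply(x, 2, function(col)
    as.numeric(coherence_at_f0(col, spec, tr = design$tr)))
  rows[[subj]] <- data.frame(
    subject = subj, region_id = colnames(x),
    tsnr = as.numeric(ts_tsnr), coherence = coh,
    stimulus_locked = coh > spec$threshold, stringsAsFactors = FALSE)
  cat(sprintf("%s: median tSNR %.1f, %d/%d regions coherent at > %.2f\n",
              subj, median(ts_tsnr), sum(coh > spec$threshold), length(coh),
              spec$threshold))
}
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.table(out, "results/signal_quality.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
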