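#!/usr/bin/env Rscript
# Build the two network families: free-viewing functional networks (MODWT
# levels 2-3, absolute Pearson correlation, BH-FDR at q = 0.01) and
# structural networks (streamline counts filtered at n > 10, log10-scaled).
#
# Reads results/data; writes results/networks/

library(fvconn)

out <- "results/networks"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
wav <- wavelet_spec()  # Daubechies d4, 5 levels, keep 2-3

subjects <- unique(sub("_.*$", "", list.files("results/data", pattern = "^subj")))
for (subj in subjects) {
  # functional networks are per-scan, as in the study; the first repetition
  # defines the subject's average free-viewing network
  x <- read_timeseries(file.path("results/data",
                                 paste0(subj, "_bold_run1.tsv")))
  cm <- correlation_matrix(x, wavelet = wav, tr = 1.5)
  thr <- fdr_threshold(cm, q = 0.01)
  write_conn_matrix(thr$weighted, file.path(out, paste0(subj, "_fv.tsv")))
  write_conn_matrix(thr$binary, file.path(out, paste0(subj, "_fv_bin.tsv")))

  cts <- read_conn_matrix(file.path("results/data", paste0(subj, "_counts.tsv")),
                          kind = "structural")
  sm <- structural_matrix(cts$values, min_streamlines = 10)
  write_conn_matrix(sm$weighted, file.path(out, paste0(subj, "_sc.tsv")))
  write_conn_matrix(sm$binary, file.path(out, paste0(subj, "_sc_bin.tsv")))

  cat(sprintf("%s: functional density %.3f, structural density %.3f\n", subj,
              network_density(thr$binary)$global,
              network_density(sm$binary)$global))
}
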