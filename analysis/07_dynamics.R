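#!/usr/bin/env Rscript
# Time-varying connectivity: MTD over 18 s windows, epoch-averaged scene
# states (averaged over the two scan repetitions), windowed centrality
# traces, per-scene hub sets (c > 1e-4, z > 1), Jaccard overlaps, and the
# poly-functional regions, checked against the planted hubs.
#
# Reads results/data; writes results/dynamics/

library(fvconn)

out <- "results/dynamics"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
design <- run_design()
epochs <- read_epochs("results/data/epochs.tsv")
truth <- jsonlite::read_json("results/data/truth.json", simplifyVector = TRUE)
labs <- epochs$label

subjects <- unique(sub("_.*$", "",
                       list.files("results/data", pattern = "bold")))
poly_all <- list()
for (subj in subjects) {
  states <- NULL
  for (r in 1:2) {
    x <- read_timeseries(file.path("results/data",
                                   sprintf("%s_bold_run%d.tsv", subj, r)))
    tens <- mtd(x, w = 12, tr = design$tr)
    if (r == 1) {
      tr_ec <- windowed_centrality(tens)
      write.table(round(tr_ec, 8),
                  file.path(out, paste0(subj, "_centrality_trace.tsv")),
                  sep = "\t", quote = FALSE, col.names = FALSE)
    }
    st <- epoch_average(tens, epochs)
    if (is.null(states)) states <- st
    else for (l in labs) states[[l]]$matrix <- states[[l]]$matrix + st[[l]]$matrix
  }
  for (l in labs) states[[l]]$matrix <- states[[l]]$matrix / 2
  cmp <- state_hub_comparison(states, z_cutoff = 1, ec_cutoff = 1e-4)
  for (l in labs) {
    planted <- unlist(truth$epoch_hubs[[l]])
    cat(sprintf("%s %-12s hubs: %-40s planted recovered: %s\n", subj, l,
                paste(cmp$hubs[[l]], collapse = " "),
                all(planted %in% cmp$hubs[[l]])))
    write_conn_matrix(states[[l]]$matrix - diag(diag(states[[l]]$matrix)),
                      file.path(out, sprintf("%s_state_%s.tsv", subj, l)))
  }
  write.table(round(cmp$jaccard, 4),
              file.path(out, paste0(subj, "_jaccard.tsv")),
              sep = "\t", quote = FALSE)
  jsonlite::write_json(cmp$hubs, file.path(out, paste0(subj, "_hubs.json")),
                       pretty = TRUE)
  poly_all[[subj]] <- cmp$poly_functional
  cat(sprintf("%s poly-functional: %s\n", subj,
              paste(cmp$poly_functional, collapse = " ")))
}
jsonlite::write_json(poly_all, file.path(out, "poly_functional.json"),
                     pretty = TRUE)
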