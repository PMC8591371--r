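#!/usr/bin/env Rscript
# Eigenvector-centrality hubs of the free-viewing networks (EC > 14e-3 and
# z > 1, the study's static thresholds) and the rank-centrality summary
# across subjects, grouped by the structural modules.
#
# Reads results/networks + results/modules.tsv;
# writes results/hubs_static.json, results/rank_centrality.tsv

library(fvconn)

parc <- read_parcellation("results/data/parcellation.tsv")
modules <- read.delim("results/modules.tsv")
parc$module <- modules$module[match(parc$region_id, modules$region_id)]

subjects <- unique(sub("_.*$", "", list.files("results/networks")))
cents <- list(); hubs <- list()
for (subj in subjects) {
  w <- read_conn_matrix(file.path("results/networks", paste0(subj, "_fv.tsv")))
  cents[[subj]] <- eigenvector_centrality(w)
  hubs[[subj]] <- detect_hubs(cents[[subj]], z_cutoff = 1, ec_cutoff = 14e-3)
  cat(sprintf("%s: lambda %.3f, %d hubs: %s\n", subj, cents[[subj]]$lambda,
              length(hubs[[subj]]), paste(hubs[[subj]], collapse = " ")))
}

summ <- rank_centrality_summary(cents, parc)
write.table(summ, "results/rank_centrality.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
jsonlite::write_json(hubs, "results/hubs_static.json", pretty = TRUE)
cat("top regions by mean centrality:\n")
print(head(summ, 8))
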