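#!/usr/bin/env Rscript
# Structure-function comparison: Spearman similarity between every pair of
# matrices (intersubject-structural, intersubject-functional,
# intrasubject-cross-modal blocks) and the node-level structure-function
# correlation with an OLS fit and 95% prediction interval.
#
# Reads results/networks; writes results/similarity.tsv,
# results/structure_function.json

library(fvconn)

subjects <- unique(sub("_.*$", "", list.files("results/networks")))
sc <- lapply(subjects, function(s)
  read_conn_matrix(file.path("results/networks", paste0(s, "_sc.tsv")),
                   kind = "structural"))
fv <- lapply(subjects, function(s)
  read_conn_matrix(file.path("results/networks", paste0(s, "_fv.tsv")),
                   kind = "functional"))

sim <- matrix_similarity(c(sc, fv), labels = rep(subjects, 2))
write.table(sim$pairs, "results/similarity.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (blk in unique(sim$pairs$block)) {
  r <- sim$pairs$rho[sim$pairs$block == blk]
  cat(sprintf("%-28s rho range %.2f-%.2f (n = %d)\n", blk, min(r), max(r),
              length(r)))
}

avg_sc <- Reduce(`+`, lapply(sc, `[[`, "values")) / length(sc)
avg_fv <- Reduce(`+`, lapply(fv, `[[`, "values")) / length(fv)
nsf <- node_structure_function(avg_sc, avg_fv)
cat(sprintf("pooled structure-function Spearman rho: %.3f\n", nsf$pooled_rho))
jsonlite::write_json(
  list(pooled_rho = nsf$pooled_rho,
       per_node_rho_median = median(nsf$per_node, na.rm = TRUE),
       fit_slope = unname(coef(nsf$fit)[2]),
       fit_intercept = unname(coef(nsf$fit)[1])),
  "results/structure_function.json", auto_unbox = TRUE, digits = NA)
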