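# TSV readers/writers (17 significant digits, so write/read round-trips are
# bit-stable), analysis configuration, and the pipeline driver.

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Write / read a square connectivity matrix as TSV
#'
#' Header row and first column carry the region ids; numeric cells are
#' written with 17 significant digits so a write/read round-trip reproduces
#' the doubles exactly.
#'
#' @param conn `fv_conn` or matrix.
#' @param path file path.
#' @export
write_conn_matrix <- function(conn, path) {
  a <- conn_values(conn)
  ids <- rownames(a)
  if (is.null(ids)) ids <- paste0("n", seq_len(nrow(a)))
  lines <- c(paste(c("region_id", ids), collapse = "\t"),
             vapply(seq_len(nrow(a)), function(i)
               paste(c(ids[i], fmt_num(a[i, ])), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  if (inherits(conn, "fv_conn") && !is.null(conn$pvalues)) {
    p <- conn$pvalues
    plines <- c(paste(c("region_id", ids), collapse = "\t"),
                vapply(seq_len(nrow(p)), function(i)
                  paste(c(ids[i], fmt_num(p[i, ])), collapse = "\t"),
                  character(1)))
    writeLines(plines, sub("\\.tsv$", ".pvals.tsv", path))
  }
  invisible(path)
}

#' @rdname write_conn_matrix
#' @param kind,weighted provenance restored on read.
#' @return [read_conn_matrix()] returns an `fv_conn`.
#' @export
read_conn_matrix <- function(path, kind = "functional", weighted = TRUE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m))
    stop_invalid("matrix in ", path, " is not square (", nrow(m), " x ", ncol(m), ")")
  if (anyDuplicated(ids))
    stop_invalid("duplicated region id in ", path, ": ",
                 ids[duplicated(ids)][1])
  if (!identical(ids, colnames(m))) {
    bad <- which(ids != colnames(m))[1]
    stop_invalid("header/column id mismatch in ", path, " at position ", bad,
                 ": '", colnames(m)[bad], "' vs '", ids[bad], "'")
  }
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    stop_invalid("NaN/NA cell in ", path, " at row ", idx[1], ", column ", idx[2])
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(ids, ids)
  conn_matrix(m, kind = kind, weighted = weighted)
}

#' Write / read a parcellation table (TSV)
#' @param parcellation an `fv_parcellation`.
#' @param path file path.
#' @export
write_parcellation <- function(parcellation, path) {
  df <- as.data.frame(parcellation)
  df$x_mm <- fmt_num(df$x_mm); df$y_mm <- fmt_num(df$y_mm); df$z_mm <- fmt_num(df$z_mm)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_parcellation
#' @export
read_parcellation <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_id", "hemisphere", "x_mm", "y_mm", "z_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_invalid("parcellation misses column(s): ",
                                 paste(miss, collapse = ", "))
  class(df) <- c("fv_parcellation", "data.frame")
  df
}

#' Write / read a regional time-series table (TSV, header = region ids)
#' @param runset `fv_bold_runset` or T x N matrix.
#' @param path file path.
#' @export
write_timeseries <- function(runset, path) {
  x <- if (inherits(runset, "fv_bold_runset")) runset$data else runset
  lines <- c(paste(colnames(x), collapse = "\t"),
             vapply(seq_len(nrow(x)), function(i)
               paste(fmt_num(x[i, ]), collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_timeseries
#' @export
read_timeseries <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  as.matrix(df)
}

#' Write / read epoch annotations (TSV: label, onset_s, offset_s)
#' @param epochs data.frame.
#' @param path file path.
#' @export
write_epochs <- function(epochs, path) {
  write.table(epochs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("label", "onset_s", "offset_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop_invalid("epochs file misses column(s): ",
                                 paste(miss, collapse = ", "))
  df
}

#' Analysis configuration
#'
#' Bundles every tunable of the pipeline. Defaults equal the study's stated
#' values wherever it states one: FDR q = 0.01, streamline cutoff n > 10,
#' MTD window 12 samples, hub z > 1 with static EC > 14e-3 and dynamic
#' c > 1e-4, coherence threshold 0.35.
#'
#' @param out_dir output directory.
#' @param seed master seed; per-stage seeds derive from it.
#' @param n_per_hemisphere,n_modules synthetic cohort geometry.
#' @param n_subjects simulated subjects.
#' @param wavelet an [wavelet_spec()].
#' @param fdr_q FDR level for functional edges.
#' @param min_streamlines strict streamline cutoff.
#' @param mtd_window MTD window, samples.
#' @param z_cutoff,ec_cutoff_static,ec_cutoff_dynamic hub thresholds.
#' @param coherence_threshold stimulus-locking cutoff.
#' @param gamma_grid,consensus_samples consensus sweep settings.
#' @param n_rewires degree-preserving null rewires per edge.
#' @param epochs_file optional path to an epochs TSV; `NULL` uses the
#'   generator's default scene epochs, `NA` disables the dynamics stage.
#' @return list of class `fv_config`.
#' @export
analysis_config <- function(out_dir = "results/pipeline", seed = 1L,
                            n_per_hemisphere = 92, n_modules = 6,
                            n_subjects = 2,
                            wavelet = wavelet_spec(),
                            fdr_q = 0.01, min_streamlines = 10,
                            mtd_window = 12,
                            z_cutoff = 1, ec_cutoff_static = 14e-3,
                            ec_cutoff_dynamic = 1e-4,
                            coherence_threshold = 0.35,
                            gamma_grid = exp(seq(log(0.5), log(2),
                                                 length.out = 40)),
                            consensus_samples = 5,
                            n_rewires = 10,
                            epochs_file = NULL) {
  structure(as.list(environment()), class = "fv_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override [analysis_config()] defaults; any path field is
#' checked for existence at load.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return `fv_config`.
#' @export
read_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_state("yaml package unavailable; use a JSON config")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- analysis_config()
  for (nm in names(raw)) cfg[[nm]] <- raw[[nm]]
  if (!is.null(cfg$epochs_file) && !is.na(cfg$epochs_file) &&
      !file.exists(cfg$epochs_file))
    stop_invalid("epochs_file does not exist: ", cfg$epochs_file)
  cfg
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages: simulate -> functional connectivity (MODWT + |r| + FDR) ->
#' structural networks -> graph measures with rewired nulls -> consensus
#' modularity -> centrality and hubs -> dynamics (MTD, epoch states, state
#' hubs) -> structure-function comparison. Deterministic given the config
#' seed; every matrix is written as TSV and a manifest JSON records all
#' parameters, seeds, the package version and output checksums (no
#' timestamps, so reruns are byte-identical).
#'
#' @param config an [analysis_config()].
#' @return (invisibly) the manifest list; outputs under `config$out_dir`.
#' @export
run_pipeline <- function(config = analysis_config()) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("fvconn")),
                   parameters = cfg[setdiff(names(cfg),
                                            c("wavelet", "gamma_grid", "out_dir"))],
                   wavelet = unclass(cfg$wavelet),
                   gamma_grid = range(cfg$gamma_grid),
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(status = "ok")
    res
  }

  # -- simulate ------------------------------------------------------------
  parc <- stage("simulate", {
    p <- generate_parcellation(cfg$n_per_hemisphere, cfg$n_modules,
                               seed = child_seed(cfg$seed, 1))
    write_parcellation(p, file.path(cfg$out_dir, "parcellation.tsv"))
    p
  })
  design <- run_design()
  epochs <- if (is.null(cfg$epochs_file)) default_epochs(design)
            else if (is.na(cfg$epochs_file)) NULL
            else read_epochs(cfg$epochs_file)
  hubs_by_epoch <- list()
  if (!is.null(epochs)) {
    # one shared hub plus one unique hub per scene, planted bilaterally
    labs <- unique(epochs$label)
    shared <- parc$region_id[1]
    uniq <- parc$region_id[1 + seq_along(labs)]
    hubs_by_epoch <- stats::setNames(
      lapply(seq_along(labs), function(i) c(shared, uniq[i])), labs)
  }
  truth <- planted_truth(parc, epoch_hubs = hubs_by_epoch)
  subjects <- paste0("subj", seq_len(cfg$n_subjects))

  runsets <- list(); counts <- list()
  for (i in seq_along(subjects)) {
    runsets[[i]] <- generate_bold(parc, design, truth,
                                  epochs = if (is.null(epochs)) data.frame(
                                    label = character(), onset_s = numeric(),
                                    offset_s = numeric()) else epochs,
                                  seed = child_seed(cfg$seed, 10 + i))
    counts[[i]] <- generate_structural_counts(parc,
                                              seed = child_seed(cfg$seed, 20 + i))
    write_timeseries(runsets[[i]],
                     file.path(cfg$out_dir, paste0(subjects[i], "_bold.tsv")))
    write_conn_matrix(counts[[i]],
                      file.path(cfg$out_dir, paste0(subjects[i], "_counts.tsv")))
  }
  if (!is.null(epochs)) write_epochs(epochs, file.path(cfg$out_dir, "epochs.tsv"))

  # -- connectivity --------------------------------------------------------
  func <- stage("connectivity", {
    lapply(seq_along(subjects), function(i) {
      cm <- correlation_matrix(runsets[[i]], wavelet = cfg$wavelet)
      thr <- fdr_threshold(cm, q = cfg$fdr_q)
      write_conn_matrix(thr$weighted,
                        file.path(cfg$out_dir, paste0(subjects[i], "_fv.tsv")))
      write_conn_matrix(thr$binary,
                        file.path(cfg$out_dir, paste0(subjects[i], "_fv_bin.tsv")))
      thr
    })
  })

  # -- structure -----------------------------------------------------------
  struct <- stage("structure", {
    lapply(seq_along(subjects), function(i) {
      sm <- structural_matrix(counts[[i]], min_streamlines = cfg$min_streamlines)
      write_conn_matrix(sm$weighted,
                        file.path(cfg$out_dir, paste0(subjects[i], "_sc.tsv")))
      write_conn_matrix(sm$binary,
                        file.path(cfg$out_dir, paste0(subjects[i], "_sc_bin.tsv")))
      sm
    })
  })

  # -- measures ------------------------------------------------------------
  measures <- stage("measures", {
    out <- lapply(seq_along(subjects), function(i) {
      res <- list()
      for (net in c("fv", "sc")) {
        b <- if (net == "fv") func[[i]]$binary else struct[[i]]$binary
        dens <- network_density(b, parc)
        cc <- clustering_coefficient(b)
        null_cc <- clustering_coefficient(
          rewire_degree_preserving(b, cfg$n_rewires,
                                   seed = child_seed(cfg$seed, 30 + i)))
        res[[net]] <- list(density = dens, clustering_mean = cc$mean,
                           clustering_null_mean = null_cc$mean,
                           path_length = characteristic_path_length(b)$L,
                           degree_range = range(degree_ccdf(b)$degree))
      }
      res
    })
    jsonlite::write_json(out, file.path(cfg$out_dir, "measures.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    out
  })

  # -- modules -------------------------------------------------------------
  consensus <- stage("modules", {
    avg_sc <- Reduce(`+`, lapply(struct, function(s) s$weighted$values)) /
      length(struct)
    cons <- multiresolution_consensus(avg_sc, gamma_grid = cfg$gamma_grid,
                                      n_samples_per_gamma = cfg$consensus_samples,
                                      seed = child_seed(cfg$seed, 40))
    write.table(data.frame(region_id = names(cons$assignment),
                           module = cons$assignment),
                file.path(cfg$out_dir, "modules.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_conn_matrix(cons$coassignment,
                      file.path(cfg$out_dir, "coassignment.tsv"))
    cons
  })

  # -- centrality ----------------------------------------------------------
  centr <- stage("centrality", {
    cents <- lapply(func, function(f) eigenvector_centrality(f$weighted))
    hubs <- lapply(cents, detect_hubs, z_cutoff = cfg$z_cutoff,
                   ec_cutoff = cfg$ec_cutoff_static)
    summ <- rank_centrality_summary(cents, parc)
    write.table(summ, file.path(cfg$out_dir, "rank_centrality.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(stats::setNames(hubs, subjects),
                         file.path(cfg$out_dir, "hubs_static.json"),
                         auto_unbox = FALSE, pretty = TRUE)
    list(cents = cents, hubs = hubs, summary = summ)
  })

  # -- dynamics ------------------------------------------------------------
  dyn <- NULL
  if (is.null(epochs)) {
    manifest$stages$dynamics <- list(status = "skipped",
                                     reason = "no epochs available")
  } else {
    dyn <- stage("dynamics", {
      lapply(seq_along(subjects), function(i) {
        tens <- mtd(runsets[[i]], w = cfg$mtd_window)
        states <- epoch_average(tens, epochs)
        cmp <- state_hub_comparison(states, z_cutoff = cfg$z_cutoff,
                                    ec_cutoff = cfg$ec_cutoff_dynamic)
        for (lab in names(states))
          write_conn_matrix(states[[lab]]$matrix - diag(diag(states[[lab]]$matrix)),
                            file.path(cfg$out_dir,
                                      paste0(subjects[i], "_state_", lab, ".tsv")))
        jsonlite::write_json(cmp$hubs,
                             file.path(cfg$out_dir,
                                       paste0(subjects[i], "_hubs_dynamic.json")),
                             auto_unbox = FALSE, pretty = TRUE)
        cmp
      })
    })
  }

  # -- compare -------------------------------------------------------------
  stage("compare", {
    mats <- c(lapply(struct, function(s) s$weighted),
              lapply(func, function(f) f$weighted))
    sim <- matrix_similarity(mats, labels = rep(subjects, 2))
    write.table(sim$pairs, file.path(cfg$out_dir, "similarity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    avg_s <- Reduce(`+`, lapply(struct, function(s) s$weighted$values)) /
      length(struct)
    avg_f <- Reduce(`+`, lapply(func, function(f) f$weighted$values)) /
      length(func)
    nsf <- node_structure_function(avg_s, avg_f)
    jsonlite::write_json(list(pooled_rho = nsf$pooled_rho),
                         file.path(cfg$out_dir, "structure_function.json"),
                         auto_unbox = TRUE, digits = NA)
    sim
  })

  files <- sort(setdiff(list.files(cfg$out_dir), "manifest.json"))
  manifest$outputs <- lapply(stats::setNames(files, files), function(f)
    unname(tools::md5sum(file.path(cfg$out_dir, f))))
  manifest$n_modules_found <- length(unique(consensus$assignment))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
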