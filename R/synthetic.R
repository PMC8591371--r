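#' Generate a bilateral parcellation with spatially contiguous modules
#'
#' Emulates a D99-style bilateral cortical parcellation: `n_per_hemisphere`
#' regions per hemisphere, mirrored across the midline (x negated), grouped
#' into `n_modules` bilateral modules. Regions of a module are scattered
#' around a module centroid so that modules are spatially contiguous and the
#' distance-decay of structural connectivity and the modular architecture are
#' mutually consistent, as in real cortex.
#'
#' Coordinates are in mm on a macaque-scale bounding box (|x| up to ~30 mm).
#'
#' @param n_per_hemisphere regions per hemisphere (the study's atlas has 92).
#' @param n_modules number of bilateral modules (the study identifies six).
#' @param seed integer seed.
#' @param scatter_mm within-module coordinate scatter (sd, mm).
#' @return a `data.frame` of class `fv_parcellation` with columns
#'   `region_id`, `hemisphere` ("L"/"R"), `x_mm`, `y_mm`, `z_mm`, `module`.
#' @export
generate_parcellation <- function(n_per_hemisphere, n_modules, seed = 1L,
                                  scatter_mm = 4) {
  if (!is_count(n_per_hemisphere) || n_per_hemisphere < 1)
    stop_invalid("n_per_hemisphere must be a positive integer")
  if (!is_count(n_modules) || n_modules < 1)
    stop_invalid("n_modules must be a positive integer")
  if (n_per_hemisphere < n_modules)
    stop_invalid("need n_per_hemisphere >= n_modules")
  set.seed(as.integer(seed))

  # Module centroids in the right hemisphere; kept well separated by
  # rejection sampling on minimum pairwise distance.
  centroids <- matrix(NA_real_, n_modules, 3)
  min_sep <- if (n_modules > 1) 16 else 0
  k <- 0L
  tries <- 0L
  while (k < n_modules) {
    cand <- c(runif(1, 8, 28), runif(1, -38, 22), runif(1, -14, 16))
    ok <- k == 0L ||
      min(sqrt(colSums((t(centroids[seq_len(k), , drop = FALSE]) - cand)^2))) >= min_sep
    tries <- tries + 1L
    if (tries > 2000L) {  # crowded box: relax separation rather than spin
      min_sep <- min_sep * 0.9
      tries <- 0L
    }
    if (ok) {
      k <- k + 1L
      centroids[k, ] <- cand
    }
  }

  # Round-robin module sizes, then scatter regions about their centroid.
  module <- rep(seq_len(n_modules), length.out = n_per_hemisphere)
  module <- sort(module)
  xyz <- centroids[module, , drop = FALSE] +
    matrix(rnorm(3 * n_per_hemisphere, sd = scatter_mm), ncol = 3)
  xyz[, 1] <- abs(xyz[, 1]) + 1  # stay in the right hemisphere (x > 0)

  ids <- sprintf("roi%03d", seq_len(n_per_hemisphere))
  right <- data.frame(
    region_id = paste0(ids, "_R"), hemisphere = "R",
    x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
    module = module, stringsAsFactors = FALSE
  )
  left <- right
  left$region_id <- paste0(ids, "_L")
  left$hemisphere <- "L"
  left$x_mm <- -right$x_mm
  parc <- rbind(left, right)
  rownames(parc) <- NULL
  stopifnot(!anyDuplicated(parc$region_id), all(is.finite(as.matrix(parc[, 3:5]))))
  class(parc) <- c("fv_parcellation", "data.frame")
  parc
}

#' Pairwise Euclidean distances between region centers (mm)
#' @param parcellation an `fv_parcellation`
#' @return symmetric N x N matrix, mm
#' @export
region_distances <- function(parcellation) {
  as.matrix(dist(as.matrix(parcellation[, c("x_mm", "y_mm", "z_mm")])))
}

#' Generate a streamline-count matrix with distance decay
#'
#' Expected count for pair (i, j) is
#' `base_count * exp(-d_ij / lambda_mm)`, multiplied by `interhemi_penalty`
#' for cross-hemisphere pairs (fewer long callosal streamlines) and by
#' `within_module_gain` for same-module pairs; the realized count is a
#' Poisson draw, symmetrized, zero diagonal.
#'
#' For cross-hemisphere pairs the decay uses the *mirrored* distance (the
#' distance after reflecting one region across the midline): callosal
#' fibres run predominantly homotopically, so mirror-image locations are
#' effectively close even though their Euclidean separation is large. This
#' keeps bilateral modules coherent while different-module interhemispheric
#' counts stay sparse — the "small number of long callosal streamlines"
#' regime of real macaque tractography. Within a hemisphere, binned mean
#' counts decay monotonically with Euclidean distance.
#'
#' The default within-module gain of 20 plants the order-of-magnitude
#' contrast between within-module and between-module streamline counts seen
#' in real connectomes, making the planted modules the dominant community
#' structure.
#'
#' @param parcellation an `fv_parcellation` (row order defines matrix order).
#' @param lambda_mm exponential length scale of the distance decay (mm).
#' @param interhemi_penalty multiplicative factor in (0, 1] applied to
#'   interhemispheric pairs.
#' @param base_count expected count at zero distance (before multipliers).
#' @param within_module_gain multiplier for same-module pairs.
#' @param seed integer seed.
#' @return integer N x N symmetric matrix with region_id dimnames.
#' @export
generate_structural_counts <- function(parcellation, lambda_mm = 7,
                                       interhemi_penalty = 0.2,
                                       base_count = 300L,
                                       within_module_gain = 20,
                                       seed = 1L) {
  if (!is.numeric(lambda_mm) || length(lambda_mm) != 1 || !is.finite(lambda_mm) && !is.infinite(lambda_mm))
    stop_invalid("lambda_mm must be a positive scalar")
  if (lambda_mm <= 0) stop_invalid("lambda_mm must be > 0")
  if (interhemi_penalty <= 0 || interhemi_penalty > 1)
    stop_invalid("interhemi_penalty must be in (0, 1]")
  if (base_count <= 0) stop_invalid("base_count must be positive")
  set.seed(as.integer(seed))

  d <- region_distances(parcellation)
  inter <- outer(parcellation$hemisphere, parcellation$hemisphere, "!=")
  # homotopic callosal routing: cross-hemisphere decay on mirrored distance
  mirrored <- parcellation
  mirrored$x_mm <- -mirrored$x_mm
  xyz <- as.matrix(parcellation[, c("x_mm", "y_mm", "z_mm")])
  xyz_m <- as.matrix(mirrored[, c("x_mm", "y_mm", "z_mm")])
  d_mirror <- sqrt(pmax(outer(rowSums(xyz_m^2), rowSums(xyz^2), "+") -
                          2 * xyz_m %*% t(xyz), 0))
  d_eff <- ifelse(inter, d_mirror, d)
  lam <- base_count * exp(-d_eff / lambda_mm)
  lam[inter] <- lam[inter] * interhemi_penalty
  same_mod <- outer(parcellation$module, parcellation$module, "==")
  lam[same_mod] <- lam[same_mod] * within_module_gain

  n <- nrow(parcellation)
  counts <- matrix(0L, n, n, dimnames = list(parcellation$region_id,
                                             parcellation$region_id))
  ut <- upper.tri(lam)
  counts[ut] <- rpois(sum(ut), lam[ut])
  counts <- counts + t(counts)
  counts
}

#' Run design (block paradigm timing)
#'
#' @param tr repetition time, s.
#' @param duration total run duration, s.
#' @param block_on stimulation (movie) block length, s.
#' @param block_off darkness block length, s.
#' @return list of class `fv_run_design` with `n_volumes = round(duration/tr)`.
#' @export
run_design <- function(tr = 1.5, duration = 300, block_on = 30, block_off = 30) {
  if (tr <= 0 || duration <= 0) stop_invalid("tr and duration must be positive")
  if (block_on <= 0 || block_off <= 0) stop_invalid("block lengths must be positive")
  structure(list(tr = tr, duration = duration, block_on = block_on,
                 block_off = block_off, n_volumes = round(duration / tr)),
            class = "fv_run_design")
}

#' Planted ground truth for the synthetic cohort
#'
#' Targets for the generator: pairwise correlation `coupling_within` inside a
#' module and `coupling_between` across modules, and per-epoch hub regions
#' that gain transient coupling (`hub_gain`) with the rest of the brain only
#' during their epoch.
#'
#' @param parcellation an `fv_parcellation`.
#' @param epoch_hubs named list: epoch label -> character vector of region_ids.
#' @param coupling_within,coupling_between correlation targets, with
#'   `0 <= coupling_between < coupling_within < 1`.
#' @param hub_gain loading (relative to noise sd) of the epoch hub latent.
#' @return list of class `fv_truth`.
#' @export
planted_truth <- function(parcellation, epoch_hubs = list(),
                          coupling_within = 0.3, coupling_between = 0.1,
                          hub_gain = 4) {
  if (coupling_between < 0 || coupling_within >= 1)
    stop_invalid("couplings must satisfy 0 <= coupling_between <= coupling_within < 1")
  if (coupling_within < coupling_between)
    stop_invalid("coupling_within must be >= coupling_between")
  bad <- setdiff(unlist(epoch_hubs), parcellation$region_id)
  if (length(bad)) stop_invalid("unknown hub region(s): ", paste(bad, collapse = ", "))
  structure(list(module_assignment = stats::setNames(parcellation$module,
                                                     parcellation$region_id),
                 epoch_hubs = epoch_hubs,
                 coupling_within = coupling_within,
                 coupling_between = coupling_between,
                 hub_gain = hub_gain),
            class = "fv_truth")
}

#' Default movie-scene epochs aligned to ON blocks
#'
#' One scene category per stimulation block: object, hand_action, ego_motion,
#' face — the study's four main scene categories.
#'
#' Scenes start at the second stimulation block by default: sliding-window
#' estimators need almost a full window of samples before their first
#' estimate, so leaving the first block scene-free gives every scene full
#' window coverage.
#'
#' @param design an `fv_run_design`.
#' @param labels epoch labels, assigned to consecutive ON blocks.
#' @param start_block 1-based index of the first ON block carrying a scene.
#' @return data.frame with columns `label`, `onset_s`, `offset_s`.
#' @export
default_epochs <- function(design,
                           labels = c("object", "hand_action", "ego_motion", "face"),
                           start_block = 2) {
  cycle <- design$block_on + design$block_off
  onsets <- seq(0, design$duration - design$block_on, by = cycle)
  onsets <- onsets[onsets >= (start_block - 1) * cycle]
  onsets <- onsets[seq_len(min(length(onsets), length(labels)))]
  data.frame(label = labels[seq_along(onsets)],
             onset_s = onsets, offset_s = onsets + design$block_on,
             stringsAsFactors = FALSE)
}

#' Generate a block-designed BOLD run with planted modules and epoch hubs
#'
#' Each region's series is the sum of:
#' \itemize{
#'   \item a global latent plus a module latent, scaled so same-module pairs
#'     reach correlation `coupling_within` and different-module pairs
#'     `coupling_between` in expectation;
#'   \item a stimulus response: the ON/OFF boxcar convolved with a
#'     gamma-variate HRF, amplitude `stim_amplitude * noise_sd`;
#'   \item white noise with sd `noise_sd`;
#'   \item during each epoch, an additive shared latent loaded at
#'     `hub_gain * noise_sd` on that epoch's hub regions and at a quarter
#'     of that on every other region, transiently raising the hubs'
#'     coupling with the whole brain. The burst of shared variance is what
#'     derivative-based dynamic connectivity estimators respond to.
#' }
#'
#' @param parcellation an `fv_parcellation`.
#' @param design an `fv_run_design`.
#' @param truth an `fv_truth`.
#' @param epochs data.frame (label, onset_s, offset_s); may be empty.
#' @param noise_sd white-noise sd (arbitrary BOLD units), > 0.
#' @param stim_amplitude stimulus response amplitude in units of `noise_sd`.
#' @param baseline additive mean BOLD level.
#' @param seed integer seed.
#' @return list of class `fv_bold_runset` with fields `data` (T x N matrix,
#'   columns in parcellation order), `design`, `parcellation`, `epochs`,
#'   `truth`, `seed`.
#' @export
generate_bold <- function(parcellation, design = run_design(),
                          truth = planted_truth(parcellation),
                          epochs = default_epochs(design),
                          noise_sd = 1, stim_amplitude = 0.5,
                          baseline = 100, seed = 1L) {
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if ((truth$coupling_within > 0 || truth$coupling_between > 0) && noise_sd == 0)
    stop_invalid("noise_sd must be > 0 when couplings are > 0")
  if (nrow(epochs) > 0) {
    ep <- epochs[order(epochs$onset_s), ]
    if (any(ep$offset_s <= ep$onset_s) || any(ep$onset_s < 0) ||
        any(ep$offset_s > design$duration))
      stop_invalid("epochs must be non-empty intervals within [0, duration]")
    if (nrow(ep) > 1 && any(ep$onset_s[-1] < ep$offset_s[-nrow(ep)]))
      stop_invalid("epochs must be non-overlapping")
  }
  set.seed(as.integer(seed))

  n <- nrow(parcellation)
  tt <- design$n_volumes
  cw <- truth$coupling_within
  cb <- truth$coupling_between

  # Variance budget: total non-stimulus variance v = noise_sd^2 / (1 - cw);
  # global latent carries cb*v, module latent (cw - cb)*v, noise noise_sd^2,
  # giving the two correlation targets exactly in expectation.
  v <- if (cw > 0 || cb > 0) noise_sd^2 / (1 - cw) else noise_sd^2
  sd_global <- sqrt(cb * v)
  sd_module <- sqrt((cw - cb) * v)

  x <- matrix(rnorm(tt * n, sd = noise_sd), tt, n,
              dimnames = list(NULL, parcellation$region_id))
  if (sd_global > 0) x <- x + rnorm(tt, sd = sd_global)
  if (sd_module > 0) {
    for (m in unique(parcellation$module)) {
      idx <- which(parcellation$module == m)
      x[, idx] <- x[, idx] + rnorm(tt, sd = sd_module)
    }
  }

  # Epoch hub latents: an additive shared latent active only inside the
  # epoch, loaded at hub_gain * noise_sd on the epoch's hubs and a quarter
  # of that on every other region. The transient amplitude burst this
  # creates is what the temporal-derivative estimator keys on: its
  # couplings are normalized by the full-run derivative sd, so a burst of
  # shared variance inside an epoch yields epoch couplings well above the
  # background correlation level.
  times <- (seq_len(tt) - 1) * design$tr
  if (nrow(epochs) > 0 && length(truth$epoch_hubs) > 0 && truth$hub_gain > 0) {
    for (lab in names(truth$epoch_hubs)) {
      rows <- which(epochs$label == lab)
      if (!length(rows)) next
      active <- rep(FALSE, tt)
      for (r in rows)
        active <- active | (times >= epochs$onset_s[r] & times < epochs$offset_s[r])
      latent <- rnorm(sum(active))
      hubs <- truth$epoch_hubs[[lab]]
      load <- ifelse(parcellation$region_id %in% hubs,
                     truth$hub_gain, truth$hub_gain / 4) * noise_sd
      x[active, ] <- x[active, ] + outer(latent, load)
    }
  }

  reg <- build_block_regressor(design)$regressor
  if (max(reg) > 0) reg <- reg / max(reg)  # unit-peak evoked response
  x <- x + stim_amplitude * noise_sd * reg

  structure(list(data = x + baseline, design = design,
                 parcellation = parcellation, epochs = epochs,
                 truth = truth, seed = as.integer(seed)),
            class = "fv_bold_runset")
}
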