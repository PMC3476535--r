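## Welch-style averaged periodogram, 2 s segments with 50% overlap
.welch_psd <- function(x, fs, seg_s = 2) {
  n <- length(x)
  L <- min(n, round(seg_s * fs))
  step <- max(1L, L %/% 2)
  starts <- seq(1L, n - L + 1L, by = step)
  win <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))
  acc <- numeric(L %/% 2 + 1)
  for (s0 in starts) {
    segx <- x[s0:(s0 + L - 1L)]
    segx <- (segx - mean(segx)) * win
    sp <- Mod(stats::fft(segx))^2 / (sum(win^2) * fs)
    acc <- acc + sp[seq_len(L %/% 2 + 1)]
  }
  list(freq = (seq_len(L %/% 2 + 1) - 1) * fs / L,
       power = acc / length(starts))
}

.band_power <- function(psd, band) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  mean(psd$power[sel])
}

#' Classify an independent component
#'
#' Applies, in order: the dipole residual-variance gate (components whose
#' equivalent dipole explains less than 85 percent of the scalp-map
#' variance are rejected); the ocular rule (anterior-inferior dipole,
#' `y > 0.8 R` and `z < 0`, with 1-4 Hz power more than twice the 4-40 Hz
#' power); the muscular rule (dipole outside the brain sphere with
#' non-decreasing 40-100 Hz log spectrum); everything else is cortical.
#'
#' @param dipole A `dipole_fit`.
#' @param activation Source activation time series.
#' @param fs Sampling rate (Hz).
#' @param sphere A [sphere_model()].
#' @param rv_limit Residual-variance gate (fraction).
#' @return One of `"rejected_rv"`, `"ocular"`, `"muscular"`, `"cortical"`.
#' @export
classify_component <- function(dipole, activation, fs,
                               sphere = sphere_model(), rv_limit = 0.15) {
  if (is.null(dipole)) stop("missing dipole fit")
  if (dipole$rv > rv_limit) return("rejected_rv")
  R <- sphere$radius
  psd <- .welch_psd(as.numeric(activation), fs)
  loc <- dipole$location
  if (loc[2] > 0.8 * R && loc[3] < 0) {
    ratio <- .band_power(psd, c(1, 4)) / .band_power(psd, c(4, 40))
    if (is.finite(ratio) && ratio > 2) return("ocular")
  }
  if (sqrt(sum(loc^2)) > sphere$brain_fraction * R) {
    sel <- psd$freq >= 40 & psd$freq <= 100
    if (sum(sel) >= 3) {
      slope <- stats::coef(stats::lm(log(psd$power[sel] + 1e-300) ~
                                       psd$freq[sel]))[2]
      if (is.finite(slope) && slope > 0) return("muscular")
    }
  }
  "cortical"
}

#' Build per-component records from a mixture ICA fit
#'
#' For every model and component: the scalp map (mixing column mapped back
#' through the PCA reduction), an equivalent-dipole fit, and the artifact
#' classification based on the dipole and the component activation.
#'
#' @param fit A [mixica()] fit.
#' @param rec The `eeg_recording` the fit was computed on.
#' @param sphere A [sphere_model()].
#' @param grid Optional precomputed [dipole_grid()].
#' @param max_psd_samples Activation samples used for the spectral rules.
#' @return List of component records (class `component_record` each):
#'   `subject_id`, `model_id`, `component_index`, `scalp_map`,
#'   `positions`, `dipole`, `class`.
#' @export
component_records <- function(fit, rec, sphere = sphere_model(),
                              grid = NULL,
                              max_psd_samples = 200000) {
  stopifnot(inherits(fit, "mixica"), inherits(rec, "eeg_recording"))
  maps <- scalp_maps(fit)
  el <- rec$electrode_positions
  if (is.null(grid)) grid <- .grid_cache(el, sphere)
  x <- rec$eeg
  if (ncol(x) > max_psd_samples)
    x <- x[, round(seq(1, ncol(x), length.out = max_psd_samples))]
  acts <- predict(fit, x, type = "sources")
  recs <- list()
  for (h in seq_along(maps)) {
    for (i in seq_len(ncol(maps[[h]]))) {
      topo <- maps[[h]][, i]
      dp <- fit_dipole(topo, el, sphere, grid = grid)
      cls <- classify_component(dp, acts[[h]][i, ], rec$fs_eeg, sphere)
      recs[[length(recs) + 1]] <- structure(
        list(subject_id = rec$subject_id, model_id = h,
             component_index = i, scalp_map = topo, positions = el,
             dipole = dp, class = cls),
        class = "component_record")
    }
  }
  recs
}

## interpolate a scalp map onto a common spherical grid (inverse-distance
## weighting over the 4 nearest electrodes), unit-normalised with a
## deterministic sign
.interp_map <- function(map, positions, grid_points, n_near = 4) {
  g <- matrix(0, nrow(grid_points), 1)
  for (p in seq_len(nrow(grid_points))) {
    d <- sqrt(colSums((t(positions) - grid_points[p, ])^2))
    o <- order(d)[seq_len(min(n_near, length(d)))]
    w <- 1 / (d[o] + 1e-6)^2
    g[p] <- sum(w * map[o]) / sum(w)
  }
  v <- as.numeric(g)
  v <- v / sqrt(sum(v^2))
  if (v[which.max(abs(v))] < 0) v <- -v
  v
}

#' Cluster cortical components across subjects
#'
#' k-means on feature vectors combining equivalent-dipole locations and
#' scalp-map shape: locations are z-scored per coordinate and weighted by
#' `location_weight` (default 3); scalp maps are interpolated to a common
#' 64-point spherical grid, reduced to `n_pc` principal components,
#' z-scored, and weighted 1.  Clusters containing components from at least
#' `ceiling(retain_fraction * n_subjects)` distinct subjects are marked
#' retained.
#'
#' @param records List of `component_record`s; only cortical ones are
#'   used.
#' @param k Number of clusters.
#' @param seed Integer seed (k-means restarts).
#' @param location_weight Weight of the dipole-location block.
#' @param n_pc Principal components of the interpolated scalp maps.
#' @param n_grid Size of the common interpolation grid.
#' @param retain_fraction Fraction of subjects required for retention.
#' @param n_subjects Total subjects in the study (default: distinct
#'   subjects among the records).
#' @param nstart k-means restarts.
#' @return List of `component_cluster` objects: `members` (indices into
#'   the cortical record list), `records`, `centroid` (mean dipole
#'   location), `subject_count`, `retained`.
#' @export
cluster_components <- function(records, k = 10, seed = 1,
                               location_weight = 3, n_pc = 10,
                               n_grid = 64, retain_fraction = 0.75,
                               n_subjects = NULL, nstart = 20) {
  cort <- Filter(function(r) r$class == "cortical", records)
  if (length(cort) < k)
    stop("fewer cortical components than clusters requested")
  ## canonical ordering makes the partition invariant to input order
  key <- vapply(cort, function(r)
    sprintf("%s_%03d_%03d", r$subject_id, r$model_id, r$component_index),
    character(1))
  cort <- cort[order(key)]
  if (is.null(n_subjects))
    n_subjects <- length(unique(vapply(cort, `[[`, character(1),
                                       "subject_id")))

  locs <- t(vapply(cort, function(r) r$dipole$location, numeric(3)))
  zloc <- scale(locs)
  zloc[!is.finite(zloc)] <- 0

  sph <- cort[[1]]$dipole$sphere
  gp <- electrode_layout(n_grid, sph)
  maps <- t(vapply(cort, function(r)
    .interp_map(r$scalp_map, r$positions, gp), numeric(n_grid)))
  pc <- stats::prcomp(maps, center = TRUE, scale. = FALSE)
  npc <- min(n_pc, ncol(pc$x))
  zmap <- scale(pc$x[, seq_len(npc), drop = FALSE])
  zmap[!is.finite(zmap)] <- 0

  feat <- cbind(location_weight * zloc, zmap)
  set.seed(seed)
  km <- stats::kmeans(feat, centers = k, nstart = nstart,
                      iter.max = 100)
  out <- vector("list", k)
  for (cl in seq_len(k)) {
    idx <- which(km$cluster == cl)
    subs <- unique(vapply(cort[idx], `[[`, character(1), "subject_id"))
    out[[cl]] <- structure(
      list(members = idx, records = cort[idx],
           centroid = colMeans(locs[idx, , drop = FALSE]),
           subject_count = length(subs),
           retained = length(subs) >= ceiling(retain_fraction * n_subjects)),
      class = "component_cluster")
  }
  attr(out, "inertia") <- km$tot.withinss
  attr(out, "n_subjects") <- n_subjects
  out
}

#' @export
print.component_cluster <- function(x, ...) {
  cat(sprintf(
    "Component cluster: %d members from %d subjects at (%.0f, %.0f, %.0f) mm%s\n",
    length(x$members), x$subject_count, x$centroid[1], x$centroid[2],
    x$centroid[3], if (x$retained) " [retained]" else ""))
  invisible(x)
}
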