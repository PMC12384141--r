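#' Radiomics extraction settings
#'
#' @param n_levels Number of gray levels for GLCM quantization (fixed bins
#'   over [0, 1] after min-max normalization).
#' @param window_radius Chebyshev radius of the per-voxel window; 1 gives
#'   the 3 x 3 x 3 neighbourhood.
#' @param pad_xy,pad_z Crop padding around the tumor bounding box, pixels.
#' @param margin_px In-plane peritumoral margin, pixels.
#' @return A list of class `radiomics_config`.
#' @export
radiomics_config <- function(n_levels = 32, window_radius = 1,
                             pad_xy = 30, pad_z = 10, margin_px = 5) {
  structure(list(n_levels = as.integer(n_levels),
                 window_radius = as.integer(window_radius),
                 pad_xy = as.integer(pad_xy), pad_z = as.integer(pad_z),
                 margin_px = as.integer(margin_px)),
            class = "radiomics_config")
}

#' Crop a subvolume around the tumor bounding box
#'
#' The output bounding box is the mask bounding box padded by `pad_xy`
#' pixels in x and y and `pad_z` in z, clipped to the volume extent; the
#' mask is cropped identically.
#'
#' @param volume A `ct_subvolume` or 3D array.
#' @param tumor_mask Logical 3D array, non-empty, same shape.
#' @param pad_xy,pad_z Padding in pixels.
#' @return A list with `volume` (same type as input) and `mask`.
#' @export
crop_subvolume <- function(volume, tumor_mask, pad_xy = 30, pad_z = 10) {
  arr <- as_volume_array(volume)
  assert_grid3d(tumor_mask, "mask")
  if (!any(tumor_mask)) abort("tumor mask is empty")
  if (!all(dim(arr) == dim(tumor_mask))) abort("mask shape differs from volume")
  idx <- which(tumor_mask, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - c(pad_xy, pad_xy, pad_z), 1L)
  hi <- pmin(apply(idx, 2, max) + c(pad_xy, pad_xy, pad_z), dim(arr))
  sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  msk <- tumor_mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out_vol <- if (inherits(volume, "ct_subvolume")) {
    ct_subvolume(sub, volume$spacing)
  } else {
    sub
  }
  list(volume = out_vol, mask = msk)
}

# one in-plane binary dilation step with a 3 x 3 square element
dilate_slice_once <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- m
  out[-1, ] <- out[-1, ] | m[-n1, ]
  out[-n1, ] <- out[-n1, ] | m[-1, ]
  out2 <- out
  out2[, -1] <- out2[, -1] | out[, -n2]
  out2[, -n2] <- out2[, -n2] | out[, -1]
  out2
}

#' Build the peritumoral shell by slice-wise axial dilation
#'
#' The tumor mask is dilated `margin_px` times with a 3 x 3 square element
#' in each axial (x-y) slice independently -- no growth in z, which is the
#' appropriate convention for thick-slice CT (about 5 mm slices against
#' sub-millimetre pixels). The peritumoral mask is the dilated region minus
#' the tumor, so the two are disjoint by construction.
#'
#' @param tumor_mask Logical 3D array, non-empty.
#' @param margin_px In-plane margin in pixels (>= 1).
#' @return An object of class `region_masks`: list with `tumoral`,
#'   `peritumoral`, `margin_px`.
#' @export
make_peritumoral_mask <- function(tumor_mask, margin_px = 5) {
  assert_grid3d(tumor_mask, "mask")
  if (!any(tumor_mask)) abort("tumor mask is empty")
  if (margin_px < 1) abort("margin_px must be >= 1")
  tumor_mask <- tumor_mask > 0
  dil <- tumor_mask
  for (z in seq_len(dim(tumor_mask)[3])) {
    sl <- dil[, , z]
    if (!any(sl)) next
    for (k in seq_len(margin_px)) sl <- dilate_slice_once(sl)
    dil[, , z] <- sl
  }
  structure(list(tumoral = tumor_mask,
                 peritumoral = dil & !tumor_mask,
                 margin_px = as.integer(margin_px)),
            class = "region_masks")
}

#' Min-max normalize a volume to [0, 1]
#'
#' Affine, order-preserving. A constant volume maps to all zeros (declared
#' convention for the degenerate case).
#'
#' @param volume A `ct_subvolume` or 3D array.
#' @return Same type as the input, intensities in [0, 1].
#' @export
minmax_normalize <- function(volume) {
  arr <- as_volume_array(volume)
  if (any(!is.finite(arr))) abort("volume contains non-finite intensities")
  rng <- range(arr)
  out <- if (rng[2] > rng[1]) (arr - rng[1]) / (rng[2] - rng[1]) else arr * 0
  if (inherits(volume, "ct_subvolume")) {
    volume$intensities <- out
    volume
  } else {
    out
  }
}

#' The 13 canonical symmetric distance-1 GLCM offsets
#'
#' Half of the 26 unit neighbours of a voxel; the other half is covered by
#' symmetric accumulation.
#'
#' @return A 13 x 3 integer matrix of (dx, dy, dz) offsets.
#' @export
glcm_offsets <- function() {
  matrix(c(1, 0, 0,  0, 1, 0,  0, 0, 1,
           1, 1, 0,  1, -1, 0,
           1, 0, 1,  1, 0, -1,
           0, 1, 1,  0, 1, -1,
           1, 1, 1,  1, 1, -1,  1, -1, 1,  1, -1, -1),
         ncol = 3, byrow = TRUE)
}

#' Accumulate a symmetric normalized GLCM over a window
#'
#' Counts co-occurrences of quantized levels at the given offset within the
#' window, in both directions (symmetric accumulation); pairs straddling
#' the window border are excluded. Entries are normalized to sum to 1.
#'
#' @param window 3D integer array of levels in `[0, n_levels)`.
#' @param offset Integer length-3 offset; must be one of the 13 canonical
#'   distance-1 directions (or its negation).
#' @param n_levels Number of gray levels.
#' @return An `n_levels` x `n_levels` matrix summing to 1 (all zeros if the
#'   window admits no pair at this offset).
#' @export
glcm_accumulate <- function(window, offset, n_levels) {
  assert_grid3d(window, "window")
  offset <- as.integer(offset)
  if (length(offset) != 3L || max(abs(offset)) != 1L) {
    abort("offset must be a unit-neighbourhood 3-vector")
  }
  if (any(window < 0) || any(window >= n_levels)) {
    abort("levels out of [0, n_levels) range")
  }
  d <- dim(window)
  g <- matrix(0, n_levels, n_levels)
  xs <- seq_len(d[1]); ys <- seq_len(d[2]); zs <- seq_len(d[3])
  for (z in zs) {
    pz <- z + offset[3]
    if (pz < 1 || pz > d[3]) next
    for (y in ys) {
      py <- y + offset[2]
      if (py < 1 || py > d[2]) next
      for (x in xs) {
        px <- x + offset[1]
        if (px < 1 || px > d[1]) next
        a <- window[x, y, z] + 1L
        b <- window[px, py, pz] + 1L
        g[a, b] <- g[a, b] + 1
        g[b, a] <- g[b, a] + 1
      }
    }
  }
  s <- sum(g)
  if (s > 0) g / s else g
}

#' Quantize a [0, 1] volume to discrete gray levels
#'
#' Fixed-bin quantization: level `floor(v * n_levels)` clamped to
#' `[0, n_levels - 1]`.
#'
#' @param volume A `ct_subvolume` or 3D array with values in [0, 1].
#' @param n_levels Number of levels.
#' @return Integer 3D array of levels.
#' @export
quantize_volume <- function(volume, n_levels = 32) {
  arr <- as_volume_array(volume)
  q <- floor(arr * n_levels)
  q[q < 0] <- 0
  q[q >= n_levels] <- n_levels - 1
  array(as.integer(q), dim = dim(arr))
}

#' Per-voxel 3D Haralick texture maps
#'
#' For every voxel, a local window (default 3 x 3 x 3, truncated at the
#' volume border) is scanned with the 13 symmetric distance-1 offsets; each
#' offset yields a symmetric normalized GLCM from which the 8 Haralick
#' statistics are computed, and the 13 per-offset values are averaged into
#' a single map per statistic.
#'
#' @param volume A `ct_subvolume` or 3D array, already normalized to [0, 1].
#' @param n_levels Gray levels for quantization.
#' @param window_radius Chebyshev window radius (1 = 3 x 3 x 3).
#' @return Named list of eight 3D arrays: `Energy`, `Entropy`,
#'   `InverseDifferenceMoment`, `Inertia`, `ClusterShade`,
#'   `ClusterProminence`, `Correlation`, `HaralickCorrelation`.
#' @export
haralick_maps <- function(volume, n_levels = 32, window_radius = 1) {
  arr <- as_volume_array(volume)
  d <- dim(arr)
  if (prod(d) < 2) abort("volume too small for any co-occurring pair")
  res <- cpp_haralick_maps(as.numeric(arr), as.integer(d),
                           as.integer(n_levels), as.integer(window_radius))
  lapply(res, function(v) array(v, dim = d))
}

#' Spacing-aware gradient magnitude map
#'
#' Central differences within the 3 x 3 x 3 neighbourhood, divided by the
#' physical spacing per axis; one-sided differences at the volume border.
#' An axis with a single slice contributes nothing (2D fallback, with a
#' warning).
#'
#' @param volume A `ct_subvolume` (spacing used) or 3D array (unit spacing).
#' @return 3D array of gradient magnitudes (intensity units per mm).
#' @export
gradient_map <- function(volume) {
  arr <- as_volume_array(volume)
  sp <- volume_spacing(volume)
  d <- dim(arr)
  g2 <- array(0, dim = d)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) {
      warn(sprintf("axis %d has a single slice; falling back to 2D differences", ax))
      next
    }
    up <- slice_shift(arr, ax, 1L)
    dn <- slice_shift(arr, ax, -1L)
    denom <- array(2 * sp[ax], dim = d)
    # one-sided at the two border slices
    border <- slice_index(d, ax, c(1L, n))
    denom[border] <- sp[ax]
    g2 <- g2 + ((up - dn) / denom)^2
  }
  sqrt(g2)
}

# shift along axis with edge replication (yields one-sided diffs at borders)
slice_shift <- function(arr, ax, by) {
  d <- dim(arr)
  idx <- pmin(pmax(seq_len(d[ax]) + by, 1L), d[ax])
  args <- list(arr, 1:d[1], 1:d[2], 1:d[3])
  args[[ax + 1L]] <- idx
  do.call(`[`, c(args, drop = FALSE))
}

# logical index array marking whole slices along an axis
slice_index <- function(d, ax, slices) {
  m <- array(FALSE, dim = d)
  args <- list(m, 1:d[1], 1:d[2], 1:d[3])
  args[[ax + 1L]] <- slices
  args$value <- TRUE
  do.call(`[<-`, args) > 0
}

#' The nine texture maps (8 Haralick + gradient magnitude)
#'
#' @inheritParams haralick_maps
#' @return Named list of nine 3D arrays; `GradientMagnitude` is the ninth.
#' @export
texture_map_set <- function(volume, n_levels = 32, window_radius = 1) {
  maps <- haralick_maps(volume, n_levels = n_levels, window_radius = window_radius)
  maps$GradientMagnitude <- gradient_map(volume)
  maps
}

#' Summary statistics of a map over a masked region
#'
#' Mean, median, population variance, skewness and Fisher (excess)
#' kurtosis as standardized central moments, and the 10th / 90th
#' percentiles (type-7 quantiles), over masked voxels only.
#'
#' @param map 3D numeric array.
#' @param mask Logical array of the same shape with at least 2 voxels.
#' @return Named numeric vector of length 7.
#' @export
region_statistics <- function(map, mask) {
  if (!all(dim(map) == dim(mask))) abort("map and mask shapes differ")
  v <- map[mask > 0]
  if (length(v) < 2L) abort("mask has fewer than 2 voxels; variance undefined")
  m <- mean(v)
  s2 <- pop_var(v)
  skew <- if (s2 > 0) mean((v - m)^3) / s2^1.5 else 0
  kurt <- if (s2 > 0) mean((v - m)^4) / s2^2 - 3 else 0
  c(mean = m, median = median(v), variance = s2, skewness = skew,
    kurtosis = kurt,
    `10thPercentile` = unname(quantile(v, 0.10, type = 7)),
    `90thPercentile` = unname(quantile(v, 0.90, type = 7)))
}

#' Extract the 63-feature radiomic vectors for both regions
#'
#' Full chain: crop around the tumor with padding, build the peritumoral
#' shell by axial dilation, min-max normalize the cropped subvolume,
#' compute the nine texture maps, and summarise each map with seven
#' statistics over each region -- 63 named features (`<Map>_<statistic>`)
#' per region. Deterministic.
#'
#' @param volume A `ct_subvolume` or 3D array.
#' @param tumor_mask Logical 3D array.
#' @param config A [radiomics_config()].
#' @return A tibble with columns `region` (`"tumoral"` / `"peritumoral"`),
#'   `feature`, `value`; 126 rows.
#' @export
extract_features <- function(volume, tumor_mask, config = radiomics_config()) {
  cropped <- crop_subvolume(volume, tumor_mask,
                            pad_xy = config$pad_xy, pad_z = config$pad_z)
  masks <- make_peritumoral_mask(cropped$mask, margin_px = config$margin_px)
  norm <- minmax_normalize(cropped$volume)
  maps <- texture_map_set(norm, n_levels = config$n_levels,
                          window_radius = config$window_radius)
  out <- list()
  for (region in c("tumoral", "peritumoral")) {
    msk <- masks[[region]]
    stats <- unlist(lapply(names(maps), function(nm) {
      s <- region_statistics(maps[[nm]], msk)
      setNames(s, paste0(nm, "_", names(s)))
    }))
    out[[region]] <- tibble::tibble(region = region,
                                    feature = names(stats),
                                    value = unname(stats))
  }
  dplyr::bind_rows(out)
}

#' Extract features for every lesion of a cohort
#'
#' @param cohort Cohort tibble from [generate_cohort()] (needs list-columns
#'   `volume` and `tumor_mask`).
#' @param config A [radiomics_config()].
#' @return A wide tibble, one row per lesion: `lesion_id`, `patient_id`,
#'   `outcome`, then 126 feature columns named `tum_*` and `peri_*`.
#' @export
extract_cohort_features <- function(cohort, config = radiomics_config()) {
  rows <- purrr::map(seq_len(nrow(cohort)), function(i) {
    feats <- extract_features(cohort$volume[[i]], cohort$tumor_mask[[i]], config)
    feats$prefix <- ifelse(feats$region == "tumoral", "tum", "peri")
    wide <- setNames(feats$value, paste0(feats$prefix, "_", feats$feature))
    dplyr::bind_cols(
      tibble::tibble(lesion_id = cohort$lesion_id[i],
                     patient_id = cohort$patient_id[i],
                     outcome = cohort$outcome[i]),
      tibble::as_tibble(as.list(wide))
    )
  })
  dplyr::bind_rows(rows)
}
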