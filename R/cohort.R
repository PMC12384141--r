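#' CT subvolume with physical spacing
#'
#' Lightweight container pairing a 3D intensity grid with its voxel spacing
#' in millimetres. Clinical chest CT is strongly anisotropic: in-plane
#' resolution is sub-millimetre while slice thickness is close to 5 mm, and
#' several downstream steps (gradient magnitude, peritumoral dilation) must
#' respect that.
#'
#' @param intensities 3D numeric array.
#' @param spacing Numeric length-3 vector `(x, y, z)` in mm, all positive.
#' @return An object of class `ct_subvolume`: a list with elements
#'   `intensities` and `spacing`.
#' @export
ct_subvolume <- function(intensities, spacing = c(1, 1, 1)) {
  assert_grid3d(intensities)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("spacing must be three positive finite numbers (mm)")
  }
  structure(list(intensities = intensities, spacing = spacing),
            class = "ct_subvolume")
}

#' @export
print.ct_subvolume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<ct_subvolume> %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

as_volume_array <- function(volume) {
  if (inherits(volume, "ct_subvolume")) volume$intensities else {
    assert_grid3d(volume)
    volume
  }
}

volume_spacing <- function(volume) {
  if (inherits(volume, "ct_subvolume")) volume$spacing else c(1, 1, 1)
}

#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: cohort size and
#' class balance, CT grid geometry and anisotropic spacing, the region and
#' size of the planted texture effect, the causal DAG behind the clinical
#' table, and the censored progression-free-survival model.
#'
#' Defaults follow the characteristics of an advanced-NSCLC immunotherapy
#' cohort: a responder fraction of 51/187, in-plane spacing drawn from
#' 0.59-0.98 mm and slice spacing from 4.8-5.0 mm, lesion-type mix dominated
#' by parenchymal lesions, and exponential progression-free survival with
#' median 16 months for responders against 5 months for non-responders.
#'
#' @param n_patients Number of patients.
#' @param lesions_per_patient_mean Mean lesions per patient (each patient has
#'   at least one; the excess is Poisson).
#' @param responder_fraction Probability of the responder class, in (0, 1).
#' @param spacing_xy_mm,spacing_z_mm Ranges (length-2) from which per-patient
#'   voxel spacings are drawn, mm.
#' @param volume_dim Grid size `(nx, ny, nz)` of each lesion subvolume.
#' @param tumor_diameter_px Range of in-plane blob diameters, voxels.
#' @param texture_effect_size Non-negative scalar controlling how strongly
#'   the texture correlation length differs between classes; 0 plants no
#'   signal.
#' @param signal_region Where the class-dependent texture lives:
#'   `"tumoral"`, `"peritumoral"`, `"both"` or `"none"`.
#' @param clinical_dag A `clinical_dag` object (see [clinical_dag()]);
#'   defaults to [default_clinical_dag()] with the configured responder
#'   fraction.
#' @param lesion_type_probs Named probabilities for parenchymal / pleural /
#'   lymph_node lesion types.
#' @param censor_rate Target probability that a subject is censored, [0, 1].
#' @param median_pfs_responder_months,median_pfs_nonresponder_months Medians
#'   of the exponential PFS distributions per class.
#' @param margin_px In-plane peritumoral margin used when planting
#'   peritumoral signal, pixels.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the config.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 60,
                          lesions_per_patient_mean = 1.3,
                          responder_fraction = 51 / 187,
                          spacing_xy_mm = c(0.59, 0.98),
                          spacing_z_mm = c(4.8, 5.0),
                          volume_dim = c(32, 32, 10),
                          tumor_diameter_px = c(6, 14),
                          texture_effect_size = 1.5,
                          signal_region = c("peritumoral", "tumoral", "both", "none"),
                          clinical_dag = NULL,
                          lesion_type_probs = c(parenchymal = 0.61, pleural = 0.09,
                                                lymph_node = 0.30),
                          censor_rate = 0.2,
                          median_pfs_responder_months = 16,
                          median_pfs_nonresponder_months = 5,
                          margin_px = 5,
                          seed = 1L) {
  signal_region <- match.arg(signal_region)
  if (n_patients < 1) abort("n_patients must be positive")
  if (responder_fraction <= 0 || responder_fraction >= 1) {
    abort("responder_fraction must lie strictly in (0, 1)")
  }
  if (any(spacing_xy_mm <= 0) || any(spacing_z_mm <= 0)) {
    abort("spacing ranges must be positive")
  }
  if (censor_rate < 0 || censor_rate > 1) abort("censor_rate must be in [0, 1]")
  if (texture_effect_size < 0) abort("texture_effect_size must be >= 0")
  if (is.null(clinical_dag)) {
    clinical_dag <- default_clinical_dag(responder_fraction)
  }
  if (length(clinical_dag$nodes) == 0) abort("clinical_dag has no nodes")
  structure(list(
    n_patients = as.integer(n_patients),
    lesions_per_patient_mean = lesions_per_patient_mean,
    responder_fraction = responder_fraction,
    spacing_xy_mm = spacing_xy_mm, spacing_z_mm = spacing_z_mm,
    volume_dim = as.integer(volume_dim),
    tumor_diameter_px = tumor_diameter_px,
    texture_effect_size = texture_effect_size,
    signal_region = signal_region,
    clinical_dag = clinical_dag,
    lesion_type_probs = lesion_type_probs,
    censor_rate = censor_rate,
    median_pfs_responder_months = median_pfs_responder_months,
    median_pfs_nonresponder_months = median_pfs_nonresponder_months,
    margin_px = as.integer(margin_px),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# separable 3D Gaussian smoothing by dense per-axis convolution matrices;
# grids here are small (tens of voxels per side) so this is exact and cheap
gaussian_smooth_3d <- function(arr, sigma) {
  assert_grid3d(arr)
  sigma <- rep_len(sigma, 3L)
  d <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    n <- d[ax]
    idx <- seq_len(n)
    k <- exp(-outer(idx, idx, "-")^2 / (2 * sigma[ax]^2))
    k <- k / rowSums(k)
    m <- matrix(aperm(out, c(ax, setdiff(1:3, ax))), nrow = n)
    m <- k %*% m
    perm <- c(ax, setdiff(1:3, ax))
    out <- aperm(array(m, dim = d[perm]), order(perm))
  }
  out
}

# boundary rings of a tumor mask: its outermost in-plane layer and the
# first in-plane halo layer just outside it
in_plane_ring <- function(tumor) {
  dil <- tumor
  ero <- tumor
  for (z in seq_len(dim(tumor)[3])) {
    sl <- tumor[, , z]
    if (!any(sl)) next
    dil[, , z] <- dilate_slice_once(sl)
    ero[, , z] <- !dilate_slice_once(!sl)
  }
  list(outer_edge = tumor & !ero, inner_halo = dil & !tumor)
}

# irregular but connected blob mask: unit-ellipsoid distance field plus a
# smooth random perturbation, emulating hand-drawn tumor contours
make_blob_mask <- function(dim3, diameter_xy, nz_extent = 3) {
  cx <- (dim3 + 1) / 2
  rx <- diameter_xy / 2
  rz <- max(nz_extent / 2, 0.6)
  gx <- (seq_len(dim3[1]) - cx[1]) / rx
  gy <- (seq_len(dim3[2]) - cx[2]) / rx
  gz <- (seq_len(dim3[3]) - cx[3]) / rz
  d2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
  pert <- gaussian_smooth_3d(array(rnorm(prod(dim3)), dim = dim3), sigma = c(2, 2, 1))
  pert <- (pert - mean(pert)) / (stats::sd(pert) + 1e-12)
  mask <- (sqrt(d2) + 0.18 * pert) < 1
  if (!any(mask)) mask <- sqrt(d2) < 1
  mask
}

#' Plant a class-dependent texture signal inside a region
#'
#' Mixes zero-mean spatially correlated noise into the chosen region. The
#' correlation length of the noise depends on the class label (responders
#' receive smoother noise), while its marginal variance is standardized, so
#' mean intensity is untouched and only local texture statistics (local
#' variance, GLCM entropy, inverse difference moment) separate the classes.
#' With `effect = 0` both classes receive identically distributed noise.
#'
#' @param volume A `ct_subvolume` or 3D array.
#' @param masks A `region_masks` object (see [make_peritumoral_mask()]).
#' @param class_label 0/1 class of the lesion (1 = responder).
#' @param effect Non-negative effect size; scales the correlation-length gap.
#' @param region `"tumoral"`, `"peritumoral"`, `"both"` or `"none"`.
#' @param amplitude Standard deviation of the mixed-in noise.
#' @return The modified volume (same type as the input).
#' @export
plant_texture_signal <- function(volume, masks, class_label, effect,
                                 region = "peritumoral", amplitude = 0.10) {
  arr <- as_volume_array(volume)
  if (effect < 0) abort("effect must be >= 0")
  if (region == "none") return(volume)
  # a one-voxel guard ring at the tumor boundary stays unmodified so that
  # radius-1 texture windows on the far side of the boundary do not absorb
  # the other region's planted signal
  ring <- in_plane_ring(masks$tumoral)
  target <- switch(region,
    tumoral = masks$tumoral & !ring$outer_edge,
    peritumoral = masks$peritumoral & !ring$inner_halo,
    both = masks$tumoral | masks$peritumoral,
    abort(sprintf("unknown region '%s'", region))
  )
  if (!any(target)) {
    target <- switch(region, tumoral = masks$tumoral,
                     peritumoral = masks$peritumoral)
  }
  if (!any(target)) abort("region mask is empty")
  sigma0 <- 0.4
  sigma <- sigma0 + 0.45 * effect * as.integer(class_label)
  noise <- gaussian_smooth_3d(array(rnorm(length(arr)), dim = dim(arr)),
                              sigma = c(sigma, sigma, 0))
  noise <- (noise - mean(noise)) / (stats::sd(noise) + 1e-12)
  arr[target] <- arr[target] + amplitude * noise[target]
  if (inherits(volume, "ct_subvolume")) {
    volume$intensities <- arr
    volume
  } else {
    arr
  }
}

#' Sample a clinical table by ancestral sampling from a causal DAG
#'
#' @param dag A `clinical_dag` (see [clinical_dag()]).
#' @param n Number of rows.
#' @param seed Integer seed.
#' @return A tibble of categorical variables, one column per node, sampled
#'   in topological order so each child honours its conditional table.
#' @export
sample_clinical_from_dag <- function(dag, n, seed = 1L) {
  stopifnot(inherits(dag, "clinical_dag"))
  order <- topological_order(dag_edges(dag), names(dag$nodes))
  out <- vector("list", length(order))
  names(out) <- order
  set.seed(as.integer(seed))
  for (v in order) {
    node <- dag$nodes[[v]]
    lv <- node$levels
    if (length(node$parents) == 0) {
      out[[v]] <- lv[sample.int(length(lv), n, replace = TRUE, prob = node$cpt)]
    } else {
      par_vals <- lapply(node$parents, function(p) out[[p]])
      cfg <- interaction(lapply(seq_along(node$parents), function(i) {
        factor(par_vals[[i]], levels = dag$nodes[[node$parents[i]]]$levels)
      }), drop = FALSE, lex.order = FALSE)
      draws <- character(n)
      for (cf in levels(cfg)) {
        rows <- which(cfg == cf)
        if (!length(rows)) next
        p <- node$cpt[, cf]
        draws[rows] <- lv[sample.int(length(lv), length(rows), replace = TRUE, prob = p)]
      }
      out[[v]] <- draws
    }
  }
  tibble::as_tibble(out)
}

#' Sample censored progression-free survival times
#'
#' Event times are exponential with a class-specific rate; censoring times
#' are exponential with rate `censor_rate / (1 - censor_rate)` times the
#' event rate, which makes censoring independent of the event time and hits
#' the target censoring probability exactly for exponential pairs.
#'
#' @param outcome 0/1 vector (1 = responder).
#' @param censor_rate Target censoring probability in [0, 1).
#' @param rate_responder,rate_nonresponder Exponential event rates (1/months).
#' @param seed Integer seed.
#' @return A tibble with `pfs_months` and `pfs_event` (1 = progression
#'   observed).
#' @export
sample_survival <- function(outcome, censor_rate = 0.2,
                            rate_responder = log(2) / 16,
                            rate_nonresponder = log(2) / 5,
                            seed = 1L) {
  if (rate_responder <= 0 || rate_nonresponder <= 0) abort("rates must be positive")
  if (censor_rate < 0 || censor_rate >= 1) abort("censor_rate must be in [0, 1)")
  set.seed(as.integer(seed))
  outcome <- as.integer(outcome)
  n <- length(outcome)
  lambda <- ifelse(outcome == 1L, rate_responder, rate_nonresponder)
  t_event <- rexp(n, rate = lambda)
  if (censor_rate == 0) {
    return(tibble::tibble(pfs_months = t_event, pfs_event = 1L))
  }
  lambda_c <- censor_rate / (1 - censor_rate) * lambda
  t_cens <- rexp(n, rate = lambda_c)
  tibble::tibble(
    pfs_months = pmin(t_event, t_cens),
    pfs_event = as.integer(t_event <= t_cens)
  )
}

numeric_from_bins <- function(bin, ranges) {
  lo <- unname(ranges[bin, 1])
  hi <- unname(ranges[bin, 2])
  lo + runif(length(bin)) * (hi - lo)
}

#' Generate a synthetic multimodal cohort
#'
#' Produces, per lesion, an anisotropic CT subvolume with a blob tumor mask
#' and a class-dependent planted texture signal, plus patient-level clinical
#' variables sampled from the configured causal DAG and censored
#' progression-free survival. The full cohort is a deterministic function of
#' the config (including its seed).
#'
#' @param config A [cohort_config()].
#' @return A tibble with one row per lesion: `patient_id`, `lesion_id`,
#'   `lesion_type`, clinical columns (`pdl1_score`, `tmb`, `smoking`, `age`,
#'   `sex`), `outcome`, `pfs_months`, `pfs_event`, and list-columns `volume`
#'   (`ct_subvolume`) and `tumor_mask` (logical array). The config is kept
#'   in the `"config"` attribute.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)

  n <- config$n_patients
  clin_cat <- sample_clinical_from_dag(config$clinical_dag, n,
                                       seed = child_seed(config$seed, "clinical"))
  set.seed(child_seed(config$seed, "numeric"))
  outcome <- as.integer(clin_cat$outcome == "1")

  pdl1 <- numeric_from_bins(clin_cat$pdl1_bin, rbind(
    "0" = c(0, 0), "1-49" = c(1, 49), ">=50" = c(50, 100)))
  tmb <- numeric_from_bins(clin_cat$tmb_bin, rbind(
    "<10" = c(0, 9.5), ">=10" = c(10, 45)))
  age_lo <- as.numeric(sub("-.*", "", clin_cat$age_bin))
  age <- floor(age_lo + runif(n) * 10)

  surv <- sample_survival(outcome, censor_rate = config$censor_rate,
                          rate_responder = log(2) / config$median_pfs_responder_months,
                          rate_nonresponder = log(2) / config$median_pfs_nonresponder_months,
                          seed = child_seed(config$seed, "survival"))

  set.seed(child_seed(config$seed, "lesions"))
  n_lesions <- 1L + rpois(n, max(config$lesions_per_patient_mean - 1, 0))
  patient_id <- sprintf("P%03d", seq_len(n))

  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sp_xy <- runif(1, config$spacing_xy_mm[1], config$spacing_xy_mm[2])
    sp_z <- runif(1, config$spacing_z_mm[1], config$spacing_z_mm[2])
    k <- n_lesions[i]
    ltype <- sample(names(config$lesion_type_probs), k, replace = TRUE,
                    prob = config$lesion_type_probs)
    vols <- vector("list", k)
    masks <- vector("list", k)
    for (j in seq_len(k)) {
      d <- config$volume_dim
      diam <- runif(1, config$tumor_diameter_px[1], config$tumor_diameter_px[2])
      mask <- make_blob_mask(d, diam, nz_extent = sample(2:4, 1))
      sm <- gaussian_smooth_3d(array(rnorm(prod(d)), dim = d),
                               sigma = c(1.5, 1.5, 0.5))
      sm <- (sm - mean(sm)) / (stats::sd(sm) + 1e-12)
      base <- 0.30 + 0.06 * sm + 0.02 * rnorm(prod(d))
      base[mask] <- base[mask] + 0.35
      vol <- ct_subvolume(array(base, dim = d), spacing = c(sp_xy, sp_xy, sp_z))
      if (config$signal_region != "none" && config$texture_effect_size > 0) {
        rm <- make_peritumoral_mask(mask, margin_px = config$margin_px)
        vol <- plant_texture_signal(vol, rm, outcome[i],
                                    effect = config$texture_effect_size,
                                    region = config$signal_region)
      }
      # air and dense-tissue anchor voxels pin the intensity range of every
      # subvolume (as air and bone do in real CT), so min-max normalization
      # rescales all volumes identically
      v <- vol$intensities
      v[v < 0] <- 0
      v[v > 1] <- 1
      v[1, 1, 1] <- 0
      v[d[1], d[2], d[3]] <- 1
      vol$intensities <- v
      vols[[j]] <- vol
      masks[[j]] <- mask
    }
    pid <- patient_id[i]
    rows[[i]] <- tibble::tibble(
      patient_id = pid,
      lesion_id = sprintf("%s_L%02d", pid, seq_len(k)),
      lesion_type = ltype,
      pdl1_score = pdl1[i], tmb = tmb[i],
      smoking = clin_cat$smoking[i], age = age[i], sex = clin_cat$sex[i],
      outcome = outcome[i],
      pfs_months = surv$pfs_months[i], pfs_event = surv$pfs_event[i],
      volume = vols, tumor_mask = masks
    )
  }
  cohort <- dplyr::bind_rows(rows)
  attr(cohort, "config") <- config
  cohort
}

#' Write a cohort to disk (NIfTI volumes + clinical CSV + manifest)
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_len(nrow(cohort))) {
    vol <- cohort$volume[[i]]
    pix <- vol$spacing
    vp <- file.path(dir, paste0(cohort$lesion_id[i], "_ct.nii.gz"))
    mp <- file.path(dir, paste0(cohort$lesion_id[i], "_mask.nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(vol$intensities, pixdim = pix), vp)
    RNifti::writeNifti(RNifti::asNifti(cohort$tumor_mask[[i]] * 1L, pixdim = pix), mp)
    paths <- c(paths, vp, mp)
  }
  clin <- dplyr::select(cohort, -dplyr::any_of(c("volume", "tumor_mask")))
  cp <- file.path(dir, "cohort.csv")
  write.csv(clin, cp, row.names = FALSE)
  cfg <- attr(cohort, "config")
  mp2 <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(
    n_patients = cfg$n_patients, seed = cfg$seed,
    signal_region = cfg$signal_region,
    texture_effect_size = cfg$texture_effect_size,
    responder_fraction = cfg$responder_fraction
  ), mp2)
  invisible(c(paths, cp, mp2))
}
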