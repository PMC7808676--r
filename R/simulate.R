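# Ground-truthed synthetic confocal stacks.
#
# The generator states a simple world with the statistical structure the
# analysis assumes: one ellipsoidal cell per stack (analytic membership
# gives a segmentation oracle), punctate signal drawn voxelwise by
# region-conditional Bernoulli sampling (so expected enrichment is a closed
# form of the occupancies), a second channel sharing an exact fraction f of
# the first channel's puncta voxels (so the true Manders overlap is f by
# construction), Gaussian point-spread blur, a dim cytoplasmic fill so
# segmentation is exercisable, and sensor noise (additive Gaussian on the
# 12-bit scale by default, Poisson optionally).

#' Specification of one synthetic cell
#'
#' Defaults state the world the analysis is validated against: a founder
#' cell-sized ellipsoid (semi-axes ~6.5 um, large enough that the deep
#' region beyond b2 = 3 um is substantial), confocal sampling at
#' `(0.3, 0.1, 0.1)` um, membrane-biased receptor occupancies
#' `(0.15, 0.05, 0.05)`, inter-channel overlap fraction 0.3, PSF sigma
#' 0.1 um, and Gaussian noise at SNR 10 (noise sd = puncta amplitude / 10).
#'
#' @param semi_axes_um ellipsoid semi-axes `(z, y, x)` in micrometres; each
#'   must exceed `2 * boundaries[2]` so the deep shell is nonempty.
#' @param spacing voxel spacing `(dz, dy, dx)` um.
#' @param occupancy_a per-shell Bernoulli occupancy of channel A puncta,
#'   `(membrane, peripheral, deep)`, each in `[0, 1]`.
#' @param overlap_f fraction of A's puncta voxels retained in channel B.
#' @param occupancy_b_only occupancy of additional B-only puncta (sampled
#'   outside A so the true overlap stays exactly `overlap_f`). The default
#'   0.025 makes channel B's total puncta volume fraction roughly 5%, so the
#'   95th-percentile threshold convention matches B's true signal volume.
#' @param boundaries shell cut points used for the truth partition.
#' @param tier `"mask"` (channels are the binary truth masks) or `"image"`
#'   (rendered intensities with PSF, fill, background and noise).
#' @param psf_sigma_um Gaussian PSF sigma (um), applied in 3D.
#' @param background,cell_fill 12-bit intensity levels.
#' @param puncta_amplitude median punctum brightness (12-bit scale).
#' @param amplitude_sdlog per-punctum brightness heterogeneity: amplitudes
#'   are iid lognormal with median `puncta_amplitude` and this log-sd
#'   (vesicle cargo load varies severalfold in real data; heterogeneous
#'   brightness also makes rank thresholding punctum-intrinsic rather than
#'   driven by regional crowding).
#' @param noise `"gaussian"` or `"poisson"`.
#' @param snr median puncta amplitude over Gaussian noise sd (`Inf` = no
#'   noise).
#' @param ventral_axis axis annotation attached to the simulated record.
#' @param pad_um background margin around the ellipsoid.
#' @param seed RNG seed for this cell.
#' @return A validated `simulation_spec` list.
#' @export
simulation_spec <- function(semi_axes_um = c(6.4, 7.0, 6.6),
                            spacing = c(0.3, 0.25, 0.25),
                            occupancy_a = c(membrane = 0.15,
                                            peripheral = 0.05,
                                            deep = 0.05),
                            overlap_f = 0.3,
                            occupancy_b_only = 0.025,
                            boundaries = c(1, 3),
                            tier = c("image", "mask"),
                            psf_sigma_um = 0.1,
                            background = 100,
                            cell_fill = 300,
                            puncta_amplitude = 1500,
                            amplitude_sdlog = 0.8,
                            noise = c("gaussian", "poisson"),
                            snr = 10,
                            ventral_axis = "+y",
                            pad_um = 1.2,
                            seed = 1L) {
  tier <- match.arg(tier)
  noise <- match.arg(noise)
  occupancy_a <- stats::setNames(as.double(occupancy_a),
                                 c("membrane", "peripheral", "deep"))
  spec <- list(semi_axes_um = as.double(semi_axes_um),
               spacing = as.double(spacing),
               occupancy_a = occupancy_a, overlap_f = as.double(overlap_f),
               occupancy_b_only = as.double(occupancy_b_only),
               boundaries = as.double(boundaries), tier = tier,
               psf_sigma_um = psf_sigma_um, background = background,
               cell_fill = cell_fill, puncta_amplitude = puncta_amplitude,
               amplitude_sdlog = amplitude_sdlog,
               noise = noise, snr = snr, ventral_axis = ventral_axis,
               pad_um = pad_um, seed = as.integer(seed))
  if (any(spec$occupancy_a < 0 | spec$occupancy_a > 1))
    stop("occupancies must be in [0, 1]")
  if (spec$overlap_f < 0 || spec$overlap_f > 1)
    stop("overlap_f must be in [0, 1]")
  if (length(spec$semi_axes_um) != 3 || any(spec$semi_axes_um <= 0))
    stop("semi_axes_um must be 3 positive numbers")
  if (any(spec$semi_axes_um <= 2 * spec$boundaries[2]))
    stop("deep region empty under spec geometry: semi-axes must exceed 2*b2")
  class(spec) <- "simulation_spec"
  spec
}

# analytic ellipsoid membership on the voxel-center lattice
render_ellipsoid_mask <- function(semi_axes_um, spacing, pad_um) {
  n <- 2L * as.integer(ceiling((semi_axes_um + pad_um) / spacing)) + 1L
  ctr <- (n + 1) / 2
  zc <- ((seq_len(n[1]) - ctr[1]) * spacing[1] / semi_axes_um[1])^2
  yc <- ((seq_len(n[2]) - ctr[2]) * spacing[2] / semi_axes_um[2])^2
  xc <- ((seq_len(n[3]) - ctr[3]) * spacing[3] / semi_axes_um[3])^2
  r2 <- outer(outer(zc, yc, "+"), xc, "+")
  array(r2 <= 1, dim = n)
}

smooth_psf_3d <- function(arr, sigma_um, spacing) {
  if (sigma_um <= 0) return(arr)
  ky <- gaussian_kernel_1d(sigma_um / spacing[2])
  kx <- gaussian_kernel_1d(sigma_um / spacing[3])
  out <- cpp_conv_planes(arr, ky, kx)
  kz <- gaussian_kernel_1d(sigma_um / spacing[1])
  if (length(kz) > 1) out <- cpp_conv_z(out, kz)
  out
}

#' Simulate one cell with exact ground truth
#'
#' Truth statistics are computed from the truth masks by direct counting
#' (independent of the quantification code paths), so mask-tier recovery is
#' an exact identity check and image-tier recovery measures the whole
#' pipeline's error.
#'
#' @param spec a [simulation_spec()].
#' @return List with `channels` (named list of [voxel_grid()]: `receptor`,
#'   `rab`), `record` (a [cell_record()]), and `truth` (mask, partition
#'   label, puncta masks, exact per-shell enrichment `E`, `moc_cell`,
#'   `moc_region`, `vd_ratio`, seed and spec).
#' @export
simulate_cell <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  sp <- spec$spacing
  mask_arr <- render_ellipsoid_mask(spec$semi_axes_um, sp, spec$pad_um)
  mask <- cell_mask(mask_arr, sp)
  dmap <- distance_map(mask)
  part <- assign_regions(dmap, spec$boundaries)
  lab <- part$label

  # channel A: region-conditional Bernoulli occupancy
  a <- array(FALSE, dim = dim(lab))
  for (k in 1:3) {
    idx <- which(lab == k)
    if (length(idx))
      a[idx] <- stats::runif(length(idx)) < spec$occupancy_a[k]
  }
  # channel B: exactly round(f * |A|) voxels of A, plus B-only puncta
  # sampled outside A (keeps the true overlap exactly f)
  b <- array(FALSE, dim = dim(lab))
  ia <- which(a)
  n_shared <- round(spec$overlap_f * length(ia))
  if (n_shared > 0) b[ia[sample.int(length(ia), n_shared)]] <- TRUE
  i_free <- which(lab > 0L & !a)
  if (spec$occupancy_b_only > 0 && length(i_free))
    b[i_free[stats::runif(length(i_free)) < spec$occupancy_b_only]] <- TRUE

  # truth statistics by direct counting on the truth masks
  n_reg <- as.numeric(part$region_voxels)
  nA <- vapply(1:3, function(k) sum(a[lab == k]), numeric(1))
  nB_and_A <- vapply(1:3, function(k) sum((a & b)[lab == k]), numeric(1))
  n_cell <- part$cell_voxels
  E_true <- ifelse(n_reg > 0,
                   (nA / n_reg) / (sum(nA) / n_cell), NA_real_)
  moc_region_true <- ifelse(nA > 0, nB_and_A / nA, NA_real_)
  split <- split_halves(mask, spec$ventral_axis)
  nv <- sum(a[split$half_label == 1L])
  nd <- sum(a[split$half_label == 2L])
  vd_true <- if (nd > 0) nv / nd else NA_real_

  if (spec$tier == "mask") {
    chA <- voxel_grid(array(as.double(a), dim = dim(a)), sp)
    chB <- voxel_grid(array(as.double(b), dim = dim(b)), sp)
  } else {
    render <- function(puncta) {
      img <- spec$background + spec$cell_fill * as.double(mask_arr)
      idx <- which(puncta)
      # iid lognormal brightness per punctum, median = puncta_amplitude
      img[idx] <- img[idx] + spec$puncta_amplitude *
        exp(stats::rnorm(length(idx), 0, spec$amplitude_sdlog))
      img <- array(img, dim = dim(lab))
      img <- smooth_psf_3d(img, spec$psf_sigma_um, sp)
      if (spec$noise == "gaussian") {
        sd <- if (is.finite(spec$snr)) spec$puncta_amplitude / spec$snr else 0
        if (sd > 0) img <- img + stats::rnorm(length(img), 0, sd)
      } else {
        img <- array(stats::rpois(length(img), pmax(img, 0)), dim = dim(img))
      }
      voxel_grid(array(round(pmin(pmax(img, 0), 4095)), dim = dim(img)), sp)
    }
    chA <- render(a)
    chB <- render(b)
  }

  record <- cell_record(cell_id = sprintf("sim_%d", spec$seed),
                        condition = "synthetic", stage = "premitotic",
                        ventral_axis = spec$ventral_axis)
  list(
    channels = list(receptor = chA, rab = chB),
    record = record,
    truth = list(
      mask = mask, partition_label = lab,
      puncta_a = puncta_mask(a, sp, "receptor"),
      puncta_b = puncta_mask(b, sp, "rab"),
      E = stats::setNames(E_true, part$region_names),
      moc_cell = if (sum(nA) > 0) sum(nB_and_A) / sum(nA) else NA_real_,
      moc_region = stats::setNames(moc_region_true, part$region_names),
      vd_ratio = vd_true,
      seed = spec$seed, spec = spec
    ))
}

jaccard_index <- function(a, b) {
  u <- sum(as_dim3(a) | as_dim3(b))
  if (u == 0) return(NA_real_)
  sum(as_dim3(a) & as_dim3(b)) / u
}

#' Parameter-recovery study over simulated cells
#'
#' Runs the full analysis on `n_cells` independent simulations and reports
#' per-cell recovered vs true statistics. In the `"mask"` tier the truth
#' mask and binary channels short-circuit segmentation and thresholding, so
#' recovery must be exact; in the `"image"` tier the pipeline (segmentation,
#' distance shells, percentile thresholding) runs from rendered intensities
#' and the report measures its error.
#'
#' @param n_cells number of simulated cells (>= 1).
#' @param tier `"mask"` or `"image"`.
#' @param seed run seed; per-cell seeds are derived by a counter scheme.
#' @param spec_base template [simulation_spec()]; its tier and seed fields
#'   are overridden per cell.
#' @param config analysis configuration (boundaries and percentile should
#'   match the generator's).
#' @return Object of class `recovery_report`: data.frame with one row per
#'   cell (true and recovered statistics, mask Jaccard) plus a `summary()`
#'   method reporting median relative errors.
#' @export
recovery_suite <- function(n_cells, tier = c("image", "mask"), seed = 1L,
                           spec_base = simulation_spec(),
                           config = default_config()) {
  tier <- match.arg(tier)
  stopifnot(n_cells >= 1)
  config <- validate_config(config)
  config$spacing <- spec_base$spacing
  config$boundaries <- spec_base$boundaries
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    spec <- spec_base
    spec$tier <- tier
    spec$seed <- cell_seed(seed, i)
    sim <- simulate_cell(spec)
    tr <- sim$truth
    if (tier == "mask") {
      mask <- tr$mask
      pA <- puncta_mask(unclass(sim$channels$receptor) > 0, spec$spacing, "receptor")
      pB <- puncta_mask(unclass(sim$channels$rab) > 0, spec$spacing, "rab")
    } else {
      mask <- segment_cell(sim$channels$receptor,
                           sigma_um = config$seg_sigma_um,
                           otsu_scale = config$otsu_scale,
                           disk_radius_px = config$disk_radius_px,
                           min_volume_um3 = config$min_volume_um3)
      pA <- threshold_puncta(sim$channels$receptor, mask,
                             sigma_um = config$quant_sigma_um,
                             percentile = config$percentile, "receptor")
      pB <- threshold_puncta(sim$channels$rab, mask,
                             sigma_um = config$quant_sigma_um,
                             percentile = config$percentile, "rab")
    }
    part <- assign_regions(distance_map(mask), config$boundaries)
    enr <- regional_enrichment(pA, part)
    cr <- manders_overlap(pA, pB, part)
    vd <- ventral_dorsal_ratio(pA, split_halves(mask, spec$ventral_axis))
    E <- stats::setNames(enr$E, enr$region)
    rows[[i]] <- data.frame(
      cell = i, seed = spec$seed, tier = tier,
      jaccard = jaccard_index(mask, tr$mask),
      E_membrane_true = tr$E[["membrane"]], E_membrane = E[["membrane"]],
      E_peripheral_true = tr$E[["peripheral"]], E_peripheral = E[["peripheral"]],
      E_deep_true = tr$E[["deep"]], E_deep = E[["deep"]],
      moc_cell_true = tr$moc_cell, moc_cell = cr$moc_cell,
      vd_ratio_true = tr$vd_ratio, vd_ratio = vd$vd_ratio,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("recovery_report", "data.frame")
  out
}

#' @export
summary.recovery_report <- function(object, ...) {
  rel <- function(est, tr) stats::median(abs(est - tr) / abs(tr), na.rm = TRUE)
  out <- c(
    median_rel_err_E_membrane = rel(object$E_membrane, object$E_membrane_true),
    median_rel_err_E_peripheral = rel(object$E_peripheral, object$E_peripheral_true),
    median_rel_err_E_deep = rel(object$E_deep, object$E_deep_true),
    median_abs_err_moc_cell = stats::median(
      abs(object$moc_cell - object$moc_cell_true), na.rm = TRUE),
    median_jaccard = stats::median(object$jaccard, na.rm = TRUE))
  out
}

# counter-based per-cell seed expansion, kept inside 32-bit integer range
cell_seed <- function(run_seed, i) {
  as.integer((as.numeric(run_seed) * 10007 + i * 101) %% 2147483629)
}
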