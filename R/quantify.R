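# Puncta thresholding and the three regional statistics: fold enrichment,
# object-based Manders' overlap, and the ventral/dorsal polarity ratio.
# All statistics are ratios of voxel counts; the constant voxel volume
# cancels, so counts are used internally and um^3 only for absolute fields.

#' Threshold punctate signal within a cell mask
#'
#' Smooths each z-plane with a 2D Gaussian (default sigma 0.1 um) and
#' binarizes at the nearest-rank percentile (default 95th) of the smoothed
#' intensities among in-mask voxels. Binarization is strict (`>`), so with a
#' constant in-mask signal no voxel qualifies (a warning, not an error):
#' ties at the threshold fall below it, which is the conservative choice for
#' 12-bit integer data.
#'
#' @param grid a [voxel_grid()].
#' @param mask the cell mask (nonempty, same shape).
#' @param sigma_um 2D smoothing sigma in micrometres (0 = none).
#' @param percentile rank in (0, 100).
#' @param source_channel optional label carried on the result.
#' @return Object of class `puncta_mask`: logical array with spacing and
#'   `source_channel` attributes.
#' @export
threshold_puncta <- function(grid, mask, sigma_um = 0.1, percentile = 95,
                             source_channel = NA_character_) {
  if (!identical(dim(grid), dim(mask))) stop("grid and mask shapes differ")
  if (!any(mask)) stop("empty mask")
  if (!(percentile > 0 && percentile < 100)) stop("percentile must be in (0, 100)")
  sm <- unclass(smooth_planes(grid, sigma_um))
  vals <- sm[as_dim3(mask)]
  n <- length(vals)
  if (max(vals) == min(vals)) {
    warning("constant in-mask intensity: empty puncta mask")
    member <- array(FALSE, dim = dim(grid))
  } else {
    rank <- ceiling(percentile / 100 * n)          # nearest-rank, no interpolation
    thr <- sort(vals, partial = rank)[rank]
    member <- array(as_dim3(mask) & sm > thr, dim = dim(grid))
  }
  puncta_mask(member, voxel_spacing(grid), source_channel)
}

#' @rdname threshold_puncta
#' @param member logical 3D array of puncta voxels.
#' @param spacing `(dz, dy, dx)` in micrometres.
#' @export
puncta_mask <- function(member, spacing, source_channel = NA_character_) {
  member <- array(as.logical(member), dim = dim(member))
  structure(member, spacing = as.double(spacing),
            source_channel = source_channel,
            class = c("puncta_mask", "array"))
}

#' @export
print.puncta_mask <- function(x, ...) {
  cat(sprintf("<puncta_mask>%s %d voxels, %.2f um^3\n",
              if (is.na(attr(x, "source_channel"))) ""
              else paste0(" [", attr(x, "source_channel"), "]"),
              sum(x), sum(x) * prod(voxel_spacing(x))))
  invisible(x)
}

check_subset <- function(puncta, label) {
  if (any(as_dim3(puncta) & label == 0L))
    stop("puncta mask is not a subset of the cell mask")
}

#' Regional fold enrichment of punctate signal
#'
#' For each distance shell, the puncta density in the shell divided by the
#' whole-cell puncta density:
#' `E_region = (V_puncta_in_region / V_region) / (V_puncta_in_cell / V_cell)`.
#' `E = 1` means the shell holds signal in proportion to its volume. Shells
#' with zero volume yield `NA` (flagged undefined, not dropped); by
#' construction `sum(E * V_region) = V_cell` over the defined shells.
#'
#' @param puncta a [puncta_mask()] within the partition's cell.
#' @param partition a [assign_regions()] result.
#' @return Object of class `enrichment_result`: data.frame with one row per
#'   shell (`region`, `E`, `V_in_region_um3`, `V_region_um3`) plus
#'   attributes `V_in_cell_um3` and `V_cell_um3`.
#' @export
regional_enrichment <- function(puncta, partition) {
  lab <- partition$label
  check_subset(puncta, lab)
  n_in <- vapply(1:3, function(k) sum(puncta[lab == k]), numeric(1))
  n_reg <- as.numeric(partition$region_voxels)
  n_cell <- partition$cell_voxels
  n_in_cell <- sum(n_in)
  if (n_in_cell == 0) stop("no puncta signal inside the cell")
  dens_cell <- n_in_cell / n_cell
  E <- ifelse(n_reg > 0, (n_in / n_reg) / dens_cell, NA_real_)
  vox <- prod(partition$spacing)
  out <- data.frame(region = partition$region_names, E = E,
                    V_in_region_um3 = n_in * vox,
                    V_region_um3 = n_reg * vox,
                    stringsAsFactors = FALSE)
  structure(out, V_in_cell_um3 = n_in_cell * vox,
            V_cell_um3 = n_cell * vox,
            class = c("enrichment_result", "data.frame"))
}

#' Object-based Manders' overlap of two puncta channels
#'
#' The fraction of channel A's thresholded volume overlapped by channel B,
#' whole-cell and per shell:
#' `MOC_cell = V(A & B) / V(A)`, `MOC_region = V(A & B in region) / V(A in
#' region)`. The statistic is asymmetric in (A, B). Shells where A has no
#' signal yield `NA` (flagged undefined). The whole-cell value decomposes as
#' the A-volume-weighted mean of the shell values.
#'
#' @param punctaA,punctaB [puncta_mask()] objects within the same cell.
#' @param partition a [assign_regions()] result.
#' @return Object of class `coloc_result`: list with `moc_cell`,
#'   `moc_region` (named), and the volume terms.
#' @export
manders_overlap <- function(punctaA, punctaB, partition) {
  lab <- partition$label
  check_subset(punctaA, lab)
  check_subset(punctaB, lab)
  inter <- as_dim3(punctaA) & as_dim3(punctaB)
  nA <- vapply(1:3, function(k) sum(punctaA[lab == k]), numeric(1))
  nAB <- vapply(1:3, function(k) sum(inter[lab == k]), numeric(1))
  moc_region <- ifelse(nA > 0, nAB / nA, NA_real_)
  names(moc_region) <- partition$region_names
  nA_cell <- sum(nA)
  vox <- prod(partition$spacing)
  structure(list(
    moc_cell = if (nA_cell > 0) sum(nAB) / nA_cell else NA_real_,
    moc_region = moc_region,
    V_A_um3 = nA_cell * vox,
    V_A_region_um3 = stats::setNames(nA * vox, partition$region_names),
    V_AB_um3 = sum(nAB) * vox
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> MOC cell %.4f; shells: %s\n", x$moc_cell,
              paste(sprintf("%s %.4f", names(x$moc_region), x$moc_region),
                    collapse = ", ")))
  invisible(x)
}

#' Ventral/dorsal enrichment ratio
#'
#' Thresholded signal volume in the ventral half over the dorsal half after
#' equal-volume bisection along the annotated dorsal-ventral axis. A dorsal
#' half with no signal yields a flagged undefined ratio, not an error.
#'
#' @param puncta a [puncta_mask()].
#' @param split a [split_halves()] result.
#' @return Object of class `polarity_result`: list with `vd_ratio`,
#'   `ventral_um3`, `dorsal_um3`, `undefined`.
#' @export
ventral_dorsal_ratio <- function(puncta, split) {
  lab <- split$half_label
  if (any(as_dim3(puncta) & lab == 0L))
    stop("puncta mask is not a subset of the cell mask")
  vox <- prod(split$spacing)
  nv <- sum(puncta[lab == 1L])
  nd <- sum(puncta[lab == 2L])
  structure(list(
    vd_ratio = if (nd > 0) nv / nd else NA_real_,
    ventral_um3 = nv * vox, dorsal_um3 = nd * vox,
    undefined = nd == 0
  ), class = "polarity_result")
}

#' Quantify one cell end to end
#'
#' Composes segmentation (unless a mask is supplied), shell partitioning,
#' puncta thresholding of the receptor channel (and of an endosome-marker
#' channel when present), regional enrichment, Manders' overlap and the
#' ventral/dorsal ratio (when the record carries an axis annotation) into a
#' single flat statistics row.
#'
#' @param channels named list of [voxel_grid()]s; must contain `receptor`,
#'   may contain `rab`.
#' @param record a [cell_record()].
#' @param config a configuration list, see [default_config()].
#' @param mask optional precomputed [cell_mask()] (bypasses segmentation,
#'   e.g. for ground-truth masks).
#' @return One-row data.frame of per-cell statistics.
#' @export
quantify_cell <- function(channels, record, config = default_config(),
                          mask = NULL) {
  if (inherits(channels, "voxel_grid")) channels <- list(receptor = channels)
  if (is.null(channels$receptor)) stop("channels must include 'receptor'")
  config <- validate_config(config)
  if (is.null(mask))
    mask <- segment_cell(channels$receptor,
                         sigma_um = config$seg_sigma_um,
                         otsu_scale = config$otsu_scale,
                         disk_radius_px = config$disk_radius_px,
                         min_volume_um3 = config$min_volume_um3)
  dmap <- distance_map(mask)
  part <- assign_regions(dmap, config$boundaries)
  pA <- threshold_puncta(channels$receptor, mask,
                         sigma_um = config$quant_sigma_um,
                         percentile = config$percentile,
                         source_channel = "receptor")
  enr <- regional_enrichment(pA, part)
  E <- stats::setNames(enr$E, enr$region)

  moc_cell <- NA_real_
  moc <- stats::setNames(rep(NA_real_, 3), part$region_names)
  if (!is.null(channels$rab)) {
    pB <- threshold_puncta(channels$rab, mask,
                           sigma_um = config$quant_sigma_um,
                           percentile = config$percentile,
                           source_channel = "rab")
    cr <- manders_overlap(pA, pB, part)
    moc_cell <- cr$moc_cell
    moc <- cr$moc_region
  }

  vd <- NA_real_
  if (!is.na(record$ventral_axis)) {
    sp <- split_halves(mask, record$ventral_axis)
    vd <- ventral_dorsal_ratio(pA, sp)$vd_ratio
  }

  data.frame(
    cell_id = record$cell_id, condition = record$condition,
    stage = record$stage,
    V_cell_um3 = part$cell_volume,
    V_receptor_um3 = attr(enr, "V_in_cell_um3"),
    E_membrane = E[["membrane"]], E_peripheral = E[["peripheral"]],
    E_deep = E[["deep"]],
    moc_cell = moc_cell, moc_membrane = moc[["membrane"]],
    moc_peripheral = moc[["peripheral"]], moc_deep = moc[["deep"]],
    vd_ratio = vd,
    b1_um = config$boundaries[1], b2_um = config$boundaries[2],
    percentile = config$percentile,
    stringsAsFactors = FALSE)
}
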