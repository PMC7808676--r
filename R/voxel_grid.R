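#' Single-channel 3D intensity image with physical voxel spacing
#'
#' The basic container of the package: a numeric 3D array in `(z, y, x)` axis
#' order together with the physical voxel spacing `(dz, dy, dx)` in
#' micrometres. Axis order is fixed package-wide to match the acquisition
#' order of confocal z-stacks.
#'
#' @param values numeric 3D array, non-negative finite intensities, axis
#'   order `(z, y, x)`; at least 2 voxels per axis.
#' @param spacing numeric length-3, `(dz, dy, dx)` in micrometres, all > 0.
#' @return An object of class `voxel_grid`: the array with a `spacing`
#'   attribute.
#' @examples
#' g <- voxel_grid(array(runif(8 * 16 * 16), dim = c(8, 16, 16)),
#'                 spacing = c(0.3, 0.1, 0.1))
#' dim(g)
#' voxel_spacing(g)
#' @export
voxel_grid <- function(values, spacing) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array in (z, y, x) order")
  if (any(dim(values) < 2L))
    stop("each axis must have at least 2 voxels")
  values <- array(as.double(values), dim = dim(values))
  if (anyNA(values) || any(!is.finite(values)))
    stop("intensities must be finite")
  if (any(values < 0))
    stop("intensities must be non-negative")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers (dz, dy, dx) in micrometres")
  structure(values, spacing = spacing, class = c("voxel_grid", "array"))
}

#' @rdname voxel_grid
#' @param x a `voxel_grid`, `cell_mask` or other spacing-carrying object.
#' @export
voxel_spacing <- function(x) {
  sp <- attr(x, "spacing")
  if (is.null(sp)) stop("object carries no voxel spacing")
  sp
}

#' Physical volume of one voxel in cubic micrometres
#' @param x a spacing-carrying object.
#' @return `dz * dy * dx` in um^3.
#' @export
voxel_volume <- function(x) prod(voxel_spacing(x))

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x)
  sp <- voxel_spacing(x)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d (z,y,x), spacing %.4g x %.4g x %.4g um, range [%.4g, %.4g]\n",
    d[1], d[2], d[3], sp[1], sp[2], sp[3], min(x), max(x)))
  invisible(x)
}

#' Boolean single-cell mask with spacing
#'
#' A boolean voxel set over the same lattice as its source grid. Created by
#' [segment_cell()] or directly from a logical array (e.g. a simulated ground
#' truth mask).
#'
#' @param member logical 3D array, `(z, y, x)` order.
#' @param spacing `(dz, dy, dx)` in micrometres.
#' @return An object of class `cell_mask`.
#' @export
cell_mask <- function(member, spacing) {
  if (!is.array(member) || length(dim(member)) != 3L)
    stop("`member` must be a 3D logical array")
  member <- array(as.logical(member), dim = dim(member))
  if (anyNA(member)) stop("mask may not contain NA")
  spacing <- as.double(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive numbers")
  structure(member, spacing = spacing, class = c("cell_mask", "array"))
}

#' @rdname cell_mask
#' @param x a `cell_mask`.
#' @export
mask_volume_um3 <- function(x) sum(x) * voxel_volume(x)

#' @export
print.cell_mask <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<cell_mask> %d x %d x %d (z,y,x), %d voxels, %.2f um^3\n",
              d[1], d[2], d[3], sum(x), mask_volume_um3(x)))
  invisible(x)
}

#' Per-cell metadata record
#'
#' Carries the externally annotated labels the analysis consumes: the
#' experimental condition, the mitotic stage (assigned manually from a
#' chromatin counterstain during acquisition review), and the annotated
#' dorsal-ventral axis used for polarity bisection.
#'
#' @param cell_id unique identifier within a run.
#' @param condition condition label (free categorical).
#' @param stage stage label; one of `stage_vocabulary()` or a treatment name
#'   declared via `extra_stages`.
#' @param ventral_axis signed axis pointing ventrally: one of
#'   `"+z","-z","+y","-y","+x","-x"`, or `NA` if unannotated.
#' @param extra_stages additional stage labels to accept.
#' @return A one-row `data.frame` of class `cell_record`.
#' @export
cell_record <- function(cell_id, condition = "control", stage = "premitotic",
                        ventral_axis = NA_character_, extra_stages = character()) {
  vocab <- c(stage_vocabulary(), extra_stages)
  if (!stage %in% vocab)
    stop(sprintf("stage '%s' not in declared vocabulary (%s)",
                 stage, paste(vocab, collapse = ", ")))
  if (!is.na(ventral_axis) && !ventral_axis %in% names(axis_table()))
    stop("ventral_axis must be one of +z,-z,+y,-y,+x,-x or NA")
  out <- data.frame(cell_id = as.character(cell_id),
                    condition = as.character(condition),
                    stage = as.character(stage),
                    ventral_axis = as.character(ventral_axis),
                    stringsAsFactors = FALSE)
  class(out) <- c("cell_record", "data.frame")
  out
}

#' Mitotic stage vocabulary
#' @return Character vector of the stage labels accepted by default.
#' @export
stage_vocabulary <- function() {
  c("premitotic", "prophase", "metaphase", "anaphase", "post-mitotic")
}

# signed axis label -> (axis index in (z,y,x), sign)
axis_table <- function() {
  list("+z" = c(1L,  1L), "-z" = c(1L, -1L),
       "+y" = c(2L,  1L), "-y" = c(2L, -1L),
       "+x" = c(3L,  1L), "-x" = c(3L, -1L))
}
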