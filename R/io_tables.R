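# Tabular results I/O, JSON run configuration, and structured logging.

#' Write per-cell statistics to CSV
#'
#' Numeric fields are written at full double precision (15 significant
#' digits), so a write/read round trip is lossless well beyond the 12
#' significant digits the results are reported at.
#'
#' @param rows a `data.frame` (possibly 0-row) sharing one schema.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("`rows` must be a data.frame")
  utils::write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default pipeline configuration
#'
#' Defaults mirror the analysis parameters the method was described with:
#' shell boundaries 1 and 3 um, 95th-percentile puncta threshold,
#' quantification smoothing sigma 0.1 um, minimum object volume 10 um^3,
#' z-step 0.3 um. The x/y pixel size of the acquisition is not derivable
#' from image files alone, so spacing must always be supplied (here the
#' ~0.1 um/px of a 40x objective with 4x zoom at 1024x1024).
#'
#' @return A named list with the configuration schema.
#' @export
default_config <- function() {
  list(
    spacing = c(0.3, 0.1, 0.1),     # (dz, dy, dx) um
    boundaries = c(1, 3),           # shell cut points b1 < b2, um
    percentile = 95,                # puncta threshold rank, % within mask
    quant_sigma_um = 0.1,           # 2D smoothing before puncta threshold
    seg_sigma_um = 0.5,             # 2D smoothing before Otsu binarization
    otsu_scale = 1.0,               # threshold = otsu * scale
    disk_radius_px = 2L,            # plane-wise dilate/fill/erode element
    min_volume_um3 = 10,            # prune objects below this, um^3
    channels = list(receptor = 1L, rab = 2L),
    seed = 1L
  )
}

#' Read and validate a pipeline configuration file (JSON)
#' @param path JSON file; keys override [default_config()].
#' @return validated config list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config not found: %s", path))
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(default_config(), user)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg configuration list.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (length(cfg$spacing) != 3 || any(cfg$spacing <= 0))
    stop("config: spacing must be 3 positive numbers (dz, dy, dx)")
  b <- cfg$boundaries
  if (length(b) != 2 || !(0 < b[1] && b[1] < b[2]))
    stop("config: boundaries must satisfy 0 < b1 < b2")
  if (!(cfg$percentile > 0 && cfg$percentile < 100))
    stop("config: percentile must be in (0, 100)")
  if (cfg$quant_sigma_um < 0 || cfg$seg_sigma_um < 0)
    stop("config: smoothing sigmas must be >= 0")
  if (cfg$otsu_scale < 0) stop("config: otsu_scale must be >= 0")
  if (cfg$min_volume_um3 < 0) stop("config: min_volume_um3 must be >= 0")
  cfg
}

# terse structured logging to stderr (and optionally a file)
cs_log <- function(fmt, ..., level = "INFO", file = NULL) {
  line <- sprintf("[cytoshell] %s %s", level, sprintf(fmt, ...))
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE, sep = "")
  invisible(line)
}
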