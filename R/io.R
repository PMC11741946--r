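# Standard-format I/O: quantity maps as 32-bit float single-page TIFF with a
# JSON sidecar, region labels as 16-bit integer TIFF, tables as CSV. The TIFF
# writer stores samples affinely mapped into [0, 1] (the float TIFF range the
# `tiff` package guarantees round-trips) and records the offset and scale in
# the sidecar, so values are restored on read (to 32-bit float precision).

#' Write a quantity map as 32-bit float TIFF with JSON sidecar
#'
#' @param values Numeric `ny` x `nx` matrix (finite).
#' @param path Output TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @param grid Optional [grid_spec()] recorded in the sidecar.
#' @param meta Optional named list of extra metadata for the sidecar.
#' @return `path`, invisibly.
#' @export
write_map_tiff <- function(values, path, grid = NULL, meta = list()) {
  values <- as.matrix(values)
  if (any(!is.finite(values)))
    stop("write_map_tiff: values must be finite", call. = FALSE)
  offset <- min(values)
  scale <- max(values) - offset
  if (scale <= 0) scale <- 1  # constant map
  tiff::writeTIFF((values - offset) / scale, path,
                  bits.per.sample = 32L, reduce = FALSE)
  side <- c(list(scale = scale, offset = offset,
                 ny = nrow(values), nx = ncol(values)), meta)
  if (!is.null(grid)) side$grid <- list(nx = grid$nx, ny = grid$ny, h = grid$h)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a map written by [write_map_tiff()]
#'
#' @param path TIFF path.
#' @return List with `values` (matrix, original scale) and `meta` (sidecar
#'   contents).
#' @export
read_map_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- tiff::readTIFF(path)
  off <- if (is.null(meta$offset)) 0 else meta$offset
  list(values = v * meta$scale + off, meta = meta)
}

#' Write a region label map as 16-bit integer TIFF
#'
#' The legend travels in the JSON sidecar.
#'
#' @param labels A [region_label_map()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_labels_tiff <- function(labels, path) {
  stopifnot(inherits(labels, "region_label_map"))
  lm <- labels$labels
  if (max(lm) > 65535L) stop("write_labels_tiff: labels exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(lm / 65535, path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(list(legend = labels$legend),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label map written by [write_labels_tiff()]
#'
#' @param path TIFF path.
#' @return A [region_label_map()].
#' @export
read_labels_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  lm <- round(tiff::readTIFF(path) * 65535)
  storage.mode(lm) <- "integer"
  region_label_map(lm, as.data.frame(meta$legend))
}

#' Write a phantom bundle to a directory
#'
#' Writes `mu_a.tif`, `mu_s_prime.tif` (32-bit float), `labels.tif`
#' (16-bit integer) and `marker.json` (marker pixel list and per-wavelength
#' absorption).
#'
#' @param phantom Phantom list with `optics`, `labels`, `marker`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_bundle <- function(phantom, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  g <- phantom$optics$grid
  write_map_tiff(phantom$optics$mu_a, file.path(dir, "mu_a.tif"), grid = g)
  write_map_tiff(phantom$optics$mu_s_prime, file.path(dir, "mu_s_prime.tif"),
                 grid = g)
  write_labels_tiff(phantom$labels, file.path(dir, "labels.tif"))
  jsonlite::write_json(
    list(pixels = phantom$marker$pixels,
         mu_a_marker = phantom$marker$mu_a_marker,
         n_in = phantom$optics$n_in, n_out = phantom$optics$n_out,
         grid = list(nx = g$nx, ny = g$ny, h = g$h)),
    file.path(dir, "marker.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom bundle written by [write_phantom_bundle()]
#'
#' @param dir Bundle directory.
#' @return Phantom list with `optics`, `labels`, `marker`.
#' @export
read_phantom_bundle <- function(dir) {
  mk <- jsonlite::read_json(file.path(dir, "marker.json"), simplifyVector = TRUE)
  g <- grid_spec(mk$grid$nx, mk$grid$ny, mk$grid$h)
  mu_a <- read_map_tiff(file.path(dir, "mu_a.tif"))$values
  mu_s <- read_map_tiff(file.path(dir, "mu_s_prime.tif"))$values
  list(optics = optical_map(mu_a, mu_s, g, n_in = mk$n_in, n_out = mk$n_out),
       labels = read_labels_tiff(file.path(dir, "labels.tif")),
       marker = marker_prior(mk$pixels, mk$mu_a_marker, g))
}

#' Write an inversion result bundle
#'
#' Writes `mu_a_hat.tif` (32-bit float), `error_trace.csv`,
#' `region_traces.csv` (when present) and `run.json` (config echo,
#' iterations, convergence).
#'
#' @param result An `inversion_result`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(result, dir) {
  stopifnot(inherits(result, "inversion_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_map_tiff(result$mu_a_hat, file.path(dir, "mu_a_hat.tif"),
                 grid = result$grid)
  utils::write.csv(data.frame(iteration = seq_along(result$error_trace),
                              log_sq_error = result$error_trace),
                   file.path(dir, "error_trace.csv"), row.names = FALSE)
  if (!is.null(result$region_traces))
    utils::write.csv(as.data.frame(result$region_traces),
                     file.path(dir, "region_traces.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(method = result$method, iterations_used = result$iterations_used,
         converged = result$converged, reason = result$reason,
         config = result$config[!vapply(result$config, is.null, logical(1))]),
    file.path(dir, "run.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
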