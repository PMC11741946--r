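#' Regular image grid specification
#'
#' Describes the pixel raster all phantoms, fluence fields and absorbed-energy
#' maps live on. Pixel `(i, j)` (row `i` from the top, column `j` from the
#' left, 1-based) has its center at `x = (j - 0.5) * h`, `y = (i - 0.5) * h`,
#' with `y` increasing downward (image convention). FEM nodes are placed at
#' pixel centers, so the meshed domain is the bounding box of the centers.
#'
#' @param nx Number of columns (pixels in x). Must be at least 3.
#' @param ny Number of rows (pixels in y). Must be at least 3.
#' @param h Pixel spacing in mm. Must be positive.
#' @return An object of class `grid_spec` with fields `nx`, `ny`, `h` and the
#'   physical `extent` `c(nx * h, ny * h)` in mm.
#' @examples
#' g <- grid_spec(100, 100, 0.2)  # 20 mm x 20 mm
#' g$extent
#' @export
grid_spec <- function(nx, ny, h) {
  nx <- as.integer(nx); ny <- as.integer(ny)
  if (is.na(nx) || is.na(ny) || nx < 3L || ny < 3L)
    stop("grid_spec: nx and ny must be integers >= 3", call. = FALSE)
  if (!is.finite(h) || h <= 0)
    stop("grid_spec: pixel spacing h must be > 0", call. = FALSE)
  structure(list(nx = nx, ny = ny, h = h, extent = c(nx * h, ny * h)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, h = %g mm (%g x %g mm)\n",
              x$nx, x$ny, x$h, x$extent[1], x$extent[2]))
  invisible(x)
}

#' Per-pixel optical property maps
#'
#' Bundles the absorption coefficient and reduced scattering coefficient maps
#' with the refractive indices used by the diffusion boundary condition. The
#' anisotropy factor is absorbed into the reduced scattering coefficient
#' `mu_s' = (1 - g) * mu_s` and is not stored separately. A warning is issued
#' when `max(mu_a) >= min(mu_s_prime)` because the diffusion approximation
#' assumes scattering-dominated transport (`mu_s' >> mu_a`).
#'
#' @param mu_a Absorption coefficient matrix (`ny` x `nx`), 1/mm, non-negative.
#' @param mu_s_prime Reduced scattering coefficient, 1/mm. Either a matrix of
#'   the same shape or a single positive scalar (expanded to the grid).
#' @param grid A [grid_spec()].
#' @param n_in Refractive index inside the boundary (tissue), default 1.33.
#' @param n_out Refractive index outside the boundary (air), default 1.0.
#' @return An object of class `optical_map`.
#' @export
optical_map <- function(mu_a, mu_s_prime, grid, n_in = 1.33, n_out = 1.0) {
  stopifnot(inherits(grid, "grid_spec"))
  mu_a <- as.matrix(mu_a)
  if (length(mu_s_prime) == 1L)
    mu_s_prime <- matrix(mu_s_prime, grid$ny, grid$nx)
  mu_s_prime <- as.matrix(mu_s_prime)
  if (!all(dim(mu_a) == c(grid$ny, grid$nx)) ||
      !all(dim(mu_s_prime) == c(grid$ny, grid$nx)))
    stop("optical_map: map shapes must be ny x nx", call. = FALSE)
  if (any(mu_a < 0)) stop("optical_map: mu_a must be >= 0", call. = FALSE)
  if (any(mu_s_prime <= 0)) stop("optical_map: mu_s_prime must be > 0", call. = FALSE)
  if (max(mu_a) >= min(mu_s_prime))
    warning("optical_map: max(mu_a) >= mu_s_prime somewhere; ",
            "diffusion approximation assumes mu_s' >> mu_a", call. = FALSE)
  structure(list(mu_a = mu_a, mu_s_prime = mu_s_prime, grid = grid,
                 n_in = n_in, n_out = n_out),
            class = "optical_map")
}

#' @export
print.optical_map <- function(x, ...) {
  cat(sprintf("<optical_map> %d x %d, mu_a in [%g, %g] 1/mm, mu_s' in [%g, %g] 1/mm\n",
              x$grid$ny, x$grid$nx, min(x$mu_a), max(x$mu_a),
              min(x$mu_s_prime), max(x$mu_s_prime)))
  invisible(x)
}

#' Fluence-marker prior
#'
#' The constraint that anchors the optical inversion: a set of pixels whose
#' absorption coefficient is known a priori (for example arterial blood whose
#' absorption follows from measured oxygen saturation and hematocrit).
#'
#' @param pixels Two-column integer matrix of pixel indices `(i, j)` (row,
#'   column, 1-based) covered by the marker. Must be non-empty.
#' @param mu_a_marker Known marker absorption in 1/mm; a vector with one value
#'   per wavelength (length 1 for single-wavelength studies). All positive.
#' @param grid A [grid_spec()] the indices refer to.
#' @return An object of class `marker_prior`.
#' @export
marker_prior <- function(pixels, mu_a_marker, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  pixels <- as.matrix(pixels)
  if (nrow(pixels) == 0L) stop("marker_prior: pixel set must be non-empty", call. = FALSE)
  if (ncol(pixels) != 2L) stop("marker_prior: pixels must be an (i, j) matrix", call. = FALSE)
  storage.mode(pixels) <- "integer"
  dimnames(pixels) <- NULL
  if (any(pixels[, 1] < 1L) || any(pixels[, 1] > grid$ny) ||
      any(pixels[, 2] < 1L) || any(pixels[, 2] > grid$nx))
    stop("marker_prior: pixel indices outside grid", call. = FALSE)
  if (any(!is.finite(mu_a_marker)) || any(mu_a_marker <= 0))
    stop("marker_prior: mu_a_marker must be > 0", call. = FALSE)
  structure(list(pixels = pixels, mu_a_marker = as.numeric(mu_a_marker),
                 grid = grid),
            class = "marker_prior")
}

#' Logical mask of marker pixels
#'
#' @param marker A [marker_prior()].
#' @return `ny` x `nx` logical matrix, `TRUE` at marker pixels.
#' @export
marker_mask <- function(marker) {
  stopifnot(inherits(marker, "marker_prior"))
  m <- matrix(FALSE, marker$grid$ny, marker$grid$nx)
  m[marker$pixels] <- TRUE
  m
}

#' Region label map
#'
#' Integer labels over the grid together with a legend mapping each label to a
#' region name and its ground-truth absorption. Label 0 is the background.
#'
#' @param labels `ny` x `nx` integer matrix of region labels (0 = background).
#' @param legend Data frame with columns `label`, `name` and `mu_a`
#'   (ground-truth absorption, 1/mm).
#' @return An object of class `region_label_map`.
#' @export
region_label_map <- function(labels, legend) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  stopifnot(is.data.frame(legend), all(c("label", "name", "mu_a") %in% names(legend)))
  used <- setdiff(unique(as.vector(labels)), 0L)
  if (!all(used %in% legend$label))
    stop("region_label_map: labels present in the map but missing from the legend",
         call. = FALSE)
  structure(list(labels = labels, legend = legend), class = "region_label_map")
}

# pixel center coordinates, vectorized over the whole grid (column-major order,
# matching as.vector() of a ny x nx matrix)
grid_coords <- function(grid) {
  i <- rep(seq_len(grid$ny), grid$nx)
  j <- rep(seq_len(grid$nx), each = grid$ny)
  cbind(x = (j - 0.5) * grid$h, y = (i - 0.5) * grid$h)
}
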