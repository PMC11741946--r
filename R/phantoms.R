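# Digital phantom generators. All geometry is specified in mm relative to the
# default physical extents and scales proportionally when a different (square)
# grid is supplied; region values are written as exact constants so legend
# entries match the mu_a grid bit-for-bit. Generation is fully deterministic.

disc_mask <- function(grid, cx, cy, r) {
  xy <- grid_coords(grid)
  matrix((xy[, "x"] - cx)^2 + (xy[, "y"] - cy)^2 <= r^2, grid$ny, grid$nx)
}

annulus_mask <- function(grid, cx, cy, r_in, r_out) {
  xy <- grid_coords(grid)
  d2 <- (xy[, "x"] - cx)^2 + (xy[, "y"] - cy)^2
  matrix(d2 > r_in^2 & d2 <= r_out^2, grid$ny, grid$nx)
}

#' Nine-region absorption phantom with a central fluence marker
#'
#' A 20 mm x 20 mm tissue-mimicking phantom carrying nine absorption levels
#' between 0.001 and 0.2 1/mm on a uniform scattering background
#' (`mu_s' = 2` 1/mm). A central disc of radius 2 mm with `mu_a = 0.2` 1/mm
#' acts as the fluence marker. Five scored regions probe depth-dependent
#' recovery accuracy:
#' \describe{
#'   \item{region1}{`mu_a = 0.020`, disc at (5, 5) mm, shallow.}
#'   \item{region2}{`mu_a = 0.075`, disc at (10, 4) mm, shallow.}
#'   \item{region3}{`mu_a = 0.150`, disc at (15, 6) mm, shallow.}
#'   \item{region4}{`mu_a = 0.075`, disc at (15, 14) mm, deep (below 10 mm),
#'     laterally offset from the marker shadow.}
#'   \item{region5}{`mu_a = 0.001` (background level), patch directly below
#'     the marker, probing the marker's shadow.}
#' }
#' Four additional unscored inclusions carry the remaining levels 0.005,
#' 0.010, 0.040 and 0.100 1/mm. Positions (given above for the default
#' extent) scale proportionally with the grid extent.
#'
#' @param grid Square [grid_spec()]; default `grid_spec(100, 100, 0.2)`.
#' @return A list with elements `optics` ([optical_map()]), `labels`
#'   ([region_label_map()]) and `marker` ([marker_prior()]).
#' @examples
#' ph <- make_nine_region_phantom()
#' ph$labels$legend
#' @export
make_nine_region_phantom <- function(grid = grid_spec(100, 100, 0.2)) {
  stopifnot(inherits(grid, "grid_spec"))
  if (grid$nx != grid$ny)
    stop("make_nine_region_phantom: grid must be square", call. = FALSE)
  if (grid$extent[1] < 16 || grid$nx < 50)
    stop("make_nine_region_phantom: grid too small to fit the documented geometry",
         call. = FALSE)
  s <- grid$extent[1] / 20  # proportional scaling of the documented layout
  bg <- 0.001
  mu_a <- matrix(bg, grid$ny, grid$nx)
  labels <- matrix(0L, grid$ny, grid$nx)

  regions <- data.frame(
    label = 1:10,
    name = c("region1", "region2", "region3", "region4", "region5",
             "inclusion_0.005", "inclusion_0.010", "inclusion_0.040",
             "inclusion_0.100", "marker"),
    mu_a = c(0.020, 0.075, 0.150, 0.075, 0.001, 0.005, 0.010, 0.040, 0.100, 0.200),
    cx = c(5, 10, 15, 15, 10, 4.0, 16.5, 5.5, 4.0, 10) * s,
    cy = c(5, 4, 6, 14, 15, 13.0, 10.0, 17.0, 9.0, 10) * s,
    r = c(1.5, 1.5, 1.5, 1.5, 1.5, 1.2, 1.2, 1.2, 1.2, 2.0) * s,
    stringsAsFactors = FALSE)

  for (k in seq_len(nrow(regions))) {
    m <- disc_mask(grid, regions$cx[k], regions$cy[k], regions$r[k])
    if (!any(m))
      stop("make_nine_region_phantom: grid too coarse for region ", regions$name[k],
           call. = FALSE)
    mu_a[m] <- regions$mu_a[k]
    labels[m] <- regions$label[k]
  }

  legend <- regions[, c("label", "name", "mu_a")]
  marker_px <- which(labels == 10L, arr.ind = TRUE)
  list(optics = optical_map(mu_a, 2, grid),
       labels = region_label_map(labels, legend),
       marker = marker_prior(marker_px, 0.200, grid))
}

#' Synthetic absorption spectra of the spectral phantom
#'
#' The five-wavelength spectrum table bundled with the package
#' (`inst/extdata/spectral_phantom_spectra.csv`). The unknown chromophore has
#' a unimodal spectrum peaking at the third wavelength; the background
#' absorption increases monotonically with wavelength (driving spectral
#' coloring); the marker is spectrally flat at 0.2 1/mm.
#'
#' @return Data frame with columns `wavelength_index`, `marker_mu_a`,
#'   `unknown_mu_a`, `background_mu_a` (all absorption values in 1/mm).
#' @export
spectral_phantom_table <- function() {
  path <- system.file("extdata", "spectral_phantom_spectra.csv",
                      package = "qpamarker", mustWork = TRUE)
  utils::read.csv(path)
}

#' Concentric-disc spectral phantom for one wavelength
#'
#' A 20 mm x 20 mm phantom with two concentric discs representing a
#' carotid-artery cross-section: the inner disc (radius 2 mm) is the fluence
#' marker with spectrally invariant `mu_a = 0.2` 1/mm; the annulus from 2 to
#' 5 mm is an unknown chromophore whose absorption follows the bundled
#' unimodal spectrum; the background absorption increases with wavelength.
#' Three scored sub-regions (small discs in the annulus) sit at distinct
#' bearings: region 1 lateral to the marker (same depth), regions 2 and 3
#' above it (shallower), so the equal-fluence baseline can be probed at
#' different displacements in depth.
#'
#' @param wavelength_index Integer in 1..5 selecting the wavelength.
#' @param grid Square [grid_spec()]; default `grid_spec(100, 100, 0.2)`.
#' @return A list with `optics`, `labels`, `marker` as in
#'   [make_nine_region_phantom()].
#' @export
make_spectral_phantom <- function(wavelength_index, grid = grid_spec(100, 100, 0.2)) {
  wavelength_index <- as.integer(wavelength_index)
  if (is.na(wavelength_index) || wavelength_index < 1L || wavelength_index > 5L)
    stop("make_spectral_phantom: wavelength_index must be in 1..5", call. = FALSE)
  stopifnot(inherits(grid, "grid_spec"))
  if (grid$nx != grid$ny)
    stop("make_spectral_phantom: grid must be square", call. = FALSE)
  if (grid$extent[1] < 14 || grid$nx < 40)
    stop("make_spectral_phantom: grid too small to fit the documented geometry",
         call. = FALSE)
  spec_tab <- spectral_phantom_table()
  row <- spec_tab[spec_tab$wavelength_index == wavelength_index, ]
  s <- grid$extent[1] / 20
  cx <- 10 * s; cy <- 10 * s
  mu_bg <- row$background_mu_a
  mu_unknown <- row$unknown_mu_a
  mu_marker <- row$marker_mu_a

  mu_a <- matrix(mu_bg, grid$ny, grid$nx)
  labels <- matrix(0L, grid$ny, grid$nx)
  ann <- annulus_mask(grid, cx, cy, 2 * s, 5 * s)
  mrk <- disc_mask(grid, cx, cy, 2 * s)
  mu_a[ann] <- mu_unknown
  mu_a[mrk] <- mu_marker
  labels[ann] <- 4L
  labels[mrk] <- 5L
  # scored sub-regions at mid-annulus radius 3.5 mm
  subs <- data.frame(label = 1:3,
                     name = c("region1_lateral", "region2_above", "region3_diagonal"),
                     cx = cx + c(3.5, 0, -3.5 / sqrt(2)) * s,
                     cy = cy + c(0, -3.5, -3.5 / sqrt(2)) * s)
  for (k in 1:3) {
    m <- disc_mask(grid, subs$cx[k], subs$cy[k], 0.6 * s) & ann
    labels[m] <- subs$label[k]
  }
  legend <- data.frame(
    label = c(1L, 2L, 3L, 4L, 5L),
    name = c(subs$name, "unknown_annulus", "marker"),
    mu_a = c(rep(mu_unknown, 4), mu_marker),
    stringsAsFactors = FALSE)
  marker_px <- which(mrk, arr.ind = TRUE)
  list(optics = optical_map(mu_a, 2, grid),
       labels = region_label_map(labels, legend),
       marker = marker_prior(marker_px, spec_tab$marker_mu_a, grid),
       wavelength_index = wavelength_index)
}

#' Carotid-plaque phantom at the lipid absorption peak
#'
#' A 24 mm x 24 mm phantom of a carotid artery cross-section with realistic
#' near-infrared tissue absorption at 930 nm (where lipid absorption peaks):
#' a superficial tissue layer at the top (0-2 mm, `mu_a = 0.040`), muscle
#' below it (2-5 mm, `mu_a = 0.050`), a blood-filled lumen disc (radius 2 mm,
#' `mu_a = 0.650`, the fluence marker) surrounded by a lipid plaque annulus
#' (2-3 mm, `mu_a = 0.013`) at mid depth, a background-tissue disc near 15 mm
#' depth (`mu_a = 0.040`), and background medium at 0.008 1/mm. Scattering is
#' uniform at 2 1/mm.
#'
#' @param grid Square [grid_spec()]; default `grid_spec(160, 160, 0.15)`.
#' @param marker_error Fractional error applied to the marker prior value
#'   only (the ground-truth map keeps 0.650): `0.1` means the prior believes
#'   the blood absorption is 10 percent higher than it truly is.
#' @return A list with `optics`, `labels`, `marker` as in
#'   [make_nine_region_phantom()].
#' @examples
#' ph <- make_carotid_phantom(marker_error = 0.1)
#' ph$marker$mu_a_marker  # 0.715 while the map keeps 0.650
#' @export
make_carotid_phantom <- function(grid = grid_spec(160, 160, 0.15), marker_error = 0) {
  stopifnot(inherits(grid, "grid_spec"))
  if (grid$nx != grid$ny)
    stop("make_carotid_phantom: grid must be square", call. = FALSE)
  if (grid$extent[1] < 18 || grid$nx < 60)
    stop("make_carotid_phantom: grid too small to fit the documented geometry",
         call. = FALSE)
  s <- grid$extent[1] / 24
  xy <- grid_coords(grid)
  ymat <- matrix(xy[, "y"], grid$ny, grid$nx)

  mu_a <- matrix(0.008, grid$ny, grid$nx)   # background (B)
  labels <- matrix(0L, grid$ny, grid$nx)
  st <- ymat < 2 * s                         # superficial tissue (ST)
  mu_a[st] <- 0.040; labels[st] <- 4L
  mus <- ymat >= 2 * s & ymat < 5 * s        # muscle (M)
  mu_a[mus] <- 0.050; labels[mus] <- 3L
  bt <- disc_mask(grid, 12 * s, 15 * s, 1.5 * s)  # background tissue (BT)
  mu_a[bt] <- 0.040; labels[bt] <- 5L
  lip <- annulus_mask(grid, 12 * s, 9 * s, 2 * s, 3 * s)  # lipid plaque (L)
  mu_a[lip] <- 0.013; labels[lip] <- 2L
  bl <- disc_mask(grid, 12 * s, 9 * s, 2 * s)     # blood lumen (BL), marker
  mu_a[bl] <- 0.650; labels[bl] <- 1L

  legend <- data.frame(
    label = c(1L, 2L, 3L, 4L, 5L, 0L),
    name = c("blood", "lipid", "muscle", "superficial_tissue",
             "background_tissue", "background"),
    mu_a = c(0.650, 0.013, 0.050, 0.040, 0.040, 0.008),
    stringsAsFactors = FALSE)
  marker_px <- which(bl, arr.ind = TRUE)
  list(optics = optical_map(mu_a, 2, grid),
       labels = region_label_map(labels, legend),
       marker = marker_prior(marker_px, 0.650 * (1 + marker_error), grid))
}

#' Analytic two-layer Beer-Lambert fixture
#'
#' Scalar absorbed-energy pair for a homogeneous unknown layer of thickness
#' `thickness_r` above a fluence marker, under one-dimensional Beer-Lambert
#' attenuation with surface fluence `phi0 = 1`:
#' `H_unknown = mu_a_unknown * phi0` at the layer surface and
#' `H_marker = mu_a_marker * phi0 * exp(-mu_a_unknown * thickness_r)` at the
#' marker. Used as the round-trip fixture for the direct marker inversion and
#' the equal-fluence baseline.
#'
#' @param mu_a_unknown Absorption of the unknown layer, 1/mm, positive.
#' @param mu_a_marker Absorption of the marker, 1/mm, positive.
#' @param thickness_r Optical path length from the surface reading to the
#'   marker, mm, non-negative.
#' @param phi0 Surface fluence (arbitrary units, default 1).
#' @return List with `H_unknown`, `H_marker` and an echo of the inputs.
#' @export
make_two_layer_phantom <- function(mu_a_unknown, mu_a_marker, thickness_r, phi0 = 1) {
  if (!is.finite(mu_a_unknown) || mu_a_unknown <= 0 ||
      !is.finite(mu_a_marker) || mu_a_marker <= 0)
    stop("make_two_layer_phantom: absorption coefficients must be > 0", call. = FALSE)
  if (!is.finite(thickness_r) || thickness_r < 0)
    stop("make_two_layer_phantom: thickness_r must be >= 0", call. = FALSE)
  if (!is.finite(phi0) || phi0 <= 0)
    stop("make_two_layer_phantom: phi0 must be > 0", call. = FALSE)
  list(H_unknown = mu_a_unknown * phi0,
       H_marker = mu_a_marker * phi0 * exp(-mu_a_unknown * thickness_r),
       mu_a_unknown = mu_a_unknown, mu_a_marker = mu_a_marker,
       thickness_r = thickness_r, phi0 = phi0)
}
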