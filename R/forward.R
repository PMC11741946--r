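# Diffusion-approximation forward model: sources, system assembly, fluence
# solves, absorbed energy and measurement-noise synthesis.

#' Default boundary source set
#'
#' Gaussian sources placed one grid spacing inside the mesh boundary,
#' equally spaced by arc length around the inset rectangle, starting at the
#' midpoint of the top edge and proceeding clockwise. Each source's nodal
#' load is normalized to unit total power.
#'
#' @param grid A [grid_spec()].
#' @param n_sources Number of sources (default 10).
#' @param width Gaussian standard deviation in mm (default the grid spacing).
#' @param power Total injected power per source in arbitrary units (default 1).
#' @return An object of class `source_set` with `positions` (n x 2, mm),
#'   `width` and `power`.
#' @export
default_sources <- function(grid, n_sources = 10, width = grid$h, power = 1) {
  stopifnot(inherits(grid, "grid_spec"))
  n_sources <- as.integer(n_sources)
  if (is.na(n_sources) || n_sources < 1L)
    stop("default_sources: n_sources must be >= 1", call. = FALSE)
  if (!is.finite(width) || width <= 0)
    stop("default_sources: width must be > 0", call. = FALSE)
  h <- grid$h
  # mesh boundary is the bounding box of the pixel centers; inset by h
  x0 <- h / 2 + h; x1 <- (grid$nx - 0.5) * h - h
  y0 <- h / 2 + h; y1 <- (grid$ny - 0.5) * h - h
  if (x1 <= x0 || y1 <= y0)
    stop("default_sources: grid too small for an inset source rectangle", call. = FALSE)
  wx <- x1 - x0; wy <- y1 - y0
  per <- 2 * (wx + wy)
  # arc-length position along the rectangle, clockwise from the top midpoint
  s <- (seq_len(n_sources) - 1) * per / n_sources
  pos <- t(vapply(s, function(si) {
    si <- (si + wx / 2) %% per  # start at top-edge midpoint
    if (si < wx) c(x0 + si, y0)
    else if (si < wx + wy) c(x1, y0 + (si - wx))
    else if (si < 2 * wx + wy) c(x1 - (si - wx - wy), y1)
    else c(x0, y1 - (si - 2 * wx - wy))
  }, numeric(2)))
  structure(list(positions = pos, width = width, power = power),
            class = "source_set")
}

# Nodal load vectors for a source set: truncated Gaussian of standard
# deviation `width` (cut at 3 * width), normalized to total power.
source_loads <- function(mesh, sources) {
  stopifnot(inherits(mesh, "fem_mesh"), inherits(sources, "source_set"))
  ns <- nrow(sources$positions)
  q <- matrix(0, mesh$n_nodes, ns)
  s2 <- sources$width^2
  cut2 <- (3 * sources$width)^2
  for (k in seq_len(ns)) {
    d2 <- (mesh$nodes[, 1] - sources$positions[k, 1])^2 +
          (mesh$nodes[, 2] - sources$positions[k, 2])^2
    g <- exp(-d2 / (2 * s2))
    g[d2 > cut2] <- 0
    tot <- sum(g)
    if (tot <= 0) stop("source_loads: source has no support on the mesh", call. = FALSE)
    q[, k] <- sources$power * g / tot
  }
  q
}

#' Assemble the FEM diffusion system
#'
#' Builds the symmetric positive-definite sparse operator for
#' `mu_a * phi - div(kappa grad phi) = q0` with `kappa = 1/(3 (mu_a + mu_s'))`
#' evaluated element-wise, and the Robin exit-only boundary term
#' `phi / (2A)` with `A` from [boundary_reflection_A()].
#'
#' @param mesh A [build_mesh()] result.
#' @param optics An [optical_map()] on the same grid.
#' @return An object of class `qpa_system`: the operator `K`, the boundary
#'   mass matrix `B` (outflow operator, already divided by `2A`), element
#'   diffusion coefficients `kappa_e`, element absorption `mu_e`, boundary
#'   coefficient `A_refl` and nodal areas `w`.
#' @export
assemble_system <- function(mesh, optics) {
  stopifnot(inherits(mesh, "fem_mesh"), inherits(optics, "optical_map"))
  if (!all(dim(optics$mu_a) == c(mesh$grid$ny, mesh$grid$nx)))
    stop("assemble_system: optics does not match mesh grid", call. = FALSE)
  if (any(optics$mu_s_prime <= 0))
    stop("assemble_system: mu_s_prime must be > 0", call. = FALSE)
  A_refl <- boundary_reflection_A(optics$n_in, optics$n_out)
  op <- fem_operator(mesh, as.vector(optics$mu_a), as.vector(optics$mu_s_prime),
                     A_refl)
  ea <- mesh$boundary_edges[, 1]; eb <- mesh$boundary_edges[, 2]
  B <- Matrix::sparseMatrix(
    i = c(ea, eb, pmax(ea, eb)), j = c(ea, eb, pmin(ea, eb)),
    x = c(mesh$edge_len * 2 / 6, mesh$edge_len * 2 / 6, mesh$edge_len / 6) /
      (2 * A_refl),
    dims = c(mesh$n_nodes, mesh$n_nodes), symmetric = TRUE)
  structure(list(K = op$K, B = B, kappa_e = op$kappa_e, mu_e = op$mu_e,
                 A_refl = A_refl, w = mesh$w),
            class = "qpa_system")
}

#' Solve for the fluence field
#'
#' Factorizes the assembled operator and solves for the fluence under the
#' given sources. With multiple sources the returned field is the
#' superposition (the solve uses the summed load, which is identical by
#' linearity). The relative residual of the solve is checked against 1e-10.
#'
#' @param mesh A [build_mesh()] result.
#' @param optics An [optical_map()].
#' @param sources A [default_sources()] source set.
#' @param by_source If `TRUE`, additionally return the per-source fields.
#' @param system Optional pre-assembled [assemble_system()] result.
#' @return An object of class `fluence_field`: `values` (`ny` x `nx` matrix,
#'   arbitrary fluence units), `role = "fluence"`, and `per_source` when
#'   requested.
#' @export
solve_fluence <- function(mesh, optics, sources, by_source = FALSE, system = NULL) {
  if (is.null(system)) system <- assemble_system(mesh, optics)
  q <- source_loads(mesh, sources)
  ch <- fem_factor(system$K)
  qt <- rowSums(q)
  phi <- as.numeric(Matrix::solve(ch, qt, system = "A"))
  res <- sqrt(sum((as.numeric(system$K %*% phi) - qt)^2)) / sqrt(sum(qt^2))
  if (!is.finite(res) || res > 1e-10)
    stop(structure(class = c("qpa_numerical_error", "error", "condition"),
                   list(message = sprintf(
                     "solve_fluence: relative residual %.3e exceeds 1e-10", res),
                     call = NULL)))
  out <- structure(list(values = matrix(phi, mesh$grid$ny, mesh$grid$nx),
                        role = "fluence", grid = mesh$grid),
                   class = "fluence_field")
  if (by_source) {
    ps <- Matrix::solve(ch, q, system = "A")
    out$per_source <- lapply(seq_len(ncol(q)), function(k)
      matrix(as.numeric(ps[, k]), mesh$grid$ny, mesh$grid$nx))
  }
  out
}

#' Absorbed energy density
#'
#' `H(i, j) = mu_a(i, j) * phi(i, j)`, the quantity an ideally reconstructed
#' photoacoustic image is proportional to (Grueneisen parameter taken as 1).
#'
#' @param optics An [optical_map()].
#' @param phi A [fluence_field][solve_fluence()] or a bare `ny` x `nx` matrix.
#' @return An object of class `absorbed_energy_map` with `values`, a
#'   `role` tag (`"modeled"`), `snr_db = Inf` and `seed = NULL`.
#' @export
absorbed_energy <- function(optics, phi) {
  v <- if (inherits(phi, "fluence_field")) phi$values else as.matrix(phi)
  if (!all(dim(v) == dim(optics$mu_a)))
    stop("absorbed_energy: shapes do not match", call. = FALSE)
  structure(list(values = optics$mu_a * v, role = "modeled",
                 snr_db = Inf, seed = NULL, grid = optics$grid),
            class = "absorbed_energy_map")
}

#' Add measurement noise at a stated SNR
#'
#' Additive zero-mean white Gaussian noise whose variance is set from the
#' measured signal power, `var = mean(H^2) / 10^(snr_db / 10)`. The result is
#' tagged as a measured map (`H_M`). `snr_db = Inf` disables noise.
#'
#' @param H An [absorbed_energy_map()] (or matrix).
#' @param snr_db Signal-to-noise ratio in decibels.
#' @param seed Integer seed making the noise reproducible; the global RNG
#'   state is restored afterwards.
#' @return An `absorbed_energy_map` with `role = "measured"`.
#' @export
add_noise <- function(H, snr_db, seed = NULL) {
  v <- if (inherits(H, "absorbed_energy_map")) H$values else as.matrix(H)
  grid <- if (inherits(H, "absorbed_energy_map")) H$grid else NULL
  if (!is.numeric(snr_db) || is.na(snr_db))
    stop("add_noise: snr_db must be numeric", call. = FALSE)
  if (is.finite(snr_db)) {
    p_sig <- mean(v^2)
    sd_n <- sqrt(p_sig / 10^(snr_db / 10))
    v <- v + local_rnorm(length(v), sd = sd_n, seed = seed)
  }
  structure(list(values = v, role = "measured", snr_db = snr_db, seed = seed,
                 grid = grid),
            class = "absorbed_energy_map")
}

# Gaussian draws under a local seed, restoring the caller's RNG state.
local_rnorm <- function(n, sd, seed = NULL) {
  if (is.null(seed)) return(stats::rnorm(n, sd = sd))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  stats::rnorm(n, sd = sd)
}

#' Beer-Lambert fluence decay
#'
#' `phi(r) = phi0 * exp(-mu_a * r)`: one-dimensional exponential attenuation
#' used by the homogeneous-medium direct inversion.
#'
#' @param phi0 Surface fluence (arbitrary units).
#' @param mu_a Absorption coefficient, 1/mm, non-negative.
#' @param r Path length, mm, non-negative.
#' @return Fluence at depth `r` (vectorized over the inputs).
#' @export
beer_lambert_fluence <- function(phi0, mu_a, r) {
  if (any(r < 0)) stop("beer_lambert_fluence: r must be >= 0", call. = FALSE)
  if (any(mu_a < 0)) stop("beer_lambert_fluence: mu_a must be >= 0", call. = FALSE)
  phi0 * exp(-mu_a * r)
}

#' Power-balance diagnostic
#'
#' Splits the injected power into absorbed power (mass-lumped
#' `sum(w * mu_a * phi)`) and boundary outflow (`sum(B phi)`). For a
#' consistent discretization the two sides agree up to the lumping error.
#'
#' @param mesh,optics,sources As in [solve_fluence()].
#' @return List with `absorbed`, `outflow`, `injected` and the relative
#'   imbalance `rel_error`.
#' @export
power_balance <- function(mesh, optics, sources) {
  system <- assemble_system(mesh, optics)
  phi <- solve_fluence(mesh, optics, sources, system = system)
  pv <- as.vector(phi$values)
  absorbed <- sum(mesh$w * as.vector(optics$mu_a) * pv)
  outflow <- sum(as.numeric(system$B %*% pv))
  injected <- nrow(sources$positions) * sources$power
  list(absorbed = absorbed, outflow = outflow, injected = injected,
       rel_error = abs(absorbed + outflow - injected) / injected)
}
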