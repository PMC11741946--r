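# Finite-element mesh derived from the Cartesian pixel grid. One node per
# pixel center; every grid cell between four neighbouring nodes is split into
# two triangles by the same diagonal (top-left to bottom-right), giving
# 2*(nx-1)*(ny-1) congruent right triangles. Element optical properties are
# taken from the pixel at the cell's top-left corner node -- no interpolation.
#
# build_mesh() also precomputes an assembly plan (sparsity pattern template
# plus a triplet-to-slot permutation) so that reassembling the FEM operator
# for a new absorption map inside the inversion loop costs only a value
# aggregation, not a fresh symbolic sparse construction.

#' Build the triangular FEM mesh for a pixel grid
#'
#' @param grid A [grid_spec()] with `nx, ny >= 2`.
#' @return An object of class `fem_mesh` with nodes (pixel centers, mm),
#'   element connectivity, the element-to-pixel assignment, boundary
#'   nodes/edges, mass-lumped nodal areas `w` (mm^2), and the precomputed
#'   assembly plan used by [assemble_system()].
#' @examples
#' m <- build_mesh(grid_spec(3, 3, 0.2))
#' m$n_nodes       # 9
#' nrow(m$elems)   # 8
#' @export
build_mesh <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  nx <- grid$nx; ny <- grid$ny; h <- grid$h
  if (nx < 2L || ny < 2L)
    stop("build_mesh: need at least a 2 x 2 grid", call. = FALSE)
  nn <- nx * ny
  nodes <- grid_coords(grid)
  idx <- function(i, j) (j - 1L) * ny + i

  ci <- rep(seq_len(ny - 1L), nx - 1L)
  cj <- rep(seq_len(nx - 1L), each = ny - 1L)
  n1 <- idx(ci, cj); n2 <- idx(ci + 1L, cj)
  n3 <- idx(ci + 1L, cj + 1L); n4 <- idx(ci, cj + 1L)
  # diagonal n1 -- n3 splits each cell into two triangles
  elems <- rbind(cbind(n1, n2, n3), cbind(n1, n3, n4))
  colnames(elems) <- NULL
  elem_pixel <- rep(idx(ci, cj), 2L)  # pixel at the cell's top-left corner
  ne <- nrow(elems)

  x1 <- nodes[elems[, 1], 1]; y1 <- nodes[elems[, 1], 2]
  x2 <- nodes[elems[, 2], 1]; y2 <- nodes[elems[, 2], 2]
  x3 <- nodes[elems[, 3], 1]; y3 <- nodes[elems[, 3], 2]
  area <- 0.5 * abs(x1 * (y2 - y3) + x2 * (y3 - y1) + x3 * (y1 - y2))
  if (any(area <= 0)) stop("build_mesh: degenerate element", call. = FALSE)
  # linear shape-function gradient coefficients: grad N_i = (b_i, c_i) / (2A)
  b1 <- y2 - y3; b2 <- y3 - y1; b3 <- y1 - y2
  c1 <- x3 - x2; c2 <- x1 - x3; c3 <- x2 - x1
  bc <- list(cbind(b1, c1), cbind(b2, c2), cbind(b3, c3))
  # unit-kappa stiffness entries for local pairs (1,1) (2,1) (2,2) (3,1) (3,2) (3,3)
  pair_i <- c(1L, 2L, 2L, 3L, 3L, 3L)
  pair_j <- c(1L, 1L, 2L, 1L, 2L, 3L)
  Sgeom <- matrix(0, ne, 6L)
  for (k in 1:6) {
    bi <- bc[[pair_i[k]]]; bj <- bc[[pair_j[k]]]
    Sgeom[, k] <- (bi[, 1] * bj[, 1] + bi[, 2] * bj[, 2]) / (4 * area)
  }
  # unit-mu_a consistent mass entries: (A/12) * [2 on diagonal, 1 off]
  Mgeom <- (area / 12) * matrix(rep(c(2, 1, 2, 1, 1, 2), each = ne), ne, 6L)

  trip_i <- as.vector(elems[, pair_i])
  trip_j <- as.vector(elems[, pair_j])

  # boundary: the outer ring of nodes, edges between consecutive ring nodes
  bi_top <- idx(1L, seq_len(nx)); bi_right <- idx(seq_len(ny), nx)
  bi_bottom <- idx(ny, rev(seq_len(nx))); bi_left <- idx(rev(seq_len(ny)), 1L)
  ring <- c(bi_top, bi_right[-1L], bi_bottom[-1L], bi_left[-1L])
  ring <- ring[-length(ring)]  # closed loop, drop repeated start
  boundary_nodes <- ring
  e_a <- ring; e_b <- c(ring[-1L], ring[1L])
  edge_len <- sqrt(rowSums((nodes[e_a, , drop = FALSE] - nodes[e_b, , drop = FALSE])^2))
  boundary_edges <- cbind(e_a, e_b)
  colnames(boundary_edges) <- NULL
  # edge mass matrix (L/6) [2 1; 1 2]; stored before division by 2A
  btrip_i <- c(e_a, e_b, pmax(e_a, e_b))
  btrip_j <- c(e_a, e_b, pmin(e_a, e_b))
  btrip_v <- c(edge_len * 2 / 6, edge_len * 2 / 6, edge_len / 6)

  # mass-lumped nodal areas
  w <- numeric(nn)
  av <- area / 3
  for (k in 1:3) {
    acc <- rowsum(av, elems[, k])
    w[as.integer(rownames(acc))] <- w[as.integer(rownames(acc))] + acc[, 1]
  }

  # assembly plan: canonical lower-triangle triplets -> template slots
  ii <- c(trip_i, btrip_i); jj <- c(trip_j, btrip_j)
  lo_i <- pmax(ii, jj); lo_j <- pmin(ii, jj)
  template <- Matrix::sparseMatrix(i = lo_i, j = lo_j, x = 1,
                                   dims = c(nn, nn), symmetric = TRUE)
  ti <- template@i + 1L
  tj <- rep(seq_len(nn), diff(template@p))
  key_t <- (pmax(ti, tj) - 1) * nn + pmin(ti, tj)
  key_trip <- (lo_i - 1) * nn + lo_j
  perm <- match(key_trip, key_t)
  stopifnot(!anyNA(perm), length(unique(perm)) == length(key_t))

  structure(list(
    grid = grid, nodes = nodes, elems = elems, elem_pixel = elem_pixel,
    area = area, Sgeom = Sgeom, Mgeom = Mgeom,
    boundary_nodes = boundary_nodes, boundary_edges = boundary_edges,
    edge_len = edge_len, w = w, n_nodes = nn,
    plan = list(template = template, perm = perm,
                n_elem_trip = length(trip_i), btrip_v = btrip_v)),
    class = "fem_mesh")
}

#' @export
print.fem_mesh <- function(x, ...) {
  cat(sprintf("<fem_mesh> %d nodes, %d triangles, %d boundary nodes\n",
              x$n_nodes, nrow(x$elems), length(x$boundary_nodes)))
  invisible(x)
}

#' Internal-reflection boundary coefficient
#'
#' Coefficient `A` of the Robin (type III) boundary condition
#' `phi + 2 A kappa dphi/dn = 0`, modelling light that can exit the tissue
#' but not return. Uses the standard polynomial fit to the effective internal
#' reflection coefficient for a refractive-index mismatch
#' (Schweiger et al., as used by diffuse-optics FEM packages):
#' `R_eff = -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n` with
#' `n = n_in / n_out`, and `A = (1 + R_eff) / (1 - R_eff)`.
#'
#' @param n_in Refractive index inside the boundary (tissue).
#' @param n_out Refractive index outside (air).
#' @return The scalar boundary coefficient `A` (close to 1 for matched
#'   indices, larger for a tissue-air mismatch).
#' @export
boundary_reflection_A <- function(n_in = 1.33, n_out = 1.0) {
  n <- n_in / n_out
  if (!is.finite(n) || n <= 0)
    stop("boundary_reflection_A: invalid refractive indices", call. = FALSE)
  r_eff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
  (1 + r_eff) / (1 - r_eff)
}

# Fast FEM operator assembly from precomputed plan.
# mu_a_vec, mu_s_vec: per-pixel values in column-major node order.
# Returns the symmetric sparse operator K encoding
#   mu_a * phi - div(kappa grad phi)  with Robin boundary term phi / (2A).
fem_operator <- function(mesh, mu_a_vec, mu_s_vec, A_refl) {
  mu_e <- mu_a_vec[mesh$elem_pixel]
  mus_e <- mu_s_vec[mesh$elem_pixel]
  kappa_e <- 1 / (3 * (mu_e + mus_e))
  vals <- as.vector(mesh$Sgeom * kappa_e + mesh$Mgeom * mu_e)
  allv <- c(vals, mesh$plan$btrip_v / (2 * A_refl))
  xu <- rowsum(allv, mesh$plan$perm)
  K <- mesh$plan$template
  K@x <- as.vector(xu)
  list(K = K, kappa_e = kappa_e, mu_e = mu_e)
}

# Cholesky factorization with optional symbolic reuse; wraps failures in a
# condition carrying class "qpa_numerical_error".
fem_factor <- function(K, factor = NULL) {
  tryCatch({
    if (is.null(factor)) Matrix::Cholesky(K, LDL = FALSE, super = TRUE)
    else Matrix::update(factor, K)
  }, error = function(e) {
    stop(structure(class = c("qpa_numerical_error", "error", "condition"),
                   list(message = paste0("FEM factorization failed: ",
                                         conditionMessage(e)),
                        call = sys.call(-1))))
  })
}
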