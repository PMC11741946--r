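# Adjoint-state machinery for the gradient-based methods. The error
# functional is the mass-lumped discrete misfit
#   epsilon(mu_a) = 1/2 sum_i w_i (H_M - H_C)_i^2,  H_C = mu_a * phi(mu_a),
# where w are the nodal areas. Because the discrete diffusion operator is
# self-adjoint, the adjoint field solves the same factorized system with the
# weighted residual as source. The gradient returned here is the exact
# gradient of the discrete functional: besides the data term and the
# adjoint-mass term it carries the sensitivity of the diffusion coefficient
# kappa = 1/(3 (mu_a + mu_s')) to mu_a (d kappa / d mu_a = -3 kappa^2),
# which a finite-difference oracle resolves at the 1e-4 relative level.

#' Discrete misfit functional
#'
#' `epsilon = 1/2 sum_i w_i (H_M - H_C)_i^2` with mass-lumped nodal areas
#' `w_i` (mm^2).
#'
#' @param H_M,H_C Measured and modeled absorbed-energy maps (matrices or
#'   `absorbed_energy_map` objects).
#' @param mesh The [build_mesh()] result providing the nodal areas.
#' @return The scalar misfit.
#' @export
error_functional <- function(H_M, H_C, mesh) {
  vm <- if (inherits(H_M, "absorbed_energy_map")) H_M$values else as.matrix(H_M)
  vc <- if (inherits(H_C, "absorbed_energy_map")) H_C$values else as.matrix(H_C)
  0.5 * sum(mesh$w * (as.vector(vm) - as.vector(vc))^2)
}

#' Solve the adjoint diffusion system
#'
#' Solves the same (self-adjoint) discrete diffusion operator as the forward
#' model with the nodal source `mu_a * w * (H_M - H_C)` -- the residual
#' weighted by absorption and nodal area. The sign convention is the one
#' under which [error_gradient()] reproduces the finite-difference gradient
#' of [error_functional()].
#'
#' @param mesh A [build_mesh()] result.
#' @param optics The [optical_map()] of the current absorption iterate.
#' @param residual `H_M - H_C` as a `ny` x `nx` matrix.
#' @param factor Optional Cholesky factor of the already-assembled operator
#'   (reused from the forward solve of the same iterate).
#' @return A `fluence_field` with `role = "adjoint"` (values may be signed).
#' @export
solve_adjoint <- function(mesh, optics, residual, factor = NULL) {
  rv <- as.vector(as.matrix(residual))
  mu <- as.vector(optics$mu_a)
  if (is.null(factor)) {
    op <- fem_operator(mesh, mu, as.vector(optics$mu_s_prime),
                       boundary_reflection_A(optics$n_in, optics$n_out))
    factor <- fem_factor(op$K)
  }
  rhs <- mu * mesh$w * rv
  phis <- as.numeric(Matrix::solve(factor, rhs, system = "A"))
  structure(list(values = matrix(phis, mesh$grid$ny, mesh$grid$nx),
                 role = "adjoint", grid = mesh$grid),
            class = "fluence_field")
}

#' Analytic gradient of the misfit with respect to the absorption map
#'
#' Per pixel `p`:
#' `g_p = -w_p (H_M - H_C)_p phi_p + phi* (dK/dmu_p) phi`, where the second
#' term expands over the two triangles of pixel `p`'s grid cell into a
#' consistent-mass contribution (`phi* M_e phi`, the `phi phi*` term of the
#' continuous gradient) minus the diffusion-sensitivity contribution
#' `3 kappa_e^2 phi* S_e phi`. At a data match (`H_M = H_C`) the gradient
#' vanishes identically.
#'
#' @param phi Forward fluence field (`fluence_field` or matrix).
#' @param phi_star Adjoint field from [solve_adjoint()].
#' @param H_M,H_C Measured and modeled absorbed-energy maps.
#' @param mesh A [build_mesh()] result.
#' @param kappa_e Per-element diffusion coefficients of the current iterate
#'   (returned by [assemble_system()]).
#' @return Gradient map as a `ny` x `nx` matrix.
#' @export
error_gradient <- function(phi, phi_star, H_M, H_C, mesh, kappa_e) {
  pv <- if (inherits(phi, "fluence_field")) phi$values else as.matrix(phi)
  sv <- if (inherits(phi_star, "fluence_field")) phi_star$values else as.matrix(phi_star)
  vm <- if (inherits(H_M, "absorbed_energy_map")) H_M$values else as.matrix(H_M)
  vc <- if (inherits(H_C, "absorbed_energy_map")) H_C$values else as.matrix(H_C)
  g <- gradient_from_fields(mesh, kappa_e, as.vector(pv), as.vector(sv),
                            as.vector(vm) - as.vector(vc))
  matrix(g, mesh$grid$ny, mesh$grid$nx)
}

# Core gradient assembly shared by error_gradient() and the inversion loop.
# phi, phis: nodal vectors; resid = H_M - H_C (nodal).
gradient_from_fields <- function(mesh, kappa_e, phi, phis, resid) {
  g <- -mesh$w * resid * phi
  P1 <- matrix(phi[mesh$elems], ncol = 3)
  P2 <- matrix(phis[mesh$elems], ncol = 3)
  # phi* M_e phi for the unit consistent mass (A/12) [2 1 1; 1 2 1; 1 1 2]
  m_e <- (mesh$area / 12) * (rowSums(P1) * rowSums(P2) + rowSums(P1 * P2))
  # phi* S_e phi for the unit stiffness; Sgeom holds the lower triangle
  Sg <- mesh$Sgeom
  s_e <- Sg[, 1] * P1[, 1] * P2[, 1] + Sg[, 3] * P1[, 2] * P2[, 2] +
    Sg[, 6] * P1[, 3] * P2[, 3] +
    Sg[, 2] * (P1[, 1] * P2[, 2] + P1[, 2] * P2[, 1]) +
    Sg[, 4] * (P1[, 1] * P2[, 3] + P1[, 3] * P2[, 1]) +
    Sg[, 5] * (P1[, 2] * P2[, 3] + P1[, 3] * P2[, 2])
  contrib <- m_e - 3 * kappa_e^2 * s_e
  acc <- rowsum(contrib, mesh$elem_pixel)
  px <- as.integer(rownames(acc))
  g[px] <- g[px] + acc[, 1]
  g
}

# Gradient at an evaluated iterate: one adjoint solve on the factorization
# cached by fwd_eval(), then the element-wise assembly above.
adjoint_gradient <- function(ctx, ev, mu) {
  rhs <- mu * ctx$w * ev$r
  phis <- as.numeric(Matrix::solve(ev$ch, rhs, system = "A"))
  gradient_from_fields(ctx$mesh, ev$op$kappa_e, ev$phi, phis, ev$r)
}
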