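# Absorption-recovery algorithms. All methods minimize (in their own sense)
# the mismatch between the measured absorbed energy H_M and the modeled
# H_C = mu_a * phi(mu_a), optionally anchored by a fluence-marker prior.

#' Inversion configuration
#'
#' Collects the tunable parameters of the iterative inversion schemes.
#'
#' @param method One of `"SIM"` (simple iterative method, fixed-point ratio
#'   update), `"GBM"` (adjoint-gradient quasi-Newton), `"GBM_CONSTRAINED"`
#'   (quasi-Newton with the marker imposed as an equality constraint),
#'   `"BL_DIRECT"` or `"EQUAL_FLUENCE"` (scalar direct inversions).
#' @param use_marker Whether the fluence-marker prior is applied.
#' @param max_iter Maximum outer iterations (default 700).
#' @param sigma SIM regularization added to the fluence in the ratio update,
#'   fluence units (default 0.002); stabilizes low-fluence regions.
#' @param init_mu_a Initial absorption guess, 1/mm (default 1e-10; any
#'   sufficiently small value behaves identically).
#' @param clamp_negative Clamp negative absorption updates to zero
#'   (default `TRUE`; noise can push the ratio update negative).
#' @param tol_error Optional stopping threshold on `||H_M - H_C||`.
#' @param tol_optimality Relative function-decrease tolerance for the
#'   quasi-Newton methods; 0 (default) runs to `max_iter` unless no decrease
#'   at all is possible.
#' @param lbfgs_memory Number of curvature pairs kept (default 10).
#' @param armijo_c1 Sufficient-decrease constant of the backtracking line
#'   search (default 1e-4).
#' @param max_backtracks Maximum step halvings per line search (default 25).
#' @param step0 Cap, in 1/mm, on the largest per-pixel change of the very
#'   first quasi-Newton step (default 0.01), before curvature information
#'   provides a natural step scale.
#' @param seed Optional integer echoed into results for bookkeeping.
#' @return An object of class `inversion_config`.
#' @export
inversion_config <- function(method = c("SIM", "GBM", "GBM_CONSTRAINED",
                                        "BL_DIRECT", "EQUAL_FLUENCE"),
                             use_marker = TRUE, max_iter = 700, sigma = 0.002,
                             init_mu_a = 1e-10, clamp_negative = TRUE,
                             tol_error = NULL, tol_optimality = 0,
                             lbfgs_memory = 10, armijo_c1 = 1e-4,
                             max_backtracks = 25, step0 = 0.01, seed = NULL) {
  method <- match.arg(method)
  max_iter <- as.integer(max_iter)
  if (is.na(max_iter) || max_iter < 1L)
    stop("inversion_config: max_iter must be >= 1", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0)
    stop("inversion_config: sigma must be > 0", call. = FALSE)
  if (!is.finite(init_mu_a) || init_mu_a < 0)
    stop("inversion_config: init_mu_a must be >= 0", call. = FALSE)
  structure(list(method = method, use_marker = isTRUE(use_marker),
                 max_iter = max_iter, sigma = sigma, init_mu_a = init_mu_a,
                 clamp_negative = isTRUE(clamp_negative),
                 tol_error = tol_error, tol_optimality = tol_optimality,
                 lbfgs_memory = as.integer(lbfgs_memory),
                 armijo_c1 = armijo_c1,
                 max_backtracks = as.integer(max_backtracks),
                 step0 = step0, seed = seed),
            class = "inversion_config")
}

#' Equal-fluence baseline inversion
#'
#' Assumes the fluence at the unknown chromophore equals the fluence at the
#' marker, giving `mu_a_unknown = (H_unknown / H_marker) * mu_a_marker`.
#' Systematically biased whenever the two fluences differ, e.g. when the
#' regions sit at different depths.
#'
#' @param H_unknown Absorbed energy at the unknown chromophore.
#' @param H_marker Absorbed energy at the marker; must be positive.
#' @param mu_a_marker Known marker absorption, 1/mm, positive.
#' @return Estimated absorption of the unknown chromophore, 1/mm.
#' @export
invert_equal_fluence <- function(H_unknown, H_marker, mu_a_marker) {
  if (any(!is.finite(H_marker)) || any(H_marker <= 0))
    stop("invert_equal_fluence: H_marker must be > 0", call. = FALSE)
  if (any(!is.finite(mu_a_marker)) || any(mu_a_marker <= 0))
    stop("invert_equal_fluence: mu_a_marker must be > 0", call. = FALSE)
  (H_unknown / H_marker) * mu_a_marker
}

#' Direct Beer-Lambert marker inversion
#'
#' For a homogeneous unknown layer of thickness `r` between the surface
#' reading and the marker, the Beer-Lambert model gives the relation
#' `x * exp(x * r) = (H_unknown / H_marker) * mu_a_marker` for the unknown
#' absorption `x`. The unique positive root is found by safeguarded Newton
#' iteration started from `init_guess`; at `r = 0` the relation reduces
#' exactly to [invert_equal_fluence()].
#'
#' @inheritParams invert_equal_fluence
#' @param r Depth distance from the unknown-region reading to the marker, mm,
#'   non-negative. Vectorized together with the energies.
#' @param init_guess Starting point of the Newton iteration (default 1e-5).
#' @return Estimated absorption, 1/mm (vectorized).
#' @export
invert_beer_lambert_marker <- function(H_unknown, H_marker, mu_a_marker, r,
                                       init_guess = 1e-5) {
  if (any(r < 0)) stop("invert_beer_lambert_marker: r must be >= 0", call. = FALSE)
  rhs <- invert_equal_fluence(H_unknown, H_marker, mu_a_marker)
  if (any(!is.finite(rhs)))
    stop("invert_beer_lambert_marker: non-finite right-hand side", call. = FALSE)
  n <- max(length(rhs), length(r))
  rhs <- rep_len(rhs, n); r <- rep_len(r, n)
  out <- numeric(n)
  for (k in seq_len(n)) {
    if (r[k] == 0 || rhs[k] == 0) { out[k] <- rhs[k]; next }
    # Newton on the log form log(x) + x r - log(rhs) = 0: monotone, concave,
    # and free of exponential overflow for large mu * r
    x <- init_guess
    converged <- FALSE
    for (it in 1:200) {
      gx <- log(x) + x * r[k] - log(rhs[k])
      x_new <- x - gx / (1 / x + r[k])
      if (!is.finite(x_new) || x_new <= 0) x_new <- x / 2  # root is positive
      if (abs(x_new - x) <= 1e-15 * max(1, abs(x_new))) {
        x <- x_new; converged <- TRUE; break
      }
      x <- x_new
    }
    if (!converged)
      stop(structure(class = c("qpa_numerical_error", "error", "condition"),
                     list(message = "invert_beer_lambert_marker: Newton iteration did not converge",
                          call = NULL)))
    out[k] <- x
  }
  out
}

#' Overwrite marker pixels with the known marker absorption
#'
#' @param mu_a Absorption map (`ny` x `nx` matrix), 1/mm.
#' @param marker A [marker_prior()].
#' @param wavelength_index Which entry of the marker's per-wavelength
#'   absorption to use (default 1).
#' @return The map with marker pixels set to the prior value; all other
#'   pixels unchanged. Idempotent.
#' @export
apply_marker <- function(mu_a, marker, wavelength_index = 1) {
  stopifnot(inherits(marker, "marker_prior"))
  val <- marker_value(marker, wavelength_index)
  mu_a[marker$pixels] <- val
  mu_a
}

marker_value <- function(marker, wavelength_index = 1) {
  v <- marker$mu_a_marker
  v[min(length(v), as.integer(wavelength_index))]
}

#' Simple iterative method (SIM)
#'
#' Fixed-point recovery of the absorption map: each iteration solves the
#' forward model for the fluence of the current estimate and updates
#' `mu_a <- H_M / (phi + sigma)` element-wise, where `sigma` regularizes
#' low-fluence regions. With a marker prior, marker pixels are reset to the
#' known value before every forward solve and once more on return.
#'
#' @param H_M Measured absorbed-energy map ([absorbed_energy_map()] or
#'   `ny` x `nx` matrix).
#' @param optics An [optical_map()] providing the known scattering map, grid
#'   and refractive indices. Its `mu_a` entry is ignored (it is the unknown).
#' @param config An [inversion_config()].
#' @param marker Optional [marker_prior()].
#' @param sources Source set; defaults to ten boundary sources.
#' @param labels Optional [region_label_map()]; when given, per-region mean
#'   absorption is traced over iterations.
#' @param wavelength_index Marker wavelength entry (default 1).
#' @return An `inversion_result`: recovered map `mu_a_hat`, per-iteration
#'   `error_trace` (`log ||H_M - H_C||^2`), optional `region_traces`,
#'   `iterations_used`, `converged` flag and `reason`.
#' @export
run_sim <- function(H_M, optics, config = inversion_config("SIM"),
                    marker = NULL, sources = default_sources(optics$grid),
                    labels = NULL, wavelength_index = 1) {
  ctx <- inv_context(H_M, optics, sources)
  nn <- ctx$nn
  mu <- rep(config$init_mu_a, nn)
  mk_idx <- NULL; mk_val <- NULL
  if (!is.null(marker)) {
    mk_idx <- marker_lin_idx(marker, ctx$grid)
    mk_val <- marker_value(marker, wavelength_index)
  }
  trace <- numeric(config$max_iter)
  rtr <- region_trace_init(labels, config$max_iter)
  ch <- NULL
  converged <- FALSE; reason <- "max_iter"
  k_used <- 0L
  for (k in seq_len(config$max_iter)) {
    if (!is.null(mk_idx)) mu[mk_idx] <- mk_val
    op <- fem_operator(ctx$mesh, mu, ctx$mu_s_vec, ctx$A_refl)
    ch <- fem_factor(op$K, ch)
    phi <- as.numeric(Matrix::solve(ch, ctx$qt, system = "A"))
    H_C <- mu * phi
    dH <- ctx$H_M_vec - H_C
    k_used <- k
    trace[k] <- log(sum(dH^2))
    rtr <- region_trace_record(rtr, labels, mu, k)
    if (!is.null(config$tol_error) && sqrt(sum(dH^2)) < config$tol_error) {
      converged <- TRUE; reason <- "tol_error"; break
    }
    mu_new <- ctx$H_M_vec / (phi + config$sigma)
    if (config$clamp_negative) mu_new[mu_new < 0] <- 0
    if (max(abs(mu_new - mu)) < 1e-14) {
      mu <- mu_new; converged <- TRUE; reason <- "stagnation"; break
    }
    mu <- mu_new
  }
  if (!is.null(mk_idx)) mu[mk_idx] <- mk_val
  inversion_result(mu, ctx, trace, rtr, k_used, converged, reason,
                   "SIM", config, labels)
}

#' Adjoint-gradient quasi-Newton method (GBM)
#'
#' Minimizes the absorbed-energy misfit
#' `epsilon = 1/2 sum_i w_i (H_M - H_C)_i^2` (nodal-area weights `w`) over
#' the full absorption map with a limited-memory BFGS iteration driven by
#' the analytic adjoint gradient ([error_gradient()]). Negative values are
#' clamped after every accepted step; with a marker prior, marker pixels are
#' additionally reset to the known value after every outer iteration.
#'
#' @inheritParams run_sim
#' @return An `inversion_result`; see [run_sim()].
#' @export
run_gbm <- function(H_M, optics, config = inversion_config("GBM"),
                    marker = NULL, sources = default_sources(optics$grid),
                    labels = NULL, wavelength_index = 1) {
  run_gbm_engine(H_M, optics, config, marker, sources, labels,
                 wavelength_index, constrained = FALSE)
}

#' Equality-constrained quasi-Newton method
#'
#' Minimizes the same misfit as [run_gbm()] subject to
#' `mu_a(marker pixels) = mu_a_marker`, implemented as reduced-space
#' optimization over the non-marker pixels (mathematically equivalent to the
#' linear equality constraint `Aeq X = Beq` with one row per marker pixel).
#' Marker pixels never move, so no post-iteration reset is needed.
#'
#' @inheritParams run_sim
#' @param marker A [marker_prior()]; required.
#' @return An `inversion_result`; see [run_sim()].
#' @export
run_gbm_constrained <- function(H_M, optics,
                                config = inversion_config("GBM_CONSTRAINED"),
                                marker, sources = default_sources(optics$grid),
                                labels = NULL, wavelength_index = 1) {
  if (missing(marker) || is.null(marker))
    stop("run_gbm_constrained: a marker prior is required", call. = FALSE)
  run_gbm_engine(H_M, optics, config, marker, sources, labels,
                 wavelength_index, constrained = TRUE)
}

# ---- shared internals -----------------------------------------------------

inv_context <- function(H_M, optics, sources) {
  stopifnot(inherits(optics, "optical_map"))
  v <- if (inherits(H_M, "absorbed_energy_map")) H_M$values else as.matrix(H_M)
  grid <- optics$grid
  if (!all(dim(v) == c(grid$ny, grid$nx)))
    stop("inversion: H_M shape does not match the optics grid", call. = FALSE)
  mesh <- build_mesh(grid)
  q <- source_loads(mesh, sources)
  list(grid = grid, mesh = mesh, nn = mesh$n_nodes,
       mu_s_vec = as.vector(optics$mu_s_prime),
       A_refl = boundary_reflection_A(optics$n_in, optics$n_out),
       qt = rowSums(q), w = mesh$w, H_M_vec = as.vector(v))
}

marker_lin_idx <- function(marker, grid) {
  (marker$pixels[, 2] - 1L) * grid$ny + marker$pixels[, 1]
}

region_trace_init <- function(labels, max_iter) {
  if (is.null(labels)) return(NULL)
  stopifnot(inherits(labels, "region_label_map"))
  lv <- labels$legend$label
  m <- matrix(NA_real_, max_iter, length(lv))
  colnames(m) <- labels$legend$name
  attr(m, "label_values") <- lv
  m
}

region_trace_record <- function(rtr, labels, mu_vec, k) {
  if (is.null(rtr)) return(NULL)
  lv <- attr(rtr, "label_values")
  lab <- as.vector(labels$labels)
  for (j in seq_along(lv)) {
    sel <- lab == lv[j]
    rtr[k, j] <- if (any(sel)) mean(mu_vec[sel]) else NA_real_
  }
  rtr
}

inversion_result <- function(mu_vec, ctx, trace, rtr, k_used, converged,
                             reason, method, config, labels) {
  res <- structure(list(
    mu_a_hat = matrix(mu_vec, ctx$grid$ny, ctx$grid$nx),
    error_trace = trace[seq_len(k_used)],
    region_traces = if (is.null(rtr)) NULL else rtr[seq_len(k_used), , drop = FALSE],
    iterations_used = k_used, converged = converged, reason = reason,
    method = method, config = config, grid = ctx$grid),
    class = "inversion_result")
  res
}

#' @export
print.inversion_result <- function(x, ...) {
  cat(sprintf("<inversion_result> %s: %d iterations (%s), final log||dH||^2 = %.3f\n",
              x$method, x$iterations_used,
              if (x$converged) paste0("converged: ", x$reason) else x$reason,
              if (x$iterations_used > 0) x$error_trace[x$iterations_used] else NA))
  invisible(x)
}

# Forward evaluation of the misfit at mu (vector over pixels): assembles the
# operator, factorizes (reusing the symbolic analysis), solves for the total
# fluence and returns everything the gradient needs.
fwd_eval <- function(ctx, mu, factor = NULL) {
  op <- fem_operator(ctx$mesh, mu, ctx$mu_s_vec, ctx$A_refl)
  ch <- fem_factor(op$K, factor)
  phi <- as.numeric(Matrix::solve(ch, ctx$qt, system = "A"))
  H_C <- mu * phi
  r <- ctx$H_M_vec - H_C
  list(op = op, ch = ch, phi = phi, H_C = H_C, r = r,
       f = 0.5 * sum(ctx$w * r^2))
}

run_gbm_engine <- function(H_M, optics, config, marker, sources, labels,
                           wavelength_index, constrained) {
  ctx <- inv_context(H_M, optics, sources)
  nn <- ctx$nn
  mk_idx <- NULL; mk_val <- NULL
  if (!is.null(marker)) {
    mk_idx <- marker_lin_idx(marker, ctx$grid)
    mk_val <- marker_value(marker, wavelength_index)
  }
  # Trial-point projection. In the constrained variant the marker pixels are
  # part of the feasible set (they never move); in the reset variant they are
  # free during the line search and reset only after the iteration, matching
  # the "marker elements reset before the next iteration" scheme -- which is
  # why that variant's error trace can oscillate transiently.
  project <- function(mu) {
    if (config$clamp_negative) mu[mu < 0] <- 0
    if (constrained && !is.null(mk_idx)) mu[mk_idx] <- mk_val
    mu
  }
  reset_marker <- function(mu) {
    if (!is.null(mk_idx)) mu[mk_idx] <- mk_val
    mu
  }
  restrict <- function(g) {            # reduced-space gradient
    if (constrained) g[mk_idx] <- 0
    g
  }
  x <- reset_marker(project(rep(config$init_mu_a, nn)))
  ev <- fwd_eval(ctx, x)
  g <- restrict(adjoint_gradient(ctx, ev, x))

  S <- list(); Y <- list(); rho <- numeric(0)
  trace <- numeric(config$max_iter)
  rtr <- region_trace_init(labels, config$max_iter)
  converged <- FALSE; reason <- "max_iter"
  k_used <- 0L
  for (k in seq_len(config$max_iter)) {
    d <- lbfgs_direction(g, S, Y, rho)
    if (sum(d * g) >= 0) d <- -g
    alpha <- if (length(S) == 0) {
      dmax <- max(abs(d))
      if (dmax > 0) min(1, config$step0 / dmax) else 1
    } else 1
    accepted <- FALSE
    evt <- NULL; xt <- NULL; st <- NULL
    for (t in seq_len(config$max_backtracks)) {
      xt <- project(x + alpha * d)
      st <- xt - x
      if (max(abs(st)) == 0) break
      evt <- fwd_eval(ctx, xt, factor = ev$ch)
      dec <- sum(g * st)
      if (evt$f <= ev$f + config$armijo_c1 * min(dec, 0)) {
        accepted <- TRUE; break
      }
      alpha <- alpha / 2
    }
    if (!accepted) { converged <- TRUE; reason <- "no_decrease"; break }
    if (!constrained && !is.null(mk_idx)) {
      xr <- reset_marker(xt)
      if (max(abs(xr - xt)) > 0) {      # re-evaluate at the reset point
        xt <- xr
        evt <- fwd_eval(ctx, xt, factor = ev$ch)
      }
      st <- xt - x
    }
    gt <- restrict(adjoint_gradient(ctx, evt, xt))
    yv <- gt - g
    sy <- sum(st * yv)
    if (sy > 1e-12 * sqrt(sum(st^2) * sum(yv^2))) {
      S <- c(S, list(st)); Y <- c(Y, list(yv)); rho <- c(rho, 1 / sy)
      if (length(S) > config$lbfgs_memory) {
        S <- S[-1]; Y <- Y[-1]; rho <- rho[-1]
      }
    }
    f_prev <- ev$f
    x <- xt; ev <- evt; g <- gt
    k_used <- k
    trace[k] <- log(sum(ev$r^2))
    rtr <- region_trace_record(rtr, labels, x, k)
    if (!is.null(config$tol_error) && sqrt(sum(ev$r^2)) < config$tol_error) {
      converged <- TRUE; reason <- "tol_error"; break
    }
    if (config$tol_optimality > 0 &&
        (f_prev - ev$f) <= config$tol_optimality * max(f_prev, .Machine$double.xmin)) {
      converged <- TRUE; reason <- "tol_optimality"; break
    }
  }
  method <- if (constrained) "GBM_CONSTRAINED"
            else if (!is.null(marker)) "GBM+marker" else "GBM"
  inversion_result(x, ctx, trace, rtr, k_used, converged, reason,
                   method, config, labels)
}

# Two-loop L-BFGS recursion; returns the descent direction -H * g.
lbfgs_direction <- function(g, S, Y, rho) {
  m <- length(S)
  if (m == 0) return(-g)
  q <- g
  al <- numeric(m)
  for (i in m:1) {
    al[i] <- rho[i] * sum(S[[i]] * q)
    q <- q - al[i] * Y[[i]]
  }
  gamma <- sum(S[[m]] * Y[[m]]) / sum(Y[[m]] * Y[[m]])
  r <- gamma * q
  for (i in 1:m) {
    be <- rho[i] * sum(Y[[i]] * r)
    r <- r + S[[i]] * (al[i] - be)
  }
  -r
}
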