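# Shared small fixtures, built in code and memoized for the test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, .fixture_env, inherits = FALSE))
    assign(key, force(expr), .fixture_env)
  get(key, .fixture_env, inherits = FALSE)
}

# Homogeneous small phantom plus its noise-free forward data.
homog_forward <- function(n = 30, h = 0.2, mu_a = 0.01, n_sources = 10) {
  memo(sprintf("homog_%d_%g_%g_%d", n, h, mu_a, n_sources), {
    g <- grid_spec(n, n, h)
    optics <- optical_map(matrix(mu_a, n, n), 2, g)
    mesh <- build_mesh(g)
    sources <- default_sources(g, n_sources)
    phi <- solve_fluence(mesh, optics, sources)
    H <- absorbed_energy(optics, phi)
    list(grid = g, optics = optics, mesh = mesh, sources = sources,
         phi = phi, H = H,
         optics_unknown = optical_map(matrix(0, n, n), 2, g))
  })
}

disc_px <- function(grid, cx, cy, r) qpamarker:::disc_mask(grid, cx, cy, r)

# Finite-difference gradient of the discrete misfit at selected pixels,
# computed purely through the public forward-model API (independent of the
# adjoint machinery it checks).
fd_gradient <- function(mesh, mu_a, mu_s, grid, sources, H_M, pixels,
                        eps = 1e-6) {
  vapply(pixels, function(p) {
    fp <- vapply(c(1, -1), function(sgn) {
      mu2 <- mu_a
      mu2[p] <- mu2[p] + sgn * eps
      o2 <- optical_map(mu2, mu_s, grid)
      phi2 <- solve_fluence(mesh, o2, sources)
      error_functional(H_M, absorbed_energy(o2, phi2), mesh)
    }, numeric(1))
    (fp[1] - fp[2]) / (2 * eps)
  }, numeric(1))
}
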