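test_that("mesh construction tessellates the grid exactly", {
  m <- build_mesh(grid_spec(3, 3, 0.2))
  expect_equal(m$n_nodes, 9L)
  expect_equal(nrow(m$elems), 8L)
  expect_equal(length(m$boundary_nodes), 8L)
  g <- grid_spec(100, 100, 0.2)
  m2 <- build_mesh(g)
  expect_equal(m2$n_nodes, 10000L)
  expect_equal(nrow(m2$elems), 2L * 99L * 99L)
  # tessellation identity: triangle areas sum to the node bounding box
  expect_equal(sum(m2$area), 99 * 99 * 0.2^2)
  expect_equal(sum(m2$w), 99 * 99 * 0.2^2)
  # boundary edges form a single closed loop
  expect_equal(nrow(m2$boundary_edges), length(m2$boundary_nodes))
  expect_setequal(m2$boundary_edges[, 1], m2$boundary_edges[, 2])
})

test_that("assembled operator is symmetric positive definite", {
  g <- grid_spec(4, 4, 0.5)
  set.seed(11)
  optics <- optical_map(matrix(runif(16, 0.01, 0.1), 4, 4),
                        matrix(runif(16, 1, 3), 4, 4), g)
  sys <- assemble_system(build_mesh(g), optics)
  K <- as.matrix(sys$K)
  expect_true(isSymmetric(K))
  expect_gt(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("boundary reflection coefficient reproduces the index mismatch", {
  a_matched <- boundary_reflection_A(1, 1)
  a_tissue <- boundary_reflection_A(1.33, 1)
  expect_equal(a_matched, 1, tolerance = 0.005)
  expect_gt(a_tissue, a_matched)  # stronger internal reflection
  # mismatch weakens the boundary sink: higher boundary fluence
  g <- grid_spec(20, 20, 0.2)
  mesh <- build_mesh(g)
  src <- default_sources(g)
  phi_m <- solve_fluence(mesh, optical_map(matrix(0.01, 20, 20), 2, g,
                                           n_in = 1, n_out = 1), src)
  phi_t <- solve_fluence(mesh, optical_map(matrix(0.01, 20, 20), 2, g), src)
  expect_gt(mean(phi_t$values), mean(phi_m$values))
})

test_that("default sources sit one grid spacing inside the boundary", {
  g <- grid_spec(100, 100, 0.2)
  src <- default_sources(g, 10)
  expect_equal(nrow(src$positions), 10L)
  expect_equal(nrow(unique(src$positions)), 10L)
  # distance from the mesh boundary (node bounding box) equals h
  d <- pmin(pmin(src$positions[, 1] - 0.1, 19.9 - src$positions[, 1]),
            pmin(src$positions[, 2] - 0.1, 19.9 - src$positions[, 2]))
  expect_equal(d, rep(g$h, 10))
  # perimeter equipartition gives 4-fold symmetry for n = 4
  s4 <- default_sources(g, 4)$positions
  ctr <- c(10, 10)
  rot90 <- cbind(ctr[1] - (s4[, 2] - ctr[2]), ctr[2] + (s4[, 1] - ctr[1]))
  expect_equal(sort(round(rot90[, 1], 9) * 1e6 + round(rot90[, 2], 9)),
               sort(round(s4[, 1], 9) * 1e6 + round(s4[, 2], 9)))
  # unit power normalization of the nodal load
  mesh <- build_mesh(g)
  q <- qpamarker:::source_loads(mesh, default_sources(g, 1))
  expect_equal(sum(q), 1)
})

test_that("fluence solves are linear, superposable and positive", {
  fx <- homog_forward(30, 0.2)
  phi <- solve_fluence(fx$mesh, fx$optics, fx$sources, by_source = TRUE)
  expect_true(all(phi$values > -1e-12 * max(phi$values)))
  # superposition over sources
  tot <- Reduce(`+`, phi$per_source)
  expect_equal(tot, phi$values, tolerance = 1e-10)
  # linearity in source power
  src2 <- fx$sources
  src2$power <- 2
  phi2 <- solve_fluence(fx$mesh, fx$optics, src2)
  expect_equal(phi2$values, 2 * phi$values, tolerance = 1e-10)
  # monotone decay away from a single central source in homogeneous medium
  g <- grid_spec(51, 51, 0.2)
  opt <- optical_map(matrix(0.01, 51, 51), 2, g)
  src1 <- default_sources(g, 1)
  src1$positions <- matrix(c(5.1, 5.1), 1)  # grid center
  p1 <- solve_fluence(build_mesh(g), opt, src1)$values
  along <- p1[26, 26:49]  # axis from the source toward the boundary
  expect_true(all(diff(along) < 0))
})

test_that("absorbed energy is the exact pointwise product", {
  fx <- homog_forward(30, 0.2)
  expect_equal(fx$H$values, fx$optics$mu_a * fx$phi$values)
  o0 <- fx$optics
  o0$mu_a[5, 5] <- 0
  H0 <- absorbed_energy(o0, fx$phi)
  expect_identical(H0$values[5, 5], 0)
  expect_equal(absorbed_energy(optical_map(matrix(0.2, 3, 3), 2, grid_spec(3, 3, 1)),
                               matrix(3.5, 3, 3))$values,
               matrix(0.7, 3, 3))
  # H / phi returns mu_a wherever phi > 0
  expect_equal(fx$H$values / fx$phi$values, fx$optics$mu_a, tolerance = 1e-12)
})

test_that("measurement noise hits the stated SNR and is reproducible", {
  set.seed(99)
  H <- matrix(runif(10000, 0, 1), 100, 100)
  hm <- add_noise(H, 30, seed = 7)
  emp_snr <- 10 * log10(mean(H^2) / mean((hm$values - H)^2))
  expect_equal(emp_snr, 30, tolerance = 0.5)
  expect_identical(hm$values, add_noise(H, 30, seed = 7)$values)
  expect_false(identical(hm$values, add_noise(H, 30, seed = 8)$values))
  expect_identical(add_noise(H, Inf)$values, H)
  expect_equal(add_noise(H, 30, seed = 1)$role, "measured")
})

test_that("energy is conserved and the discrete operator is self-adjoint", {
  g <- grid_spec(50, 50, 0.4)
  optics <- optical_map(matrix(0.01, 50, 50), 2, g)
  mesh <- build_mesh(g)
  pb <- power_balance(mesh, optics, default_sources(g, 10))
  expect_lt(pb$rel_error, 0.02)
  # reciprocity: <g, K^-1 f> == <f, K^-1 g>
  sys <- assemble_system(mesh, optics)
  ch <- qpamarker:::fem_factor(sys$K)
  set.seed(3)
  f <- runif(mesh$n_nodes); gvec <- runif(mesh$n_nodes)
  lhs <- sum(gvec * as.numeric(Matrix::solve(ch, f, system = "A")))
  rhs <- sum(f * as.numeric(Matrix::solve(ch, gvec, system = "A")))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("region-mean fluence converges under grid refinement", {
  mean_central <- function(n, h, src) {
    g <- grid_spec(n, n, h)
    optics <- optical_map(matrix(0.01, n, n), 2, g)
    mesh <- build_mesh(g)
    phi <- solve_fluence(mesh, optics, src)
    xy <- qpamarker:::grid_coords(g)
    sel <- (xy[, 1] - n * h / 2)^2 + (xy[, 2] - n * h / 2)^2 <= 4
    sum(mesh$w[sel] * as.vector(phi$values)[sel]) / sum(mesh$w[sel])
  }
  src <- default_sources(grid_spec(60, 60, 0.2), 10)  # fixed physical sources
  coarse <- mean_central(60, 0.2, src)
  fine <- mean_central(120, 0.1, src)
  expect_lt(abs(fine - coarse) / coarse, 0.05)
})

test_that("Beer-Lambert fluence decay matches the closed form", {
  expect_equal(beer_lambert_fluence(1, 0.3, 0), 1)
  expect_equal(beer_lambert_fluence(1, 0.5, 2), exp(-1))
  expect_equal(beer_lambert_fluence(2, 0.5, 2), 2 * beer_lambert_fluence(1, 0.5, 2))
  expect_error(beer_lambert_fluence(1, 0.5, -1), "r must be")
})
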