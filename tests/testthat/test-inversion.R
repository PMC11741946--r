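test_that("equal-fluence inversion is exact algebra and guards its domain", {
  expect_equal(invert_equal_fluence(0.44, 0.44, 0.2), 0.2)
  expect_equal(invert_equal_fluence(0.255, 0.44, 0.44), 0.255)
  expect_error(invert_equal_fluence(1, 0, 0.2), "H_marker")
  expect_error(invert_equal_fluence(1, 1, -0.1), "mu_a_marker")
  # on the two-layer fixture with r > 0 the equal-fluence assumption
  # overestimates the true absorption (it ignores the attenuation to the
  # marker), and the marker method beats it at every r
  for (r in c(0.5, 1, 2, 5)) {
    tl <- make_two_layer_phantom(0.51, 0.44, r)
    ef <- invert_equal_fluence(tl$H_unknown, tl$H_marker, 0.44)
    bl <- invert_beer_lambert_marker(tl$H_unknown, tl$H_marker, 0.44, r)
    expect_gt(ef, 0.51)
    expect_gte(abs(ef - 0.51), abs(bl - 0.51))
  }
})

test_that("Beer-Lambert marker inversion round-trips the two-layer model", {
  tl <- make_two_layer_phantom(0.51, 0.44, 1.0)
  expect_equal(invert_beer_lambert_marker(tl$H_unknown, tl$H_marker, 0.44, 1.0),
               0.51, tolerance = 1e-8)
  # r = 0 reduces exactly to the equal-fluence formula
  expect_identical(invert_beer_lambert_marker(0.3, 0.5, 0.44, 0),
                   invert_equal_fluence(0.3, 0.5, 0.44))
  # sweep: forward-then-invert identity over the stated grid
  mu_true <- c(0.01, 0.05, 0.1, 0.25, 0.5, 0.75, 1.0)
  rs <- c(0, 0.5, 1, 2, 3.5, 5)
  for (mu in mu_true) for (r in rs) {
    tl <- make_two_layer_phantom(mu, 0.44, r)
    rec <- invert_beer_lambert_marker(tl$H_unknown, tl$H_marker, 0.44, r)
    expect_equal(rec, mu, tolerance = 1e-8)
  }
  expect_error(invert_beer_lambert_marker(0.3, 0.5, 0.44, -1), "r must be")
})

test_that("Beer-Lambert root agrees with the Lambert-W closed form", {
  skip_if_not_installed("pracma")
  set.seed(21)
  for (k in 1:25) {
    mu <- runif(1, 0.01, 1)
    r <- runif(1, 0.01, 5)
    tl <- make_two_layer_phantom(mu, 0.44, r)
    rhs <- tl$H_unknown / tl$H_marker * 0.44
    w_root <- pracma::lambertWp(r * rhs) / r
    expect_equal(invert_beer_lambert_marker(tl$H_unknown, tl$H_marker, 0.44, r),
                 w_root, tolerance = 1e-9)
  }
})

test_that("apply_marker overwrites exactly the marker pixels, idempotently", {
  g <- grid_spec(10, 10, 0.2)
  mk <- marker_prior(cbind(c(4, 5), c(4, 4)), 0.2, g)
  z <- matrix(0, 10, 10)
  a <- apply_marker(z, mk)
  expect_equal(sum(a != 0), 2L)
  expect_true(all(a[mk$pixels] == 0.2))
  expect_identical(apply_marker(a, mk), a)
  already <- z; already[mk$pixels] <- 0.2
  expect_identical(apply_marker(already, mk), already)
})

test_that("SIM recovers a homogeneous phantom and fixes trivial cases", {
  fx <- homog_forward(30, 0.2)
  res <- run_sim(fx$H$values, fx$optics_unknown,
                 inversion_config("SIM", max_iter = 50))
  ctr <- 8:23
  expect_lt(max(abs(res$mu_a_hat[ctr, ctr] - 0.01) / 0.01), 0.02)
  expect_equal(length(res$error_trace), res$iterations_used)
  # zero data is a fixed point after one update
  res0 <- run_sim(matrix(0, 30, 30), fx$optics_unknown,
                  inversion_config("SIM", max_iter = 3))
  expect_true(all(res0$mu_a_hat == 0))
})

test_that("quasi-Newton inversion reaches machine-accurate recovery noise-free", {
  fx <- homog_forward(30, 0.2)
  res <- run_gbm(fx$H$values, fx$optics_unknown,
                 inversion_config("GBM", max_iter = 200))
  ctr <- 8:23
  expect_lt(max(abs(res$mu_a_hat[ctr, ctr] - 0.01) / 0.01), 0.01)
  # misfit drops by many orders from the near-zero initial guess
  drop_orders <- (res$error_trace[1] -
                    res$error_trace[res$iterations_used]) / (2 * log(10))
  expect_gt(drop_orders, 3)
})

test_that("marker fidelity and non-negativity hold for every method", {
  fx <- homog_forward(30, 0.2)
  g <- fx$grid
  mk <- marker_prior(which(disc_px(g, 3, 3, 0.8), arr.ind = TRUE), 0.05, g)
  H_M <- add_noise(fx$H, 25, seed = 4)  # strong noise provokes clamping
  cfg <- function(m) inversion_config(m, max_iter = 40)
  runs <- list(
    run_sim(H_M, fx$optics_unknown, cfg("SIM"), marker = mk),
    run_gbm(H_M, fx$optics_unknown, cfg("GBM"), marker = mk),
    run_gbm_constrained(H_M, fx$optics_unknown, cfg("GBM_CONSTRAINED"),
                        marker = mk))
  for (r in runs) {
    expect_true(all(r$mu_a_hat[mk$pixels] == 0.05))
    expect_true(all(r$mu_a_hat >= 0))
  }
  expect_error(run_gbm_constrained(H_M, fx$optics_unknown,
                                   inversion_config("GBM_CONSTRAINED"),
                                   marker = NULL),
               "marker prior is required")
})

test_that("constrained optimization reduces to the masked free-pixel gradient", {
  # the reduced-space gradient equals the full gradient with marker pixels
  # zeroed; verified through one engine iteration's bookkeeping
  fx <- homog_forward(20, 0.2)
  g <- fx$grid
  mk <- marker_prior(cbind(10, 10), 0.05, g)
  sys <- assemble_system(fx$mesh, fx$optics)
  phi <- solve_fluence(fx$mesh, fx$optics, fx$sources, system = sys)
  H_C <- absorbed_energy(fx$optics, phi)
  H_M <- fx$H$values * 1.05
  phi_star <- solve_adjoint(fx$mesh, fx$optics, H_M - H_C$values)
  g_full <- error_gradient(phi, phi_star, H_M, H_C, fx$mesh, sys$kappa_e)
  g_red <- g_full
  g_red[mk$pixels] <- 0
  expect_equal(sum(g_red != 0), sum(g_full != 0) - 1L)
  expect_equal(g_red[-((10 - 1) * 20 + 10)], g_full[-((10 - 1) * 20 + 10)])
})

test_that("inversion configuration validates its parameters", {
  expect_error(inversion_config("SIM", sigma = 0), "sigma")
  expect_error(inversion_config("SIM", max_iter = 0), "max_iter")
  expect_error(inversion_config("SIM", init_mu_a = -1), "init_mu_a")
  expect_error(inversion_config("NOPE"), "arg")
})

test_that("error traces and region traces are recorded per iteration", {
  fx <- homog_forward(30, 0.2)
  g <- fx$grid
  labs <- region_label_map(matrix(c(rep(1L, 450), rep(2L, 450)), 30, 30),
                           data.frame(label = 1:2, name = c("left", "right"),
                                      mu_a = c(0.01, 0.01)))
  res <- run_sim(fx$H$values, fx$optics_unknown,
                 inversion_config("SIM", max_iter = 10), labels = labs)
  expect_equal(nrow(res$region_traces), res$iterations_used)
  expect_equal(colnames(res$region_traces), c("left", "right"))
  # traces move toward the truth
  expect_lt(abs(res$region_traces[res$iterations_used, 1] - 0.01),
            abs(res$region_traces[1, 1] - 0.01))
})
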