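test_that("grid and optical map constructors validate their invariants", {
  g <- grid_spec(100, 100, 0.2)
  expect_equal(g$extent, c(20, 20))
  expect_error(grid_spec(2, 10, 0.2), "nx and ny")
  expect_error(grid_spec(10, 10, 0), "h must be")
  expect_error(optical_map(matrix(-0.1, 3, 3), 2, grid_spec(3, 3, 1)), "mu_a")
  expect_error(optical_map(matrix(0.1, 3, 3), 0, grid_spec(3, 3, 1)), "mu_s_prime")
  expect_warning(optical_map(matrix(2.5, 3, 3), 2, grid_spec(3, 3, 1)),
                 "diffusion approximation")
})

test_that("nine-region phantom carries the documented levels and marker", {
  ph <- make_nine_region_phantom()
  lg <- ph$labels$legend
  # marker pixels all at 0.2 1/mm and legend spans [0.001, 0.2]
  expect_true(all(ph$optics$mu_a[marker_mask(ph$marker)] == 0.2))
  expect_equal(range(c(lg$mu_a, 0.001)), c(0.001, 0.2))
  expect_equal(sort(unique(c(lg$mu_a, 0.001))),
               c(0.001, 0.005, 0.010, 0.020, 0.040, 0.075, 0.100, 0.150, 0.200))
  # scored region ground truths
  expect_equal(lg$mu_a[match(paste0("region", 1:5), lg$name)],
               c(0.020, 0.075, 0.150, 0.075, 0.001))
  # every labeled pixel equals its legend value exactly
  for (k in seq_len(nrow(lg))) {
    sel <- ph$labels$labels == lg$label[k]
    expect_true(all(ph$optics$mu_a[sel] == lg$mu_a[k]),
                info = lg$name[k])
  }
  expect_true(all(ph$optics$mu_s_prime == 2))
  # depth classes: regions 1-3 shallower than 10 mm from the top boundary,
  # region 4 deeper
  depth_of <- function(lab) {
    px <- which(ph$labels$labels == lab, arr.ind = TRUE)
    mean(px[, 1] - 0.5) * ph$optics$grid$h
  }
  expect_true(all(vapply(1:3, depth_of, numeric(1)) < 10))
  expect_gt(depth_of(4), 10)
  expect_error(make_nine_region_phantom(grid_spec(5, 5, 0.2)), "too small")
})

test_that("phantom generation is deterministic and maps stay physical", {
  for (ph in list(make_nine_region_phantom(), make_spectral_phantom(3),
                  make_carotid_phantom())) {
    expect_true(all(ph$optics$mu_a >= 0))
    expect_true(all(ph$optics$mu_s_prime > 0))
    expect_true(all(ph$optics$mu_a[ph$marker$pixels] > 0))
  }
  a <- make_nine_region_phantom()
  b <- make_nine_region_phantom()
  expect_identical(a$optics$mu_a, b$optics$mu_a)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_identical(make_carotid_phantom()$optics$mu_a,
                   make_carotid_phantom()$optics$mu_a)
})

test_that("spectral phantom follows the bundled spectrum table", {
  tab <- spectral_phantom_table()
  expect_equal(nrow(tab), 5L)
  # unknown chromophore: unimodal with the peak at wavelength 3
  expect_equal(which.max(tab$unknown_mu_a), 3L)
  expect_true(all(diff(tab$unknown_mu_a[1:3]) > 0))
  expect_true(all(diff(tab$unknown_mu_a[3:5]) < 0))
  # background: monotone increasing (drives spectral coloring)
  expect_true(all(diff(tab$background_mu_a) > 0))
  for (wl in 1:5) {
    ph <- make_spectral_phantom(wl)
    expect_true(all(ph$optics$mu_a[marker_mask(ph$marker)] == 0.2))
    ann <- ph$labels$labels == 4L
    expect_true(all(ph$optics$mu_a[ann] == tab$unknown_mu_a[wl]))
    expect_equal(ph$optics$mu_a[1, 1], tab$background_mu_a[wl])
  }
  expect_false(make_spectral_phantom(1)$optics$mu_a[1, 1] ==
                 make_spectral_phantom(2)$optics$mu_a[1, 1])
  expect_error(make_spectral_phantom(0), "wavelength_index")
  expect_error(make_spectral_phantom(6), "wavelength_index")
})

test_that("carotid phantom matches its component ground truths", {
  ph <- make_carotid_phantom()
  lg <- ph$labels$legend
  get_mu <- function(nm) unique(ph$optics$mu_a[ph$labels$labels ==
                                                 lg$label[lg$name == nm]])
  expect_equal(get_mu("blood"), 0.650)
  expect_equal(get_mu("lipid"), 0.013)
  expect_equal(get_mu("muscle"), 0.050)
  expect_equal(get_mu("superficial_tissue"), 0.040)
  expect_equal(get_mu("background_tissue"), 0.040)
  expect_equal(ph$marker$mu_a_marker, 0.650)
  # marker-error option perturbs only the prior, not the ground truth
  ph10 <- make_carotid_phantom(marker_error = 0.1)
  expect_equal(ph10$marker$mu_a_marker, 0.715)
  expect_true(all(ph10$optics$mu_a[marker_mask(ph10$marker)] == 0.650))
})

test_that("two-layer fixture evaluates the Beer-Lambert forward model", {
  tl <- make_two_layer_phantom(0.51, 0.44, 0)
  expect_equal(tl$H_unknown / tl$H_marker, 0.51 / 0.44)
  tl1 <- make_two_layer_phantom(0.51, 0.44, 1.0)
  expect_equal(tl1$H_marker, 0.44 * exp(-0.51))
  # H -> 0 as the unknown absorption vanishes
  expect_lt(make_two_layer_phantom(1e-9, 0.44, 1)$H_unknown, 1e-8)
  expect_error(make_two_layer_phantom(-0.1, 0.44, 1), "must be > 0")
  expect_error(make_two_layer_phantom(0.5, 0, 1), "must be > 0")
})
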