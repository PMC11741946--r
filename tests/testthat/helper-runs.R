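# Memoized full-scale nine-region study runs shared by the acceptance tests:
# for a given noise seed, the measured data and all five method variants at
# the study conditions (10 sources, SNR 30 dB, up to 700 iterations).

nine_region_study_seeds <- c(1L, 2L, 3L)

nine_region_study <- function(seed) {
  memo(sprintf("nine_region_study_%d", seed), {
    ph <- make_nine_region_phantom()
    g <- ph$optics$grid
    mesh <- build_mesh(g)
    sources <- default_sources(g, 10)
    phi <- solve_fluence(mesh, ph$optics, sources)
    H <- absorbed_energy(ph$optics, phi)
    H_M <- add_noise(H, 30, seed = seed)
    optics_unknown <- optical_map(matrix(0, g$ny, g$nx), 2, g)
    cfg <- function(m) inversion_config(m, max_iter = 700, seed = seed)
    runs <- list(
      SIM = run_sim(H_M, optics_unknown, cfg("SIM"), marker = NULL,
                    sources = sources),
      SIM_MARKER = run_sim(H_M, optics_unknown, cfg("SIM"),
                           marker = ph$marker, sources = sources),
      GBM = run_gbm(H_M, optics_unknown, cfg("GBM"), marker = NULL,
                    sources = sources),
      GBM_MARKER = run_gbm(H_M, optics_unknown, cfg("GBM"),
                           marker = ph$marker, sources = sources),
      GBM_CONSTRAINED = run_gbm_constrained(H_M, optics_unknown,
                                            cfg("GBM_CONSTRAINED"),
                                            marker = ph$marker,
                                            sources = sources))
    mm <- marker_mask(ph$marker)
    list(phantom = ph, H_M = H_M, runs = runs,
         psnr = vapply(runs, function(r)
           psnr(r$mu_a_hat, ph$optics$mu_a, mm), numeric(1)),
         regions = lapply(runs, function(r)
           region_means(r$mu_a_hat, ph$labels)))
  })
}

region_recovered <- function(study, method, label) {
  rr <- study$regions[[method]]
  rr$recovered[rr$label == label]
}
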