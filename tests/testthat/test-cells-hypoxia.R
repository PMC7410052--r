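test_that("nucleus counting is exact on planted renders and filters distractors", {
  sim <- fixture_sim()
  img <- sim$image
  nuc <- count_nuclei(img$channels$fli1, sim$masks$pecam, pixel_size = 1)
  expect_equal(nuc$count, sim$truth$n_nuclei)
  expect_true(all(nuc$particles$area_px2 > 20))
  # blank channel counts nothing
  blank <- matrix(0.05, 600, 600)
  expect_equal(count_nuclei(blank, sim$masks$pecam, pixel_size = 1)$count, 0)
  # without the vessel-containment rule the same nuclei are still found
  all_nuc <- count_nuclei(img$channels$fli1, NULL, pixel_size = 1)
  expect_gte(all_nuc$count, nuc$count)
})

test_that("nuclei outside the vessel mask are excluded", {
  chan <- matrix(0.05, 200, 200)
  vess <- flatquant:::stamp_segments(c(200, 200), 1, 20, 60, 180, 60, 8)
  on_v <- flatquant:::stamp_ellipse(matrix(FALSE, 200, 200), 1, 100, 60, 64)
  off_v <- flatquant:::stamp_ellipse(matrix(FALSE, 200, 200), 1, 100, 150, 64)
  chan[on_v | off_v] <- 0.9
  res <- count_nuclei(chan, vess, pixel_size = 1)
  expect_equal(res$count, 1)
  expect_equal(count_nuclei(chan, NULL, pixel_size = 1)$count, 2)
})

test_that("proliferation fraction recovers the planted positive share", {
  sim <- fixture_sim()
  nuc <- count_nuclei(sim$image$channels$fli1, sim$masks$pecam, pixel_size = 1)
  pf <- proliferation_fraction(sim$image$channels$phh3, nuc)
  expect_equal(pf, sim$truth$n_proliferating / sim$truth$n_nuclei)
  # no pHH3 signal at all -> 0; all bright -> 1
  expect_equal(proliferation_fraction(matrix(0.05, 600, 600), nuc), 0)
  expect_equal(proliferation_fraction(matrix(1, 600, 600), nuc,
                                      positivity_threshold = 0.5), 1)
  empty <- nuc; empty$particles <- nuc$particles[0, ]
  expect_error(proliferation_fraction(sim$image$channels$phh3, empty), "nuclei")
})

test_that("apoptotic-EC density matches the planted count over region area", {
  sim <- fixture_sim()
  central <- sim$regions$regions$central
  apo <- count_apoptotic_ecs(sim$image$channels$casp3, sim$masks$pecam,
                             sim$masks$coliv, central, pixel_size = 1)
  expect_equal(apo$count, sim$truth$n_apoptotic)
  expect_equal(apo$density_per_mm2, sim$truth$n_apoptotic / (sum(central) / 1e6))
  # no signal -> zero
  none <- count_apoptotic_ecs(matrix(0.05, 600, 600), sim$masks$pecam,
                              sim$masks$coliv, central, pixel_size = 1)
  expect_equal(none$count, 0)
})

test_that("caspase particles outside collagen IV are not apoptotic ECs", {
  chan <- matrix(0.05, 200, 200)
  vess <- flatquant:::stamp_segments(c(200, 200), 1, 20, 60, 180, 60, 10)
  inside <- flatquant:::stamp_ellipse(matrix(FALSE, 200, 200), 1, 100, 60, 64)
  outside <- flatquant:::stamp_ellipse(matrix(FALSE, 200, 200), 1, 100, 150, 64)
  chan[inside | outside] <- 0.9
  region <- matrix(TRUE, 200, 200)
  res <- count_apoptotic_ecs(chan, vess, vess, region, pixel_size = 1)
  expect_equal(res$count, 1)
})

test_that("hypoxic-area fraction recovers planted fractions and degenerate cases", {
  sim <- fixture_sim()
  central <- sim$regions$regions$central
  expect_equal(hypoxic_area_fraction(matrix(1, 600, 600), central,
                                     threshold = 0.5, pixel_size = 1), 1)
  expect_equal(hypoxic_area_fraction(matrix(0.05, 600, 600), central,
                                     pixel_size = 1), 0)
  hf <- hypoxic_area_fraction(sim$image$channels$pimo, central, pixel_size = 1)
  expect_equal(hf, sim$truth$hypoxic_fraction, tolerance = 0.02)
})

test_that("hypoxic fraction is monotone non-increasing in the manual threshold", {
  sim <- fixture_sim()
  central <- sim$regions$regions$central
  thrs <- c(0.1, 0.3, 0.5, 0.7)
  fr <- vapply(thrs, function(t)
    hypoxic_area_fraction(sim$image$channels$pimo, central, threshold = t,
                          pixel_size = 1), numeric(1))
  expect_true(all(diff(fr) <= 0))
})

test_that("neovascular area is specific on tuft-free renders and recovers planted area", {
  net <- fixture_net()
  sim0 <- render_flatmount(net, extras = list(n_nuclei = 0, n_tufts = 0),
                           config = render_config(rng_seed = 31))
  whole <- sim0$regions$regions$whole
  nv0 <- neovascular_area(sim0$image$channels$coliv, sim0$masks$coliv, whole, 1)
  expect_equal(nv0$total_area_um2, 0)
  simt <- render_flatmount(net, extras = list(n_nuclei = 0, n_tufts = 5),
                           config = render_config(rng_seed = 32))
  nvt <- neovascular_area(simt$image$channels$coliv,
                          simt$masks$coliv & !simt$masks$tufts, whole, 1)
  expect_equal(nvt$total_area_um2, simt$truth$tuft_area_um2, tolerance = 0.1)
  expect_true(all(nvt$lesions$solidity >= 0.85))
  # infinite intensity factor keeps nothing
  nv_inf <- neovascular_area(simt$image$channels$coliv, simt$masks$coliv, whole, 1,
                             intensity_factor = Inf)
  expect_equal(nv_inf$total_area_um2, 0)
})

test_that("tuft recovery holds under blur and 10% noise", {
  net <- fixture_net()
  simn <- render_flatmount(net, extras = list(n_nuclei = 0, n_tufts = 5),
                           config = render_config(psf_sigma = 1,
                                                  gaussian_noise_sd = 0.04,
                                                  rng_seed = 33))
  whole <- simn$regions$regions$whole
  nvn <- neovascular_area(simn$image$channels$coliv,
                          simn$masks$coliv & !simn$masks$tufts, whole, 1)
  rel <- abs(nvn$total_area_um2 - simn$truth$tuft_area_um2) / simn$truth$tuft_area_um2
  expect_lt(rel, 0.25)
})
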