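test_that("vessel area fraction handles the degenerate and planted cases", {
  region <- matrix(TRUE, 50, 50)
  expect_equal(vessel_area_fraction(region, region), 1)
  expect_equal(vessel_area_fraction(matrix(FALSE, 50, 50), region), 0)
  expect_error(vessel_area_fraction(region, matrix(FALSE, 50, 50)), "empty")
  sim <- fixture_sim()
  central <- sim$regions$regions$central
  planted <- sum(sim$masks$pecam & central) / sum(central)
  expect_equal(vessel_area_fraction(sim$masks$pecam, central), planted,
               tolerance = 0.02)
})

test_that("regression ratio: identical, empty and planted-fraction cases", {
  m <- flatquant:::stamp_segments(c(80, 200), 1, 10, 40, 190, 40, 8)
  same <- regression_ratio(m, m, pixel_size = 1)
  expect_equal(same$ec_over_coliv, 1)
  expect_equal(same$regressing_over_coliv, 0)
  gone <- regression_ratio(matrix(FALSE, 80, 200), m, pixel_size = 1)
  expect_equal(gone$regressing_over_coliv, 1)
  expect_error(regression_ratio(m, matrix(FALSE, 80, 200), pixel_size = 1),
               "undefined")
  sim <- fixture_sim()
  tr <- attr(sim, "truth_regression")
  rr <- regression_ratio(sim$masks$pecam, sim$masks$coliv, pixel_size = 1)
  expect_equal(rr$regressing_over_coliv, tr$regression_fraction, tolerance = 0.03)
  expect_equal(rr$ec_over_coliv + rr$regressing_over_coliv, 1, tolerance = 1e-9)
  ir <- icam_regression_ratio(sim$masks$icam, sim$masks$coliv, pixel_size = 1)
  expect_equal(ir$regressing_over_coliv, tr$regression_fraction, tolerance = 0.03)
})

test_that("fragmentation index counts planted components per area", {
  region1mm <- matrix(TRUE, 1000, 1000) # 1 mm^2 at 1 um/px
  plus <- matrix(FALSE, 1000, 1000); plus[500, 100:900] <- TRUE
  expect_equal(fragmentation_index(plus, region1mm, 1), 1)
  expect_equal(fragmentation_index(matrix(FALSE, 1000, 1000), region1mm, 1), 0)
  sim <- fixture_sim()
  K <- attr(sim, "truth_regression")$n_components
  field <- sim$regions$regions$field
  idx <- fragmentation_index(sim$masks$pecam, field, 1)
  expect_equal(idx * sum(field) / 1e6, K)
})

test_that("branch density matches planted junction counts approximately", {
  region1mm <- matrix(TRUE, 1000, 1000)
  plus <- matrix(FALSE, 1000, 1000)
  plus[496:504, 100:900] <- TRUE; plus[100:900, 496:504] <- TRUE
  expect_equal(branch_density(plus, region1mm, 1), 1)
  bar <- bar_mask(1000, 1000, 496, 504, 100, 900)
  expect_equal(branch_density(bar, region1mm, 1), 0)
  # planted honeycomb: interior nodes are 3-valent junctions
  net <- fixture_net()
  sim0 <- render_flatmount(net, extras = list(n_nuclei = 0),
                           config = render_config(rng_seed = 2))
  field <- sim0$regions$regions$field
  measured <- branch_density(sim0$masks$coliv, field, 1) * sum(field) / 1e6
  deg <- tabulate(c(net$edges$from, net$edges$to), nrow(net$nodes))
  planted <- sum(deg >= 3)
  expect_lt(abs(measured - planted) / planted, 0.10)
})

test_that("mean vessel width recovers planted ribbon widths and scales", {
  m10 <- flatquant:::stamp_segments(c(60, 260), 1, 20, 30, 220, 30, 10)
  expect_equal(mean_vessel_width(m10, pixel_size = 1), 10, tolerance = 0.1)
  m20 <- flatquant:::stamp_segments(c(80, 260), 1, 20, 40, 220, 40, 20)
  w10 <- mean_vessel_width(m10, pixel_size = 1)
  w20 <- mean_vessel_width(m20, pixel_size = 1)
  expect_equal(w20 / w10, 2, tolerance = 0.1)
  expect_error(mean_vessel_width(matrix(FALSE, 10, 10), pixel_size = 1), "undefined")
})

test_that("metrics are invariant under translation and pixel-size refinement", {
  sim <- fixture_sim()
  crop <- sim$masks$pecam[101:500, 101:500]
  reg <- matrix(TRUE, 400, 400)
  w1 <- mean_vessel_width(crop, reg, 1)
  shifted <- matrix(FALSE, 400, 400)
  shifted[21:400, 21:400] <- crop[1:380, 1:380]
  reg_s <- matrix(FALSE, 400, 400); reg_s[21:400, 21:400] <- TRUE
  expect_equal(mean_vessel_width(shifted, reg_s, 1),
               mean_vessel_width(crop[1:380, 1:380], matrix(TRUE, 380, 380), 1),
               tolerance = 1e-9)
  # half the pixel size, same geometry in um
  net <- fixture_net()
  simf <- render_flatmount(net, extras = list(n_nuclei = 0),
                           config = render_config(pixel_size = 0.5, rng_seed = 2))
  sim1 <- render_flatmount(net, extras = list(n_nuclei = 0),
                           config = render_config(pixel_size = 1, rng_seed = 2))
  wf <- mean_vessel_width(simf$masks$coliv, pixel_size = 0.5)
  w1 <- mean_vessel_width(sim1$masks$coliv, pixel_size = 1)
  expect_equal(wf, w1, tolerance = 0.05)
})

test_that("fragmentation is monotone along a regression ladder", {
  net <- fixture_net()
  counts <- vapply(c(0, 0.2, 0.4, 0.6, 0.8), function(tf) {
    rg <- apply_regression(net, tf, mode = "cluster-contraction", n_clusters = 12,
                           rng_seed = 5)
    rg$truth$n_components
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("vaso-obliterated area: full coverage 0, empty 1, planted disc recovered", {
  sim <- fixture_sim()
  whole <- sim$regions$regions$whole
  expect_equal(vaso_obliterated_area(matrix(TRUE, 600, 600), whole, 1), 0)
  expect_equal(vaso_obliterated_area(matrix(FALSE, 600, 600), whole, 1), 1)
  net <- apply_vaso_obliteration(fixture_net(), sqrt(0.25 * sum(whole) / pi))
  sv <- render_flatmount(net, extras = list(n_nuclei = 0),
                         config = render_config(rng_seed = 2))
  expect_lt(abs(vaso_obliterated_area(sv$masks$coliv, whole, 1) - 0.25), 0.03)
})

test_that("regression recovery is linear in the planted fraction across seeds", {
  fracs <- rep(c(0, 0.25, 0.5, 0.75, 1), each = 2)
  seeds <- seq_along(fracs)
  res <- vapply(seq_along(fracs), function(i) {
    net <- generate_plexus(400, 0.002, n_arteries = 2, rng_seed = 300 + i)
    rg <- apply_regression(net, fracs[i], mode = "cluster-contraction",
                           n_clusters = 6, rng_seed = i)
    sim <- render_flatmount(rg$network, extras = list(n_nuclei = 0),
                            config = render_config(rng_seed = i))
    c(truth = rg$truth$regression_fraction,
      meas = regression_ratio(sim$masks$pecam, sim$masks$coliv,
                              pixel_size = 1)$regressing_over_coliv)
  }, numeric(2))
  err <- res["meas", ] - res["truth", ]
  expect_lt(max(abs(err)), 0.03)
  fit <- stats::lm(res["meas", ] ~ res["truth", ])
  expect_gt(coef(fit)[2], 0.9)
  expect_lt(coef(fit)[2], 1.1)
  expect_lt(abs(coef(fit)[1]), 0.05)
})
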