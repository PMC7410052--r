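# comb-shaped planted fixture: a horizontal artery with vertical teeth
comb_fixture <- function(n_teeth = 7, tooth_len = 60, spacing = 40) {
  w <- 8
  width <- (n_teeth + 1) * spacing
  dim <- c(tooth_len + 60, width)
  artery <- flatquant:::stamp_segments(dim, 1, 10, 30, width - 10, 30, w)
  teeth <- matrix(FALSE, dim[1], dim[2])
  for (k in seq_len(n_teeth)) {
    x <- k * spacing
    teeth <- teeth | flatquant:::stamp_segments(dim, 1, x, 30, x, 30 + tooth_len, 6)
  }
  cl <- cbind(row = rep(30L, width - 20), col = 10:(width - 11))
  list(mask = artery | teeth, artery = artery, centerline = cl, dim = dim,
       tooth_x = seq_len(n_teeth) * spacing)
}

test_that("side branches are detected on a comb with deterministic ordering", {
  fx <- comb_fixture(7)
  sk <- skeletonize(fx$mask, 1)
  br <- detect_side_branches(sk, fx$centerline)
  expect_equal(nrow(br), 7)
  expect_true(all(diff(br$arc_pos_um) > 0))
  expect_equal(sort(unname(br$junction_col)), sort(fx$tooth_x), tolerance = 2)
  # artery without branches
  sk0 <- skeletonize(fx$artery, 1)
  expect_equal(nrow(detect_side_branches(sk0, fx$centerline)), 0)
  # short teeth fall below min_branch_length
  fx2 <- comb_fixture(5, tooth_len = 8)
  br2 <- detect_side_branches(skeletonize(fx2$mask, 1), fx2$centerline,
                              min_branch_length_um = 20)
  expect_equal(nrow(br2), 0)
  # centerline nowhere near the skeleton errors
  far <- cbind(row = rep(fx$dim[1] - 2L, 50), col = 1:50)
  expect_error(detect_side_branches(sk, far), "snap")
})

test_that("branch classification follows the lectin/ICAM2/collagen IV logic", {
  fx <- comb_fixture(4, tooth_len = 70)
  sk <- skeletonize(fx$mask, 1)
  br <- detect_side_branches(sk, fx$centerline)
  coliv <- fx$mask
  full <- fx$mask
  none <- fx$artery
  # perfused: lectin and icam everywhere
  call <- classify_side_branch(br[1, ], full, full, coliv, 1)
  expect_equal(call$state, "perfused")
  # attached: no lectin on the tooth, icam intact
  call <- classify_side_branch(br[1, ], none, full, coliv, 1)
  expect_equal(call$state, "attached")
  expect_true(call$coliv_continuous)
  # detached: 10 um icam gap (2x tolerance) at the junction
  jx <- br$junction_col[2]
  icam_gap <- flatquant:::cut_branch_gap(full, 1, c(jx, 30), c(jx, 100), 6, 16, 8)
  call <- classify_side_branch(br[2, ], none, icam_gap, coliv, 1, gap_tolerance_um = 5)
  expect_equal(call$state, "detached")
  expect_gt(call$max_icam_gap_um, 5)
  # disrupted: 2.5 um gaps (0.5x tolerance)
  icam_small <- flatquant:::cut_branch_gap(full, 1, c(jx, 30), c(jx, 100), 8, 10.5, 8)
  icam_small <- flatquant:::cut_branch_gap(icam_small, 1, c(jx, 30), c(jx, 100), 16, 18.5, 8)
  call <- classify_side_branch(br[2, ], none, icam_small, coliv, 1, gap_tolerance_um = 5)
  expect_equal(call$state, "disrupted")
  expect_lte(call$max_icam_gap_um, 5)
  # unclassifiable when collagen IV is broken too
  cv_gap <- flatquant:::cut_branch_gap(coliv, 1, c(jx, 30), c(jx, 100), 6, 16, 8)
  call <- classify_side_branch(br[2, ], none, icam_gap, cv_gap, 1)
  expect_equal(call$state, "unclassifiable")
})

test_that("calls are invariant to branch enumeration order", {
  fx <- comb_fixture(5)
  sk <- skeletonize(fx$mask, 1)
  br <- detect_side_branches(sk, fx$centerline)
  fwd <- classify_side_branches(br, fx$mask, fx$mask, fx$mask, 1)
  rev_order <- br[rev(seq_len(nrow(br))), ]
  bwd <- classify_side_branches(rev_order, fx$mask, fx$mask, fx$mask, 1)
  expect_equal(fwd$state, rev(bwd$state))
})

test_that("perfused branch density is count over artery length", {
  calls <- tibble::tibble(state = c(rep("perfused", 10), rep("attached", 3)))
  artery <- list(cbind(row = rep(5L, 2001), col = 1:2001)) # 2 mm at 1 um/px
  expect_equal(perfused_branch_density(calls, artery, 1), 5, tolerance = 0.01)
  expect_equal(perfused_branch_density(tibble::tibble(state = character(0)),
                                       artery, 1), 0)
  expect_error(perfused_branch_density(calls, list()), "artery")
})

test_that("planted vs called class confusion matrix is diagonal on full renders", {
  net <- generate_plexus(600, 0.002, n_arteries = 2, rng_seed = 55)
  pf <- apply_perfusion_loss(net, 9, c(attached = 1/3, disrupted = 1/3,
                                       detached = 1/3), rng_seed = 8)
  sim <- render_flatmount(pf$network, extras = list(n_nuclei = 0),
                          config = render_config(rng_seed = 2))
  skc <- skeletonize(sim$masks$coliv, 1)
  calls <- NULL
  for (ai in seq_along(sim$regions$arteries)) {
    br <- detect_side_branches(skc, sim$regions$arteries[[ai]])
    calls <- rbind(calls, classify_side_branches(br, sim$masks$lectin,
                                                 sim$masks$icam, sim$masks$coliv, 1))
  }
  sb <- pf$network$side_branches
  hits <- match_planted_calls(calls, sb, pf$network$nodes, pf$network$edges)
  expect_false(anyNA(hits))
  expect_equal(hits, sb$state)
})
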