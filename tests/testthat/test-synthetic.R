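test_that("generate_plexus validates arguments and is deterministic", {
  expect_error(generate_plexus(-1, 0.002), "> 0")
  expect_error(generate_plexus(500, 0), "> 0")
  expect_error(generate_plexus(500, 0.002, n_arteries = 0), ">= 1")
  n1 <- generate_plexus(400, 0.002, n_arteries = 2, rng_seed = 5)
  n2 <- generate_plexus(400, 0.002, n_arteries = 2, rng_seed = 5)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$nodes, n2$nodes)
})

test_that("the plexus is connected with density-implied total edge length", {
  net <- generate_plexus(1000, 0.002, n_arteries = 2, rng_seed = 12)
  g_edges <- lapply(seq_len(nrow(net$edges)),
                    function(i) c(net$edges$from[i], net$edges$to[i]))
  expect_equal(uf_components(g_edges, seq_len(nrow(net$nodes))), 1)
  target <- 1000^2 * sqrt(2 * 0.002 / sqrt(3))
  actual <- sum(sqrt(rowSums((net$nodes[net$edges$from, ] -
                              net$nodes[net$edges$to, ])^2)))
  expect_lt(abs(actual - target) / target, 0.15)
  expect_true(all(net$edges$width_um > 0))
  expect_true(all(net$edges$ec_present) && all(net$edges$perfused))
})

test_that("regression modes hit their length budget and component count", {
  net <- fixture_net()
  r0 <- apply_regression(net, 0, rng_seed = 1)
  expect_identical(r0$network$edges, net$edges)
  expect_equal(r0$truth$n_components, 1)
  r1 <- apply_regression(net, 1, rng_seed = 1)
  expect_false(any(r1$network$edges$ec_present))
  expect_equal(r1$truth$regression_fraction, 1)
  expect_error(apply_regression(net, 1.2), "\\[0, 1\\]")

  rr <- apply_regression(net, 0.4, mode = "random-edge", rng_seed = 9)
  total <- sum(net$edges$length_um)
  lost <- sum(net$edges$length_um[!rr$network$edges$ec_present])
  expect_lt(abs(lost - 0.4 * total), max(net$edges$length_um)) # within one edge

  for (K in c(1, 3, 12)) {
    rc <- apply_regression(net, 0.5, mode = "cluster-contraction",
                           n_clusters = K, rng_seed = 2)
    # oracle: union-find over the ec_present edge list
    e <- rc$network$edges
    keep <- which(e$ec_present)
    edges <- lapply(keep, function(i) c(e$from[i], e$to[i]))
    nodes <- unique(unlist(edges))
    expect_equal(rc$truth$n_components, K)
    expect_equal(uf_components(edges, nodes), K)
  }
})

test_that("perfusion loss propagates downstream and classes are apportioned", {
  net <- fixture_net()
  p0 <- apply_perfusion_loss(net, 0, rng_seed = 1)
  expect_true(all(p0$network$edges$perfused))
  expect_equal(p0$truth$n_perfused_side_branches, nrow(net$side_branches))
  expect_error(apply_perfusion_loss(net, nrow(net$side_branches) + 1), "closures")

  pd <- apply_perfusion_loss(net, 3, c(detached = 1), rng_seed = 2)
  expect_equal(unname(pd$truth$side_branch_class_counts),
               c(0, 0, 3))

  pf <- apply_perfusion_loss(net, 8, rng_seed = 4)
  e <- pf$network$edges
  # oracle: reachability from the root through open (non-closed) edges
  closed <- pf$network$side_branches$edge[pf$network$side_branches$state != "perfused"]
  open_edges <- lapply(setdiff(seq_len(nrow(e)), closed),
                       function(i) c(e$from[i], e$to[i]))
  # BFS from root
  adj <- vector("list", nrow(pf$network$nodes))
  for (ed in open_edges) {
    adj[[ed[1]]] <- c(adj[[ed[1]]], ed[2]); adj[[ed[2]]] <- c(adj[[ed[2]]], ed[1])
  }
  reach <- logical(nrow(pf$network$nodes)); frontier <- pf$network$root
  reach[frontier] <- TRUE
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[!is.na(nxt) & !reach[nxt]]
    reach[nxt] <- TRUE
    frontier <- nxt
  }
  expect_equal(e$perfused,
               reach[e$from] & reach[e$to] & !(seq_len(nrow(e)) %in% closed))
})

test_that("rendering respects mask containment, counts and determinism", {
  sim <- fixture_sim()
  m <- sim$masks
  expect_true(all(m$pecam <= m$coliv))
  expect_true(all(m$lectin <= m$icam | !m$pecam)) # lectin within icam away from gaps
  expect_true(all(m$lectin <= m$pecam))
  tr <- sim$truth
  expect_equal(tr$n_nuclei, 40)
  expect_equal(tr$n_proliferating, 8)
  expect_equal(tr$n_apoptotic, 12)
  expect_equal(tr$tuft_area_um2, sum(m$tufts))
  # determinism: identical seed/config give an identical image
  rg <- apply_regression(fixture_net(), 0.5, mode = "cluster-contraction",
                         n_clusters = 12, rng_seed = 7)
  sim2 <- render_flatmount(rg$network,
                           extras = list(n_nuclei = 40, n_distractors = 10,
                                         prolif_fraction = 0.2,
                                         n_apoptotic = 12, n_tufts = 4),
                           config = render_config(rng_seed = 3))
  expect_identical(sim$image$channels, sim2$image$channels)
})

test_that("a single rendered ribbon has the analytic pixel area", {
  net <- structure(list(
    nodes = rbind(c(50, 30), c(150, 30)),
    edges = tibble::tibble(from = 1L, to = 2L, length_um = 100, width_um = 10,
                           is_artery = FALSE, is_side_branch = FALSE,
                           ec_present = TRUE, perfused = TRUE),
    arteries = list(), side_branches = NULL, root = 1L, field_size_um = 200),
    class = "vessel_network")
  sim <- render_flatmount(net, extras = list(n_nuclei = 0, n_apoptotic = 0,
                                             hypoxic_fraction = 0),
                          config = render_config(rng_seed = 1))
  # capsule area = L*w + pi*(w/2)^2; rasterization within a few edge pixels
  expect_equal(sum(sim$masks$coliv), 100 * 10 + pi * 25, tolerance = 0.03)
})

test_that("hypoxia field hits the requested area fraction by construction", {
  for (f in c(0.1, 0.5, 0.9)) {
    net <- fixture_net()
    sim <- render_flatmount(net, extras = list(n_nuclei = 0, hypoxic_fraction = f),
                            config = render_config(rng_seed = 6))
    expect_equal(sim$truth$hypoxic_fraction, f, tolerance = 0.01)
  }
})

test_that("rendered regression fraction matches the flag-based ground truth", {
  sim <- fixture_sim()
  tr <- attr(sim, "truth_regression")
  rr <- regression_ratio(sim$masks$pecam, sim$masks$coliv, pixel_size = 1)
  expect_equal(rr$regressing_over_coliv, tr$regression_fraction, tolerance = 0.03)
})
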