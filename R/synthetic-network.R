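#' Synthetic planar vascular network
#'
#' A jittered honeycomb capillary mesh (3-valent, like a capillary
#' plexus) with radial arteries walked out from a central root node.
#' Every edge carries a width and the biological state flags the OIR
#' perturbations manipulate: `ec_present` (endothelium still occupies
#' the basement-membrane sleeve) and `perfused` (reachable by blood from
#' the artery root).
#'
#' `capillary_density` is the mesh-edge count per square micrometre; the
#' honeycomb edge length is then `sqrt(2 / (sqrt(3) * density))`, so the
#' density-implied total edge length is
#' `field_area * sqrt(2 * density / sqrt(3))`. The default density of
#' 0.002 edges/um^2 gives ~24 um edges and ~40 um capillary spacing.
#'
#' @param field_size_um side of the square field of view, micrometres.
#' @param capillary_density mesh edges per um^2 (> 0).
#' @param n_arteries number of radial arteries (>= 1).
#' @param rng_seed seed; identical seeds give identical networks.
#' @param jitter node position jitter as a fraction of edge length.
#' @param width_capillary_um,width_artery_um ribbon widths.
#' @return an object of class `vessel_network`: `nodes` (n x 2 matrix of
#'   x,y um), `edges` (tibble: from, to, length_um, width_um, is_artery,
#'   is_side_branch, ec_present, perfused), `arteries` (list of node
#'   paths), `side_branches` (tibble), `root`, `field_size_um`.
#' @export
generate_plexus <- function(field_size_um, capillary_density = 0.002,
                            n_arteries = 4, rng_seed = 1, jitter = 0.15,
                            width_capillary_um = 6, width_artery_um = 12) {
  abort_if(field_size_um <= 0, "field_size_um must be > 0")
  abort_if(capillary_density <= 0, "capillary_density must be > 0")
  abort_if(n_arteries < 1, "n_arteries must be >= 1")
  ell <- sqrt(2 / (sqrt(3) * capillary_density))
  withr::with_seed(rng_seed, {
    net <- honeycomb_network(field_size_um, ell, jitter)
    net <- largest_component(net)
    net$edges$width_um <- width_capillary_um
    net$edges$is_artery <- FALSE
    net$edges$is_side_branch <- FALSE
    net$edges$ec_present <- TRUE
    net$edges$perfused <- TRUE
    net <- add_arteries(net, n_arteries, width_artery_um)
  })
  net$field_size_um <- field_size_um
  net$params <- list(capillary_density = capillary_density, edge_length_um = ell,
                     rng_seed = rng_seed, jitter = jitter)
  class(net) <- "vessel_network"
  net
}

honeycomb_network <- function(field, ell, jitter) {
  # basis A = (0,0), B = (sqrt(3)/2, 1/2)*ell; lattice u = (sqrt(3),0)*ell,
  # v = (sqrt(3)/2, 3/2)*ell. A(i,j) bonds to B(i,j), B(i-1,j), B(i,j-1).
  ux <- sqrt(3) * ell
  vx <- sqrt(3) / 2 * ell; vy <- 1.5 * ell
  bx <- sqrt(3) / 2 * ell; by <- 0.5 * ell
  jmax <- ceiling(field / vy) + 1
  key <- function(i, j, b) paste(i, j, b, sep = "_")
  ids <- new.env(parent = emptyenv())
  xs <- numeric(0); ys <- numeric(0); nid <- 0
  add_node <- function(i, j, b) {
    x <- i * ux + j * vx + b * bx
    y <- j * vy + b * by
    if (x < -ell || x > field + ell || y < -ell || y > field + ell) return(NA_integer_)
    k <- key(i, j, b)
    if (!is.null(ids[[k]])) return(ids[[k]])
    nid <<- nid + 1
    ids[[k]] <- nid
    xs[nid] <<- x; ys[nid] <<- y
    nid
  }
  from <- integer(0); to <- integer(0)
  for (j in -1:jmax) {
    irange <- floor((-ell - j * vx) / ux):ceiling((field + ell - j * vx) / ux)
    for (i in irange) {
      a <- add_node(i, j, 0)
      if (is.na(a)) next
      for (nbr in list(c(i, j), c(i - 1, j), c(i, j - 1))) {
        b <- add_node(nbr[1], nbr[2], 1)
        if (!is.na(b)) { from <- c(from, a); to <- c(to, b) }
      }
    }
  }
  nodes <- cbind(x = xs, y = ys)
  # jitter then trim to the field with a margin for ribbon widths
  nodes <- nodes + matrix(runif(2 * nrow(nodes), -jitter * ell, jitter * ell),
                          ncol = 2)
  margin <- 2
  keep <- nodes[, 1] >= margin & nodes[, 1] <= field - margin &
          nodes[, 2] >= margin & nodes[, 2] <= field - margin
  remap <- cumsum(keep)
  ok <- keep[from] & keep[to]
  edges <- tibble(from = remap[from][ok], to = remap[to][ok])
  nodes <- nodes[keep, , drop = FALSE]
  edges$length_um <- sqrt(rowSums((nodes[edges$from, , drop = FALSE] -
                                   nodes[edges$to, , drop = FALSE])^2))
  list(nodes = nodes, edges = edges)
}

network_graph <- function(net, edge_subset = NULL) {
  e <- net$edges
  if (!is.null(edge_subset)) e <- e[edge_subset, , drop = FALSE]
  igraph::make_graph(as.integer(t(as.matrix(e[, c("from", "to")]))),
                     n = nrow(net$nodes), directed = FALSE)
}

largest_component <- function(net) {
  g <- network_graph(net)
  comp <- igraph::components(g)
  keep_nodes <- comp$membership == which.max(comp$csize)
  remap <- cumsum(keep_nodes)
  ok <- keep_nodes[net$edges$from] & keep_nodes[net$edges$to]
  net$edges <- net$edges[ok, , drop = FALSE]
  net$edges$from <- remap[net$edges$from]
  net$edges$to <- remap[net$edges$to]
  net$nodes <- net$nodes[keep_nodes, , drop = FALSE]
  net
}

adjacency_list <- function(net) {
  n <- nrow(net$nodes)
  adj <- vector("list", n)
  for (k in seq_len(nrow(net$edges))) {
    a <- net$edges$from[k]; b <- net$edges$to[k]
    adj[[a]] <- c(adj[[a]], k)
    adj[[b]] <- c(adj[[b]], k)
  }
  adj
}

other_end <- function(edges, k, v) ifelse(edges$from[k] == v, edges$to[k], edges$from[k])

add_arteries <- function(net, n_arteries, width_artery_um) {
  ctr <- c(mean(range(net$nodes[, 1])), mean(range(net$nodes[, 2])))
  root <- which.min((net$nodes[, 1] - ctr[1])^2 + (net$nodes[, 2] - ctr[2])^2)
  adj <- adjacency_list(net)
  angles <- 2 * pi * (seq_len(n_arteries) - 1) / n_arteries + runif(1, 0, 2 * pi)
  arteries <- list()
  for (ai in seq_len(n_arteries)) {
    dir <- c(cos(angles[ai]), sin(angles[ai]))
    perp <- c(-dir[2], dir[1])
    path <- root
    cur <- root
    repeat {
      cand <- vapply(adj[[cur]], other_end, numeric(1), edges = net$edges, v = cur)
      cand <- cand[!(cand %in% path)]
      if (length(cand) == 0) break
      rel <- sweep(net$nodes[cand, , drop = FALSE], 2, net$nodes[root, ])
      along <- rel %*% dir
      aperp <- abs(rel %*% perp)
      cur_along <- sum((net$nodes[cur, ] - net$nodes[root, ]) * dir)
      score <- along - cur_along - 0.8 * aperp
      ok <- along > cur_along
      if (!any(ok)) break
      nxt <- cand[ok][which.max(score[ok])]
      path <- c(path, nxt)
      cur <- nxt
    }
    if (length(path) < 3) next
    arteries[[length(arteries) + 1]] <- path
  }
  # flag artery edges
  eid <- function(a, b) which((net$edges$from == a & net$edges$to == b) |
                              (net$edges$from == b & net$edges$to == a))[1]
  for (p in arteries) {
    for (k in seq_len(length(p) - 1)) {
      id <- eid(p[k], p[k + 1])
      net$edges$is_artery[id] <- TRUE
      net$edges$width_um[id] <- width_artery_um
    }
  }
  # side branches: non-artery edges leaving interior artery-path nodes
  sb <- list()
  for (ai in seq_along(arteries)) {
    p <- arteries[[ai]]
    arc <- c(0, cumsum(sqrt(rowSums((net$nodes[p[-1], , drop = FALSE] -
                                     net$nodes[p[-length(p)], , drop = FALSE])^2))))
    for (k in seq(2, length(p) - 1)) {
      v <- p[k]
      for (e in adj[[v]]) {
        if (!net$edges$is_artery[e]) {
          net$edges$is_side_branch[e] <- TRUE
          sb[[length(sb) + 1]] <- tibble(
            edge = e, artery = ai, junction_node = v,
            arc_pos_um = arc[k],
            x = net$nodes[v, 1], y = net$nodes[v, 2])
        }
      }
    }
  }
  net$root <- root
  net$arteries <- arteries
  net$side_branches <- if (length(sb)) dplyr::bind_rows(sb) else
    tibble(edge = integer(0), artery = integer(0), junction_node = integer(0),
           arc_pos_um = numeric(0), x = numeric(0), y = numeric(0))
  if (nrow(net$side_branches)) net$side_branches$state <- "perfused"
  net
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf(paste0("<vessel_network> %d nodes, %d edges (%.0f um total), ",
                     "%d arteries, %d side branches\n"),
              nrow(x$nodes), nrow(x$edges), sum(x$edges$length_um),
              length(x$arteries), nrow(x$side_branches)))
  invisible(x)
}

#' Ground truth carried by a synthetic network
#'
#' Recomputed from the edge flags: length-weighted regression fraction,
#' EC-subgraph component count, perfused side-branch census and class
#' counts. Rendering adds the cell/hypoxia/tuft fields.
#'
#' @param net a `vessel_network`.
#' @return a list of class `ground_truth`.
#' @export
network_truth <- function(net) {
  e <- net$edges
  regression_fraction <- sum(e$length_um[!e$ec_present]) / sum(e$length_um)
  ec_idx <- which(e$ec_present)
  n_components <- if (length(ec_idx) == 0) 0L else {
    comp <- igraph::components(network_graph(net, ec_idx))
    ec_nodes <- unique(c(e$from[ec_idx], e$to[ec_idx]))
    length(unique(comp$membership[ec_nodes]))
  }
  sb <- net$side_branches
  states <- if (!is.null(sb) && nrow(sb)) sb$state else character(0)
  structure(list(
    regression_fraction = regression_fraction,
    n_components = n_components,
    n_perfused_side_branches = sum(states == "perfused"),
    side_branch_class_counts = c(attached = sum(states == "attached"),
                                 disrupted = sum(states == "disrupted"),
                                 detached = sum(states == "detached")),
    n_nuclei = NA_integer_, n_proliferating = NA_integer_,
    n_apoptotic = NA_integer_, hypoxic_fraction = NA_real_,
    tuft_area_um2 = NA_real_), class = "ground_truth")
}

#' Remove endothelium from a fraction of the network
#'
#' Sets `ec_present = FALSE` on edges totalling `target_fraction` of
#' edge length. `"random-edge"` mode removes shuffled edges until the
#' length budget is met (within one edge). `"cluster-contraction"` mode
#' emulates the contraction of surviving apoptosis-blocked endothelium
#' into isolated clusters: `n_clusters` seed nodes (pairwise >= 3 hops
#' apart) grow node-disjoint connected regions in round-robin until the
#' retained EC length reaches `1 - target_fraction` of the total;
#' every edge not inside a single region regresses, so the EC subgraph
#' has exactly `n_clusters` components whenever each region keeps an
#' edge.
#'
#' @param net a `vessel_network`.
#' @param target_fraction fraction of total edge length to regress.
#' @param mode `"random-edge"` or `"cluster-contraction"`.
#' @param n_clusters planted EC component count (cluster mode).
#' @param rng_seed seed.
#' @return list with elements `network` and `truth`.
#' @export
apply_regression <- function(net, target_fraction,
                             mode = c("random-edge", "cluster-contraction"),
                             n_clusters = 12, rng_seed = 1) {
  mode <- match.arg(mode)
  abort_if(!is.numeric(target_fraction) || target_fraction < 0 || target_fraction > 1,
           "target_fraction must be in [0, 1]")
  e <- net$edges
  total <- sum(e$length_um)
  if (target_fraction == 0) {
    return(list(network = net, truth = network_truth(net)))
  }
  if (target_fraction == 1) {
    net$edges$ec_present <- FALSE
    return(list(network = net, truth = network_truth(net)))
  }
  withr::with_seed(rng_seed, {
    if (mode == "random-edge") {
      ord <- sample(nrow(e))
      cum <- cumsum(e$length_um[ord])
      n_out <- which(cum >= target_fraction * total)[1]
      net$edges$ec_present[ord[seq_len(n_out)]] <- FALSE
    } else {
      net <- cluster_contraction(net, target_fraction, n_clusters)
    }
  })
  list(network = net, truth = network_truth(net))
}

cluster_contraction <- function(net, target_fraction, n_clusters) {
  n <- nrow(net$nodes)
  adj <- adjacency_list(net)
  g <- network_graph(net)
  # seeds: sampled, pairwise >= 3 hops apart
  seeds <- integer(0)
  cand <- sample(n)
  for (v in cand) {
    if (length(seeds) == n_clusters) break
    if (length(seeds) == 0 ||
        min(igraph::distances(g, v = v, to = seeds)) >= 3) seeds <- c(seeds, v)
  }
  abort_if(length(seeds) < n_clusters,
           "could not place the requested number of cluster seeds")
  claimed <- integer(n)
  claimed[seeds] <- seq_along(seeds)
  budget <- (1 - target_fraction) * sum(net$edges$length_um)
  retained <- 0
  members <- as.list(seeds)
  growing <- rep(TRUE, n_clusters)
  while (retained < budget && any(growing)) {
    for (k in which(growing)) {
      if (retained >= budget) break
      # unclaimed neighbours of cluster k
      nbrs <- unique(unlist(lapply(members[[k]], function(v)
        vapply(adj[[v]], other_end, numeric(1), edges = net$edges, v = v))))
      nbrs <- nbrs[claimed[nbrs] == 0]
      if (length(nbrs) == 0) { growing[k] <- FALSE; next }
      v <- if (length(nbrs) == 1) nbrs else sample(nbrs, 1)
      claimed[v] <- k
      members[[k]] <- c(members[[k]], v)
      new_edges <- adj[[v]][claimed[vapply(adj[[v]], other_end, numeric(1),
                                           edges = net$edges, v = v)] == k]
      retained <- retained + sum(net$edges$length_um[new_edges])
    }
  }
  same_cluster <- claimed[net$edges$from] != 0 &
    claimed[net$edges$from] == claimed[net$edges$to]
  net$edges$ec_present <- same_cluster
  net
}

#' Close arterial side branches and propagate perfusion loss
#'
#' Marks `n_closed` randomly chosen side branches as closed, recomputes
#' perfusion as graph reachability from the artery root with the closed
#' branch edges removed, and assigns each closed branch a lumen-
#' integrity class with the given proportions (largest-remainder
#' apportionment): `attached` (ICAM2 rendered intact), `disrupted`
#' (>= 2 sub-tolerance ICAM2 gaps near the junction) or `detached`
#' (one supra-tolerance ICAM2 gap at the junction, collagen IV
#' continuous).
#'
#' @param net a `vessel_network`.
#' @param n_closed_side_branches number of branches to close.
#' @param detach_fractions named proportions over
#'   `c("attached", "disrupted", "detached")`, summing to <= 1 (the
#'   remainder stays perfused-classified but closed branches always get
#'   one of the three classes after renormalization).
#' @param rng_seed seed.
#' @return list with `network` and `truth`.
#' @export
apply_perfusion_loss <- function(net, n_closed_side_branches,
                                 detach_fractions = c(attached = 1/3, disrupted = 1/3,
                                                      detached = 1/3),
                                 rng_seed = 1) {
  sb <- net$side_branches
  abort_if(n_closed_side_branches > nrow(sb),
           sprintf("requested %d closures but only %d side branches exist",
                   n_closed_side_branches, nrow(sb)))
  fr <- detach_fractions[c("attached", "disrupted", "detached")]
  fr[is.na(fr)] <- 0
  names(fr) <- c("attached", "disrupted", "detached")
  abort_if(sum(fr) > 1 + 1e-9, "detach_fractions must sum to <= 1")
  if (n_closed_side_branches == 0) {
    return(list(network = net, truth = network_truth(net)))
  }
  fr <- fr / sum(fr)
  withr::with_seed(rng_seed, {
    closed <- sample(nrow(sb), n_closed_side_branches)
    # largest-remainder apportionment of classes
    raw <- fr * n_closed_side_branches
    cnt <- floor(raw)
    rem <- n_closed_side_branches - sum(cnt)
    if (rem > 0) {
      ord <- order(raw - cnt, decreasing = TRUE)
      cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
    }
    classes <- sample(rep(names(fr), times = cnt))
    net$side_branches$state[closed] <- classes
  })
  # perfusion: reachability from root without the closed branch edges
  closed_edges <- sb$edge[closed]
  open_idx <- setdiff(seq_len(nrow(net$edges)), closed_edges)
  g <- network_graph(net, open_idx)
  comp <- igraph::components(g)
  root_comp <- comp$membership[net$root]
  reach <- comp$membership == root_comp
  net$edges$perfused <- reach[net$edges$from] & reach[net$edges$to]
  net$edges$perfused[closed_edges] <- FALSE
  list(network = net, truth = network_truth(net))
}

#' Clear all vessels from a central disc
#'
#' Emulates hyperoxic vaso-obliteration: removes every edge with either
#' endpoint within `radius_um` of the field centre (the empty sleeve is
#' removed too, so the zone is truly avascular).
#'
#' @param net a `vessel_network`.
#' @param radius_um disc radius, micrometres.
#' @return the modified network.
#' @export
apply_vaso_obliteration <- function(net, radius_um) {
  ctr <- rep(net$field_size_um / 2, 2)
  mid <- (net$nodes[net$edges$from, , drop = FALSE] +
          net$nodes[net$edges$to, , drop = FALSE]) / 2
  drop <- (mid[, 1] - ctr[1])^2 + (mid[, 2] - ctr[2])^2 < radius_um^2
  net$edges <- net$edges[!drop, , drop = FALSE]
  # side branch bookkeeping: drop branches whose edge was removed
  if (nrow(net$side_branches)) {
    keep_map <- cumsum(!drop)
    kept <- !drop[net$side_branches$edge]
    sb <- net$side_branches[kept, , drop = FALSE]
    sb$edge <- keep_map[sb$edge]
    net$side_branches <- sb
  }
  net
}
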