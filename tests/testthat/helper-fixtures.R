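# Shared synthetic fixtures, built once per test run.

fixture_net <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_plexus(600, 0.002, n_arteries = 4,
                                                  rng_seed = 101)
    cache
  }
})

fixture_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rg <- apply_regression(fixture_net(), 0.5, mode = "cluster-contraction",
                             n_clusters = 12, rng_seed = 7)
      sim <- render_flatmount(rg$network,
                              extras = list(n_nuclei = 40, n_distractors = 10,
                                            prolif_fraction = 0.2,
                                            n_apoptotic = 12, n_tufts = 4),
                              config = render_config(rng_seed = 3))
      attr(sim, "truth_regression") <- rg$truth
      cache <<- sim
    }
    cache
  }
})

# match planted side branches to measured calls by junction position and
# take-off direction; returns the called state per planted branch
match_planted_calls <- function(calls, sb, nodes, edges, max_d2 = 64) {
  vapply(seq_len(nrow(sb)), function(i) {
    jr <- flatquant:::um_to_px(sb$y[i], 1)
    jc <- flatquant:::um_to_px(sb$x[i], 1)
    far <- nodes[flatquant:::other_end(edges, sb$edge[i], sb$junction_node[i]), ]
    u <- c(far[2] - sb$y[i], far[1] - sb$x[i])  # (drow, dcol)
    u <- u / sqrt(sum(u^2))
    d2 <- (calls$junction_row - jr)^2 + (calls$junction_col - jc)^2
    cand <- which(d2 <= max_d2)
    if (length(cand) == 0) return(NA_character_)
    align <- calls$takeoff_drow[cand] * u[1] + calls$takeoff_dcol[cand] * u[2]
    calls$state[cand[which.max(align)]]
  }, character(1))
}
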