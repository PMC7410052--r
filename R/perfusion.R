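# --- skeleton path tracing -------------------------------------------------

# neighbours of linear index i in an nr x nc matrix, 8-connectivity,
# restricted to foreground; returned sorted for determinism
px_neighbors <- function(i, skel, nr, nc) {
  r <- (i - 1L) %% nr + 1L
  c <- (i - 1L) %/% nr + 1L
  out <- integer(0)
  for (dc in -1:1) for (dr in -1:1) {
    if (dr == 0 && dc == 0) next
    r2 <- r + dr; c2 <- c + dc
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    j <- (c2 - 1L) * nr + r2
    if (skel[j]) out <- c(out, j)
  }
  sort(out)
}

# Trace pixel paths between skeleton nodes (degree != 2 pixels).
# Returns a list of edges: list(ends = c(i, j), path = integer vector of
# linear indices from i to j inclusive).
trace_skeleton_paths <- function(sk) {
  skel <- sk$pixels
  nr <- nrow(skel); nc <- ncol(skel)
  node_px <- which(skel & (sk$degree != 2))
  is_node <- logical(nr * nc)
  is_node[node_px] <- TRUE
  used <- new.env(parent = emptyenv(), size = 4L * length(node_px) + 64L)
  mark <- function(a, b) assign(paste(a, b), TRUE, envir = used)
  seen <- function(a, b) !is.null(used[[paste(a, b)]])
  edges <- list()
  for (p in node_px) {
    for (q in px_neighbors(p, skel, nr, nc)) {
      if (seen(p, q)) next
      path <- c(p, q)
      mark(p, q); mark(q, p)
      prev <- p; cur <- q
      while (!is_node[cur]) {
        nb <- px_neighbors(cur, skel, nr, nc)
        nb <- nb[nb != prev & !vapply(nb, function(x) seen(cur, x), logical(1))]
        if (length(nb) == 0) break
        nxt <- nb[1]
        mark(cur, nxt); mark(nxt, cur)
        path <- c(path, nxt)
        prev <- cur; cur <- nxt
      }
      edges[[length(edges) + 1]] <- list(ends = c(p, cur), path = path)
    }
  }
  edges
}

path_rc <- function(path, nr) cbind(row = (path - 1L) %% nr + 1L,
                                    col = (path - 1L) %/% nr + 1L)

path_steps_um <- function(rc, pixel_size) {
  if (nrow(rc) < 2) return(numeric(0))
  d <- abs(diff(rc))
  ifelse(rowSums(d) == 2, sqrt(2), 1) * pixel_size
}

# --- side-branch detection -------------------------------------------------

#' Detect arterial side branches on a vessel skeleton
#'
#' Traces the skeleton as a graph, identifies the artery as the set of
#' skeleton paths lying inside a corridor around the supplied
#' centerline (snap radius), and returns every non-artery path leaving
#' an artery junction: one candidate side branch per take-off, ordered
#' by position along the artery.
#'
#' @param skeleton a `skeleton_graph` (typically of the collagen IV
#'   mask, which stays continuous through lumen loss).
#' @param artery_centerline 2-column matrix of ordered (row, col)
#'   pixels.
#' @param min_branch_length_um branches shorter than this are dropped.
#' @param snap_radius_px corridor half-width around the centerline.
#' @param corridor_frac fraction of a path's pixels that must fall in
#'   the corridor for it to count as artery rather than branch.
#' @param max_parallel_cos candidates whose initial direction is this
#'   parallel (|cos| above the threshold) to the local centerline
#'   tangent are treated as continuations of the artery (e.g. skeleton
#'   running past the end of the annotated centerline), not branches.
#' @return tibble: branch_id, junction row/col, arc_pos_um, length_um,
#'   and a `path` list-column of (row, col) pixel matrices starting at
#'   the junction.
#' @export
detect_side_branches <- function(skeleton, artery_centerline,
                                 min_branch_length_um = 10,
                                 snap_radius_px = 3, corridor_frac = 0.6,
                                 max_parallel_cos = 0.9) {
  skel <- skeleton$pixels
  nr <- nrow(skel)
  ps <- skeleton$pixel_size
  cl <- as.matrix(artery_centerline)
  corridor <- matrix(FALSE, nr, ncol(skel))
  corridor[cbind(cl[, 1], cl[, 2])] <- TRUE
  corridor <- dilate_px(corridor, snap_radius_px)
  abort_if(!any(skel & corridor),
           "artery centerline does not overlap the skeleton within the snap radius")
  edges <- trace_skeleton_paths(skeleton)
  if (length(edges) == 0) return(empty_branch_table())
  in_corridor <- vapply(edges, function(ed) mean(corridor[ed$path]), numeric(1))
  is_artery <- in_corridor >= corridor_frac
  junctions <- unique(unlist(lapply(edges[is_artery], function(ed) ed$ends)))
  junctions <- junctions[corridor[junctions]]
  # centerline arc length lookup
  cl_steps <- c(0, cumsum(sqrt(rowSums(diff(cl)^2)) * ps))
  out <- list()
  for (k in which(!is_artery)) {
    ed <- edges[[k]]
    at_j <- ed$ends %in% junctions
    if (!any(at_j)) next
    path <- ed$path
    if (!at_j[1]) path <- rev(path)
    rc <- path_rc(path, nr)
    len <- sum(path_steps_um(rc, ps))
    if (len < min_branch_length_um) next
    j_rc <- rc[1, ]
    near <- which.min((cl[, 1] - j_rc[1])^2 + (cl[, 2] - j_rc[2])^2)
    # reject artery continuations: initial direction parallel to the tangent
    tang <- cl[min(near + 3, nrow(cl)), ] - cl[max(near - 3, 1), ]
    take <- rc[min(6, nrow(rc)), ] - rc[1, ]
    denom <- sqrt(sum(tang^2) * sum(take^2))
    if (denom > 0 && abs(sum(tang * take)) / denom > max_parallel_cos) next
    out[[length(out) + 1]] <- tibble(
      junction_row = j_rc[1], junction_col = j_rc[2],
      arc_pos_um = cl_steps[near], length_um = len,
      takeoff_drow = take[1] / sqrt(sum(take^2)),
      takeoff_dcol = take[2] / sqrt(sum(take^2)),
      path = list(rc))
  }
  if (length(out) == 0) return(empty_branch_table())
  br <- dplyr::bind_rows(out)
  br <- br[order(br$arc_pos_um, br$junction_row), ]
  br$branch_id <- seq_len(nrow(br))
  br[, c("branch_id", "junction_row", "junction_col", "arc_pos_um",
         "length_um", "takeoff_drow", "takeoff_dcol", "path")]
}

empty_branch_table <- function() {
  tibble(branch_id = integer(0), junction_row = integer(0),
         junction_col = integer(0), arc_pos_um = numeric(0),
         length_um = numeric(0), takeoff_drow = numeric(0),
         takeoff_dcol = numeric(0), path = list())
}

mask_gaps_along <- function(rc, steps, present) {
  # lengths (um) of maximal runs of absent pixels; trailing/leading runs count
  if (all(present)) return(numeric(0))
  r <- rle(!present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  arc <- c(0, cumsum(steps))
  gaps <- numeric(0)
  for (i in which(r$values)) {
    g <- arc[ends[i]] - arc[starts[i]] + mean(steps)
    gaps <- c(gaps, g)
  }
  gaps
}

#' Classify one side branch by perfusion and lumen integrity
#'
#' Walks the branch path over its first `window_um` from the junction
#' and scores marker continuity: the branch is `perfused` when lectin
#' signal (checked in a 1-px dilated neighbourhood of the path) runs
#' continuously, i.e. with no gap longer than `gap_tolerance_um`, and
#' ICAM2 is continuous too. Non-perfused branches are `attached` when
#' ICAM2 shows no gap at all, `disrupted` for sub-tolerance ICAM2 gaps,
#' `detached` when an ICAM2 gap exceeds tolerance while collagen IV
#' stays continuous; a branch whose collagen IV is itself broken is
#' `unclassifiable`.
#'
#' @param branch one row of [detect_side_branches()] output (or a
#'   (row, col) path matrix).
#' @param lectin_mask,icam_mask,coliv_mask co-registered masks.
#' @param pixel_size micrometres per pixel.
#' @param gap_tolerance_um maximum tolerated signal gap.
#' @param window_um evaluation window from the junction.
#' @return one-row tibble: state, lectin_continuous, max_icam_gap_um,
#'   n_icam_gaps, coliv_continuous.
#' @export
classify_side_branch <- function(branch, lectin_mask, icam_mask, coliv_mask,
                                 pixel_size = 1, gap_tolerance_um = 5,
                                 window_um = 50) {
  rc <- if (is.matrix(branch)) branch else branch$path[[1]]
  lec <- as_logical_matrix(lectin_mask)
  ica <- as_logical_matrix(icam_mask)
  col <- as_logical_matrix(coliv_mask)
  steps <- path_steps_um(rc, pixel_size)
  arc <- c(0, cumsum(steps))
  keep <- arc <= window_um
  rc <- rc[keep, , drop = FALSE]
  steps <- steps[head(which(keep), -1)]
  if (length(steps) == 0) steps <- pixel_size
  nb_present <- function(mask) {
    vapply(seq_len(nrow(rc)), function(i) {
      r <- rc[i, 1]; c <- rc[i, 2]
      rs <- max(1, r - 1):min(nrow(mask), r + 1)
      cs <- max(1, c - 1):min(ncol(mask), c + 1)
      any(mask[rs, cs])
    }, logical(1))
  }
  px_present <- function(mask) mask[rc]
  lec_gaps <- mask_gaps_along(rc, steps, nb_present(lec))
  icam_gaps <- mask_gaps_along(rc, steps, px_present(ica))
  coliv_gaps <- mask_gaps_along(rc, steps, px_present(col))
  lectin_ok <- length(lec_gaps) == 0 || max(lec_gaps) <= gap_tolerance_um
  icam_max <- if (length(icam_gaps)) max(icam_gaps) else 0
  coliv_ok <- length(coliv_gaps) == 0 || max(coliv_gaps) <= gap_tolerance_um
  state <- if (lectin_ok && icam_max <= gap_tolerance_um) "perfused"
  else if (icam_max == 0) "attached"
  else if (icam_max <= gap_tolerance_um) "disrupted"
  else if (coliv_ok) "detached"
  else "unclassifiable"
  tibble(state = state, lectin_continuous = lectin_ok,
         max_icam_gap_um = icam_max, n_icam_gaps = length(icam_gaps),
         coliv_continuous = coliv_ok)
}

#' Classify every detected side branch
#'
#' @param branches output of [detect_side_branches()].
#' @inheritParams classify_side_branch
#' @return the `branches` tibble with the classification columns bound.
#' @export
classify_side_branches <- function(branches, lectin_mask, icam_mask, coliv_mask,
                                   pixel_size = 1, gap_tolerance_um = 5,
                                   window_um = 50) {
  calls <- purrr::map_dfr(seq_len(nrow(branches)), function(i)
    classify_side_branch(branches$path[[i]], lectin_mask, icam_mask, coliv_mask,
                         pixel_size, gap_tolerance_um, window_um))
  dplyr::bind_cols(branches[, setdiff(names(branches), "path")], calls)
}

#' Perfused side-branch density per artery length
#'
#' @param calls classification table with a `state` column.
#' @param artery_centerlines list of (row, col) pixel paths.
#' @param pixel_size micrometres per pixel.
#' @return perfused branches per millimetre of artery.
#' @export
perfused_branch_density <- function(calls, artery_centerlines, pixel_size = 1) {
  abort_if(length(artery_centerlines) == 0, "at least one artery path required")
  total_mm <- sum(vapply(artery_centerlines, function(cl) {
    cl <- as.matrix(cl)
    if (nrow(cl) < 2) return(0)
    sum(sqrt(rowSums(diff(cl)^2))) * pixel_size / 1000
  }, numeric(1)))
  abort_if(total_mm == 0, "zero artery length")
  sum(calls$state == "perfused") / total_mm
}
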