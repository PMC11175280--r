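#' Two-objective Pareto front
#'
#' Returns the indices of the non-dominated points. Point `q` dominates `p`
#' when `q` is at least as good as `p` in both objectives and strictly better
#' in at least one (ties alone never dominate); duplicates of a front point
#' are all retained. Sort-and-scan, O(n log n).
#'
#' @param points n x 2 numeric matrix of objective values, all finite.
#' @param directions length-2 character vector, each `"max"` or `"min"`.
#' @return Sorted integer vector of front row indices.
#' @export
pareto_front_2d <- function(points, directions) {
  pts <- .check_points(points, 2L)
  s <- .canonical_max(pts, directions)
  n <- nrow(s)
  ord <- order(-s[, 1], -s[, 2])
  x <- s[ord, 1]; y <- s[ord, 2]
  keep <- logical(n)
  best_strict <- -Inf  # max y among points with strictly larger x
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[j + 1L] == x[i]) j <- j + 1L
    gy <- y[i:j]                       # same-x group, y descending
    gmax <- gy[1L]
    # survives iff no same-x point has strictly better y and no larger-x
    # point has y at least as good
    keep[i:j] <- (gy == gmax) & (gy > best_strict)
    best_strict <- max(best_strict, gmax)
    i <- j + 1L
  }
  sort(ord[keep])
}

.check_points <- function(points, ncols) {
  pts <- as.matrix(points)
  if (!nrow(pts))
    npl_stop("empty point set", "npl_data_error")
  if (ncol(pts) != ncols)
    npl_stop(sprintf("points must have %d columns", ncols), "npl_data_error")
  if (any(!is.finite(pts)))
    npl_stop("non-finite objective value", "npl_data_error")
  pts
}

# flip "min" objectives so that larger is better in every column
.canonical_max <- function(pts, directions) {
  if (length(directions) != ncol(pts) || !all(directions %in% c("max", "min")))
    npl_stop("directions must be one of 'max'/'min' per objective", "npl_data_error")
  for (a in seq_along(directions))
    if (directions[a] == "min") pts[, a] <- -pts[, a]
  pts
}

# the three soft objectives in fixed order, with their senses
.OBJECTIVES <- data.frame(name = c("S1", "S2", "S3"),
                          direction = c("max", "min", "max"),
                          stringsAsFactors = FALSE)

.objective_pairs <- function() list(c(1L, 2L), c(1L, 3L), c(2L, 3L))

#' Global Pareto screening over all objective pairs
#'
#' The three soft objectives (clearance, maximized; length, minimized; capsule
#' angle, maximized) are combined in pairs; the two-objective Pareto front is
#' computed in each pairwise coordinate system, and the global front is the
#' set intersection of the per-pair fronts. A pair in which either objective
#' is constant over the feasible set carries no trade-off information and is
#' excluded from the intersection (were it kept, its front would collapse to
#' the argmax of the other objective and the intersection would be
#' spuriously empty); if no discriminative pair remains, every feasible
#' candidate is returned. When the intersection of discriminative pairs is
#' empty, the `fallback` flag is set and the weighted-sum top-k is reported
#' alongside the per-pair fronts.
#'
#' @param fs a `feasible_set` with at least one feasible candidate.
#' @param config a [planning_config()] (used only for the fallback ranking).
#' @return An object of class `pareto_result`: `pair_fronts` (per-pair row
#'   indices into [feasible_paths()]), `pairs`, `global` (indices), `fallback`
#'   flag and `fallback_top` (data frame or `NULL`).
#' @export
global_pareto <- function(fs, config = fs$config) {
  df <- feasible_paths(fs)
  if (!nrow(df))
    npl_stop("cannot screen an empty feasible set", "npl_config_error")
  vals <- cbind(df$S1, df$S2, df$S3)
  # an all-Inf clearance column (no risk structures) is constant: treat as such
  vals[!is.finite(vals)] <- max(vals[is.finite(vals)], 0) + 1
  pairs <- .objective_pairs()
  fronts <- vector("list", length(pairs))
  active <- logical(length(pairs))
  for (p in seq_along(pairs)) {
    ab <- pairs[[p]]
    fronts[[p]] <- pareto_front_2d(vals[, ab, drop = FALSE],
                                   .OBJECTIVES$direction[ab])
    active[p] <- all(apply(vals[, ab, drop = FALSE], 2,
                           function(v) max(v) > min(v)))
  }
  names(fronts) <- vapply(pairs, function(ab)
    paste(.OBJECTIVES$name[ab], collapse = "-"), "")
  global <- if (any(active)) Reduce(intersect, fronts[active]) else seq_len(nrow(df))
  fallback <- length(global) == 0L
  fallback_top <- NULL
  if (fallback)
    fallback_top <- rank_paths(fs, config)$top
  structure(list(pair_fronts = fronts, pairs = pairs, global = sort(global),
                 active_pairs = active, fallback = fallback,
                 fallback_top = fallback_top, paths = df),
            class = "pareto_result")
}

#' @export
print.pareto_result <- function(x, ...) {
  sizes <- vapply(x$pair_fronts, length, 0L)
  cat("<pareto_result> per-pair fronts:",
      paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", "), "\n")
  if (x$fallback)
    cat("global intersection empty; weighted-sum fallback reported\n")
  else
    cat(sprintf("global front: %d path(s)\n", length(x$global)))
  invisible(x)
}

#' Dominators of a query point in one objective pair
#'
#' Low-level screening kernel: indices of all points that dominate `query`
#' (at least as good in both objectives, strictly better in at least one).
#'
#' @param points n x 2 matrix of objective values.
#' @param directions length-2 `"max"`/`"min"` vector.
#' @param query length-2 numeric, objective values of the query.
#' @return Integer vector of dominating row indices.
#' @export
dominators_2d <- function(points, directions, query) {
  pts <- .check_points(points, 2L)
  s <- .canonical_max(pts, directions)
  q <- .canonical_max(matrix(as.numeric(query), 1), directions)
  ge <- s[, 1] >= q[1] & s[, 2] >= q[2]
  gt <- s[, 1] > q[1] | s[, 2] > q[2]
  which(ge & gt)
}

#' Interactive screening: which planned paths beat a clinician's entry point?
#'
#' Evaluates the user-chosen entry point (or accepts an already evaluated
#' candidate) and returns every feasible candidate that dominates it in the
#' chosen objective pair, sorted by weighted score, best first. The default
#' pair is (path length, clearance), the standard screening coordinate
#' system. An infeasible user entry still gets screened, with a warning.
#'
#' @param entry world mm entry point, or a one-row candidate from
#'   [evaluate_user_path()].
#' @param fs a `feasible_set`.
#' @param volume the [label_volume()] (needed when `entry` is a point).
#' @param config a [planning_config()].
#' @param pair character pair of objective names among `"S1"`, `"S2"`, `"S3"`.
#' @return Data frame of dominating candidates (possibly empty), with scores.
#' @export
dominators_of <- function(entry, fs, volume = NULL, config = fs$config,
                          pair = c("S2", "S1")) {
  if (inherits(entry, "path_candidate") || is.data.frame(entry)) {
    cand <- entry
  } else {
    if (is.null(volume))
      npl_stop("volume is required to evaluate a raw entry point", "npl_config_error")
    cand <- evaluate_user_path(entry, volume, config)
  }
  if (!isTRUE(cand$feasible))
    npl_warn(sprintf("user entry point is infeasible (%s); screening against it anyway",
                     if (is.na(cand$reason)) "unknown" else cand$reason))
  ia <- match(pair, .OBJECTIVES$name)
  if (any(is.na(ia)) || length(ia) != 2L)
    npl_stop("pair must name two of S1, S2, S3", "npl_config_error")
  ranked <- rank_paths(fs, config, k = n_feasible(fs))$ranking
  pts <- cbind(ranked[[pair[1]]], ranked[[pair[2]]])
  qv <- c(cand[[pair[1]]], cand[[pair[2]]])
  if (any(!is.finite(qv)) || any(!is.finite(pts))) {
    cap <- max(c(pts[is.finite(pts)], qv[is.finite(qv)]), 0) + 1
    pts[!is.finite(pts)] <- cap
    qv[!is.finite(qv)] <- cap
  }
  dom <- dominators_2d(pts, .OBJECTIVES$direction[ia], qv)
  out <- ranked[dom, , drop = FALSE]  # ranked is already Pscore-descending
  rownames(out) <- NULL
  out
}
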