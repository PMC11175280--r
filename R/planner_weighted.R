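#' Normalize soft-constraint values to 0-10 scores
#'
#' Min-max normalization of each raw soft value over the feasible set, scaled
#' to `[0, 10]` and direction-aware so that larger is always better: clearance
#' `S1` and capsule angle `S3` map their maximum to 10, path length `S2` maps
#' its minimum to 10. A criterion that does not discriminate (max equals min,
#' including the all-`Inf` clearance of a plan without risk structures) scores
#' 10 for every candidate, so a globally dominant candidate can reach the
#' ceiling of 10.
#'
#' @param fs a `feasible_set` with at least one feasible candidate.
#' @return The feasible set with `Ps1`, `Ps2`, `Ps3` filled in on feasible rows.
#' @export
normalize_soft_scores <- function(fs) {
  ok <- fs$paths$feasible
  if (!any(ok))
    npl_stop("cannot normalize an empty feasible set", "npl_config_error")
  fs$paths$Ps1[ok] <- .minmax_score(fs$paths$S1[ok], larger_better = TRUE)
  fs$paths$Ps2[ok] <- .minmax_score(fs$paths$S2[ok], larger_better = FALSE)
  fs$paths$Ps3[ok] <- .minmax_score(fs$paths$S3[ok], larger_better = TRUE)
  fs$normalized <- TRUE
  fs
}

.minmax_score <- function(x, larger_better) {
  lo <- min(x); hi <- max(x)
  if (!is.finite(lo) || !is.finite(hi) || hi == lo)
    return(rep(10, length(x)))
  s <- (x - lo) / (hi - lo) * 10
  if (larger_better) s else 10 - s
}

#' Score a user-evaluated path against a feasible set's normalization
#'
#' Applies the feasible set's min-max normalization bounds to the raw soft
#' values of an externally evaluated candidate (clamping to `[0, 10]`, since a
#' user path may fall outside the feasible set's value range) and computes its
#' weighted score, so an interactively chosen entry point can be read on the
#' same 0-10 scale as the automatic recommendation.
#'
#' @param cand one-row candidate from [evaluate_user_path()].
#' @param fs the `feasible_set` providing the normalization population.
#' @param config a [planning_config()].
#' @return `cand` with `Ps1`, `Ps2`, `Ps3` and `Pscore` columns filled
#'   (`NA` when a raw value is undefined, e.g. no capsule crossing).
#' @export
score_user_path <- function(cand, fs, config = fs$config) {
  ok <- fs$paths$feasible
  if (!any(ok))
    npl_stop("feasible set is empty; no normalization population", "npl_config_error")
  clamp <- function(s) pmin(pmax(s, 0), 10)
  rescale <- function(x, pop, larger_better) {
    lo <- min(pop); hi <- max(pop)
    if (!is.finite(lo) || !is.finite(hi) || hi == lo) return(rep(10, length(x)))
    s <- (x - lo) / (hi - lo) * 10
    clamp(if (larger_better) s else 10 - s)
  }
  cand$Ps1 <- rescale(cand$S1, fs$paths$S1[ok], TRUE)
  cand$Ps2 <- rescale(cand$S2, fs$paths$S2[ok], FALSE)
  cand$Ps3 <- if (is.na(cand$S3)) NA_real_ else rescale(cand$S3, fs$paths$S3[ok], TRUE)
  cand$Pscore <- if (anyNA(c(cand$Ps1, cand$Ps2, cand$Ps3))) NA_real_
                 else weighted_score(c(cand$Ps1, cand$Ps2, cand$Ps3), config)
  cand
}

#' Weighted path score
#'
#' The scalarized priority of a candidate: the weighted sum of its three
#' normalized soft scores, `Pscore = Ps1*a1 + Ps2*a2 + Ps3*a3`. With scores in
#' `[0, 10]` and weights summing to 1 the result is in `[0, 10]`; 10 marks the
#' optimal path under the scoring criteria.
#'
#' @param ps numeric triple `(Ps1, Ps2, Ps3)`, or an n x 3 matrix.
#' @param config a [planning_config()] (its `weights` are used), or a numeric
#'   weight triple.
#' @return Score(s).
#' @export
weighted_score <- function(ps, config = planning_config()) {
  w <- if (inherits(config, "planning_config")) config$weights else as.numeric(config)
  if (length(w) != 3L || any(!is.finite(w)) || any(w < 0))
    npl_stop("weights must be three non-negative numbers", "npl_config_error")
  if (abs(sum(w) - 1) > 1e-9) w <- w / sum(w)
  m <- if (is.null(dim(ps))) matrix(ps, ncol = 3) else ps
  as.numeric(m %*% w)
}

#' Rank feasible paths by weighted score
#'
#' Orders the feasible candidates by descending `Pscore` and recommends the
#' top `k` (default 3, so the operator can choose among 2-3 good paths). Ties
#' are broken deterministically: higher `Ps1` (clearance), then lower `S2`
#' (length), then lexicographic entry voxel index.
#'
#' @param fs a `feasible_set`; normalized automatically if needed.
#' @param config a [planning_config()].
#' @param k how many paths to recommend; defaults to `config$top_k`.
#' @return An object of class `ranked_plan` with `ranking` (all feasible
#'   candidates, best first), `top` (first `k`) and `k`.
#' @export
rank_paths <- function(fs, config = fs$config, k = config$top_k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L)
    npl_stop("k must be a positive integer", "npl_config_error")
  if (!isTRUE(fs$normalized)) fs <- normalize_soft_scores(fs)
  df <- feasible_paths(fs)
  df$Pscore <- weighted_score(cbind(df$Ps1, df$Ps2, df$Ps3), config)
  ord <- if (all(c("vi", "vj", "vk") %in% names(df)))
    order(-df$Pscore, -df$Ps1, df$S2, df$vi, df$vj, df$vk)
  else
    order(-df$Pscore, -df$Ps1, df$S2)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(ranking = df, top = head(df, k), k = k,
                 target = fs$target, config = config),
            class = "ranked_plan")
}

#' @export
print.ranked_plan <- function(x, ...) {
  cat(sprintf("<ranked_plan> %d feasible paths, top %d recommended\n",
              nrow(x$ranking), nrow(x$top)))
  cols <- intersect(c("entry_x", "entry_y", "entry_z", "S1", "S2", "S3",
                      "Ps1", "Ps2", "Ps3", "Pscore"), names(x$top))
  print(format(x$top[, cols], digits = 4), ...)
  invisible(x)
}
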