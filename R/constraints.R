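#' Planning configuration
#'
#' Clinical and numerical parameters of the path planner.
#'
#' @param needle_length ablation needle length L in mm; a path is feasible
#'   only if strictly shorter. Default 150 mm (a common long ablation needle;
#'   set it to the actual hardware).
#' @param angle_min clinical lower bound on the liver-capsule insertion angle,
#'   degrees in `[0, 90]`. Default 20.
#' @param weights non-negative soft-constraint weights `(a1, a2, a3)` for
#'   (clearance, length, angle); renormalized to sum 1 when they do not
#'   already (within 1e-9). Defaults to the system defaults `(0.3, 0.4, 0.3)`.
#' @param step segment sampling step in mm; `NULL` means half the minimum
#'   voxel spacing of the volume at hand.
#' @param skin_stride positive integer; every `skin_stride`-th skin voxel (in
#'   the deterministic enumeration order) becomes a candidate.
#' @param risk_roles roles treated as forbidden/risk structures. Liver and
#'   tumor are never risk structures.
#' @param normal_sigma Gaussian scale (mm) for capsule-normal estimation;
#'   `NULL` means twice the maximum voxel spacing.
#' @param top_k how many paths to recommend (default 3).
#' @return An object of class `planning_config`.
#' @export
planning_config <- function(needle_length = 150, angle_min = 20,
                            weights = c(0.3, 0.4, 0.3), step = NULL,
                            skin_stride = 1L,
                            risk_roles = c("vessel", "bone", "lung"),
                            normal_sigma = NULL, top_k = 3L) {
  if (!is.finite(needle_length) || needle_length <= 0)
    npl_stop("needle_length must be positive (mm)", "npl_config_error")
  if (!is.finite(angle_min) || angle_min < 0 || angle_min > 90)
    npl_stop("angle_min must be in [0, 90] degrees", "npl_config_error")
  weights <- as.numeric(weights)
  if (length(weights) != 3L || any(!is.finite(weights)) || any(weights < 0))
    npl_stop("weights must be three non-negative numbers", "npl_config_error")
  if (sum(weights) <= 0)
    npl_stop("at least one weight must be positive", "npl_config_error")
  if (abs(sum(weights) - 1) > 1e-9)
    weights <- weights / sum(weights)
  if (!is.null(step) && (!is.finite(step) || step <= 0))
    npl_stop("step must be positive (mm)", "npl_config_error")
  skin_stride <- as.integer(skin_stride)
  if (is.na(skin_stride) || skin_stride < 1L)
    npl_stop("skin_stride must be a positive integer", "npl_config_error")
  top_k <- as.integer(top_k)
  if (is.na(top_k) || top_k < 1L)
    npl_stop("top_k must be a positive integer", "npl_config_error")
  if (any(c("liver", "tumor") %in% risk_roles))
    npl_stop("liver and tumor cannot be risk roles", "npl_config_error")
  structure(list(needle_length = needle_length, angle_min = angle_min,
                 weights = weights, step = step, skin_stride = skin_stride,
                 risk_roles = as.character(risk_roles),
                 normal_sigma = normal_sigma, top_k = top_k),
            class = "planning_config")
}

#' @export
print.planning_config <- function(x, ...) {
  cat(sprintf("<planning_config> L=%g mm, angle_min=%g deg, weights=(%g, %g, %g), stride=%d, risk roles: %s\n",
              x$needle_length, x$angle_min, x$weights[1], x$weights[2],
              x$weights[3], x$skin_stride,
              if (length(x$risk_roles)) paste(x$risk_roles, collapse = ", ") else "none"))
  invisible(x)
}

.config_step <- function(config, grid)
  if (is.null(config$step)) .default_step(grid) else config$step

.config_sigma <- function(config, grid)
  if (is.null(config$normal_sigma)) 2 * max(grid$spacing) else config$normal_sigma

#' Tumor target point
#'
#' The needle target is the unweighted centroid of the tumor voxel centers in
#' world mm. A tumor mask with several connected components (6-connectivity)
#' still yields the centroid of the union, with a warning.
#'
#' @param volume a [label_volume()] with a non-empty tumor role.
#' @return World mm triple.
#' @export
tumor_target <- function(volume) {
  .require_roles(volume, "tumor")
  mask <- role_mask(volume, "tumor")
  if (!any(mask))
    npl_stop("tumor mask is empty", "npl_config_error")
  if (.count_components(mask) > 1L)
    npl_warn("tumor mask has multiple connected components; using centroid of the union")
  unname(colMeans(.mask_world_coords(mask, volume$grid)))
}

# number of 6-connected components of a mask (masks here are small)
.count_components <- function(mask) {
  sh <- dim(mask)
  comp <- array(0L, dim = sh)
  ncomp <- 0L
  todo <- which(mask)
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (start in todo) {
    if (comp[start] > 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    comp[start] <- ncomp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      ci <- arrayInd(cur, sh)
      nb <- sweep(offs, 2, as.integer(ci), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= sh[1] & nb[, 2] >= 1 & nb[, 2] <= sh[2] &
            nb[, 3] >= 1 & nb[, 3] <= sh[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + sh[1] * (nb[, 2] - 1L) + sh[1] * sh[2] * (nb[, 3] - 1L)
      new <- lin[mask[lin] & comp[lin] == 0L]
      comp[new] <- ncomp
      queue <- c(queue, new)
    }
  }
  ncomp
}

#' Enumerate candidate paths from the skin to the tumor target
#'
#' One candidate per skin voxel (subsampled by `skin_stride`), each a straight
#' segment from the voxel center to [tumor_target()]. Candidates are ordered
#' lexicographically by 0-based voxel index `(i, j, k)`, so enumeration is
#' deterministic; the stride keeps every `skin_stride`-th candidate of that
#' ordering.
#'
#' @param volume a [label_volume()] with non-empty skin, liver and tumor roles.
#' @param config a [planning_config()].
#' @return An object of class `candidate_set`: a data frame of entry voxels
#'   and world coordinates plus the shared target point.
#' @export
enumerate_candidates <- function(volume, config) {
  .require_roles(volume)
  skin <- role_mask(volume, "skin")
  if (!any(skin))
    npl_stop("skin mask is empty", "npl_config_error")
  target <- tumor_target(volume)
  idx <- which(skin, arr.ind = TRUE) - 1L
  ord <- order(idx[, 1], idx[, 2], idx[, 3])
  idx <- idx[ord, , drop = FALSE]
  keep <- seq(1L, nrow(idx), by = config$skin_stride)
  idx <- idx[keep, , drop = FALSE]
  entry <- voxel_to_world(idx, volume$grid)
  paths <- data.frame(vi = idx[, 1], vj = idx[, 2], vk = idx[, 3],
                      entry_x = entry[, 1], entry_y = entry[, 2], entry_z = entry[, 3])
  structure(list(paths = paths, target = as.numeric(target), grid = volume$grid),
            class = "candidate_set")
}

#' Apply the hard constraints
#'
#' Keeps exactly the candidates that (a) touch no risk-structure voxel along
#' the path, (b) are strictly shorter than the needle length, and (c) cross
#' the liver capsule with an insertion angle at or above the threshold (a path
#' that never crosses the capsule is rejected: the needle must traverse liver
#' parenchyma). Each kept candidate carries the raw soft-constraint values:
#' `S1` the minimum world distance (mm) of the path to the union of risk
#' structures (`Inf` when no risk structure is present), `S2` the path length
#' (mm), `S3` the capsule angle (degrees). Each rejected candidate carries its
#' first failed constraint, checked in the order collision, length,
#' no-crossing, angle.
#'
#' An empty feasible set is not an error: the result carries a rejection
#' histogram for diagnosis.
#'
#' @param candidates a [candidate_set][enumerate_candidates()].
#' @param volume the [label_volume()] the candidates came from.
#' @param config a [planning_config()].
#' @return An object of class `feasible_set`; see [feasible_paths()].
#' @export
apply_hard_constraints <- function(candidates, volume, config) {
  grid <- volume$grid
  step <- .config_step(config, grid)
  sigma <- .config_sigma(config, grid)
  liver <- role_mask(volume, "liver")
  risk <- role_mask(volume, config$risk_roles)
  risk_field <- if (any(risk)) distance_transform(risk, grid) else NULL

  df <- candidates$paths
  n <- nrow(df)
  target <- candidates$target
  E <- cbind(df$entry_x, df$entry_y, df$entry_z)
  TT <- matrix(target, n, 3, byrow = TRUE)

  ev <- .evaluate_paths(E, TT, liver, risk, risk_field, grid, step, sigma, config)
  df$S1 <- ev$S1; df$S2 <- ev$S2; df$S3 <- ev$S3
  df$feasible <- ev$feasible
  df$reason <- ev$reason
  df$Ps1 <- df$Ps2 <- df$Ps3 <- df$Pscore <- NA_real_

  rejections <- table(factor(df$reason[!df$feasible],
                             levels = c("collision", "length", "no_crossing", "angle")))
  structure(list(paths = df, target = target, config = config,
                 grid = grid, rejections = as.list(rejections),
                 normalized = FALSE),
            class = "feasible_set")
}

# Shared hard-constraint evaluation for n segments entry -> target.
# Returns S1/S2/S3 (NA where not computed), feasibility and rejection reason.
.evaluate_paths <- function(E, TT, liver, risk, risk_field, grid, step, sigma, config) {
  n <- nrow(E)
  S2 <- sqrt(rowSums((TT - E)^2))
  if (any(S2 <= 0))
    npl_stop("candidate entry coincides with the target", "npl_geometry_error")

  ns <- as.integer(ceiling(S2 / step)) + 1L
  id <- rep.int(seq_len(n), ns)
  frac <- (sequence(ns) - 1) / (ns[id] - 1)
  P <- E[id, , drop = FALSE] + frac * (TT - E)[id, , drop = FALSE]

  # exact voxel traversal: the collision verdict must not depend on sampling
  # density (a grazing path can slip between point samples)
  collide <- rep(FALSE, n)
  if (any(risk))
    collide <- as.logical(.seg_hits_cpp(as.logical(risk), grid$shape,
                                        grid$spacing, grid$origin, E, TT))
  S1 <- rep(Inf, n)
  if (!is.null(risk_field)) {
    vals <- interp_field(risk_field, P)
    S1 <- vapply(split(vals, factor(id, levels = seq_len(n))), min, 0)
  }

  too_long <- S2 >= config$needle_length

  cr <- .capsule_crossing_multi(E, TT, liver, grid, step)
  no_cross <- is.na(cr$frac)

  S3 <- rep(NA_real_, n)
  need_angle <- !no_cross
  if (any(need_angle)) {
    pts <- cr$point[need_angle, , drop = FALSE]
    nrm <- .surface_normal_multi(pts, liver, grid, sigma)
    dir <- (TT - E) / S2
    d <- dir[need_angle, , drop = FALSE]
    cosang <- abs(rowSums(d * nrm))
    S3[need_angle] <- 90 - acos(pmin(pmax(cosang, 0), 1)) * 180 / pi
  }
  angle_bad <- !no_cross & S3 < config$angle_min

  reason <- rep(NA_character_, n)
  reason[angle_bad] <- "angle"
  reason[no_cross] <- "no_crossing"
  reason[too_long] <- "length"
  reason[collide] <- "collision"
  feasible <- is.na(reason)
  list(S1 = S1, S2 = S2, S3 = S3, feasible = feasible, reason = reason)
}

#' Feasible paths of a feasible set
#'
#' @param fs a [apply_hard_constraints()] result.
#' @return Data frame of the candidates satisfying all hard constraints.
#' @export
feasible_paths <- function(fs) fs$paths[fs$paths$feasible, , drop = FALSE]

#' Number of feasible paths
#' @param fs a `feasible_set`.
#' @return Integer count.
#' @export
n_feasible <- function(fs) sum(fs$paths$feasible)

#' @export
print.feasible_set <- function(x, ...) {
  cat(sprintf("<feasible_set> %d/%d candidates feasible\n",
              n_feasible(x), nrow(x$paths)))
  rej <- unlist(x$rejections)
  if (sum(rej) > 0)
    cat("rejections:", paste(sprintf("%s=%d", names(rej), rej), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a feasible set from precomputed soft values
#'
#' Builds a `feasible_set` directly from raw soft-constraint values, for
#' programmatic use (e.g. scoring externally supplied candidates). All rows
#' are taken as feasible.
#'
#' @param paths data frame with at least columns `S1`, `S2`, `S3`; optional
#'   entry coordinates/voxel indices are preserved.
#' @param config a [planning_config()].
#' @param target world mm triple (optional).
#' @return A `feasible_set`.
#' @export
feasible_set <- function(paths, config = planning_config(), target = c(NA, NA, NA)) {
  need <- c("S1", "S2", "S3")
  if (!all(need %in% names(paths)))
    npl_stop("paths must contain columns S1, S2, S3", "npl_config_error")
  df <- as.data.frame(paths)
  if (is.null(df$feasible)) df$feasible <- TRUE
  if (is.null(df$reason)) df$reason <- NA_character_
  for (col in c("Ps1", "Ps2", "Ps3", "Pscore")) if (is.null(df[[col]])) df[[col]] <- NA_real_
  structure(list(paths = df, target = as.numeric(target), config = config,
                 grid = NULL,
                 rejections = list(collision = 0L, length = 0L,
                                   no_crossing = 0L, angle = 0L),
                 normalized = FALSE),
            class = "feasible_set")
}

#' Evaluate a user-specified entry point
#'
#' Builds the segment from `entry` to the tumor centroid, checks every hard
#' constraint and computes the raw soft values that are defined for it. Never
#' raises on an infeasible path; only an entry outside the grid is an error.
#'
#' @param entry world mm point inside the grid.
#' @param volume a [label_volume()].
#' @param config a [planning_config()].
#' @return A one-row data frame shaped like the rows of a `feasible_set`
#'   (class `path_candidate`): entry/target coordinates, `S1`-`S3`,
#'   `feasible`, `reason`.
#' @export
evaluate_user_path <- function(entry, volume, config = planning_config()) {
  grid <- volume$grid
  entry <- as.numeric(entry)
  v <- world_to_voxel(entry, grid)
  if (any(v < -0.5) || any(v > grid$shape - 0.5))
    npl_stop("entry point lies outside the grid", "npl_bounds_error")
  .require_roles(volume)
  target <- tumor_target(volume)
  liver <- role_mask(volume, "liver")
  risk <- role_mask(volume, config$risk_roles)
  risk_field <- if (any(risk)) distance_transform(risk, grid) else NULL
  ev <- .evaluate_paths(matrix(entry, 1), matrix(target, 1), liver, risk,
                        risk_field, grid, .config_step(config, grid),
                        .config_sigma(config, grid), config)
  out <- data.frame(entry_x = entry[1], entry_y = entry[2], entry_z = entry[3],
                    target_x = target[1], target_y = target[2], target_z = target[3],
                    S1 = ev$S1, S2 = ev$S2, S3 = ev$S3,
                    feasible = ev$feasible, reason = ev$reason)
  class(out) <- c("path_candidate", class(out))
  out
}

#' Export a feasible set to CSV or JSON
#'
#' One row/object per candidate with entry and target coordinates, raw soft
#' values, normalized scores (when computed), feasibility and rejection
#' reason.
#'
#' @param fs a `feasible_set`.
#' @param path output file.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_feasible_set <- function(fs, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- fs$paths
  df$target_x <- fs$target[1]; df$target_y <- fs$target[2]; df$target_z <- fs$target[3]
  if (format == "csv") {
    write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", digits = NA, na = "null")
  }
  invisible(path)
}
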