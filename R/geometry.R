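#' Straight needle segment
#'
#' A segment in world coordinates from `p0` (skin entry) to `p1` (intratumoral
#' target), with derived length (mm) and unit direction.
#'
#' @param p0,p1 world mm triples.
#' @return An object of class `segment` with fields `p0`, `p1`, `length`, `dir`.
#' @export
segment <- function(p0, p1) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (length(p0) != 3L || length(p1) != 3L || any(!is.finite(c(p0, p1))))
    npl_stop("segment endpoints must be finite mm triples", "npl_geometry_error")
  len <- sqrt(sum((p1 - p0)^2))
  if (len <= 0)
    npl_stop("zero-length segment", "npl_geometry_error")
  structure(list(p0 = p0, p1 = p1, length = len, dir = (p1 - p0) / len),
            class = "segment")
}

#' Sample points along a segment
#'
#' Returns `ceiling(length/step) + 1` equally spaced points including both
#' endpoints; consecutive samples are at most `step` mm apart.
#'
#' @param seg a [segment()].
#' @param step maximum sample spacing in mm (> 0).
#' @return An n x 3 matrix of world points, ordered from `p0` to `p1`.
#' @export
sample_segment <- function(seg, step) {
  if (!is.finite(step) || step <= 0)
    npl_stop("step must be positive", "npl_geometry_error")
  n <- as.integer(ceiling(seg$length / step)) + 1L
  frac <- seq(0, 1, length.out = n)
  outer(frac, seg$p1 - seg$p0) + matrix(seg$p0, n, 3, byrow = TRUE)
}

# default sampling step: half the smallest voxel size
.default_step <- function(grid) min(grid$spacing) / 2

#' Does a segment pass through a mask?
#'
#' The segment is sampled every `step` mm and each sample is tested against
#' the nearest voxel of the mask. A segment entirely outside the grid is
#' treated as non-intersecting with a warning.
#'
#' @param mask logical 3D array.
#' @param grid the mask's [voxel_grid()].
#' @param seg a [segment()].
#' @param step sample spacing in mm; defaults to half the minimum spacing.
#' @return `TRUE` if any sample lies in a mask voxel.
#' @export
segment_intersects <- function(mask, grid, seg, step = NULL) {
  if (is.null(step)) step <- .default_step(grid)
  pts <- sample_segment(seg, step)
  lin <- .world_to_linear(pts, grid)
  inb <- !is.na(lin)
  if (!any(inb)) {
    npl_warn("segment lies entirely outside the grid; treated as non-intersecting")
    return(FALSE)
  }
  any(mask[lin[inb]])
}

#' World Euclidean distance field to a structure
#'
#' Exact anisotropic Euclidean distance (mm) from every voxel center to the
#' nearest voxel center of the mask, computed by a separable lower-envelope
#' transform. Zero exactly on the structure.
#'
#' @param mask logical 3D array, non-empty.
#' @param grid the mask's [voxel_grid()].
#' @return An object of class `distance_field` with fields `grid`, `values`.
#' @export
distance_transform <- function(mask, grid) {
  if (!any(mask))
    npl_stop(paste("empty mask: no structure to measure distance to;",
                   "treat the distance as +Inf at configuration level"),
             "npl_config_error")
  vals <- .edt_cpp(as.logical(mask), grid$shape, grid$spacing)
  structure(list(grid = grid, values = array(vals, dim = grid$shape)),
            class = "distance_field")
}

#' Trilinear interpolation of a distance field
#'
#' @param field a [distance_transform()] result.
#' @param points world mm point or n x 3 matrix; must lie within the grid
#'   extent (voxel centers padded by half a voxel).
#' @return Interpolated value(s) in mm.
#' @export
interp_field <- function(field, points) {
  pts <- if (is.null(dim(points))) matrix(points, nrow = 1) else points
  g <- field$grid
  cont <- sweep(sweep(pts, 2, g$origin), 2, g$spacing, "/")
  for (a in 1:3) {
    if (any(cont[, a] < -0.5 - 1e-9 | cont[, a] > g$shape[a] - 0.5 + 1e-9))
      npl_stop("point outside grid extent", "npl_bounds_error")
    cont[, a] <- pmin(pmax(cont[, a], 0), g$shape[a] - 1)
  }
  .trilinear(field$values, g$shape, cont)
}

# cont: n x 3 continuous 0-based indices already clamped to [0, shape-1]
.trilinear <- function(values, shape, cont) {
  i0 <- matrix(0, nrow(cont), 3)
  fr <- matrix(0, nrow(cont), 3)
  for (a in 1:3) {
    i0[, a] <- pmin(floor(cont[, a]), max(shape[a] - 2, 0))
    fr[, a] <- cont[, a] - i0[, a]
    if (shape[a] == 1L) { i0[, a] <- 0; fr[, a] <- 0 }
  }
  nx <- shape[1]; nxy <- shape[1] * shape[2]
  base <- i0[, 1] + nx * i0[, 2] + nxy * i0[, 3] + 1
  dx <- as.integer(shape[1] > 1L); dy <- as.integer(shape[2] > 1L)
  dz <- as.integer(shape[3] > 1L)
  v000 <- values[base]
  v100 <- values[base + dx]
  v010 <- values[base + dy * nx]
  v110 <- values[base + dx + dy * nx]
  v001 <- values[base + dz * nxy]
  v101 <- values[base + dx + dz * nxy]
  v011 <- values[base + dy * nx + dz * nxy]
  v111 <- values[base + dx + dy * nx + dz * nxy]
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
  (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
  (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
  (v011 * (1 - fx) + v111 * fx) * fy * fz
}

#' Minimum distance-field value along a segment
#'
#' Realizes the path clearance: the segment is sampled every `step` mm and the
#' minimum trilinearly interpolated field value is returned. This is the
#' quantity used as the distance-to-risk soft constraint.
#'
#' @inheritParams segment_intersects
#' @param field a [distance_transform()] result.
#' @return Minimum clearance in mm (>= 0).
#' @export
min_distance_along_segment <- function(field, seg, step = NULL) {
  if (is.null(step)) step <- .default_step(field$grid)
  pts <- sample_segment(seg, step)
  min(interp_field(field, pts))
}

#' First crossing of the liver capsule
#'
#' Walks the segment from entry to target at `step` mm, finds the first sample
#' inside the liver, and refines the boundary crossing by bisection to within
#' `tol` mm. The boundary is that of the nearest-voxel (rasterized) liver
#' mask. A segment starting inside the liver returns the entry point flagged
#' degenerate; a segment that never enters the liver is an error of class
#' `npl_no_crossing` (such candidates are rejected by the planner).
#'
#' @inheritParams segment_intersects
#' @param liver_mask logical 3D array of the liver.
#' @param tol bisection tolerance in mm.
#' @return List with `point` (world mm) and `degenerate` flag.
#' @export
capsule_crossing <- function(liver_mask, grid, seg, step = NULL, tol = 0.1) {
  if (is.null(step)) step <- .default_step(grid)
  res <- .capsule_crossing_multi(matrix(seg$p0, 1), matrix(seg$p1, 1),
                                 liver_mask, grid, step, tol)
  if (is.na(res$frac[1]))
    npl_stop("segment never enters the liver", "npl_no_crossing")
  list(point = as.numeric(res$point[1, ]), degenerate = res$degenerate[1])
}

# Vectorized capsule crossing for many segments sharing nothing but the grid.
# E: n x 3 entries, TT: n x 3 targets. Returns frac (NA if no crossing),
# point (n x 3) and degenerate flag.
.capsule_crossing_multi <- function(E, TT, liver_mask, grid, step, tol = 0.1) {
  n <- nrow(E)
  len <- sqrt(rowSums((TT - E)^2))
  ns <- as.integer(ceiling(len / step)) + 1L
  id <- rep.int(seq_len(n), ns)
  j <- sequence(ns)
  frac <- (j - 1) / (ns[id] - 1)
  P <- E[id, , drop = FALSE] + frac * (TT - E)[id, , drop = FALSE]
  lin <- .world_to_linear(P, grid)
  inside <- !is.na(lin) & liver_mask[ifelse(is.na(lin), 1, lin)]
  w <- which(inside)
  first <- w[!duplicated(id[w])]                 # first inside sample per segment
  out_frac <- rep(NA_real_, n)
  degen <- rep(FALSE, n)
  hit <- id[first]
  if (length(first)) {
    f_hi <- frac[first]
    is_first_sample <- j[first] == 1L
    degen[hit[is_first_sample]] <- TRUE
    out_frac[hit[is_first_sample]] <- 0
    ref <- !is_first_sample
    if (any(ref)) {
      ridx <- hit[ref]
      lo <- frac[first[ref] - 1L]                # sample before: outside
      hi <- f_hi[ref]
      rl <- len[ridx]
      # refine only unconverged brackets so each candidate's bisection
      # trajectory is independent of the rest of the batch
      repeat {
        act <- which((hi - lo) * rl > tol)
        if (!length(act)) break
        mid <- (lo[act] + hi[act]) / 2
        Pm <- E[ridx[act], , drop = FALSE] +
              mid * (TT - E)[ridx[act], , drop = FALSE]
        lm <- .world_to_linear(Pm, grid)
        ins <- !is.na(lm) & liver_mask[ifelse(is.na(lm), 1, lm)]
        hi[act[ins]] <- mid[ins]
        lo[act[!ins]] <- mid[!ins]
      }
      out_frac[ridx] <- (lo + hi) / 2
    }
  }
  pt <- E + out_frac * (TT - E)
  list(frac = out_frac, point = pt, degenerate = degen, length = len)
}

#' Outward surface normal of a rasterized structure
#'
#' The normal is the normalized gradient of the Gaussian-smoothed (scale
#' `sigma`) mask indicator at `point`, oriented away from the mask interior.
#' Computed locally from mask voxels within 3.5 sigma of the point.
#'
#' @inheritParams segment_intersects
#' @param point world mm point on or near the mask boundary.
#' @param sigma smoothing scale in mm; defaults to twice the maximum spacing.
#' @return Unit 3-vector.
#' @export
surface_normal <- function(mask, grid, point, sigma = NULL) {
  if (is.null(sigma)) sigma <- 2 * max(grid$spacing)
  n <- .surface_normal_multi(matrix(point, 1), mask, grid, sigma)
  as.numeric(n[1, ])
}

.surface_normal_multi <- function(pts, mask, grid, sigma) {
  out <- matrix(NA_real_, nrow(pts), 3)
  sh <- grid$shape
  rad <- 3.5 * sigma
  for (q in seq_len(nrow(pts))) {
    p <- pts[q, ]
    lo <- pmax(floor((p - rad - grid$origin) / grid$spacing), 0)
    hi <- pmin(ceiling((p + rad - grid$origin) / grid$spacing), sh - 1)
    sub <- mask[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1, drop = FALSE]
    vox <- which(sub, arr.ind = TRUE)
    if (!nrow(vox))
      npl_stop("no mask voxels near point; cannot estimate surface normal",
               "npl_geometry_error")
    wpts <- sweep(sweep(vox - 1, 2, lo, "+") *
                    matrix(grid$spacing, nrow(vox), 3, byrow = TRUE),
                  2, grid$origin, "+")
    d <- sweep(wpts, 2, p)                      # v - x, points into the mask
    g <- exp(-rowSums(d^2) / (2 * sigma^2))
    grad <- colSums(d * g)                      # inward gradient direction
    nrm <- sqrt(sum(grad^2))
    if (nrm < 1e-12)
      npl_stop("vanishing smoothed gradient; surface normal is degenerate",
               "npl_geometry_error")
    out[q, ] <- -grad / nrm                     # outward
  }
  out
}

#' Insertion angle at the liver capsule
#'
#' Defined against the tangent plane of the capsule at the crossing point:
#' `90 - angle(path direction, outward capsule normal)` degrees, using the
#' absolute cosine so the normal's sign convention is irrelevant. 90 degrees
#' means perpendicular insertion (safest), 0 means a grazing path.
#'
#' @inheritParams capsule_crossing
#' @param sigma normal-estimation scale in mm (see [surface_normal()]).
#' @return Angle in degrees, in `[0, 90]`.
#' @export
capsule_angle <- function(liver_mask, grid, seg, step = NULL, sigma = NULL) {
  cr <- capsule_crossing(liver_mask, grid, seg, step = step)
  nrm <- surface_normal(liver_mask, grid, cr$point, sigma = sigma)
  .angle_from_normal(seg$dir, nrm)
}

.angle_from_normal <- function(dir, nrm) {
  cosang <- abs(sum(dir * nrm))
  90 - acos(pmin(pmax(cosang, 0), 1)) * 180 / pi
}
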