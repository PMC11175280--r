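# Independent brute-force oracles. These deliberately avoid the package's
# algorithms: domination is checked pairwise in O(n^2), distances by direct
# nearest-voxel search, and collisions by very dense segment sampling.

# canonical "larger is better" transform
oracle_canon <- function(points, directions) {
  pts <- as.matrix(points)
  for (a in seq_along(directions))
    if (directions[a] == "min") pts[, a] <- -pts[, a]
  pts
}

# logical vector: is point i dominated by some other point?
oracle_dominated <- function(points, directions) {
  s <- oracle_canon(points, directions)
  n <- nrow(s)
  out <- logical(n)
  for (i in seq_len(n)) {
    ge <- rep(TRUE, n)
    gt <- rep(FALSE, n)
    for (a in seq_len(ncol(s))) {
      ge <- ge & s[, a] >= s[i, a]
      gt <- gt | s[, a] > s[i, a]
    }
    out[i] <- any(ge & gt)
  }
  out
}

oracle_front <- function(points, directions) which(!oracle_dominated(points, directions))

# indices of points dominating a query value vector
oracle_dominators <- function(points, directions, query) {
  s <- oracle_canon(points, directions)
  q <- as.numeric(oracle_canon(matrix(query, 1), directions))
  ge <- rep(TRUE, nrow(s)); gt <- rep(FALSE, nrow(s))
  for (a in seq_len(ncol(s))) {
    ge <- ge & s[, a] >= q[a]
    gt <- gt | s[, a] > q[a]
  }
  which(ge & gt)
}

# exact distance-to-mask by direct search over mask voxel centers
oracle_edt <- function(mask, grid) {
  all_w <- needleplan::voxel_to_world(which(array(TRUE, dim(mask)), arr.ind = TRUE) - 1L, grid)
  mask_w <- needleplan::voxel_to_world(which(mask, arr.ind = TRUE) - 1L, grid)
  vals <- vapply(seq_len(nrow(all_w)), function(i)
    sqrt(min(colSums((t(mask_w) - all_w[i, ])^2))), 0)
  array(vals, dim = dim(mask))
}

# does the segment p0 -> p1 hit the mask, judged by very dense sampling?
oracle_segment_hits <- function(mask, grid, p0, p1, step) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len / step) + 1L)
  frac <- seq(0, 1, length.out = n)
  pts <- outer(frac, p1 - p0) + matrix(p0, n, 3, byrow = TRUE)
  v <- round(sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/"))
  sh <- grid$shape
  inb <- v[, 1] >= 0 & v[, 1] <= sh[1] - 1 & v[, 2] >= 0 & v[, 2] <= sh[2] - 1 &
         v[, 3] >= 0 & v[, 3] <= sh[3] - 1
  if (!any(inb)) return(FALSE)
  lin <- v[inb, 1] + sh[1] * (v[inb, 2] + sh[2] * v[inb, 3]) + 1
  any(mask[lin])
}

# minimum world distance from densely sampled segment points to mask voxel centers
oracle_segment_clearance <- function(mask, grid, p0, p1, step) {
  len <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, ceiling(len / step) + 1L)
  frac <- seq(0, 1, length.out = n)
  pts <- outer(frac, p1 - p0) + matrix(p0, n, 3, byrow = TRUE)
  mask_w <- needleplan::voxel_to_world(which(mask, arr.ind = TRUE) - 1L, grid)
  min(vapply(seq_len(n), function(i)
    sqrt(min(colSums((t(mask_w) - pts[i, ])^2))), 0))
}

half_diag <- function(grid) sqrt(sum((grid$spacing / 2)^2))
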