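#' Synthetic abdominal phantom configuration
#'
#' Describes an analytic phantom emulating the anatomy the planner assumes: a
#' closed ellipsoidal skin shell, a liver ellipsoid containing a small
#' spherical tumor (default radius 10 mm, honoring the sub-3-cm-diameter
#' regime the planner targets), and obstructing risk structures (sphere, box
#' or cylinder primitives playing vessel/bone/lung roles) between skin and
#' tumor. All geometry is in world mm.
#'
#' The defaults produce a 64^3 volume at 2.5 mm isotropic spacing (160 mm
#' field of view) with one rib-like bone slab partially blocking the +x
#' hemisphere and one intrahepatic vessel near the tumor.
#'
#' @param shape,spacing,origin grid specification (see [voxel_grid()]).
#' @param skin list with `center`, `radii` (outer ellipsoid semi-axes, mm) and
#'   optional `thickness` (shell thickness in mm; default `max(spacing)`).
#' @param liver list with `center` and `radii` (ellipsoid, mm).
#' @param tumor list with `center` and `radius` (sphere, mm).
#' @param obstacles list of primitives, each a list with `role` (one of
#'   vessel/bone/lung/other) and `type` = `"sphere"` (`center`, `radius`),
#'   `"box"` (`lo`, `hi`) or `"cylinder"` (`p0`, `p1`, `radius`).
#' @param seed integer fixing stochastic choices (used by
#'   [random_phantom_config()]; the generator itself is deterministic).
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(64, 64, 64),
                           spacing = c(2.5, 2.5, 2.5),
                           origin = c(0, 0, 0),
                           skin = NULL, liver = NULL, tumor = NULL,
                           obstacles = NULL, seed = 1L) {
  grid <- voxel_grid(shape, spacing, origin)
  ctr <- origin + spacing * (shape - 1) / 2
  if (is.null(skin))
    skin <- list(center = ctr, radii = c(70, 65, 72))
  if (is.null(skin$thickness)) skin$thickness <- max(spacing)
  if (is.null(liver))
    liver <- list(center = ctr + c(12, -8, 6), radii = c(42, 32, 38))
  if (is.null(tumor))
    tumor <- list(center = liver$center + c(6, 4, 5), radius = 10)
  if (is.null(obstacles))
    obstacles <- list(
      list(role = "bone", type = "box",
           lo = ctr + c(59, -31, -24), hi = ctr + c(66, 31, 36)),
      list(role = "vessel", type = "cylinder",
           p0 = ctr + c(-1, -17, -17), p1 = ctr + c(5, 3, 29), radius = 4))
  cfg <- structure(list(grid = grid, skin = skin, liver = liver, tumor = tumor,
                        obstacles = obstacles, seed = as.integer(seed)),
                   class = "phantom_config")
  .validate_phantom_config(cfg)
  cfg
}

# ~uniform unit directions (Fibonacci sphere), deterministic
.fib_directions <- function(n = 400) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

.inside_ellipsoid <- function(pts, center, radii) {
  rowSums(sweep(sweep(pts, 2, center), 2, radii, "/")^2) <= 1
}

.validate_phantom_config <- function(cfg) {
  u <- .fib_directions()
  tum <- sweep(u * cfg$tumor$radius, 2, cfg$tumor$center, "+")
  if (!all(.inside_ellipsoid(tum, cfg$liver$center, cfg$liver$radii)))
    npl_stop("tumor sphere is not fully inside the liver ellipsoid",
             "npl_config_error")
  liv <- sweep(sweep(u, 2, cfg$liver$radii, "*"), 2, cfg$liver$center, "+")
  inner <- pmax(cfg$skin$radii - cfg$skin$thickness, 1e-6)
  if (!all(.inside_ellipsoid(liv, cfg$skin$center, inner)))
    npl_stop("liver ellipsoid is not fully inside the skin shell",
             "npl_config_error")
  g <- cfg$grid
  lo_w <- g$origin - g$spacing / 2
  hi_w <- g$origin + g$spacing * (g$shape - 1) + g$spacing / 2
  bb <- .phantom_bbox(cfg)
  if (any(bb$lo < lo_w) || any(bb$hi > hi_w))
    npl_stop("phantom primitives exceed the grid extent", "npl_config_error")
  invisible(cfg)
}

.phantom_bbox <- function(cfg) {
  lo <- cfg$skin$center - cfg$skin$radii
  hi <- cfg$skin$center + cfg$skin$radii
  for (ob in cfg$obstacles) {
    b <- switch(ob$type,
      sphere = list(lo = ob$center - ob$radius, hi = ob$center + ob$radius),
      box = list(lo = ob$lo, hi = ob$hi),
      cylinder = list(lo = pmin(ob$p0, ob$p1) - ob$radius,
                      hi = pmax(ob$p0, ob$p1) + ob$radius),
      npl_stop(sprintf("unknown obstacle type '%s'", ob$type), "npl_config_error"))
    lo <- pmin(lo, b$lo); hi <- pmax(hi, b$hi)
  }
  list(lo = lo, hi = hi)
}

# fixed label assignment used by generated phantoms
.PHANTOM_LABELS <- c(skin = 1L, liver = 2L, tumor = 3L, vessel = 4L,
                     bone = 5L, lung = 6L, other = 7L)

#' Generate a labeled phantom volume with analytic ground truth
#'
#' Rasterizes the configured primitives onto the voxel grid (a voxel belongs
#' to a primitive when its center does). Later structures take precedence in
#' the order liver, tumor, obstacles, skin shell, so role masks are pairwise
#' disjoint. Deterministic: the same configuration always yields a bitwise
#' identical volume.
#'
#' @param config a [phantom_config()].
#' @return List with `volume` (a [label_volume()]) and `truth`, the analytic
#'   ground truth (tumor centroid in world mm, primitive geometry).
#' @export
generate_phantom <- function(config) {
  .validate_phantom_config(config)
  g <- config$grid
  nx <- g$shape[1]; ny <- g$shape[2]; nz <- g$shape[3]
  x <- g$origin[1] + g$spacing[1] * (seq_len(nx) - 1)
  y <- g$origin[2] + g$spacing[2] * (seq_len(ny) - 1)
  z <- g$origin[3] + g$spacing[3] * (seq_len(nz) - 1)
  X <- array(rep(x, times = ny * nz), dim = g$shape)
  Y <- array(rep(rep(y, each = nx), times = nz), dim = g$shape)
  Z <- array(rep(z, each = nx * ny), dim = g$shape)

  ell <- function(center, radii)
    ((X - center[1]) / radii[1])^2 + ((Y - center[2]) / radii[2])^2 +
    ((Z - center[3]) / radii[3])^2

  labels <- array(0L, dim = g$shape)
  labels[ell(config$liver$center, config$liver$radii) <= 1] <- .PHANTOM_LABELS["liver"]
  labels[ell(config$tumor$center, rep(config$tumor$radius, 3)) <= 1] <- .PHANTOM_LABELS["tumor"]
  for (ob in config$obstacles) {
    lab <- .PHANTOM_LABELS[ob$role]
    if (is.na(lab))
      npl_stop(sprintf("unknown obstacle role '%s'", ob$role), "npl_config_error")
    inside <- switch(ob$type,
      sphere = ell(ob$center, rep(ob$radius, 3)) <= 1,
      box = X >= ob$lo[1] & X <= ob$hi[1] & Y >= ob$lo[2] & Y <= ob$hi[2] &
            Z >= ob$lo[3] & Z <= ob$hi[3],
      cylinder = .in_cylinder(X, Y, Z, ob$p0, ob$p1, ob$radius))
    labels[inside] <- lab
  }
  outer_e <- ell(config$skin$center, config$skin$radii)
  inner_e <- ell(config$skin$center, pmax(config$skin$radii - config$skin$thickness, 1e-6))
  labels[outer_e <= 1 & inner_e > 1 & labels == 0L] <- .PHANTOM_LABELS["skin"]

  present <- unique(as.vector(labels))
  role_map <- lapply(.PHANTOM_LABELS, function(l) if (l %in% present) l else integer(0))
  volume <- label_volume(labels, g, role_map)
  truth <- list(tumor_centroid = config$tumor$center,
                tumor_radius = config$tumor$radius,
                liver = config$liver, skin = config$skin,
                obstacles = config$obstacles, seed = config$seed)
  list(volume = volume, truth = truth)
}

.in_cylinder <- function(X, Y, Z, p0, p1, radius) {
  ax <- p1 - p0
  L <- sqrt(sum(ax^2))
  u <- ax / L
  dx <- X - p0[1]; dy <- Y - p0[2]; dz <- Z - p0[3]
  t <- dx * u[1] + dy * u[2] + dz * u[3]
  rad2 <- dx^2 + dy^2 + dz^2 - t^2
  t >= 0 & t <= L & rad2 <= radius^2
}

#' Randomized phantom configuration
#'
#' Draws a phantom with a randomly displaced tumor inside the liver and a
#' randomly placed spherical bone obstacle between liver and skin, for
#' property-style testing. All draws come from `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param seed integer seed.
#' @param shape,spacing grid specification.
#' @return A [phantom_config()].
#' @export
random_phantom_config <- function(seed, shape = c(64, 64, 64),
                                  spacing = c(2.5, 2.5, 2.5)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  origin <- c(0, 0, 0)
  ctr <- origin + spacing * (shape - 1) / 2
  liver <- list(center = ctr + c(12, -8, 6), radii = c(42, 32, 38))
  off <- runif(3, -8, 8)
  tumor <- list(center = liver$center + off, radius = runif(1, 7, 12))
  dir <- .fib_directions(50)[sample.int(50, 1), ]
  bone_c <- ctr + dir * runif(1, 55, 62)
  obstacles <- list(
    list(role = "bone", type = "sphere", center = bone_c, radius = runif(1, 8, 14)),
    list(role = "vessel", type = "cylinder",
         p0 = ctr + c(-1, -17, -17), p1 = ctr + c(5, 3, 29), radius = 4))
  phantom_config(shape = shape, spacing = spacing, origin = origin,
                 liver = liver, tumor = tumor, obstacles = obstacles, seed = seed)
}

#' Two-objective demonstration point set for Pareto screening
#'
#' A constructed trade-off set over (clearance from risk structures, to be
#' maximized; path length, to be minimized) whose combinatorial structure
#' matches the interactive-screening scenario the planner implements: exactly
#' six points are mutually non-dominated (the Pareto front) and exactly three
#' points dominate the designated query point `P`. Coordinates are synthetic.
#'
#' @return List with `points` (n x 2 matrix, columns `clearance` and
#'   `length`), `directions` (`c("max", "min")`) and `p_index`, the row of the
#'   designated query point.
#' @export
pareto_demo_pointset <- function() {
  pts <- rbind(
    c(10, 40), c(20, 50), c(30, 60), c(40, 70), c(50, 80), c(60, 90),  # front
    c(35, 72),                                    # dominates P, off the front
    c(25, 75),                                    # P
    c(15, 85), c(45, 95), c(55, 95))              # dominated fillers
  colnames(pts) <- c("clearance", "length")
  list(points = pts, directions = c("max", "min"), p_index = 8L)
}
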