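#' Voxel grid geometry
#'
#' A `voxel_grid` fixes the mapping between 0-based voxel indices and world
#' coordinates: the center of voxel `(i, j, k)` lies at
#' `origin + spacing * c(i, j, k)` (componentwise, in mm).
#'
#' @param shape integer triple `(nx, ny, nz)`, all >= 1.
#' @param spacing positive mm triple, voxel size per axis.
#' @param origin world mm triple, center of voxel `(0, 0, 0)`.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(4, 4, 4), spacing = c(2, 2, 2), origin = c(10, 20, 30))
#' voxel_to_world(c(0, 0, 0), g)
#' @export
voxel_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    npl_stop("shape must be three integers >= 1", "npl_config_error")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    npl_stop("spacing must be three positive numbers (mm)", "npl_config_error")
  if (length(origin) != 3L || any(!is.finite(origin)))
    npl_stop("origin must be three finite numbers (mm)", "npl_config_error")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Convert voxel indices to world coordinates
#'
#' @param index 0-based integer triple, or an n x 3 matrix of triples.
#' @param grid a [voxel_grid()].
#' @return World mm point(s), same shape as `index`.
#' @export
voxel_to_world <- function(index, grid) {
  m <- !is.null(dim(index))
  idx <- if (m) index else matrix(index, nrow = 1)
  if (ncol(idx) != 3L)
    npl_stop("index must have three components", "npl_config_error")
  if (any(idx < 0) || any(sweep(idx, 2, grid$shape - 1L) > 0))
    npl_stop("voxel index out of bounds", "npl_bounds_error")
  w <- sweep(sweep(idx, 2, grid$spacing, "*"), 2, grid$origin, "+")
  if (m) w else as.numeric(w)
}

#' Convert world coordinates to (continuous) voxel indices
#'
#' Returns continuous 0-based indices; round to get the nearest voxel. Exact
#' inverse of [voxel_to_world()] on voxel centers.
#'
#' @param point world mm triple, or an n x 3 matrix.
#' @param grid a [voxel_grid()].
#' @return Continuous index triple(s).
#' @export
world_to_voxel <- function(point, grid) {
  m <- !is.null(dim(point))
  p <- if (m) point else matrix(point, nrow = 1)
  v <- sweep(sweep(p, 2, grid$origin), 2, grid$spacing, "/")
  if (m) v else as.numeric(v)
}

# nearest-voxel 1-based linear indices, NA when outside the grid
.world_to_linear <- function(pts, grid) {
  v <- round(sweep(sweep(pts, 2, grid$origin), 2, grid$spacing, "/"))
  sh <- grid$shape
  inb <- v[, 1] >= 0 & v[, 1] <= sh[1] - 1 &
         v[, 2] >= 0 & v[, 2] <= sh[2] - 1 &
         v[, 3] >= 0 & v[, 3] <= sh[3] - 1
  lin <- rep(NA_real_, nrow(pts))
  lin[inb] <- v[inb, 1] + sh[1] * (v[inb, 2] + sh[2] * v[inb, 3]) + 1
  lin
}

#' Labeled volume
#'
#' Bundles an integer label array with its grid geometry and a `role_map`
#' assigning semantic roles (skin, liver, tumor, vessel, bone, lung, ...) to
#' one or more integer labels. Planning is driven by roles, never by raw
#' label values, so multiple labels (e.g. hepatic and portal vessels) may
#' share a role. Label 0 is background.
#'
#' @param labels 3D non-negative integer array.
#' @param grid a [voxel_grid()] whose shape matches `dim(labels)`.
#' @param role_map named list mapping role names to integer label vectors; an
#'   empty vector marks a role as explicitly absent.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, grid, role_map) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    npl_stop("labels must be a 3D array", "npl_type_error")
  if (is.double(labels)) {
    if (any(labels != round(labels)))
      npl_stop("labels must be integer-valued", "npl_type_error")
    storage.mode(labels) <- "integer"
  }
  if (!is.integer(labels))
    npl_stop("labels must be an integer array", "npl_type_error")
  if (any(labels < 0L))
    npl_stop("labels must be non-negative", "npl_type_error")
  if (!identical(dim(labels), grid$shape))
    npl_stop("dim(labels) does not match grid shape", "npl_config_error")
  if (is.null(names(role_map)) || any(!nzchar(names(role_map))))
    npl_stop("role_map must be a named list", "npl_config_error")
  role_map <- lapply(role_map, as.integer)
  present <- sort(unique(as.vector(labels)))
  for (role in names(role_map)) {
    miss <- setdiff(role_map[[role]], present)
    if (length(miss))
      npl_stop(sprintf("role '%s' maps to label(s) %s absent from the volume",
                       role, paste(miss, collapse = ", ")),
               "npl_config_error")
  }
  structure(list(grid = grid, labels = labels, role_map = role_map),
            class = "label_volume")
}

#' Binary mask for a semantic role
#'
#' @param volume a [label_volume()].
#' @param role role name(s); the mask is the union over all listed roles.
#' @return Logical 3D array; all-`FALSE` for an explicitly empty role.
#' @export
role_mask <- function(volume, role) {
  unknown <- setdiff(role, names(volume$role_map))
  if (length(unknown))
    npl_stop(sprintf("unknown role(s): %s", paste(unknown, collapse = ", ")),
             "npl_config_error")
  labs <- unique(unlist(volume$role_map[role], use.names = FALSE))
  if (!length(labs))
    return(array(FALSE, dim = volume$grid$shape))
  array(volume$labels %in% labs, dim = volume$grid$shape)
}

# roles that must be non-empty before planning can run
.require_roles <- function(volume, roles = c("skin", "liver", "tumor")) {
  for (r in roles) {
    if (!r %in% names(volume$role_map) || !length(volume$role_map[[r]]))
      npl_stop(sprintf("role '%s' is required for planning but empty", r),
               "npl_config_error")
  }
  invisible(TRUE)
}

#' @export
print.label_volume <- function(x, ...) {
  print(x$grid)
  counts <- vapply(names(x$role_map), function(r) sum(role_mask(x, r)), 0)
  cat("roles:", paste(sprintf("%s=%d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

# world coordinates (n x 3) of all TRUE voxels in a mask
.mask_world_coords <- function(mask, grid) {
  idx <- which(mask, arr.ind = TRUE) - 1L
  sweep(sweep(idx, 2, grid$spacing, "*"), 2, grid$origin, "+")
}
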