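# Small hand-built label volumes used across tests.

STD_ROLES <- list(skin = 1L, liver = 2L, tumor = 3L, vessel = 4L,
                  bone = 5L, lung = 6L, other = 7L)

# role map restricted to labels actually present
roles_present <- function(labels) {
  present <- unique(as.vector(labels))
  lapply(STD_ROLES, function(l) if (l %in% present) l else integer(0))
}

make_volume <- function(labels, grid) {
  label_volume(labels, grid, roles_present(labels))
}

# logical mask from world-coordinate predicate f(X, Y, Z)
grid_mask <- function(grid, f) {
  sh <- grid$shape
  x <- grid$origin[1] + grid$spacing[1] * (seq_len(sh[1]) - 1)
  y <- grid$origin[2] + grid$spacing[2] * (seq_len(sh[2]) - 1)
  z <- grid$origin[3] + grid$spacing[3] * (seq_len(sh[3]) - 1)
  X <- array(rep(x, times = sh[2] * sh[3]), dim = sh)
  Y <- array(rep(rep(y, each = sh[1]), times = sh[3]), dim = sh)
  Z <- array(rep(z, each = sh[1] * sh[2]), dim = sh)
  f(X, Y, Z)
}

# default study phantom shared by several tests (deterministic)
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(phantom_config())
    cache
  }
})

# add an encircling bone shell around the tumor with a conical aperture along
# `axis`; radii in mm from the tumor centroid
with_bone_shell <- function(ph, r_in = 40, r_out = 46, axis = c(0, 0, 1),
                            half_angle_deg = NULL) {
  vol <- ph$volume
  ctr <- ph$truth$tumor_centroid
  u <- axis / sqrt(sum(axis^2))
  shell <- grid_mask(vol$grid, function(X, Y, Z) {
    dx <- X - ctr[1]; dy <- Y - ctr[2]; dz <- Z - ctr[3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    inside <- r >= r_in & r <= r_out
    if (!is.null(half_angle_deg)) {
      cosang <- (dx * u[1] + dy * u[2] + dz * u[3]) / pmax(r, 1e-9)
      inside <- inside & cosang < cos(half_angle_deg * pi / 180)
    }
    inside
  })
  labels <- vol$labels
  labels[shell & labels != STD_ROLES$skin] <- STD_ROLES$bone
  make_volume(labels, vol$grid)
}

# random small label volume for I/O round trips
random_label_volume <- function(seed, shape = c(5, 4, 6),
                                spacing = c(0.7, 0.7, 2.5),
                                origin = c(-3.5, 10, 2.25)) {
  set.seed(seed)
  labels <- array(sample(0:3, prod(shape), replace = TRUE), dim = shape)
  labels[1, 1, 1] <- 1L; labels[2, 1, 1] <- 2L; labels[3, 1, 1] <- 3L
  label_volume(labels, voxel_grid(shape, spacing, origin),
               list(skin = 1L, liver = 2L, tumor = 3L, vessel = integer(0)))
}
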