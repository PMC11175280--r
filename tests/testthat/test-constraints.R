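test_that("the tumor target is the world centroid of the tumor mask", {
  ph <- default_phantom()
  ctr <- tumor_target(ph$volume)
  expect_lt(sqrt(sum((ctr - ph$truth$tumor_centroid)^2)),
            0.5 * max(ph$volume$grid$spacing))

  # single tumor voxel: its own center
  g <- voxel_grid(c(8, 8, 8), c(2, 2, 2), c(1, 1, 1))
  labels <- array(0L, dim = g$shape)
  labels[1, , ] <- 1L          # skin plate so required roles exist
  labels[5, 5, 5] <- 2L
  labels[5, 5, 6] <- 3L
  vol <- make_volume(labels, g)
  expect_equal(tumor_target(vol), voxel_to_world(c(4, 4, 5), g))

  # two disjoint components: centroid of the union, with a warning
  labels[5, 5, 6] <- 2L
  labels[3, 3, 3] <- 3L
  labels[7, 7, 7] <- 3L
  vol2 <- make_volume(labels, g)
  expect_warning(ctr2 <- tumor_target(vol2), class = "npl_warning")
  expect_equal(ctr2, colMeans(rbind(voxel_to_world(c(2, 2, 2), g),
                                    voxel_to_world(c(6, 6, 6), g))))
})

test_that("candidate enumeration is deterministic and stride-decimated", {
  ph <- default_phantom()
  cfg1 <- planning_config(skin_stride = 1)
  cands <- enumerate_candidates(ph$volume, cfg1)
  n_skin <- sum(role_mask(ph$volume, "skin"))
  expect_identical(nrow(cands$paths), n_skin)

  # independent recount of the stride decimation
  for (stride in c(2, 5, 9)) {
    cs <- enumerate_candidates(ph$volume, planning_config(skin_stride = stride))
    expect_identical(nrow(cs$paths), length(seq(1, n_skin, by = stride)))
    # stride-k candidates are a prefix-decimation of the stride-1 ordering
    expect_identical(cs$paths$vi, cands$paths$vi[seq(1, n_skin, by = stride)])
  }

  again <- enumerate_candidates(ph$volume, cfg1)
  expect_identical(cands$paths, again$paths)

  # lexicographic ordering by voxel index
  o <- order(cands$paths$vi, cands$paths$vj, cands$paths$vk)
  expect_identical(o, seq_len(n_skin))
})

test_that("hard constraints keep exactly the clinically admissible paths", {
  ph <- default_phantom()
  cfg <- planning_config(skin_stride = 9)
  cands <- enumerate_candidates(ph$volume, cfg)
  fs <- apply_hard_constraints(cands, ph$volume, cfg)
  fp <- feasible_paths(fs)
  expect_gt(nrow(fp), 0)
  expect_true(all(fp$S2 < cfg$needle_length))
  expect_true(all(fp$S3 >= cfg$angle_min))
  expect_true(all(fp$S1 > 0))

  # re-check a sample of feasible paths against the dense-sampling oracle
  risk <- role_mask(ph$volume, c("vessel", "bone", "lung"))
  target <- fs$target
  pick <- seq(1, nrow(fp), by = 17)
  for (i in pick) {
    p0 <- c(fp$entry_x[i], fp$entry_y[i], fp$entry_z[i])
    expect_false(oracle_segment_hits(risk, ph$volume$grid, p0, target, step = 0.125))
  }

  # rejected-for-collision candidates really do hit (or at worst graze) a
  # risk structure: dense sampling finds the hit, or the path passes within
  # half a voxel diagonal of a risk voxel center
  rej <- fs$paths[!fs$paths$feasible & fs$paths$reason == "collision", ]
  for (i in seq(1, nrow(rej), by = 23)) {
    p0 <- c(rej$entry_x[i], rej$entry_y[i], rej$entry_z[i])
    hit <- oracle_segment_hits(risk, ph$volume$grid, p0, target, step = 0.2)
    graze <- oracle_segment_clearance(risk, ph$volume$grid, p0, target,
                                      step = 0.2) <= half_diag(ph$volume$grid)
    expect_true(hit || graze)
  }
})

test_that("an unreachable tumor yields an empty feasible set with diagnostics", {
  ph <- default_phantom()
  cfg <- planning_config(needle_length = 30, skin_stride = 15)  # below skin-tumor distance
  cands <- enumerate_candidates(ph$volume, cfg)
  fs <- apply_hard_constraints(cands, ph$volume, cfg)
  expect_identical(n_feasible(fs), 0L)
  non_coll <- fs$paths$reason[fs$paths$reason != "collision"]
  expect_true(all(non_coll == "length"))
  expect_identical(sum(unlist(fs$rejections)), nrow(fs$paths))
})

test_that("relaxing all constraints keeps every capsule-crossing candidate", {
  ph <- default_phantom()
  cfg <- planning_config(angle_min = 0, risk_roles = character(0), skin_stride = 15)
  cands <- enumerate_candidates(ph$volume, cfg)
  fs <- apply_hard_constraints(cands, ph$volume, cfg)
  expect_true(all(fs$paths$reason[!fs$paths$feasible] == "no_crossing"))
  expect_true(all(is.infinite(feasible_paths(fs)$S1)))
})

test_that("an encircling bone shell restricts entries to the aperture cone", {
  ph <- default_phantom()
  half_angle <- 35
  vol <- with_bone_shell(ph, axis = c(0, 0, 1), half_angle_deg = half_angle)
  cfg <- planning_config(skin_stride = 7)
  fs <- apply_hard_constraints(enumerate_candidates(vol, cfg), vol, cfg)
  fp <- feasible_paths(fs)
  expect_gt(nrow(fp), 0)
  ctr <- ph$truth$tumor_centroid
  # every feasible entry direction lies inside the aperture cone (plus slack
  # for the voxelized shell rim)
  dirs <- sweep(cbind(fp$entry_x, fp$entry_y, fp$entry_z), 2, ctr)
  cosang <- dirs[, 3] / sqrt(rowSums(dirs^2))
  expect_true(all(cosang > cos((half_angle + 6) * pi / 180)))
  # and paths from well outside the cone are rejected by the oracle too
  bone <- role_mask(vol, "bone")
  out_cone <- fs$paths[!fs$paths$feasible, ]
  dirs_r <- sweep(cbind(out_cone$entry_x, out_cone$entry_y, out_cone$entry_z), 2, ctr)
  cos_r <- dirs_r[, 3] / sqrt(rowSums(dirs_r^2))
  deep <- which(cos_r < cos((half_angle + 25) * pi / 180))
  expect_gt(length(deep), 0)
  for (i in deep[seq(1, length(deep), by = 37)]) {
    p0 <- c(out_cone$entry_x[i], out_cone$entry_y[i], out_cone$entry_z[i])
    expect_true(oracle_segment_hits(bone, vol$grid, p0, fs$target, step = 0.3))
  }
})

test_that("feasibility is monotone in needle length and angle threshold", {
  ph <- default_phantom()
  base <- planning_config(skin_stride = 11)
  cands <- enumerate_candidates(ph$volume, base)
  feas_ids <- function(cfg) {
    fs <- apply_hard_constraints(cands, ph$volume, cfg)
    which(fs$paths$feasible)
  }
  for (Ls in list(c(150, 100), c(100, 80))) {
    a <- feas_ids(planning_config(needle_length = Ls[1], skin_stride = 11))
    b <- feas_ids(planning_config(needle_length = Ls[2], skin_stride = 11))
    expect_true(all(b %in% a))
  }
  for (angs in list(c(10, 30), c(30, 60))) {
    a <- feas_ids(planning_config(angle_min = angs[1], skin_stride = 11))
    b <- feas_ids(planning_config(angle_min = angs[2], skin_stride = 11))
    expect_true(all(b %in% a))
  }
})

test_that("user-path evaluation is consistent with batch planning", {
  ph <- default_phantom()
  cfg <- planning_config(skin_stride = 9)
  fs <- apply_hard_constraints(enumerate_candidates(ph$volume, cfg), ph$volume, cfg)
  fp <- feasible_paths(fs)
  i <- ceiling(nrow(fp) / 2)
  cand <- evaluate_user_path(c(fp$entry_x[i], fp$entry_y[i], fp$entry_z[i]),
                             ph$volume, cfg)
  expect_true(cand$feasible)
  expect_identical(cand$S1, fp$S1[i])
  expect_identical(cand$S2, fp$S2[i])
  expect_identical(cand$S3, fp$S3[i])

  # a path through the bone slab is infeasible with reason collision
  rej <- fs$paths[!fs$paths$feasible & fs$paths$reason == "collision", ][1, ]
  c2 <- evaluate_user_path(c(rej$entry_x, rej$entry_y, rej$entry_z), ph$volume, cfg)
  expect_false(c2$feasible)
  expect_identical(c2$reason, "collision")

  # too-short needle: reason length
  c3 <- evaluate_user_path(c(fp$entry_x[1], fp$entry_y[1], fp$entry_z[1]), ph$volume,
                           planning_config(needle_length = 10))
  expect_identical(c3$reason, "length")

  expect_error(evaluate_user_path(c(-500, 0, 0), ph$volume, cfg),
               class = "npl_bounds_error")
})

test_that("feasible paths withstand re-checking at ten-fold finer sampling", {
  ph <- default_phantom()
  cfg <- planning_config(skin_stride = 19)
  fs <- apply_hard_constraints(enumerate_candidates(ph$volume, cfg), ph$volume, cfg)
  fp <- feasible_paths(fs)
  fine <- planning_config(step = (min(ph$volume$grid$spacing) / 2) / 10,
                          skin_stride = 19)
  risk <- role_mask(ph$volume, cfg$risk_roles)
  liver <- role_mask(ph$volume, "liver")
  g <- ph$volume$grid
  for (i in seq_len(nrow(fp))) {
    seg <- segment(c(fp$entry_x[i], fp$entry_y[i], fp$entry_z[i]), fs$target)
    expect_false(segment_intersects(risk, g, seg, step = fine$step))
    expect_lt(seg$length, cfg$needle_length)
    expect_gte(capsule_angle(liver, g, seg, step = fine$step), cfg$angle_min)
  }
})
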