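test_that("phantom generation is deterministic per seed", {
  a <- make_phantom(phantom_spec(seed = 7))
  b <- make_phantom(phantom_spec(seed = 7))
  expect_identical(a$planned$vertices, b$planned$vertices)
  expect_identical(unclass(a$t_true), unclass(b$t_true))
  expect_identical(a$holes_reduced, b$holes_reduced)
  c <- make_phantom(phantom_spec(seed = 8))
  expect_false(isTRUE(all.equal(unclass(a$t_true), unclass(c$t_true))))
})

test_that("phantom structure matches the surgical setting", {
  ph <- make_phantom(phantom_spec(seed = 7))
  expect_gte(nrow(mesh_region_vertices(ph$planned, "zygoma")), 200)
  expect_length(ph$planned$face_labels, nrow(ph$planned$faces))
  expect_setequal(unique(ph$planned$face_labels), c("fixed", "zygoma"))
  expect_identical(nrow(ph$landmarks), 3L)     # nasion + two suture points
  expect_identical(nrow(ph$marks), 3L)         # three surface marks
  expect_identical(nrow(ph$holes_reduced), 12L) # three plates x four screws
})

test_that("dislocation moves exactly the zygoma region by the ground truth", {
  ph <- make_phantom(phantom_spec(seed = 7))
  fx_p <- mesh_region_vertices(ph$planned, "fixed")
  fx_d <- mesh_region_vertices(ph$dislocated, "fixed")
  expect_identical(fx_p, fx_d)
  zy_p <- mesh_region_vertices(ph$planned, "zygoma")
  zy_d <- mesh_region_vertices(ph$dislocated, "zygoma")
  expect_equal(rt_apply(ph$t_true, zy_d), zy_p, tolerance = 1e-9)
  # the two regions share no vertices (the fracture gap separates them)
  expect_identical(nrow(fx_p) + nrow(zy_p), nrow(ph$planned$vertices))
})

test_that("a zero dislocation leaves the phantom unchanged", {
  ph <- make_phantom(phantom_spec(seed = 3, rot_max_deg = 0, trans_max_mm = 0))
  expect_equal(ph$dislocated$vertices, ph$planned$vertices, tolerance = 1e-12)
  expect_equal(unclass(ph$t_true), diag(4), tolerance = 1e-12)
})

test_that("dislocation magnitude respects the configured bounds", {
  for (seed in 1:10) {
    ph <- small_phantom(seed = seed, rot_max_deg = 15, trans_max_mm = 10)
    expect_lte(sqrt(sum(ph$t_true[1:3, 4]^2)), 10)
    gap <- transform_gap(ph$t_true, rt_identity())
    expect_lte(gap["rot_deg"], 15)
  }
})

test_that("degenerate phantom specs are rejected", {
  expect_error(phantom_spec(patch_deg = 0))
  expect_error(make_phantom(phantom_spec(patch_deg = 0.5)), "no faces|no area")
})

test_that("simulated probes hit the FNRPs when the fragment is reduced", {
  ph <- small_phantom(seed = 10)
  plan <- reduction_fit(mesh_region_vertices(ph$dislocated, "zygoma"),
                        mesh_region_vertices(ph$planned, "zygoma"),
                        init = list(source = ph$marks, target = ph$marks_reduced))
  fn <- generate_fnrps(plan, ph$marks)
  reduced <- simulate_probe_readings(fn, current_pose = plan$transform, sd = 0)
  expect_lt(max(reduced$distance), 1e-9)
  # unreduced fragment: distances equal the mark-to-FNRP gaps
  unred <- simulate_probe_readings(fn, current_pose = rt_identity(), sd = 0)
  gaps <- sqrt(rowSums((as.matrix(fn[, c("xd", "yd", "zd")]) -
                          as.matrix(fn[, c("xr", "yr", "zr")]))^2))
  expect_equal(unred$distance, unname(gaps), tolerance = 1e-9)
  # depth bias shifts every probe by the same vector
  biased <- simulate_probe_readings(fn, current_pose = plan$transform, sd = 0,
                                    depth_bias = c(0, 0, 0.4))
  expect_equal(biased$distance, rep(0.4, 3), tolerance = 1e-9)
})

test_that("probe noise follows the Maxwell closed form", {
  marks <- random_points(1000, seed = 30)
  rownames(marks) <- sprintf("m%d", 1:1000)
  fn <- data.frame(name = rownames(marks), xd = marks[, 1], yd = marks[, 2],
                   zd = marks[, 3], xr = marks[, 1], yr = marks[, 2],
                   zr = marks[, 3])
  class(fn) <- c("fnrp_set", "data.frame")
  r <- simulate_probe_readings(fn, current_pose = rt_identity(), sd = 0.3,
                               seed = 5)
  expect_equal(mean(r$distance), maxwell_mean(0.3), tolerance = 0.05)
})

test_that("drilling simulation is exact at zero noise and seed-reproducible", {
  holes <- random_points(12, seed = 2)
  expect_equal(simulate_drilling(holes, sd = 0), holes)
  expect_identical(simulate_drilling(holes, sd = 0.5, seed = 9),
                   simulate_drilling(holes, sd = 0.5, seed = 9))
  expect_false(isTRUE(all.equal(simulate_drilling(holes, sd = 0.5, seed = 9),
                                simulate_drilling(holes, sd = 0.5, seed = 10))))
})

test_that("end-to-end: plan, FNRPs, probes, pose recovery", {
  ph <- small_phantom(seed = 20)
  plan <- reduction_fit(mesh_region_vertices(ph$dislocated, "zygoma"),
                        mesh_region_vertices(ph$planned, "zygoma"),
                        init = list(source = ph$marks, target = ph$marks_reduced))
  fn <- generate_fnrps(plan, ph$marks)
  # noiseless probes of the reduced fragment recover the ground truth pose
  probed <- simulate_probe_readings(fn, current_pose = ph$t_true, sd = 0)
  est <- pose_from_probes(fn, as.matrix(probed[, c("x", "y", "z")]))
  expect_lt(max(transform_gap(est$transform, ph$t_true)), 1e-6)
  # noisy probes: the fragment-centre translation error stays sub-half-mm in
  # the median across seeds
  ctr <- geometric_center(mesh_region_vertices(ph$dislocated, "zygoma"))
  errs <- vapply(1:25, function(s) {
    pr <- simulate_probe_readings(fn, current_pose = ph$t_true, sd = 0.3,
                                  seed = s)
    est <- pose_from_probes(fn, as.matrix(pr[, c("x", "y", "z")]))
    pose_error_at(est$transform, ph$t_true, ctr)
  }, numeric(1))
  expect_lt(median(errs), 0.5)
})

test_that("phantom randomness does not leak into the caller's RNG stream", {
  withr::with_seed(123, {
    before <- stats::runif(1)
  })
  withr::with_seed(123, {
    invisible(small_phantom(seed = 50))
    invisible(simulate_drilling(random_points(5, seed = 1), sd = 1, seed = 2))
    after <- stats::runif(1)
  })
  expect_identical(before, after)
})
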