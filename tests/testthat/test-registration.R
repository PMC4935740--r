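test_that("landmark fit is exact on noiseless correspondences", {
  src <- rbind(a = c(0, 0, 0), b = c(10, 0, 0), c = c(0, 10, 0))
  fit0 <- landmark_fit(src, src)
  expect_equal(unclass(fit0$transform), diag(4), tolerance = 1e-12)
  expect_equal(fit0$rms, 0, tolerance = 1e-12)
  for (seed in 1:20) {
    t_true <- random_rigid_transform(rot_max_deg = 40, trans_max_mm = 30,
                                     seed = seed)
    src <- random_points(5, seed = seed + 100)
    fit <- landmark_fit(src, rt_apply(t_true, src))
    expect_lt(max(transform_gap(fit$transform, t_true)), 1e-9)
    expect_lt(fit$rms, 1e-9)
  }
})

test_that("degenerate landmark configurations are refused", {
  expect_error(landmark_fit(rbind(c(0, 0, 0), c(1, 0, 0)),
                            rbind(c(0, 0, 0), c(1, 0, 0))),
               "at least 3")
  line <- cbind(seq(0, 10, length.out = 5), 0, 0)
  expect_error(landmark_fit(line, line + 1), "collinear.*1\\.000")
  expect_error(landmark_fit(rbind(c(0, 0, 0)), rbind(c(1, 1, 1))), "at least 3")
})

test_that("reflection-requiring pairings resolve to the best proper rotation", {
  src <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0, 0, 0))
  tgt <- src
  tgt[, 3] <- -tgt[, 3]                         # mirrored target
  fit <- landmark_fit(src, tgt)
  expect_equal(det(unclass(fit$transform)[1:3, 1:3]), 1, tolerance = 1e-9)
  # and no grid rotation may do better than the constrained optimum
  expect_gte(quaternion_grid_rms(src, tgt) - fit$rms, -1e-6)
})

test_that("closed-form fit is optimal against a quaternion-grid search", {
  for (case in 1:25) {
    n <- 3 + (case %% 4)
    src <- random_points(n, seed = case)
    t_true <- random_rigid_transform(60, 40, seed = case + 500)
    noise <- withr::with_seed(case + 900,
      matrix(stats::rnorm(3 * n, 0, 0.4), ncol = 3))
    tgt <- rt_apply(t_true, src) + noise
    fit <- landmark_fit(src, tgt)
    expect_gte(quaternion_grid_rms(src, tgt) - fit$rms, -1e-6)
  }
})

test_that("fiducial registration error matches its expectation under noise", {
  # E[FRE^2] = (1 - 2/N) * 3 sigma^2 for N fiducials, isotropic noise sigma
  n <- 3; sigma <- 0.3
  src <- rbind(c(0, 0, 0), c(40, 0, 0), c(0, 40, 0))
  fre2 <- withr::with_seed(42, replicate(400, {
    tgt <- src + matrix(stats::rnorm(3 * n, 0, sigma), ncol = 3)
    landmark_fit(src, tgt)$rms^2
  }))
  expect_equal(mean(fre2), (1 - 2 / n) * 3 * sigma^2, tolerance = 0.1)
})

test_that("ICP converges immediately on aligned clouds", {
  p <- random_points(120, seed = 3)
  res <- icp(p, p)
  expect_lte(res$iterations, 2L)
  expect_true(res$converged)
  expect_lt(max(abs(unclass(res$transform) - diag(4))), 1e-6)
})

test_that("ICP recovers a known dislocation on the noiseless phantom", {
  ph <- small_phantom(seed = 5, rot_max_deg = 15, trans_max_mm = 10)
  zy_d <- mesh_region_vertices(ph$dislocated, "zygoma")
  zy_p <- mesh_region_vertices(ph$planned, "zygoma")
  init <- landmark_fit(ph$marks, ph$marks_reduced)$transform
  res <- icp(zy_d, zy_p, init = init)
  gap <- transform_gap(res$transform, ph$t_true)
  expect_lt(gap["trans_mm"], 0.01)
  expect_lt(gap["rot_deg"], 0.01)
  expect_true(res$converged)
})

test_that("untrimmed ICP RMS trace is non-increasing", {
  for (seed in 1:6) {
    ph <- small_phantom(seed = seed)
    src <- mesh_region_vertices(ph$dislocated, "zygoma")
    tgt <- mesh_region_vertices(ph$planned, "zygoma")
    init <- landmark_fit(ph$marks, ph$marks_reduced)$transform
    # perturb the init so the trace has several iterations to descend
    init <- rt_compose(rt_translate(c(1, -1, 0.5)), init)
    res <- icp(src, tgt, init = init)
    expect_true(all(diff(res$rms_trace) <= 1e-12))
  }
})

test_that("ICP input validation and correspondence gating", {
  p <- random_points(30, seed = 1)
  expect_error(icp(p[0, , drop = FALSE], p), "empty")
  expect_error(icp(p, p[1:2, ]), "at least 3")
  expect_error(icp(p + 500, p, params = icp_params(max_correspondence_distance = 1)),
               "correspondence")
  expect_error(icp_params(trim_fraction = 0.6), "trim_fraction")
  expect_error(icp_params(tol = 0))
})

test_that("trimmed ICP ignores gross outliers", {
  ph <- small_phantom(seed = 9)
  src <- mesh_region_vertices(ph$dislocated, "zygoma")
  tgt <- mesh_region_vertices(ph$planned, "zygoma")
  src_out <- rbind(src, matrix(300, nrow = 5, ncol = 3))   # 5 far outliers
  init <- landmark_fit(ph$marks, ph$marks_reduced)$transform
  res <- icp(src_out, tgt, init = init, params = icp_params(trim_fraction = 0.1))
  gap <- transform_gap(res$transform, ph$t_true)
  expect_lt(gap["trans_mm"], 0.05)
  expect_lt(gap["rot_deg"], 0.05)
})

test_that("fine alignment refines a coarse fit from noiseless surface points", {
  ph <- small_phantom(seed = 2)
  fixed <- mesh_region_vertices(ph$planned, "fixed")
  pts <- fixed[withr::with_seed(8, sample.int(nrow(fixed), 20)), ]
  res <- fine_alignment(rt_identity(), pts, ph$planned, regions = "fixed")
  expect_lt(res$rms, 1e-6)
  expect_error(fine_alignment(rt_identity(), pts[1:3, ], ph$planned),
               "at least 4")
})

test_that("fine alignment tolerates realistic picking noise", {
  # 20 tracked points with 0.3 mm isotropic noise: the recovered patient-to-
  # image transform should sit within 0.5 mm of truth nearly always
  ph <- small_phantom(seed = 4)
  fixed <- mesh_region_vertices(ph$planned, "fixed")
  ok <- withr::with_seed(21, replicate(60, {
    pts <- fixed[sample.int(nrow(fixed), 20), ] +
      matrix(stats::rnorm(60, 0, 0.3), ncol = 3)
    res <- fine_alignment(rt_identity(), pts, ph$planned, regions = "fixed")
    sqrt(sum(res$transform[1:3, 4]^2)) < 0.5
  }))
  expect_gte(mean(ok), 0.95)
})
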