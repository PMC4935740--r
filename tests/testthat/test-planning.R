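# One phantom and fitted plan shared across the planning tests.
ph <- small_phantom(seed = 12)
plan <- reduction_fit(mesh_region_vertices(ph$dislocated, "zygoma"),
                      mesh_region_vertices(ph$planned, "zygoma"),
                      init = list(source = ph$marks, target = ph$marks_reduced))

test_that("reduction fit recovers the ground-truth transform", {
  gap <- transform_gap(plan$transform, ph$t_true)
  expect_lt(gap["trans_mm"], 0.01)
  expect_lt(gap["rot_deg"], 0.01)
  expect_true(plan$registration$converged)
  expect_lt(max(residuals(plan)), 1e-5)
  co <- coef(plan)
  expect_named(co, c("tx", "ty", "tz", "rx", "ry", "rz"))
  expect_equal(unname(co[1:3]), unname(plan$transform[1:3, 4]))
})

test_that("reduction fit of a cloud onto itself is the identity", {
  zy <- mesh_region_vertices(ph$planned, "zygoma")
  fit <- reduction_fit(zy, zy)
  expect_lt(max(abs(unclass(fit$transform) - diag(4))), 1e-6)
})

test_that("a misfit beyond the RMS threshold refuses to produce a plan", {
  zy <- mesh_region_vertices(ph$planned, "zygoma")
  other <- random_points(100, scale = 60, seed = 77)   # unrelated cloud
  expect_error(reduction_fit(other, zy, rms_threshold = 0.5), "threshold|converge")
})

test_that("reduction fit under cloud noise stays within clinical tolerance", {
  zy_d <- mesh_region_vertices(ph$dislocated, "zygoma")
  zy_p <- mesh_region_vertices(ph$planned, "zygoma")
  init <- landmark_fit(ph$marks, ph$marks_reduced)$transform
  errs <- vapply(1:30, function(s) {
    noise <- withr::with_seed(3000 + s,
      matrix(stats::rnorm(length(zy_d), 0, 0.2), ncol = 3))
    fit <- reduction_fit(zy_d + noise, zy_p, init = init)
    unname(transform_gap(fit$transform, ph$t_true)["trans_mm"])
  }, numeric(1))
  expect_lt(max(errs), 0.3)
})

test_that("FNRPs are the marks mapped through the fitted transform", {
  fn <- generate_fnrps(plan, ph$marks)
  expect_s3_class(fn, "fnrp_set")
  expect_equal(fn$name, rownames(ph$marks))
  # independent hand multiplication of the homogeneous matrix per mark
  for (i in seq_len(nrow(ph$marks))) {
    expected <- (unclass(plan$transform) %*% c(ph$marks[i, ], 1))[1:3]
    expect_equal(unname(unlist(fn[i, c("xr", "yr", "zr")])), expected,
                 tolerance = 1e-12)
  }
  # identity plan: FNRPs coincide with the marks
  zy <- mesh_region_vertices(ph$planned, "zygoma")
  id_plan <- reduction_fit(zy, zy)
  fn_id <- generate_fnrps(id_plan, ph$marks_reduced)
  expect_equal(as.matrix(fn_id[, c("xr", "yr", "zr")]),
               as.matrix(fn_id[, c("xd", "yd", "zd")]),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("pure translations shift FNRPs by exactly the planned offset", {
  zy <- mesh_region_vertices(ph$planned, "zygoma")
  lm <- zy[c(1, 11, 31), ]
  fit <- reduction_fit(rt_apply(rt_translate(c(0, 0, 4)), zy), zy,
                       init = list(source = rt_apply(rt_translate(c(0, 0, 4)), lm),
                                   target = lm))
  expect_warning(generate_fnrps(fit, rbind(m = c(10, 10, 10))), "three")
  fn <- suppressWarnings(generate_fnrps(fit, rbind(m = c(10, 10, 10))))
  expect_equal(unname(unlist(fn[1, c("xr", "yr", "zr")])), c(10, 10, 6),
               tolerance = 1e-6)
})

test_that("mark registration is closed once the plan is flagged reduced", {
  done <- mark_reduced(plan)
  expect_error(generate_fnrps(done, ph$marks), "before")
  expect_error(generate_fnrps(plan, ph$marks[0, , drop = FALSE]), "no marks")
})

test_that("screw-hole back-calculation inverts FNRP generation exactly", {
  holes_d <- back_calculate_holes(plan, ph$holes_reduced)
  expect_equal(rt_apply(plan$transform, holes_d), ph$holes_reduced,
               tolerance = 1e-9)
  expect_equal(holes_d, rt_apply(rt_invert(ph$t_true), ph$holes_reduced),
               tolerance = 0.01)
  zy <- mesh_region_vertices(ph$planned, "zygoma")
  id_plan <- reduction_fit(zy, zy)
  expect_equal(back_calculate_holes(id_plan, ph$holes_reduced),
               ph$holes_reduced, tolerance = 1e-6)
})

test_that("probe readings report the offset from the FNRP", {
  fn <- generate_fnrps(plan, ph$marks)
  ref <- as.matrix(fn[, c("xr", "yr", "zr")])
  exact <- probe_readings(fn, ref)
  expect_equal(exact$distance, rep(0, 3))
  shifted <- ref + rep(c(0, 0, 1), each = 3)
  r <- probe_readings(fn, shifted)
  expect_equal(r$distance, rep(1, 3))
  expect_equal(r$dz, rep(1, 3))
  expect_equal(r$dx, rep(0, 3))
  expect_error(probe_readings(fn, ref[1:2, ]), "one probed position per FNRP")
})

test_that("the fragment pose is recovered from noiseless probes", {
  fn <- generate_fnrps(plan, ph$marks)
  # fragment at an arbitrary intermediate pose
  pose <- random_rigid_transform(8, 5, seed = 31)
  probed <- rt_apply(pose, as.matrix(fn[, c("xd", "yd", "zd")]))
  est <- pose_from_probes(fn, probed)
  expect_lt(max(transform_gap(est$transform, pose)), 1e-6)
  # at perfect reduction the recovered pose equals the plan transform
  probed_red <- rt_apply(plan$transform, as.matrix(fn[, c("xd", "yd", "zd")]))
  est_red <- pose_from_probes(fn, probed_red)
  expect_lt(max(transform_gap(est_red$transform, plan$transform)), 1e-6)
})

test_that("collinear FNRPs cannot determine the fragment pose", {
  marks <- cbind(seq(2, 12, length.out = 4), 1, 1)
  rownames(marks) <- sprintf("m%d", 1:4)
  fn <- generate_fnrps(plan, marks)
  expect_error(pose_from_probes(fn, as.matrix(fn[, c("xr", "yr", "zr")])),
               "collinear")
})

test_that("FNRP generation is equivariant under a global frame change", {
  g <- random_rigid_transform(25, 15, seed = 41)
  zy_d <- mesh_region_vertices(ph$dislocated, "zygoma")
  zy_p <- mesh_region_vertices(ph$planned, "zygoma")
  plan_g <- reduction_fit(rt_apply(g, zy_d), rt_apply(g, zy_p),
                          init = list(source = rt_apply(g, ph$marks),
                                      target = rt_apply(g, ph$marks_reduced)))
  fn <- generate_fnrps(plan, ph$marks)
  fn_g <- generate_fnrps(plan_g, rt_apply(g, ph$marks))
  expect_equal(as.matrix(fn_g[, c("xr", "yr", "zr")]),
               rt_apply(g, as.matrix(fn[, c("xr", "yr", "zr")])),
               ignore_attr = TRUE, tolerance = 1e-6)
})
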