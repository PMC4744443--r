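toy <- make_two_rib_toy(n_ref = 1, n_ribs = 4)

test_that("parasternal activation ramps from sternal edge to zero laterally", {
  f <- parasternal_field(toy)
  sel <- toy$region == "parasternal"
  expect_true(all(f[!sel] == 0))
  d <- toy$elem_data$dorsalness[sel]
  g <- as.numeric(f)[sel]
  expect_equal(max(g[d == min(d)]), 1.0)      # sternal edge fully active
  expect_equal(min(g[d == max(d)]), 0.0)      # costochondral boundary
  # linear ramp in the lateral coordinate
  expect_equal(g, (max(d) - d) / (max(d) - min(d)))
})

test_that("external intercostal field peaks dorsally in the top interspace", {
  f <- external_intercostal_field(toy)
  sel <- toy$region == "intercostal"
  expect_true(all(f[!sel] == 0))
  g <- as.numeric(f)[sel]
  d <- toy$elem_data$dorsalness[sel]
  k <- toy$elem_data$interspace[sel]
  expect_equal(max(g[k == 1 & d == max(d)]), 1.0)
  expect_equal(min(g[d == min(d)]), 0.0)      # ventral-most -> 0
  # monotone non-increasing along the caudal traversal at fixed dorsalness
  for (dd in unique(d)) {
    prof <- vapply(sort(unique(k)), function(kk)
      mean(g[k == kk & d == dd]), 1)
    expect_true(all(diff(prof) <= 1e-12))
  }
})

test_that("internal intercostal field mirrors the external pattern", {
  f <- internal_intercostal_field(toy)
  sel <- toy$region == "intercostal"
  g <- as.numeric(f)[sel]
  d <- toy$elem_data$dorsalness[sel]
  k <- toy$elem_data$interspace[sel]
  expect_equal(max(g[k == max(k) & d == max(d)]), 1.0)
  # monotone non-increasing along the cranial traversal
  for (dd in unique(d)) {
    prof <- vapply(sort(unique(k), decreasing = TRUE), function(kk)
      mean(g[k == kk & d == dd]), 1)
    expect_true(all(diff(prof) <= 1e-12))
  }
  expect_error(internal_intercostal_field(make_strip(1, 1, 1)), "region")
})

test_that("field scaling and bounds behave as specified", {
  f <- external_intercostal_field(toy)
  expect_equal(as.numeric(scale_field(f, 0.3)), 0.3 * as.numeric(f))
  expect_equal(as.numeric(scale_field(f, 0)), rep(0, length(f)))
  expect_identical(as.numeric(scale_field(f, 1)), as.numeric(f))
  expect_error(scale_field(f, 1.2))
  expect_true(all(as.numeric(f) >= 0 & as.numeric(f) <= 1))
})

test_that("waveforms interpolate, clamp, and peak at full activation", {
  wf <- waveform(c(0, 1, 2, 4), c(0, 1, 1, 0))
  expect_equal(alpha_at(wf, c(0, 1, 2, 4)), c(0, 1, 1, 0))
  expect_equal(alpha_at(wf, 0.5), 0.5)
  expect_equal(alpha_at(wf, 3), 0.5)
  # clamped outside the table span
  expect_equal(alpha_at(wf, -1), 0)
  expect_equal(alpha_at(wf, 10), 0)
  expect_equal(max(alpha_at(default_breath_waveform(5),
                            seq(0, 5, by = 0.01))), 1.0)
  expect_error(waveform(c(0, 1), c(0, 1.5)))
})

test_that("schedules combine fields, ramps and waveform evaluation", {
  mesh <- make_strip(4, 2, 2, nx = 2)
  sched <- activation_schedule(
    fields = list(structure(rep(0.5, nrow(mesh$tets)),
                            class = "activation_field", group = "muscle")),
    waveform = ramp_waveform(), span = c(0, 2))
  model <- fe_model(mesh, list(muscle = muscle_params(a = 2, A = 0.5)),
                    pressures = list(list(face_set = "x1", from = 0,
                                          to = 2e-3),
                                     list(face_set = "x0", from = -0.5e-3,
                                          to = -0.75e-3)),
                    activation = sched)
  s0 <- apply_schedule(0, model)
  expect_equal(s0$pressures$x1, 0)
  expect_equal(s0$pressures$x0, -0.5e-3)
  expect_equal(s0$alpha, 0)
  s1 <- apply_schedule(2, model)
  expect_equal(s1$pressures$x1, 2e-3)
  expect_equal(s1$pressures$x0, -0.75e-3)
  smid <- apply_schedule(1, model)
  expect_equal(smid$pressures$x1, 1e-3)
  expect_equal(smid$pressures$x0, -0.625e-3)
  expect_equal(smid$load_factor, 0.5)
  expect_warning(apply_schedule(3, model), "clamped")
})
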