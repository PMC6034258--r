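test_that("complete curves are cut at the Z turnaround", {
  z <- c(seq(0, 100, length.out = 101), seq(99, 0, length.out = 100))
  curve <- fcvolume:::new_fv_curve(tibble::tibble(z = z, deflection = seq_along(z)))
  appr <- split_approach(curve, "complete")
  expect_equal(nrow(appr), 101L)
  expect_equal(max(appr$z), 100)

  # a flat apex splits at the *last* plateau sample (argmax-last oracle)
  z2 <- c(0:10, 10, 10, 9:0)
  oracle <- max(which(z2 == max(z2)))
  curve2 <- fcvolume:::new_fv_curve(tibble::tibble(z = z2, deflection = seq_along(z2)))
  expect_equal(nrow(split_approach(curve2, "complete")), oracle)

  expect_identical(
    nrow(split_approach(curve, "approach_only")), nrow(curve)
  )
  mono <- fcvolume:::new_fv_curve(tibble::tibble(z = 1:10, deflection = 1:10))
  expect_warning(split_approach(mono, "complete"), "turnaround")
})

test_that("deflection volts convert to nanonewtons via F = D K_C / S", {
  curve <- fcvolume:::new_fv_curve(tibble::tibble(z = 0:3, deflection = c(0, 0.5, 1, 2)))
  # constants of the validation acquisition
  acq <- fv_acquisition(1, cantilever_k = 0.164, detector_sensitivity = 0.025)
  expect_equal(to_physical(curve, acq)$force[3], 6.56)
  # constants of the soft-cantilever acquisition
  acq2 <- fv_acquisition(1, cantilever_k = 0.02, detector_sensitivity = 0.0013)
  expect_equal(to_physical(curve, acq2)$force[3], 0.02 / 0.0013, tolerance = 1e-12)
  expect_equal(to_physical(curve, acq2)$force[3], 15.3846, tolerance = 1e-4)

  # nN input passes through with K_C = S = 1
  curve_n <- fcvolume:::new_fv_curve(
    tibble::tibble(z = 0:3, deflection = c(0, 0.5, 1, 2)),
    deflection_unit = "N"
  )
  acq_n <- fv_acquisition(1, 1, 1, deflection_unit = "N")
  expect_identical(to_physical(curve_n, acq_n)$force, curve_n$deflection)
  expect_error(
    fv_acquisition(1, 0.164, 0.025, deflection_unit = "N"),
    class = "fcv_param_error"
  )
  expect_error(fv_acquisition(1, -1, 1), class = "fcv_param_error")
})

test_that("force conversion is linear and unit-neutral", {
  set.seed(1)
  d <- runif(50)
  acq <- fv_acquisition(1000, cantilever_k = 0.164, detector_sensitivity = 0.025)
  curve <- function(defl, unit = "V") {
    fcvolume:::new_fv_curve(
      tibble::tibble(z = seq_along(defl), deflection = defl),
      deflection_unit = unit
    )
  }
  # linearity in the deflection signal
  expect_equal(
    to_physical(curve(3.7 * d), acq)$force,
    3.7 * to_physical(curve(d), acq)$force
  )
  # the same physical curve given in V (true K_C, S) or in nN (K_C = S = 1)
  # yields identical forces to machine precision
  f_from_v <- to_physical(curve(d), acq)$force
  acq_n <- fv_acquisition(1000, 1, 1, deflection_unit = "N")
  f_from_n <- to_physical(curve(d * 0.164 / 0.025, "N"), acq_n)$force
  expect_equal(f_from_v, f_from_n, tolerance = 1e-15)
  # z stage scaling to nm
  expect_equal(to_physical(curve(d), acq)$z, 1000 * seq_along(d))
})

test_that("inverted-Z instruments are flipped to the internal convention", {
  acq <- fv_acquisition(1, 0.164, 0.025, z_direction = "decreasing")
  curve <- fcvolume:::new_fv_curve(tibble::tibble(z = 10:1, deflection = rep(0, 10)))
  expect_equal(to_physical(curve, acq)$z, -(10:1)) # now increasing toward sample
})

test_that("zeroline fit recovers exact lines and flat baselines", {
  z <- seq(0, 100, length.out = 201)
  line <- make_curve(z, 2 + 0.01 * z)
  fit <- fit_zeroline(line, c(0, 70))
  expect_equal(fit$slope, 0.01, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-12)

  flat <- make_curve(z, rep(5, length(z)))
  fit2 <- fit_zeroline(flat, c(10, 90))
  expect_equal(fit2$slope, 0)
  expect_equal(fit2$intercept, 5)

  expect_error(fit_zeroline(line, c(70, 10)), class = "fcv_window_error")

  # matches lm() on the same window
  idx <- floor(10 / 100 * 200):floor(70 / 100 * 200) + 1
  ref <- lm(force ~ z, data = as.data.frame(line)[idx, ])
  fit3 <- fit_zeroline(line, c(10, 70))
  expect_equal(fit3$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit3$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
})

test_that("on noisy flat baselines the fitted slope is statistically zero", {
  z <- seq(0, 500, length.out = 301)
  inside <- vapply(1:100, function(s) {
    set.seed(s)
    curve <- make_curve(z, rnorm(length(z), sd = 0.05))
    fit <- fit_zeroline(curve, c(10, 70))
    abs(fit$slope) <= 3 * fit$se_slope
  }, TRUE)
  expect_gte(mean(inside), 0.95) # 3-sigma coverage over seeded trials
})

test_that("zeroline subtraction zeroes the baseline and is idempotent", {
  z <- seq(0, 100, length.out = 201)
  line <- make_curve(z, 2 + 0.01 * z)
  sub <- subtract_zeroline(line, fit_zeroline(line, c(0, 70)))
  expect_equal(max(abs(sub$force)), 0, tolerance = 1e-12)
  expect_true(attr(sub, "baseline_removed"))

  # refit on the subtracted curve is the zero line; re-subtracting changes nothing
  refit <- fit_zeroline(sub, c(0, 70))
  expect_equal(abs(refit$slope), 0, tolerance = 1e-14)
  sub2 <- subtract_zeroline(sub, refit)
  expect_equal(sub2$force, sub$force, tolerance = 1e-12)
})

test_that("a linear tilt does not change the recovered contact region", {
  scene <- quick_scene(e_field = 30, n_x = 1, n_y = 1, include_withdraw = FALSE)
  acq <- scene_acquisition(scene)
  raw <- generate_curve(scene, 0, 0) # has offset + tilt baseline already
  scene_flat <- quick_scene(
    e_field = 30, n_x = 1, n_y = 1, include_withdraw = FALSE,
    baseline_offset_v = 0, baseline_tilt_v_per_nm = 0
  )
  raw_flat <- generate_curve(scene_flat, 0, 0)
  clean <- function(r) {
    cal <- to_physical(r, acq)
    subtract_zeroline(cal, fit_zeroline(cal, c(0, 40)))
  }
  expect_equal(clean(raw)$force, clean(raw_flat)$force, tolerance = 1e-9)
})
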