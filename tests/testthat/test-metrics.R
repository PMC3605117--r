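test_that("waveform metrics on a constructed trapezoid trace", {
  t <- seq(0, 60, by = 0.1)
  v <- rep(-0.056, length(t))
  v[t >= 10 & t < 10.5] <- -0.016                   # spike
  v[t >= 10.5 & t < 40] <- -0.025                   # flat plateau
  v[t >= 40 & t < 42] <- -0.06                      # undershoot
  wm <- waveform_metrics(data.frame(t = t, v_m = v), resting = -0.056)
  expect_true(wm$ap_detected)
  expect_equal(wm$peak_vm, -0.016)
  expect_equal(wm$plateau_mean, -0.025, tolerance = 0.01)
  expect_equal(wm$duration_s, 30, tolerance = 0.02)
})

test_that("a constant trace yields the no-AP signal", {
  wm <- waveform_metrics(data.frame(t = 0:100, v_m = rep(-0.056, 101)),
                         resting = -0.056)
  expect_false(wm$ap_detected)
  expect_true(is.na(wm$peak_vm))
})

test_that("waveform metrics are invariant to time shift and resampling", {
  p <- table_params()
  tr <- integrate_space_clamped(p, pulse_drive(p, 1, 0.02), t_end = 90,
                                dt = 0.01, output_stride = 5L)
  m1 <- waveform_metrics(data.frame(t = tr$t, v_m = tr$v_m), resting = p$v_mr)
  m2 <- waveform_metrics(data.frame(t = tr$t + 132, v_m = tr$v_m),
                         resting = p$v_mr)
  expect_equal(m1$peak_vm, m2$peak_vm)
  expect_equal(m1$duration_s, m2$duration_s)
  t3 <- seq(0, 90, by = 0.11)
  m3 <- waveform_metrics(data.frame(t = t3,
                                    v_m = approx(tr$t, tr$v_m, t3)$y),
                         resting = p$v_mr)
  expect_equal(m3$peak_vm, m1$peak_vm, tolerance = 5e-4)
  expect_equal(m3$duration_s, m1$duration_s, tolerance = 0.5)
  expect_equal(m3$plateau_mean, m1$plateau_mean, tolerance = 1e-3)
})

test_that("contracting fraction spans 0-100 and respects element volumes", {
  sh <- fx_shell()
  ser <- sh$sol$v_m
  hot <- field_series(c(0, 1), cbind(rep(0, nrow(ser$values)),
                                     rep(0, nrow(ser$values))), ser$mesh)
  expect_equal(suppressWarnings(
    contracting_fraction(hot, threshold = -0.04)$percent), c(100, 100))
  cold <- field_series(c(0, 1), matrix(-0.056, nrow(ser$values), 2), ser$mesh)
  expect_equal(suppressWarnings(
    contracting_fraction(cold, threshold = -0.04)$percent), c(0, 0))
  expect_warning(contracting_fraction(cold, threshold = -0.06), "at rest")
  # invariance to element relabeling (permutation of elements)
  cf1 <- contracting_fraction(ser)
  perm <- sample(nrow(ser$mesh$elems))
  m2 <- ser$mesh
  m2$elems <- m2$elems[perm, , drop = FALSE]
  m2$elem_label <- m2$elem_label[perm]
  ser2 <- field_series(ser$times, ser$values, m2)
  expect_equal(contracting_fraction(ser2)$percent, cf1$percent)
})

test_that("front speed recovers a constructed front exactly", {
  m <- mesh_cable(0.2, 1e-3)
  x <- m$nodes[, 1]
  times <- seq(0, 25, by = 0.25)
  V <- vapply(times, function(t)
    ifelse(x <= 0.01 * t, -0.016, -0.056), numeric(length(x)))
  ser <- field_series(times, V, m)
  probes <- matrix(seq(0.05, 0.15, by = 0.01), ncol = 1)
  fs <- front_speed(ser, probes)
  expect_equal(fs$speed, 0.01, tolerance = 1e-3)
  expect_gt(fs$r_squared, 0.9999)
  # unreliable fits warn: arrivals scattered without order
  set.seed(2)
  arr_rand <- runif(length(x), 1, 20)
  V2 <- vapply(times, function(t)
    ifelse(arr_rand <= t, -0.016, -0.056), numeric(length(x)))
  noisy <- field_series(times, V2, m)
  expect_warning(front_speed(noisy, probes), "unreliable")
})

test_that("front speed scales diffusively with conductivity", {
  p <- table_params()
  s1 <- fx_cable()$speed
  s2 <- simulate_cable(p, 2 * 0.68, 0.8, dt = 0.01, t_end = 30)$speed
  expect_equal(s2 / s1, sqrt(2), tolerance = 0.05)
})

test_that("the refractory protocol brackets and converges", {
  p <- table_params()
  rp <- fx_refractory()
  expect_true(rp$recovered)
  expect_true(is.finite(rp$interval))
  # an early second pulse is not a full AP, a late one is
  dur <- rp$duration
  full_at <- function(gap) {
    dr <- pulse_drive(p, c(1, 1 + gap), dur)
    tr <- integrate_space_clamped(p, dr, t_end = 1 + gap + 90, dt = 0.01)
    sec <- max(tr$v_m[tr$t > 1 + gap + dur])
    abs(sec - rp$first_peak) < 5e-3
  }
  expect_false(full_at(10))
  expect_true(full_at(500))
  expect_false(full_at(rp$interval - 10))
  expect_true(full_at(rp$interval + 10))
})

test_that("recovery to rest takes much longer than the plateau itself", {
  p <- table_params()
  rt <- fixture("recovery_time", recovery_time(p))
  expect_true(is.finite(rt))
  expect_gt(rt, 100)
})
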