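test_that("quadrature b-value matches the Stejskal-Tanner closed form", {
  # trapezoid pair with on-grid ramps: piecewise-linear profile is exact on
  # the sampling grid, so quadrature should agree with the analytic formula
  G <- 60; delta <- 20; Delta <- 30; zeta <- 0.5
  w <- st_trapezoid_waveform(G, delta, Delta, zeta, dt = 0.01)
  sh <- btensor_shape(btensor_from_waveform(w))
  b_ref <- st_trapezoid_b(G, delta, Delta, zeta)
  expect_equal(sh$b, b_ref, tolerance = 1e-6)
  expect_equal(sh$b_delta, 1, tolerance = 1e-9)

  # near-rectangular limit approaches gamma^2 G^2 delta^2 (Delta - delta/3)
  w2 <- st_trapezoid_waveform(G, delta, Delta, zeta = 0.01, dt = 0.01)
  b2 <- btensor_shape(btensor_from_waveform(w2))$b
  expect_equal(b2, st_trapezoid_b(G, delta, Delta, 0.01), tolerance = 1e-6)

  # Richardson check: halving dt moves b by < 1e-6 relative
  w3 <- st_trapezoid_waveform(G, delta, Delta, zeta, dt = 0.005)
  b3 <- btensor_shape(btensor_from_waveform(w3))$b
  expect_equal(b3, sh$b, tolerance = 1e-6)
})

test_that("zero and non-refocused waveforms are handled", {
  w0 <- dividemri:::new_grad_waveform(0.01, matrix(0, 101, 3))
  expect_equal(max(abs(unclass(btensor_from_waveform(w0)))), 0)
  # a single unbalanced lobe never refocuses
  bad <- st_trapezoid_waveform(40, 10, 20, 0.5)
  bad$g[bad$g < 0] <- 0
  expect_error(btensor_from_waveform(bad), "not refocused")
})

test_that("rotating waveform samples conjugates the b-tensor", {
  w <- st_trapezoid_waveform(50, 15, 25, 0.4, axis = c(1, 2, 2))
  B <- btensor_from_waveform(w)
  set.seed(11)
  for (R in random_rotations(5)) {
    wr <- w
    wr$g <- w$g %*% t(R)
    Br <- btensor_from_waveform(wr)
    expect_equal(unclass(Br), unclass(rotate_btensor(B, R)), tolerance = 1e-9)
    shr <- btensor_shape(Br)
    expect_equal(shr$b, btensor_shape(B)$b, tolerance = 1e-9)
  }
})

test_that("bipolar LTE synthesis hits the target b within hardware limits", {
  # timings of the high-performance 3T configuration
  w <- make_bipolar_lte_waveform(2, delta1 = 26, delta2 = 26, delta_P = 8,
                                 G_max = 80, S_max = 200, dt = 0.01)
  sh <- btensor_shape(btensor_from_waveform(w))
  expect_lt(abs(sh$b - 2) / 2, 0.005)
  expect_equal(sh$b_delta, 1, tolerance = 1e-6)
  expect_lte(w$g_max_used, 80)
  expect_lte(w$slew_max_used, 200 * 1.001)

  # asymmetric lobes still refocus and hit b
  wa <- make_bipolar_lte_waveform(1.5, delta1 = 30, delta2 = 22, delta_P = 10,
                                  G_max = 80, S_max = 150)
  sha <- btensor_shape(btensor_from_waveform(wa))
  expect_lt(abs(sha$b - 1.5) / 1.5, 0.005)
  expect_equal(sha$b_delta, 1, tolerance = 1e-6)

  # amplitude agrees with independent bisection on the quadrature b-value
  b_of_G <- function(G) {
    wf <- dividemri:::bipolar_lte_at_amplitude(G, 26, 26, 8, 200, 0.01,
                                               c(0, 0, 1))
    btensor_shape(btensor_from_waveform(wf))$b
  }
  G_star <- uniroot(function(G) b_of_G(G) - 2, c(1, 80), tol = 1e-7)$root
  expect_equal(w$g_max_used, G_star, tolerance = 1e-4)

  # zero target: silent waveform
  w0 <- make_bipolar_lte_waveform(0, 26, 26, 8, 80, 200)
  expect_equal(max(abs(w0$g)), 0)

  # unreachable target names the maximum achievable b
  expect_error(make_bipolar_lte_waveform(2, 26, 26, 8, G_max = 10, S_max = 200),
               "maximum achievable")
})

test_that("waveform text files round-trip", {
  w <- make_bipolar_lte_waveform(1, 20, 20, 6, 60, 180, dt = 0.02)
  path <- tempfile(fileext = ".txt")
  write_waveform(w, path)
  w2 <- read_waveform(path)
  expect_equal(w2$dt, w$dt)
  expect_equal(w2$g, w$g, tolerance = 1e-10)
  b1 <- btensor_shape(btensor_from_waveform(w))$b
  b2 <- btensor_shape(btensor_from_waveform(w2))$b
  expect_equal(b1, b2, tolerance = 1e-9)
  expect_error(read_waveform(textConnection("1 2 3")), "dt_ms")
})
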