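# shared fixtures and independent oracles

# default 80-sample protocol, built once
default_protocol <- function() {
  if (is.null(.test_env$proto)) .test_env$proto <- build_divide_protocol(5000, 115)
  .test_env$proto
}
.test_env <- new.env()

# closed-form b-value of a trapezoidal Stejskal-Tanner pair:
# b = gamma^2 G^2 [ delta^2 (Delta - delta/3) + zeta^3/30 - delta zeta^2/6 ]
# G mT/m, times ms, zeta the ramp time, delta = ramp + plateau,
# Delta = lobe start separation; returns ms/um^2
st_trapezoid_b <- function(G, delta, Delta, zeta, gamma = 2.6751e8) {
  G_si <- G * 1e-3
  d <- delta * 1e-3; D <- Delta * 1e-3; z <- zeta * 1e-3
  gamma^2 * G_si^2 * (d^2 * (D - d / 3) + z^3 / 30 - d * z^2 / 6) * 1e-9
}

# sampled trapezoidal Stejskal-Tanner effective waveform along an axis,
# using the textbook convention: ramp zeta, plateau delta - zeta, ramp zeta
# (lobe duration delta + zeta, gradient area G * delta); second lobe starts
# at Delta. Ramps and plateaus are multiples of dt so the piecewise-linear
# profile is represented exactly on the grid.
st_trapezoid_waveform <- function(G, delta, Delta, zeta, dt = 0.01,
                                  axis = c(0, 0, 1)) {
  stopifnot(zeta >= dt, delta > zeta, Delta >= delta + zeta)
  total <- Delta + delta + zeta
  t <- seq(0, total, by = dt)
  lobe <- function(t0) {
    u <- t - t0
    pmin(pmax(u / zeta, 0), 1, pmax((delta + zeta - u) / zeta, 0))
  }
  prof <- G * (lobe(0) - lobe(Delta))
  dividemri:::new_grad_waveform(dt, outer(prof, axis / sqrt(sum(axis^2))))
}

# exact powder-averaged LTE signal of one axisymmetric Gaussian compartment:
# mean over the sphere of exp(-b (l_perp + (l_par - l_perp) cos^2 t))
# = exp(-b l_perp) * sqrt(pi/(4 x)) * erf(sqrt(x)), x = b (l_par - l_perp)
powder_lte_axisym <- function(b, l_par, l_perp) {
  x <- b * (l_par - l_perp)
  pre <- exp(-b * l_perp)
  ifelse(abs(x) < 1e-12, pre,
         pre * sqrt(pi / (4 * x)) * (2 * stats::pnorm(sqrt(2 * x)) - 1))
}

# exact powder-averaged LTE signal of a multi-compartment axisymmetric model
powder_lte_model <- function(model, b) {
  sum(vapply(model$compartments, function(cp) {
    l <- sort(cp$eigenvalues, decreasing = TRUE)
    if (abs(l[2] - l[3]) > 1e-12) stop("oracle needs prolate axisymmetric compartments")
    cp$f * powder_lte_axisym(b, l[1], l[2])
  }, 1))
}
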