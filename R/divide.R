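#' Powder-average a volume series over directions
#'
#' The powder average is the arithmetic mean of the signal across encoding
#' directions for each (b, b_delta) shell; STE repeats are averaged the same
#' way. Powder averaging removes the effect of orientation dispersion, which
#' is what allows microscopic anisotropy to be estimated from the shell
#' means.
#'
#' @param signal numeric vector of per-volume signals for one voxel, aligned
#'   with the protocol entries.
#' @param protocol a \code{divide_protocol}.
#' @return a \code{powder_signal}: data frame with one row per (b, b_delta)
#'   shell holding \code{b}, \code{b_delta}, \code{shape}, \code{S_mean} and
#'   \code{n} (number of averaged samples), ordered by b then b_delta.
#' @export
powder_average <- function(signal, protocol) {
  stopifnot(inherits(protocol, "divide_protocol"))
  if (length(signal) != protocol$n_samples)
    stop("signal has ", length(signal), " volumes but the protocol has ",
         protocol$n_samples)
  e <- protocol$entries
  key <- paste(signif(e$b, 10), signif(e$b_delta, 10))
  agg <- tapply(seq_along(signal), key, function(idx) {
    c(b = e$b[idx[1]], b_delta = e$b_delta[idx[1]],
      S_mean = mean(signal[idx]), n = length(idx))
  })
  tab <- as.data.frame(do.call(rbind, agg))
  tab$shape <- ifelse(abs(tab$b_delta - 1) < 1e-9, "LTE",
                      ifelse(abs(tab$b_delta) < 1e-9, "STE", "other"))
  tab <- tab[order(tab$b, tab$b_delta), c("b", "b_delta", "shape", "S_mean", "n")]
  rownames(tab) <- NULL
  new_powder_signal(tab)
}

#' Construct a powder signal directly from shell values
#'
#' @param b,b_delta shell b-values (ms/um^2) and shapes.
#' @param S_mean powder-averaged signal per shell.
#' @param n number of samples averaged into each shell.
#' @rdname powder_average
#' @export
powder_signal <- function(b, b_delta, S_mean, n = 1) {
  tab <- data.frame(b = b, b_delta = b_delta,
                    shape = ifelse(abs(b_delta - 1) < 1e-9, "LTE",
                                   ifelse(abs(b_delta) < 1e-9, "STE", "other")),
                    S_mean = S_mean, n = n)
  if (anyDuplicated(tab[, c("b", "b_delta")]))
    stop("shells must be unique in (b, b_delta)")
  tab <- tab[order(tab$b, tab$b_delta), ]
  rownames(tab) <- NULL
  new_powder_signal(tab)
}

new_powder_signal <- function(tab) {
  stopifnot(all(tab$S_mean >= 0), all(tab$n >= 1))
  structure(tab, class = c("powder_signal", "data.frame"))
}

#' Gamma-model powder signal equation
#'
#' The powder-averaged signal of a gamma distribution of apparent
#' diffusivities with mean MD and variance \eqn{\mu_2 = V_I + b_\Delta^2 V_A}
#' is the Laplace transform
#' \deqn{\bar S(b, b_\Delta) = S_0 (1 + b \mu_2 / MD)^{-MD^2/\mu_2}.}
#' As \eqn{\mu_2 \to 0} this reduces continuously to the monoexponential
#' \eqn{S_0 e^{-b\,MD}}; a series expansion is used near that limit for
#' numerical stability. Parameter points where the base \eqn{1 + b\mu_2/MD}
#' is non-positive (possible for negative variances at large b) yield
#' \code{NA} and are rejected during fitting.
#'
#' @param b,b_delta b-value(s), ms/um^2, and shape(s).
#' @param S0 signal at b = 0.
#' @param MD mean diffusivity, um^2/ms (> 0).
#' @param VI,VA isotropic / anisotropic diffusional variance, um^4/ms^2 (may
#'   be negative).
#' @return predicted powder-averaged signal(s).
#' @examples
#' eq1_signal(2, 0, S0 = 1, MD = 1, VI = 0.25, VA = 0)  # 1.5^-4
#' @export
eq1_signal <- function(b, b_delta, S0, MD, VI, VA) {
  stopifnot(MD > 0, S0 > 0)
  mu2 <- VI + b_delta^2 * VA
  x <- b * mu2 / MD
  n <- max(length(b), length(b_delta))
  x <- rep_len(x, n); b <- rep_len(b, n); mu2 <- rep_len(mu2, n)
  logS <- rep(NA_real_, n)
  small <- abs(x) < 1e-5
  # series: log S = log S0 - b MD + b^2 mu2/2 - b^3 mu2^2/(3 MD) + ...
  logS[small] <- log(S0) - b[small] * MD + b[small]^2 * mu2[small] / 2 -
    b[small]^3 * mu2[small]^2 / (3 * MD) + b[small]^4 * mu2[small]^3 / (4 * MD^2)
  ok <- !small & (1 + x > 0)
  logS[ok] <- log(S0) - (MD^2 / mu2[ok]) * log1p(x[ok])
  exp(logS)
}

#' Microscopic fractional anisotropy from DIVIDE parameters
#'
#' \deqn{\mu FA = \sqrt{3/2}\,\left(1 + \frac{MD^2 + V_I}{\frac{5}{2} V_A}\right)^{-1/2},}
#' the Westin-style definition that includes the \eqn{V_I} contribution. It
#' can be read as the FA that would be observed were all microscopic
#' structures aligned in parallel. For \eqn{V_A \le 0} the expression is
#' undefined; the convention here returns 0 (no microscopic anisotropy) and
#' callers that need it can test \code{VA > 0}.
#'
#' @param MD mean diffusivity, um^2/ms.
#' @param VI,VA isotropic / anisotropic diffusional variance, um^4/ms^2.
#' @return value(s) in [0, 1]; 0 where \code{VA <= 0}.
#' @examples
#' mufa(0.7, 0, (4 / 45) * 2.1^2)  # single stick: exactly 1
#' @export
mufa <- function(MD, VI, VA) {
  out <- ifelse(VA > 0,
                sqrt(3 / 2) / sqrt(1 + (MD^2 + VI) / (2.5 * VA)),
                0)
  unname(out)
}

#' Fit the DIVIDE gamma model to a powder-averaged signal
#'
#' Jointly fits linear and spherical tensor-encoded shells with the gamma
#' signal model (see \code{\link{eq1_signal}}) by weighted nonlinear least
#' squares (Levenberg-Marquardt), with weights equal to the square root of
#' the number of samples averaged into each shell (heteroscedasticity of the
#' shell means). The fit is run from several starting points - seeded random
#' draws plus one moment-based (cumulant) start - and the lowest weighted SSE
#' wins. The variances V_I and V_A are unconstrained in sign: negative
#' estimates are possible under noise and are deliberately not clipped, to
#' avoid positive bias near zero. MD and S0 are kept positive structurally by
#' optimizing their logarithms.
#'
#' @param powder a \code{powder_signal} (needs >= 4 shells spanning at least
#'   two b-values and both b-tensor shapes).
#' @param restarts number of random restarts (default 5).
#' @param seed integer seed for the restart draws.
#' @param moment_start also include a deterministic cumulant-based starting
#'   point (default \code{TRUE}).
#' @param ftol relative function tolerance passed to the optimizer.
#' @return an object of class \code{divide_fit} with components
#'   \code{coefficients} (S0, MD, VI, VA), \code{MKI}, \code{MKA}, \code{uFA}
#'   (\eqn{MK_x = 3 V_x / MD^2}), \code{converged}, \code{sse} (weighted),
#'   \code{powder}, and the usual accessor methods (\code{coef},
#'   \code{predict}, \code{fitted}, \code{residuals}, \code{summary},
#'   \code{plot}, \code{simulate}).
#' @examples
#' p <- build_divide_protocol(TR = 5000, TE = 115)
#' s <- dwi_signal(tissue_preset("wm_mimic"), p$btensors)
#' fit <- divide_fit(powder_average(s, p))
#' coef(fit)
#' @export
divide_fit <- function(powder, restarts = 5, seed = 1, moment_start = TRUE,
                       ftol = 1e-10) {
  stopifnot(inherits(powder, "powder_signal"))
  tab <- as.data.frame(powder)
  if (nrow(tab) < 4 || length(unique(tab$b)) < 2 ||
      length(unique(round(tab$b_delta, 6))) < 2)
    stop("need at least 4 shells spanning >= 2 b-values and >= 2 b-tensor shapes")
  w <- sqrt(tab$n)
  resid_fun <- function(theta) {
    S0 <- exp(theta[1]); MD <- exp(theta[2])
    pred <- eq1_signal(tab$b, tab$b_delta, S0, MD, theta[3], theta[4])
    bad <- !is.finite(pred)
    if (any(bad)) {
      mu2 <- theta[3] + tab$b_delta^2 * theta[4]
      viol <- pmax(-(1 + tab$b * mu2 / MD), 0)
      pred[bad] <- 0
      r <- w * (tab$S_mean - pred)
      r[bad] <- r[bad] + 1e3 * (1 + viol[bad])
      return(r)
    }
    w * (tab$S_mean - pred)
  }

  starts <- list()
  if (moment_start) starts <- list(divide_moment_start(tab, w))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  s0_scale <- max(tab$S_mean)
  for (r in seq_len(restarts)) {
    starts[[length(starts) + 1L]] <- c(
      log(s0_scale * stats::runif(1, 0.8, 1.2)),
      log(stats::runif(1, 0.1, 3)),
      stats::runif(1, -0.2, 1.5),
      stats::runif(1, -0.2, 1.5))
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())

  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           ftol = ftol, ptol = 1e-12, maxiter = 500)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }

  if (is.null(best)) {
    cf <- c(S0 = NaN, MD = NaN, VI = NaN, VA = NaN)
    out <- list(coefficients = cf, MKI = NaN, MKA = NaN, uFA = NaN,
                uFA_defined = FALSE, converged = FALSE, sse = NaN,
                powder = powder, weights = w, n_starts = length(starts))
  } else {
    th <- unname(best$fit$par)
    cf <- c(S0 = exp(th[1]), MD = exp(th[2]), VI = th[3], VA = th[4])
    out <- list(
      coefficients = cf,
      MKI = 3 * cf[["VI"]] / cf[["MD"]]^2,
      MKA = 3 * cf[["VA"]] / cf[["MD"]]^2,
      uFA = mufa(cf[["MD"]], cf[["VI"]], cf[["VA"]]),
      uFA_defined = cf[["VA"]] > 0,
      converged = TRUE, sse = best$sse,
      powder = powder, weights = w, n_starts = length(starts))
  }
  class(out) <- "divide_fit"
  out
}

# cumulant (moment) starting point: weighted quadratic regression of log
# signal in b, shared intercept and slope, per-shape curvature
divide_moment_start <- function(tab, w) {
  ok <- tab$S_mean > 0
  t2 <- tab[ok, ]
  y <- log(t2$S_mean)
  bd2 <- t2$b_delta^2
  X <- cbind(1, -t2$b, t2$b^2 / 2, bd2 * t2$b^2 / 2)  # logS0, MD, VI, VA
  cf <- tryCatch(stats::lm.wfit(X, y, w[ok]^2)$coefficients,
                 error = function(e) rep(NA_real_, 4))
  if (any(!is.finite(cf))) return(c(log(max(tab$S_mean)), log(1), 0.1, 0.5))
  unname(c(cf[1], log(min(max(cf[2], 0.05), 4)), cf[3], cf[4]))
}

#' @export
print.divide_fit <- function(x, digits = 4, ...) {
  cat("DIVIDE gamma-model fit\n")
  if (!x$converged) {
    cat("  did not converge from any starting point\n")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat(sprintf("  S0 = %.*g, MD = %.*g um^2/ms\n", digits, cf[["S0"]],
              digits, cf[["MD"]]))
  cat(sprintf("  V_I = %.*g, V_A = %.*g um^4/ms^2\n", digits, cf[["VI"]],
              digits, cf[["VA"]]))
  cat(sprintf("  MK_I = %.*g, MK_A = %.*g, uFA = %.*g%s\n",
              digits, x$MKI, digits, x$MKA, digits, x$uFA,
              if (!x$uFA_defined) " (V_A <= 0: uFA set to 0)" else ""))
  invisible(x)
}

#' @export
coef.divide_fit <- function(object, ...) object$coefficients

#' @export
fitted.divide_fit <- function(object, ...) {
  cf <- object$coefficients
  eq1_signal(object$powder$b, object$powder$b_delta,
             cf[["S0"]], cf[["MD"]], cf[["VI"]], cf[["VA"]])
}

#' @export
residuals.divide_fit <- function(object, type = c("response", "weighted"), ...) {
  type <- match.arg(type)
  r <- object$powder$S_mean - fitted(object)
  if (type == "weighted") r <- r * object$weights
  r
}

#' Predict powder-averaged signal from a fitted DIVIDE model
#'
#' @param object a \code{divide_fit}.
#' @param newdata data frame with columns \code{b} and \code{b_delta};
#'   defaults to the fitted shells.
#' @param ... unused.
#' @export
predict.divide_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(fitted(object))
  cf <- object$coefficients
  eq1_signal(newdata$b, newdata$b_delta,
             cf[["S0"]], cf[["MD"]], cf[["VI"]], cf[["VA"]])
}

#' @export
summary.divide_fit <- function(object, ...) {
  out <- list(
    coefficients = object$coefficients,
    derived = c(MKI = object$MKI, MKA = object$MKA, uFA = object$uFA),
    converged = object$converged, sse = object$sse,
    n_shells = nrow(object$powder),
    n_samples = sum(object$powder$n),
    residuals = if (object$converged) residuals(object) else NULL)
  class(out) <- "summary.divide_fit"
  out
}

#' @export
print.summary.divide_fit <- function(x, digits = 4, ...) {
  cat("DIVIDE gamma-model fit:",
      x$n_shells, "shells from", x$n_samples, "signal samples\n")
  print(round(c(x$coefficients, x$derived), digits))
  if (x$converged)
    cat(sprintf("weighted SSE: %.3g; residual range: [%.3g, %.3g]\n",
                x$sse, min(x$residuals), max(x$residuals)))
  else cat("fit did not converge\n")
  invisible(x)
}

#' Simulate noisy powder-averaged data from a fitted DIVIDE model
#'
#' Regenerates per-sample signals at each fitted shell from the model
#' prediction, adds Rician noise at the requested SNR (defined at S0), and
#' powder-averages back to shell means - the parametric-bootstrap analogue of
#' the acquisition.
#'
#' @param object a converged \code{divide_fit}.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param snr signal-to-noise ratio at S0 (default 30).
#' @param ... unused.
#' @return a list of \code{nsim} \code{powder_signal} objects.
#' @export
simulate.divide_fit <- function(object, nsim = 1, seed = NULL, snr = 30, ...) {
  stopifnot(object$converged)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  pred <- fitted(object)
  n <- object$powder$n
  S0 <- object$coefficients[["S0"]]
  lapply(seq_len(nsim), function(i) {
    S_mean <- vapply(seq_along(pred), function(k) {
      mean(add_rice_noise(rep(pred[k], n[k]), snr = snr, S0 = S0))
    }, 1)
    powder_signal(object$powder$b, object$powder$b_delta, S_mean, n)
  })
}

#' Plot a fitted DIVIDE model
#'
#' Shell means (points) and fitted gamma-model curves (lines) against the
#' b-value, one curve per b-tensor shape, on a log signal axis. The gap that
#' opens between the LTE and STE curves with increasing b is the signature of
#' microscopic anisotropy.
#'
#' @param x a converged \code{divide_fit}.
#' @param ... passed to \code{plot}.
#' @export
plot.divide_fit <- function(x, ...) {
  stopifnot(x$converged)
  tab <- as.data.frame(x$powder)
  bb <- seq(0, max(tab$b), length.out = 100)
  cf <- x$coefficients
  shapes <- unique(tab[, c("b_delta", "shape")])
  cols <- stats::setNames(seq_len(nrow(shapes)) + 1, shapes$shape)
  graphics::plot(tab$b, tab$S_mean, log = "y",
                 xlab = "b [ms/um^2]", ylab = "powder-averaged signal",
                 pch = 19, col = cols[tab$shape], ...)
  for (i in seq_len(nrow(shapes))) {
    graphics::lines(bb, eq1_signal(bb, shapes$b_delta[i], cf[["S0"]],
                                   cf[["MD"]], cf[["VI"]], cf[["VA"]]),
                    col = cols[shapes$shape[i]])
  }
  graphics::legend("topright", legend = shapes$shape, col = cols, lty = 1,
                   pch = 19, bty = "n")
  invisible(x)
}

#' Voxel-wise DIVIDE fit of a 4D volume
#'
#' Powder-averages and fits every voxel of a 4D data array acquired with the
#' given protocol, returning 3D parameter maps.
#'
#' @param data 4D numeric array (x, y, z, volume).
#' @param protocol a \code{divide_protocol} aligned with the 4th axis.
#' @param mask optional logical 3D array of voxels to fit.
#' @param restarts,seed,... passed to \code{\link{divide_fit}}.
#' @return named list of 3D arrays: \code{s0}, \code{md}, \code{vi},
#'   \code{va}, \code{mki}, \code{mka}, \code{ufa}, \code{converged}.
#' @export
divide_fit_image <- function(data, protocol, mask = NULL, restarts = 5,
                             seed = 1, ...) {
  stopifnot(length(dim(data)) == 4L)
  dims <- dim(data)
  if (dims[4] != protocol$n_samples)
    stop("4th axis length ", dims[4], " does not match protocol (",
         protocol$n_samples, " samples)")
  if (is.null(mask)) mask <- array(TRUE, dims[1:3])
  stopifnot(all(dim(mask) == dims[1:3]))
  maps <- c("s0", "md", "vi", "va", "mki", "mka", "ufa", "converged")
  out <- stats::setNames(
    replicate(length(maps), array(NA_real_, dims[1:3]), simplify = FALSE), maps)
  vox <- which(mask)
  nvox <- prod(dims[1:3])
  flat <- matrix(data, nrow = nvox)
  for (v in vox) {
    pw <- powder_average(flat[v, ], protocol)
    f <- divide_fit(pw, restarts = restarts, seed = seed, ...)
    cf <- f$coefficients
    out$s0[v] <- cf[["S0"]]; out$md[v] <- cf[["MD"]]
    out$vi[v] <- cf[["VI"]]; out$va[v] <- cf[["VA"]]
    out$mki[v] <- f$MKI; out$mka[v] <- f$MKA; out$ufa[v] <- f$uFA
    out$converged[v] <- as.numeric(f$converged)
  }
  out
}
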