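#' SNR maps and summary fractions from repeated spherical encoding
#'
#' Because the spherical (STE) shells are acquired as repeats of one and the
#' same encoding, the per-voxel SNR at each b-value can be estimated as the
#' ratio of the mean to the standard deviation of the STE signal across
#' repeats. The summary fractions Q3 and Q6 report the proportion of masked
#' voxels with SNR above 3 and above 6 at the highest b-value; voxels with
#' mean diffusivity of 1.5 um^2/ms or more are excluded from the mask to
#' avoid regions dominated by CSF. Voxels with (near) zero variance across
#' repeats are flagged infinite and excluded from the fractions.
#'
#' @param data 4D signal array aligned with the protocol entries.
#' @param protocol a \code{divide_protocol} (must contain STE shells with at
#'   least two repeats each).
#' @param md_map 3D mean diffusivity map, um^2/ms, used for the mask.
#' @param md_max mask threshold: include voxels with MD < \code{md_max}
#'   (default 1.5).
#' @return an object of class \code{snr_report}: list with \code{snr_maps}
#'   (one 3D array per STE b-value, named by b), \code{Q3}, \code{Q6}
#'   (fractions in [0, 1] at the highest b), \code{b_highest}, and
#'   \code{mask}.
#' @export
snr_map <- function(data, protocol, md_map, md_max = 1.5) {
  stopifnot(length(dim(data)) == 4L, inherits(protocol, "divide_protocol"))
  dims <- dim(data)
  stopifnot(all(dim(md_map) == dims[1:3]))
  e <- protocol$entries
  ste_b <- sort(unique(e$b[e$shape == "STE"]))
  if (!length(ste_b)) stop("protocol contains no STE shells")
  flat <- matrix(data, nrow = prod(dims[1:3]))
  snr_maps <- list()
  for (b in ste_b) {
    idx <- which(e$shape == "STE" & e$b == b)
    if (length(idx) < 2)
      stop("need >= 2 STE repeats at b = ", b, " to estimate SNR")
    m <- rowMeans(flat[, idx, drop = FALSE])
    s <- apply(flat[, idx, drop = FALSE], 1, stats::sd)
    s <- pmax(s, 0)
    snr <- ifelse(s <= 1e-12 * abs(m), Inf, m / s)
    snr_maps[[as.character(b)]] <- array(snr, dims[1:3])
  }
  b_hi <- max(ste_b)
  mask <- md_map < md_max
  snr_hi <- snr_maps[[as.character(b_hi)]]
  usable <- mask & is.finite(snr_hi)
  n_use <- sum(usable)
  Q3 <- if (n_use) sum(snr_hi[usable] > 3) / n_use else NA_real_
  Q6 <- if (n_use) sum(snr_hi[usable] > 6) / n_use else NA_real_
  structure(list(snr_maps = snr_maps, Q3 = Q3, Q6 = Q6,
                 b_highest = b_hi, mask = mask),
            class = "snr_report")
}

#' @export
print.snr_report <- function(x, ...) {
  cat(sprintf(
    "SNR report: Q3 = %.1f%%, Q6 = %.1f%% at b = %g ms/um^2 (%d masked voxels)\n",
    100 * x$Q3, 100 * x$Q6, x$b_highest, sum(x$mask)))
  invisible(x)
}

#' Normalized signal attenuation at b = 2 ms/um^2
#'
#' The powder-averaged signal at the highest shell, normalized by the fitted
#' S0 and reported in percent: A(L) for linear and A(S) for spherical
#' encoding. For purely Gaussian (monoexponential) diffusion the two agree;
#' microscopic anisotropy lifts A(L) above A(S).
#'
#' @param powder a \code{powder_signal} containing b = 2 shells for both
#'   shapes.
#' @param S0 signal at b = 0 (e.g. from \code{\link{divide_fit}}).
#' @param b_ref the shell b-value to report (default 2 ms/um^2).
#' @return named vector \code{c(A_L, A_S)} in percent.
#' @export
attenuation_summary <- function(powder, S0, b_ref = 2) {
  stopifnot(inherits(powder, "powder_signal"), S0 > 0)
  tab <- as.data.frame(powder)
  pick <- function(shape) {
    i <- which(abs(tab$b - b_ref) < 1e-9 & tab$shape == shape)
    if (!length(i))
      stop("powder signal lacks a ", shape, " shell at b = ", b_ref)
    tab$S_mean[i]
  }
  c(A_L = 100 * pick("LTE") / S0, A_S = 100 * pick("STE") / S0)
}

#' Test-retest repeatability of parameter maps
#'
#' Computes the voxel-wise difference \eqn{\Delta X = X_1 - X_2} between two
#' co-registered acquisitions for each parameter map, restricted to a tissue
#' mask (by default voxels with uFA > 0.7 and MD < 1.5 um^2/ms, to avoid the
#' misaligned brain periphery and CSF partial volume). Reports the mean
#' (bias) and standard deviation (precision) of each difference distribution
#' together with Bland-Altman summaries (voxel-wise average vs difference,
#' with the mean and +/- 2 SD reference lines).
#'
#' @param maps1,maps2 named lists of 3D parameter maps from the two
#'   acquisitions (same names and dimensions).
#' @param mufa_map,md_map 3D maps used to build the inclusion mask.
#' @param mufa_min,md_max mask thresholds (defaults 0.7 and 1.5).
#' @return an object of class \code{repeatability_report}: list with
#'   \code{stats} (data frame: parameter, mean, sd, n), \code{mask}, and
#'   \code{bland_altman} (per parameter: data frame of avg/diff plus
#'   \code{lines = c(mean, lower, upper)}).
#' @export
repeatability <- function(maps1, maps2, mufa_map, md_map,
                          mufa_min = 0.7, md_max = 1.5) {
  stopifnot(is.list(maps1), is.list(maps2),
            identical(sort(names(maps1)), sort(names(maps2))))
  dims <- dim(maps1[[1]])
  for (nm in names(maps1))
    if (!all(dim(maps1[[nm]]) == dims) || !all(dim(maps2[[nm]]) == dims))
      stop("map dimensions differ between acquisitions for '", nm, "'")
  stopifnot(all(dim(mufa_map) == dims), all(dim(md_map) == dims))
  mask <- mufa_map > mufa_min & md_map < md_max & is.finite(mufa_map) &
    is.finite(md_map)
  stats_rows <- list()
  ba <- list()
  for (nm in names(maps1)) {
    x1 <- maps1[[nm]][mask]
    x2 <- maps2[[nm]][mask]
    ok <- is.finite(x1) & is.finite(x2)
    d <- x1[ok] - x2[ok]
    m <- mean(d)
    s <- if (length(d) > 1) stats::sd(d) else 0
    stats_rows[[nm]] <- data.frame(parameter = nm, mean = m, sd = s,
                                   n = length(d))
    ba[[nm]] <- list(
      points = data.frame(avg = (x1[ok] + x2[ok]) / 2, diff = d),
      lines = c(mean = m, lower = m - 2 * s, upper = m + 2 * s))
  }
  structure(list(stats = do.call(rbind, c(stats_rows, make.row.names = FALSE)),
                 mask = mask, bland_altman = ba),
            class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, digits = 4, ...) {
  cat("test-retest repeatability (masked voxels:", sum(x$mask), ")\n")
  tab <- x$stats
  tab$mean <- signif(tab$mean, digits)
  tab$sd <- signif(tab$sd, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
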