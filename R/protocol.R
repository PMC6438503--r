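#' Build a tensor-valued diffusion encoding protocol
#'
#' Constructs the sampling scheme used for diffusional variance decomposition:
#' shells at given b-values, each acquired with both linear (LTE) and
#' spherical (STE) tensor encoding. LTE shells use electrostatic-repulsion
#' direction sets; STE is assumed rotation invariant and is repeated rather
#' than rotated (an option rotates it anyway for robustness studies). The
#' default scheme uses b = 0.1, 0.7, 1.4 and 2 ms/um^2 with 6, 6, 12 and 16
#' LTE directions and equally many STE repeats: 80 samples in total. The
#' sampling order is volume-interleaved (round-robin over shell/shape groups)
#' to spread gradient load evenly over the acquisition, and the total
#' acquisition time is \code{T_tot = n_samples * TR}.
#'
#' @param TR repetition time, ms.
#' @param TE echo time, ms (bookkeeping only; not used in any computation).
#' @param b shell b-values, ms/um^2.
#' @param n_lte number of LTE directions per shell.
#' @param n_ste number of STE repeats per shell.
#' @param interleaved order entries volume-interleaved (default) or grouped
#'   shell by shell.
#' @return an object of class \code{divide_protocol}: a list with
#'   \code{entries} (data frame with b, b_delta, shape, shell, index and
#'   direction), \code{btensors} (list of \code{btensor}), \code{TR},
#'   \code{TE}, \code{n_samples} and \code{T_tot} (seconds).
#' @examples
#' p <- build_divide_protocol(TR = 5000, TE = 115)
#' p$n_samples   # 80
#' p$T_tot      # 400 s = 6:40
#' @export
build_divide_protocol <- function(TR, TE,
                                  b = c(0.1, 0.7, 1.4, 2.0),
                                  n_lte = c(6, 6, 12, 16),
                                  n_ste = c(6, 6, 12, 16),
                                  interleaved = TRUE) {
  stopifnot(TR > 0, TE > 0, length(n_lte) == length(b),
            length(n_ste) == length(b), all(b >= 0))
  rows <- list()
  for (s in seq_along(b)) {
    if (n_lte[s] > 0) {
      dirs <- get_direction_set(n_lte[s])
      rows[[length(rows) + 1L]] <- data.frame(
        b = b[s], b_delta = 1, shape = "LTE", shell = s,
        index = seq_len(n_lte[s]),
        x = dirs[, 1], y = dirs[, 2], z = dirs[, 3])
    }
    if (n_ste[s] > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        b = b[s], b_delta = 0, shape = "STE", shell = s,
        index = seq_len(n_ste[s]), x = 0, y = 0, z = 1)
    }
  }
  entries <- do.call(rbind, rows)
  if (interleaved) entries <- entries[interleave_order(entries$shell, entries$shape), ]
  rownames(entries) <- NULL
  btensors <- lapply(seq_len(nrow(entries)), function(i) {
    e <- entries[i, ]
    make_btensor(e$shape, e$b, c(e$x, e$y, e$z))
  })
  structure(list(
    entries = entries, btensors = btensors,
    TR = TR, TE = TE,
    n_samples = nrow(entries),
    T_tot = nrow(entries) * TR / 1000), class = "divide_protocol")
}

#' @export
print.divide_protocol <- function(x, ...) {
  cat(sprintf(
    "DIVIDE protocol: %d samples, TR = %g ms, TE = %g ms, T_tot = %g s (%d:%02d)\n",
    x$n_samples, x$TR, x$TE, x$T_tot,
    floor(x$T_tot / 60), round(x$T_tot %% 60)))
  tab <- stats::aggregate(index ~ b + shape, data = x$entries, FUN = length)
  names(tab)[3] <- "n"
  print(tab[order(tab$b, tab$shape), ], row.names = FALSE)
  invisible(x)
}

#' Volume-interleaved ordering of protocol entries
#'
#' Returns a permutation that cycles round-robin across the (shell, shape)
#' groups, visiting groups in order of ascending b-value with LTE before STE,
#' so that consecutive samples of the same shell and shape are minimized.
#'
#' @param shell integer shell label per entry.
#' @param shape shape label per entry (e.g. \code{"LTE"}/\code{"STE"}).
#' @return an integer permutation of \code{seq_along(shell)}.
#' @export
interleave_order <- function(shell, shape) {
  stopifnot(length(shell) == length(shape))
  key <- paste(shell, shape, sep = "/")
  grp_order <- unique(key[order(shell, shape)])
  pools <- lapply(grp_order, function(k) which(key == k))
  out <- integer(0)
  repeat {
    nonempty <- vapply(pools, length, 1L) > 0
    if (!any(nonempty)) break
    for (gi in seq_along(pools)) {
      if (length(pools[[gi]])) {
        out <- c(out, pools[[gi]][1])
        pools[[gi]] <- pools[[gi]][-1]
      }
    }
  }
  out
}

#' Write / read a protocol as a b-tensor table plus JSON sidecar
#'
#' The b-tensor table holds one row per volume with nine whitespace-separated
#' row-major tensor components in ms/um^2 (comment lines start with
#' \code{#}). The JSON sidecar records TR, TE, shells, counts and the
#' ordering labels.
#'
#' @param protocol a \code{divide_protocol}.
#' @param stem output path stem; writes \code{<stem>.btens} and
#'   \code{<stem>.json}.
#' @rdname protocol_io
#' @export
write_protocol <- function(protocol, stem) {
  stopifnot(inherits(protocol, "divide_protocol"))
  write_btens(protocol$btensors, paste0(stem, ".btens"))
  side <- list(
    TR_ms = protocol$TR, TE_ms = protocol$TE,
    n_samples = protocol$n_samples, T_tot_s = protocol$T_tot,
    shells = protocol$entries$shell, shape = protocol$entries$shape,
    b = protocol$entries$b, index = protocol$entries$index)
  jsonlite::write_json(side, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @param stem path stem as used by \code{write_protocol}.
#' @rdname protocol_io
#' @export
read_protocol <- function(stem) {
  btensors <- read_btens(paste0(stem, ".btens"))
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  shapes <- btensor_table(btensors)
  entries <- data.frame(
    b = side$b, b_delta = shapes$b_delta, shape = side$shape,
    shell = side$shells, index = side$index,
    x = shapes$x, y = shapes$y, z = shapes$z)
  structure(list(
    entries = entries, btensors = btensors,
    TR = side$TR_ms, TE = side$TE_ms,
    n_samples = length(btensors),
    T_tot = length(btensors) * side$TR_ms / 1000), class = "divide_protocol")
}

# per-tensor (b, b_delta, axis) summary table
btensor_table <- function(btensors) {
  sh <- lapply(btensors, btensor_shape, strict = FALSE)
  data.frame(
    b = vapply(sh, `[[`, 1, "b"),
    b_delta = vapply(sh, `[[`, 1, "b_delta"),
    x = vapply(sh, function(s) s$axis[1], 1),
    y = vapply(sh, function(s) s$axis[2], 1),
    z = vapply(sh, function(s) s$axis[3], 1))
}
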