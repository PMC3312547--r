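#' Adjacent-pair stimulation and measurement protocol
#'
#' Current is driven through neighbouring electrode pairs in rotation:
#' injection \eqn{\ell} drives the pair \eqn{(\ell, \ell+1)} (cyclic), and for
#' each injection the voltage is measured on every adjacent electrode pair not
#' containing a drive electrode, ordered starting from the pair that follows
#' the drive pair. This yields \eqn{N(N-3)} measurements per frame; with 16
#' electrodes, 16 x 13 = 208.
#'
#' @param n_el Number of electrodes (>= 4).
#' @param amplitude_mA Drive current amplitude in mA (default 1 mA).
#' @return An `eit_protocol`: drive pairs, per-injection measurement pairs,
#'   measurement table and count.
#' @export
adjacent_protocol <- function(n_el = 16L, amplitude_mA = 1) {
  n_el <- as.integer(n_el)
  if (n_el < 4L) stop("adjacent protocol needs at least 4 electrodes")
  wrap <- function(k) (k - 1L) %% n_el + 1L
  drive <- cbind(seq_len(n_el), wrap(seq_len(n_el) + 1L))
  meas <- vector("list", n_el)
  rows <- vector("list", n_el)
  for (l in seq_len(n_el)) {
    m <- wrap(l + 1L + seq_len(n_el - 3L))
    meas[[l]] <- matrix(c(m, wrap(m + 1L)), ncol = 2L)
    rows[[l]] <- cbind(injection = l, m_pos = m, m_neg = wrap(m + 1L))
  }
  structure(list(
    n_el = n_el,
    amplitude_mA = amplitude_mA,
    drive = drive,
    meas = meas,
    table = do.call(rbind, rows),
    n_measurements = n_el * (n_el - 3L)
  ), class = "eit_protocol")
}

#' @export
print.eit_protocol <- function(x, ...) {
  cat("EIT adjacent protocol:", x$n_el, "electrodes,",
      x$n_measurements, "measurements,", x$amplitude_mA, "mA drive\n")
  invisible(x)
}

protocol_identical <- function(a, b) {
  identical(a$n_el, b$n_el) && identical(a$table, b$table) &&
    isTRUE(all.equal(a$amplitude_mA, b$amplitude_mA))
}
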