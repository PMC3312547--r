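# Sensitivity (Jacobian) of the adjacent-protocol measurements with respect
# to per-element conductivity, by the adjoint-field method.
#
# For measurement m = (drive pair d, measurement pair g), with w_l the CEM
# field driven by a unit current through adjacent pair (l, l+1),
#
#   dV_m / dsigma_k = -I_drive * int_k grad w_d . grad w_g dV ,
#
# exact for the discrete P1 system (gradients are constant per element).
# Under the adjacent protocol the measurement pairs coincide with the drive
# pairs, so all 16 adjoint fields come from one factorization.

#' Compute the conductivity sensitivity matrix
#'
#' Assembles the CEM system on the (coarse) inverse mesh at the reference
#' conductivity and returns the n_measurements x n_elements Jacobian of the
#' measurement frame with respect to per-element conductivity, scaled to the
#' protocol's drive amplitude (volts per S/m).
#'
#' @param inverse_mesh `eit_mesh` used for reconstruction (distinct from the
#'   forward mesh, to avoid the inverse crime).
#' @param sigma_ref Reference `eit_sigma` on `inverse_mesh`.
#' @param electrodes Electrode set of `inverse_mesh`.
#' @param protocol An `eit_protocol`.
#' @param gauge Passed to [assemble_cem()].
#' @return An `eit_jacobian` with the dense matrix `J` and its provenance.
#' @export
compute_jacobian <- function(inverse_mesh, sigma_ref, electrodes, protocol,
                             gauge = "sum") {
  system <- assemble_cem(inverse_mesh, sigma_ref, electrodes, gauge = gauge)
  n_el <- protocol$n_el
  currents <- matrix(0, n_el, n_el)
  for (l in seq_len(n_el)) {
    currents[protocol$drive[l, 1L], l] <- 1
    currents[protocol$drive[l, 2L], l] <- -1
  }
  sol <- solve_patterns(system, currents)       # unit-current fields
  eg <- system$gradients
  elems <- inverse_mesh$elements
  ne <- nrow(elems)
  gx <- gy <- gz <- matrix(0, ne, n_el)
  for (l in seq_len(n_el)) {
    u <- sol$u[, l]
    gx[, l] <- u[elems[, 1]] * eg$g[[1]][, 1] + u[elems[, 2]] * eg$g[[2]][, 1] +
               u[elems[, 3]] * eg$g[[3]][, 1] + u[elems[, 4]] * eg$g[[4]][, 1]
    gy[, l] <- u[elems[, 1]] * eg$g[[1]][, 2] + u[elems[, 2]] * eg$g[[2]][, 2] +
               u[elems[, 3]] * eg$g[[3]][, 2] + u[elems[, 4]] * eg$g[[4]][, 2]
    gz[, l] <- u[elems[, 1]] * eg$g[[1]][, 3] + u[elems[, 2]] * eg$g[[2]][, 3] +
               u[elems[, 3]] * eg$g[[3]][, 3] + u[elems[, 4]] * eg$g[[4]][, 3]
  }
  I_amp <- protocol$amplitude_mA * 1e-3
  tab <- protocol$table
  J <- matrix(0, nrow(tab), ne)
  for (m in seq_len(nrow(tab))) {
    d <- tab[m, "injection"]; g <- tab[m, "m_pos"]
    J[m, ] <- -I_amp * eg$vol *
      (gx[, d] * gx[, g] + gy[, d] * gy[, g] + gz[, d] * gz[, g])
  }
  structure(list(J = J, protocol = protocol, sigma_ref = sigma_ref,
                 n_elements = ne, volumes = inverse_mesh$volumes,
                 mesh = inverse_mesh, electrodes = electrodes, gauge = gauge,
                 cache = new.env(parent = emptyenv())),
            class = "eit_jacobian")
}

#' @export
print.eit_jacobian <- function(x, ...) {
  cat("EIT sensitivity matrix:", nrow(x$J), "measurements x",
      ncol(x$J), "elements\n")
  invisible(x)
}
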