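# Complete electrode model (CEM) forward solver.
#
# Unknowns are the vertex potentials u plus the N_el electrode voltages U.
# The weak form gives the symmetric block system
#
#   [ K + sum_l M_l / z_l ,  -S / z ] [u]   [0]
#   [      -S^T / z       ,  D / z  ] [U] = [I]
#
# with K the sigma-weighted P1 stiffness matrix, M_l the facet mass matrix of
# electrode patch l, S the facet load vectors, and D = diag(|e_l|). The system
# is singular up to an additive constant; the default gauge restricts U to the
# zero-sum subspace (sum_l U_l = 0), a grounded-node gauge (potential pinned
# at the bottom-centre vertex) is available for fidelity to tank practice.
# Difference frames are gauge invariant.

# Per-element P1 shape-function gradients and volumes.
element_gradients <- function(mesh) {
  v <- mesh$vertices; e <- mesh$elements
  p1 <- v[e[, 1L], , drop = FALSE]
  a <- v[e[, 2L], , drop = FALSE] - p1
  b <- v[e[, 3L], , drop = FALSE] - p1
  d <- v[e[, 4L], , drop = FALSE] - p1
  cross <- function(u, w) cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                                u[, 1] * w[, 2] - u[, 2] * w[, 1])
  det6 <- rowSums(a * cross(b, d))       # 6 * signed volume (> 0 by build)
  g2 <- cross(b, d) / det6
  g3 <- cross(d, a) / det6
  g4 <- cross(a, b) / det6
  g1 <- -(g2 + g3 + g4)
  list(g = list(g1, g2, g3, g4), vol = det6 / 6)
}

#' Assemble the complete-electrode-model FEM system
#'
#' Builds the symmetric CEM operator for a mesh, conductivity field and
#' electrode set, applies the gauge, and factorizes it (sparse Cholesky). The
#' factorization is reused across all injections of a protocol.
#'
#' @param mesh An `eit_mesh`.
#' @param sigma An `eit_sigma` conductivity field on the same mesh.
#' @param electrodes The `eit_electrodes` set of the mesh.
#' @param gauge `"sum"` (electrode voltages sum to zero, the default) or
#'   `"node"` (potential pinned at the vertex nearest the bottom centre).
#' @return An `eit_system` holding the factorized operator.
#' @export
assemble_cem <- function(mesh, sigma, electrodes, gauge = c("sum", "node")) {
  gauge <- match.arg(gauge)
  if (length(sigma$values) != nrow(mesh$elements))
    stop("conductivity field does not match the mesh")
  if (any(sigma$values <= 0)) stop("conductivity must be positive")
  n <- nrow(mesh$vertices)
  n_el <- length(electrodes)

  eg <- element_gradients(mesh)
  sv <- sigma$values * eg$vol
  # stiffness triplets: 16 blocks of (i, j, sigma V g_i . g_j)
  ii <- jj <- vector("list", 16L); xx <- vector("list", 16L)
  k <- 0L
  for (i in 1:4) for (j in 1:4) {
    k <- k + 1L
    ii[[k]] <- mesh$elements[, i]
    jj[[k]] <- mesh$elements[, j]
    xx[[k]] <- sv * rowSums(eg$g[[i]] * eg$g[[j]])
  }
  ii <- unlist(ii); jj <- unlist(jj); xx <- unlist(xx)

  # electrode surface terms
  for (l in seq_len(n_el)) {
    el <- electrodes[[l]]
    if (nrow(el$faces) == 0L || sum(el$areas) <= 0)
      stop("electrode ", l, " has zero area")
    zc <- el$z_c
    A <- el$areas
    for (i in 1:3) for (j in 1:3) {
      ii <- c(ii, el$faces[, i]); jj <- c(jj, el$faces[, j])
      xx <- c(xx, A / (12 * zc) * (1 + (i == j)))
    }
    # coupling u - U (both triangles) and electrode diagonal
    nf3 <- 3L * nrow(el$faces)
    ii <- c(ii, as.vector(el$faces), rep(n + l, nf3), n + l)
    jj <- c(jj, rep(n + l, nf3), as.vector(el$faces), n + l)
    xx <- c(xx, rep(-A / (3 * zc), 6L), sum(A) / zc)
  }
  A_full <- Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                                 dims = c(n + n_el, n + n_el), symmetric = FALSE)
  A_full <- Matrix::forceSymmetric((A_full + Matrix::t(A_full)) / 2, uplo = "U")

  if (gauge == "sum") {
    B <- rbind(Matrix::Diagonal(n_el - 1L),
               Matrix::Matrix(-1, 1L, n_el - 1L, sparse = TRUE))
    P <- Matrix::bdiag(Matrix::Diagonal(n), B)
    keep <- NULL
  } else {
    v <- mesh$vertices
    ground <- which.min(v[, 1]^2 + v[, 2]^2 + 1e3 * v[, 3]^2)
    keep <- setdiff(seq_len(n + n_el), ground)
    P <- Matrix::sparseMatrix(i = keep, j = seq_along(keep), x = 1,
                              dims = c(n + n_el, length(keep)))
    B <- NULL
  }
  Ared <- Matrix::forceSymmetric(Matrix::t(P) %*% A_full %*% P, uplo = "U")
  fac <- tryCatch(Matrix::Cholesky(Ared, LDL = FALSE, perm = TRUE),
                  error = function(e)
                    stop("CEM system not positive definite after gauge fixing: ",
                         conditionMessage(e)))
  structure(list(factor = fac, P = P, n_vert = n, n_el = n_el,
                 gauge = gauge, mesh = mesh, sigma = sigma,
                 electrodes = electrodes, gradients = eg),
            class = "eit_system")
}

#' @export
print.eit_system <- function(x, ...) {
  cat("Assembled CEM system:", x$n_vert, "vertex potentials +", x$n_el,
      "electrode voltages; gauge:", x$gauge, "\n")
  invisible(x)
}

# Solve the CEM system for a matrix of electrode current patterns
# (n_el x n_patterns, amperes). Returns u (n x k) and U (n_el x k).
solve_patterns <- function(system, currents) {
  n <- system$n_vert; n_el <- system$n_el
  rhs_full <- rbind(Matrix::Matrix(0, n, ncol(currents), sparse = TRUE),
                    Matrix::Matrix(currents, sparse = TRUE))
  rhs <- Matrix::t(system$P) %*% rhs_full
  sol_red <- Matrix::solve(system$factor, rhs, system = "A")
  sol <- as.matrix(system$P %*% sol_red)
  list(u = sol[seq_len(n), , drop = FALSE],
       U = sol[n + seq_len(n_el), , drop = FALSE])
}

#' Solve the forward problem for a stimulation protocol
#'
#' Runs every injection of the protocol through the factorized CEM system and
#' extracts the measurement frame (electrode-pair voltage differences).
#'
#' @param system An `eit_system` from [assemble_cem()].
#' @param protocol An `eit_protocol`.
#' @return A list with `solution` (interior potentials `u`, electrode
#'   voltages `U`, one column per injection) and `frame` (an `eit_frame` of
#'   `n_measurements` voltages).
#' @export
solve_forward <- function(system, protocol) {
  n_el <- system$n_el
  if (protocol$n_el != n_el)
    stop("protocol electrode count does not match the system")
  I_amp <- protocol$amplitude_mA * 1e-3
  currents <- matrix(0, n_el, n_el)
  for (l in seq_len(n_el)) {
    currents[protocol$drive[l, 1L], l] <- I_amp
    currents[protocol$drive[l, 2L], l] <- -I_amp
  }
  sol <- solve_patterns(system, currents)
  tab <- protocol$table
  values <- sol$U[cbind(tab[, "m_pos"], tab[, "injection"])] -
            sol$U[cbind(tab[, "m_neg"], tab[, "injection"])]
  frame <- structure(list(values = values, protocol = protocol, noise = NULL),
                     class = "eit_frame")
  list(solution = structure(list(u = sol$u, U = sol$U, protocol = protocol),
                            class = "eit_forward_solution"),
       frame = frame)
}

#' @export
print.eit_frame <- function(x, ...) {
  cat("EIT measurement frame:", length(x$values), "voltages;",
      if (is.null(x$noise)) "noise-free" else
        paste0("noise level ", x$noise$relative_level,
               " (seed ", x$noise$seed, ")"), "\n")
  invisible(x)
}

#' Gaussian measurement-noise model
#'
#' Additive zero-mean Gaussian noise at a relative level of the signal. With
#' the default `"proportional"` scaling each channel's standard deviation is
#' `relative_level` times that channel's reference voltage magnitude (a
#' measurement-accuracy model; 5e-4 is 0.05 percent of the signal). The
#' `"frame_max"` alternative uses one common standard deviation,
#' `relative_level` times the peak reference voltage (white noise across the
#' frame).
#'
#' @param relative_level Noise standard deviation relative to the reference
#'   voltage (dimensionless, >= 0).
#' @param seed RNG seed for reproducible draws.
#' @param scaling `"proportional"` (per-channel) or `"frame_max"`.
#' @return An `eit_noise_model`.
#' @export
noise_model <- function(relative_level = 5e-4, seed = 1L,
                        scaling = c("proportional", "frame_max")) {
  if (relative_level < 0) stop("noise level must be non-negative")
  structure(list(relative_level = relative_level, seed = as.integer(seed),
                 scaling = match.arg(scaling)),
            class = "eit_noise_model")
}

#' Add measurement noise to a frame
#'
#' @param frame An `eit_frame`.
#' @param model An [noise_model()].
#' @param reference Frame whose voltages set the noise scale (defaults to
#'   `frame` itself; the study pipeline passes the target-free reference
#'   frame so both states of a difference pair share one noise scale).
#' @return The noisy `eit_frame`, with noise metadata attached.
#' @export
apply_noise <- function(frame, model, reference = frame) {
  stopifnot(inherits(frame, "eit_frame"), inherits(model, "eit_noise_model"))
  if (model$relative_level == 0) return(frame)
  sd_n <- if (identical(model$scaling, "frame_max"))
    rep(model$relative_level * max(abs(reference$values)),
        length(frame$values))
  else model$relative_level * abs(reference$values)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(model$seed)
  frame$values <- frame$values + stats::rnorm(length(frame$values), 0, sd_n)
  frame$noise <- list(relative_level = model$relative_level,
                      seed = model$seed, scaling = model$scaling)
  frame
}

#' Voltage difference between two measurement frames
#'
#' Element-wise difference `target - reference`, the data vector of
#' difference imaging.
#'
#' @param frame_with_target,frame_reference Frames under the same protocol.
#' @return An `eit_frame` holding the difference.
#' @export
difference_frame <- function(frame_with_target, frame_reference) {
  if (!protocol_identical(frame_with_target$protocol, frame_reference$protocol))
    stop("frames were measured under different protocols")
  structure(list(values = frame_with_target$values - frame_reference$values,
                 protocol = frame_with_target$protocol,
                 noise = frame_with_target$noise),
            class = "eit_frame")
}
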