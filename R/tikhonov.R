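# Linearized one-step Tikhonov difference reconstruction and L-curve
# regularization-parameter selection.
#
# The reconstruction solves
#
#   argmin || L_n (dV - J dsigma) ||^2 + lambda^2 || L_ds (dsigma - ds*) ||^2
#
# For the default priors the minimizer is evaluated through the dual
# (underdetermined) form dsigma = J' (J J' + lambda^2 I)^-1 dV; the L-curve
# scan and corner reconstruction reuse one economy SVD of the whitened
# Jacobian (cached on the Jacobian object), so a whole lambda grid costs a
# single decomposition.

#' Prior model for Tikhonov reconstruction
#'
#' @param delta_sigma_star Prior mean of the conductivity change (scalar or
#'   per-element vector; default 0).
#' @param L_dsigma Regularization operator: `NULL` (identity on element
#'   coefficients), a positive per-element vector (diagonal weighting; the
#'   study pipeline uses `sqrt(element volumes)`, the L2 identity on a graded
#'   mesh), or a full-rank square matrix.
#' @param L_n Noise-whitening operator: `NULL` (identity, white noise), a
#'   positive per-measurement vector, or a matrix.
#' @return An `eit_prior`.
#' @export
prior_model <- function(delta_sigma_star = 0, L_dsigma = NULL, L_n = NULL) {
  for (L in list(L_dsigma, L_n))
    if (!is.null(L) && is.numeric(L) && is.null(dim(L)) && any(L <= 0))
      stop("diagonal prior operators must be strictly positive")
  structure(list(delta_sigma_star = delta_sigma_star,
                 L_dsigma = L_dsigma, L_n = L_n),
            class = "eit_prior")
}

# Apply operator L (NULL = identity, vector = diagonal, matrix) to x.
apply_op <- function(L, x) {
  if (is.null(L)) x
  else if (is.null(dim(L))) L * x
  else L %*% x
}

op_fingerprint <- function(L) {
  if (is.null(L)) "id"
  else paste(class(L)[1], paste(dim(L), collapse = "x"), length(L),
             format(sum(L), digits = 15), format(sum(L^2), digits = 15))
}

# Whitened operator in the transformed variable x = L_ds (dsigma - ds*):
# Jt = L_n J L_ds^-1, with back(x) = ds* + L_ds^-1 x.
whiten_operator <- function(Jmat, prior) {
  n <- ncol(Jmat)
  Jw <- as.matrix(apply_op(prior$L_n, Jmat))
  Ld <- prior$L_dsigma
  if (is.null(Ld)) {
    list(Jt = Jw, back = function(x) x)
  } else if (is.null(dim(Ld))) {
    Ldv <- rep(Ld, length.out = n)
    list(Jt = sweep(Jw, 2L, Ldv, "/"), back = function(x) x / Ldv)
  } else {
    if (nrow(Ld) != ncol(Ld)) stop("matrix L_dsigma must be square full rank")
    Ldi <- solve(Ld)
    list(Jt = Jw %*% Ldi, back = function(x) as.numeric(Ldi %*% x))
  }
}

# Whitened data vector bt = L_n (dV - J ds*).
whiten_data <- function(Jmat, prior, dV) {
  ds0 <- rep(prior$delta_sigma_star, length.out = ncol(Jmat))
  b <- dV - if (all(ds0 == 0)) 0 else as.numeric(Jmat %*% ds0)
  list(bt = as.numeric(apply_op(prior$L_n, b)), ds0 = ds0)
}

jac_matrix <- function(J) if (inherits(J, "eit_jacobian")) J$J else as.matrix(J)
frame_values <- function(dV) if (inherits(dV, "eit_frame")) dV$values else as.numeric(dV)

# Economy SVD of the whitened operator, cached on eit_jacobian objects.
tik_decomp <- function(J, prior) {
  Jmat <- jac_matrix(J)
  key <- paste("svd", op_fingerprint(prior$L_n), op_fingerprint(prior$L_dsigma))
  cache <- if (inherits(J, "eit_jacobian")) J$cache
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  op <- whiten_operator(Jmat, prior)
  m <- nrow(op$Jt)
  sv <- svd(op$Jt, nu = m, nv = min(m, ncol(op$Jt)))
  d <- c(sv$d, rep(0, m - length(sv$d)))
  dec <- list(u = sv$u, d = d, v = sv$v, back = op$back, m = m)
  if (!is.null(cache)) cache[[key]] <- dec
  dec
}

#' One-step Tikhonov reconstruction at a fixed regularization parameter
#'
#' @param J An `eit_jacobian` (or plain matrix).
#' @param dV An `eit_frame` (or numeric vector) of voltage differences.
#' @param lambda Positive regularization parameter.
#' @param prior A [prior_model()].
#' @return An `eit_recon`: per-element conductivity change `delta_sigma`
#'   (S/m), `lambda_used`, whitened `residual_norm` and `solution_seminorm`.
#' @export
reconstruct <- function(J, dV, lambda, prior = prior_model()) {
  if (length(lambda) != 1L || !is.finite(lambda) || lambda <= 0)
    stop("lambda must be a single positive number")
  Jmat <- jac_matrix(J)
  op <- whiten_operator(Jmat, prior)
  wd <- whiten_data(Jmat, prior, frame_values(dV))
  m <- nrow(op$Jt)
  G <- tcrossprod(op$Jt)
  y <- solve(G + diag(lambda^2, m), wd$bt)
  x <- as.numeric(crossprod(op$Jt, y))
  structure(list(delta_sigma = wd$ds0 + op$back(x), lambda_used = lambda,
                 residual_norm = sqrt(sum((wd$bt - op$Jt %*% x)^2)),
                 solution_seminorm = sqrt(sum(x^2))),
            class = "eit_recon")
}

#' @export
print.eit_recon <- function(x, ...) {
  cat("EIT reconstruction:", length(x$delta_sigma), "elements; lambda =",
      format(x$lambda_used, digits = 4),
      "; residual", format(x$residual_norm, digits = 4),
      "; seminorm", format(x$solution_seminorm, digits = 4), "\n")
  invisible(x)
}

#' Default logarithmic regularization grid
#'
#' 141 points, 0.05 decades apart, spanning [1e-8, 1e-1]; fine enough that
#' corner positions of different data sets are not quantized onto a common
#' grid point.
#'
#' @param n Number of grid points (>= 10).
#' @param range Two positive endpoints spanning at least 6 decades.
#' @return Descending numeric vector of lambdas.
#' @export
lambda_grid <- function(n = 141L, range = c(1e-8, 1e-1)) {
  sort(10^seq(log10(range[1]), log10(range[2]), length.out = n),
       decreasing = TRUE)
}

#' Scan the L-curve over a regularization grid
#'
#' Computes the whitened residual norm and solution seminorm for every lambda
#' and locates the corner as the point of maximum signed curvature of the
#' (log residual, log seminorm) curve, endpoints excluded, ties broken toward
#' smaller lambda. For all-zero data the corner is the smallest grid lambda
#' by convention.
#'
#' @inheritParams reconstruct
#' @param lambdas Positive grid, at least 10 points spanning at least 6
#'   decades (default [lambda_grid()]).
#' @return An `eit_lcurve`: descending `lambdas`, `residual_norms`,
#'   `solution_seminorms`, `curvature`, `corner_index`, `lambda_corner`.
#' @export
lcurve_scan <- function(J, dV, prior = prior_model(), lambdas = lambda_grid()) {
  if (length(lambdas) < 10L || any(lambdas <= 0) ||
      diff(range(log10(lambdas))) < 6 - 1e-9)
    stop("lambda grid must have >= 10 positive points spanning >= 6 decades")
  lambdas <- sort(lambdas, decreasing = TRUE)
  dec <- tik_decomp(J, prior)
  wd <- whiten_data(jac_matrix(J), prior, frame_values(dV))
  beta <- as.numeric(crossprod(dec$u, wd$bt))
  d <- dec$d
  res <- semi <- numeric(length(lambdas))
  for (i in seq_along(lambdas)) {
    l2 <- lambdas[i]^2
    semi[i] <- sqrt(sum((d * beta / (d^2 + l2))^2))
    res[i] <- sqrt(sum((l2 * beta / (d^2 + l2))^2))
  }
  if (max(abs(wd$bt)) == 0) {
    corner <- length(lambdas)            # smallest lambda (grid is descending)
    kappa <- rep(NA_real_, length(lambdas))
  } else {
    kappa <- lcurve_curvature(lambdas, res, semi)
    interior <- which(is.finite(kappa))
    # max curvature; ties toward smaller lambda = later index on descending grid
    kmax <- max(kappa[interior])
    corner <- max(interior[kappa[interior] >= kmax - 1e-12])
  }
  structure(list(lambdas = lambdas, residual_norms = res,
                 solution_seminorms = semi, curvature = kappa,
                 corner_index = corner, lambda_corner = lambdas[corner]),
            class = "eit_lcurve")
}

# Signed curvature of (log residual, log seminorm) parameterized by log
# lambda, central finite differences; endpoints NA.
lcurve_curvature <- function(lambdas, res, semi) {
  t <- log(lambdas)
  eps <- .Machine$double.xmin
  x <- log(pmax(res, eps)); y <- log(pmax(semi, eps))
  n <- length(t)
  k <- rep(NA_real_, n)
  for (i in 2:(n - 1L)) {
    h1 <- t[i] - t[i - 1L]; h2 <- t[i + 1L] - t[i]
    xp <- (x[i + 1L] - x[i - 1L]) / (h1 + h2)
    yp <- (y[i + 1L] - y[i - 1L]) / (h1 + h2)
    xpp <- 2 * (h1 * x[i + 1L] - (h1 + h2) * x[i] + h2 * x[i - 1L]) /
      (h1 * h2 * (h1 + h2))
    ypp <- 2 * (h1 * y[i + 1L] - (h1 + h2) * y[i] + h2 * y[i - 1L]) /
      (h1 * h2 * (h1 + h2))
    den <- (xp^2 + yp^2)^1.5
    k[i] <- if (den > 0) (xp * ypp - yp * xpp) / den else NA_real_
  }
  k
}

#' @export
print.eit_lcurve <- function(x, ...) {
  cat("EIT L-curve:", length(x$lambdas), "lambdas in [",
      format(min(x$lambdas)), ",", format(max(x$lambdas)),
      "]; corner lambda =", format(x$lambda_corner, digits = 4), "\n")
  invisible(x)
}

#' Reconstruct at the L-curve corner
#'
#' Scans the L-curve and returns the Tikhonov reconstruction at the corner
#' lambda (evaluated from the same SVD, identical to [reconstruct()] at that
#' lambda up to numerical precision).
#'
#' @inheritParams lcurve_scan
#' @return List with `recon` (an `eit_recon`, `lambda_used` equal to the
#'   corner lambda) and `lcurve` (the `eit_lcurve`).
#' @export
reconstruct_at_corner <- function(J, dV, prior = prior_model(),
                                  lambdas = lambda_grid()) {
  lc <- lcurve_scan(J, dV, prior, lambdas)
  dec <- tik_decomp(J, prior)
  wd <- whiten_data(jac_matrix(J), prior, frame_values(dV))
  beta <- as.numeric(crossprod(dec$u, wd$bt))
  l2 <- lc$lambda_corner^2
  r <- min(ncol(dec$v), length(dec$d))
  x <- dec$v %*% ((dec$d[seq_len(r)] * beta[seq_len(r)]) /
                    (dec$d[seq_len(r)]^2 + l2))
  rec <- structure(list(
    delta_sigma = wd$ds0 + dec$back(as.numeric(x)),
    lambda_used = lc$lambda_corner,
    residual_norm = lc$residual_norms[lc$corner_index],
    solution_seminorm = lc$solution_seminorms[lc$corner_index]),
    class = "eit_recon")
  list(recon = rec, lcurve = lc)
}
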