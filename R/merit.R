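# GREIT-style figures of merit on a mid-plane raster of the reconstruction.
#
# The reconstruction lives on the 3D inverse mesh; evaluation happens on a
# square pixel grid over the electrode plane z = 0.4. Metrics follow the
# GREIT consensus conventions: the quarter-amplitude pixel set (>= 1/4 of the
# peak amplitude in the target's sign direction) defines the reconstructed
# target; amplitude response is normalized by the true contrast so a perfect
# reconstruction scores 1; shape deformation is the spill-over area outside
# the true target, normalized by the true target area.

# Cache of pixel-centre -> element maps (mesh geometry is immutable, so the
# map depends only on the mesh and the raster size).
.raster_cache <- new.env(parent = emptyenv())

mesh_fingerprint <- function(mesh) {
  paste(nrow(mesh$vertices), nrow(mesh$elements), mesh$spec$arrangement,
        format(sum(mesh$vertices), digits = 15),
        format(sum(abs(mesh$vertices[, 1])), digits = 15))
}

# Pixel-centre -> containing-element map at the electrode plane.
pixel_map <- function(mesh, grid_size) {
  key <- paste(mesh_fingerprint(mesh), grid_size)
  if (!is.null(.raster_cache[[key]])) return(.raster_cache[[key]])
  spec <- mesh$spec
  R <- spec$boundary_diameter / 2
  n <- as.integer(grid_size)
  px <- 2 * R / n
  cx <- -R + (seq_len(n) - 0.5) * px
  centers <- expand.grid(x = cx, y = cx)
  zb <- mesh$grid$zbreaks
  zq <- spec$electrode_center_z
  layer <- findInterval(zq, zb, rightmost.closed = TRUE)
  layer <- min(max(layer, 1L), length(zb) - 1L)

  tri_of <- integer(nrow(centers))
  xy <- mesh$grid$xy; tris <- mesh$grid$tris
  r2 <- centers$x^2 + centers$y^2
  cand <- which(r2 <= R^2)
  for (t in seq_len(nrow(tris))) {
    px1 <- xy[tris[t, 1L], ]; px2 <- xy[tris[t, 2L], ]; px3 <- xy[tris[t, 3L], ]
    lo_x <- min(px1[1], px2[1], px3[1]); hi_x <- max(px1[1], px2[1], px3[1])
    lo_y <- min(px1[2], px2[2], px3[2]); hi_y <- max(px1[2], px2[2], px3[2])
    sub <- cand[centers$x[cand] >= lo_x - 1e-12 & centers$x[cand] <= hi_x + 1e-12 &
                centers$y[cand] >= lo_y - 1e-12 & centers$y[cand] <= hi_y + 1e-12]
    if (!length(sub)) next
    d <- (px2[1] - px1[1]) * (px3[2] - px1[2]) - (px3[1] - px1[1]) * (px2[2] - px1[2])
    b1 <- ((px2[1] - centers$x[sub]) * (px3[2] - centers$y[sub]) -
           (px3[1] - centers$x[sub]) * (px2[2] - centers$y[sub])) / d
    b2 <- ((px3[1] - centers$x[sub]) * (px1[2] - centers$y[sub]) -
           (px1[1] - centers$x[sub]) * (px3[2] - centers$y[sub])) / d
    b3 <- 1 - b1 - b2
    inside <- b1 >= -1e-9 & b2 >= -1e-9 & b3 >= -1e-9
    tri_of[sub[inside]] <- t
  }

  ntri <- nrow(tris)
  elem_of <- integer(nrow(centers))      # 0 = outside the medium
  hit <- which(tri_of > 0L)
  if (length(hit)) {
    # the prism (tri, layer) holds 3 tets; pick the one containing the point
    prism <- (layer - 1L) * ntri + tri_of[hit]
    best_te <- integer(length(hit))
    best_b <- rep(-Inf, length(hit))
    v <- mesh$vertices
    for (s in 1:3) {
      te <- 3L * (prism - 1L) + s
      p1 <- v[mesh$elements[te, 1L], , drop = FALSE]
      a <- v[mesh$elements[te, 2L], , drop = FALSE] - p1
      b <- v[mesh$elements[te, 3L], , drop = FALSE] - p1
      d3 <- v[mesh$elements[te, 4L], , drop = FALSE] - p1
      q <- cbind(centers$x[hit], centers$y[hit], zq) - p1
      det3v <- function(A, B, C) A[, 1] * (B[, 2] * C[, 3] - B[, 3] * C[, 2]) -
        A[, 2] * (B[, 1] * C[, 3] - B[, 3] * C[, 1]) +
        A[, 3] * (B[, 1] * C[, 2] - B[, 2] * C[, 1])
      D <- det3v(a, b, d3)
      l2 <- det3v(q, b, d3) / D
      l3 <- det3v(a, q, d3) / D
      l4 <- det3v(a, b, q) / D
      minb <- pmin(1 - l2 - l3 - l4, l2, l3, l4)
      better <- minb > best_b
      best_b[better] <- minb[better]
      best_te[better] <- te[better]
    }
    elem_of[hit] <- best_te
  }
  map <- list(elem = elem_of, n = n, x = cx, pixel_size = px)
  .raster_cache[[key]] <- map
  map
}

#' Resample a reconstruction onto the electrode-plane pixel grid
#'
#' Point-samples the per-element conductivity change at each pixel centre of
#' a `grid_size` x `grid_size` raster covering the boundary circle at the
#' electrode plane. Pixels outside the boundary circle (or inside the
#' oesophageal channel, where there is no medium) are masked, never
#' extrapolated.
#'
#' @param recon An `eit_recon` (or numeric per-element vector).
#' @param mesh The `eit_mesh` the reconstruction lives on.
#' @param grid_size Pixels per side (default 64).
#' @return An `eit_image`: `values` matrix (NA outside the mask), logical
#'   `mask`, pixel centre coordinates and pixel size.
#' @export
rasterize <- function(recon, mesh, grid_size = 64L) {
  vals <- if (inherits(recon, "eit_recon")) recon$delta_sigma else as.numeric(recon)
  if (length(vals) != nrow(mesh$elements))
    stop("reconstruction length does not match the mesh")
  map <- pixel_map(mesh, grid_size)
  values <- rep(NA_real_, length(map$elem))
  inside <- map$elem > 0L
  values[inside] <- vals[map$elem[inside]]
  structure(list(values = matrix(values, map$n, map$n),
                 mask = matrix(inside, map$n, map$n),
                 x = map$x, y = map$x, pixel_size = map$pixel_size,
                 grid_size = map$n),
            class = "eit_image")
}

#' @export
print.eit_image <- function(x, ...) {
  cat("EIT planar image:", x$grid_size, "x", x$grid_size, "pixels;",
      sum(x$mask), "inside the boundary\n")
  invisible(x)
}

#' Quarter-amplitude pixel set of an image
#'
#' Pixels whose amplitude, in the direction of the image's peak-amplitude
#' sign, is at least one quarter of the peak amplitude. For an all-zero image
#' the set is empty and flagged.
#'
#' @param image An `eit_image`.
#' @return Logical matrix (the pixel set) with attributes `sign` (+1/-1) and
#'   `empty`.
#' @export
quarter_amplitude_set <- function(image) {
  v <- image$values
  if (all(is.na(v)) || max(abs(v), na.rm = TRUE) == 0) {
    qs <- image$mask & FALSE
    attr(qs, "sign") <- 1; attr(qs, "empty") <- TRUE
    return(qs)
  }
  peak_idx <- which.max(abs(v))
  s <- sign(v[peak_idx])
  qs <- !is.na(v) & (s * v >= 0.25 * s * v[peak_idx])
  attr(qs, "sign") <- s; attr(qs, "empty") <- FALSE
  qs
}

#' Ground-truth target description on the pixel grid
#'
#' @param spec The `eit_phantom_spec`.
#' @param offset Radial offset of the target centre.
#' @param grid_size Raster size matching [rasterize()].
#' @param target_diameter Target diameter (defaults to the spec's).
#' @return An `eit_truth`: centre, radius, per-pixel indicator and true
#'   contrast (blood minus background, S/m).
#' @export
target_truth <- function(spec, offset = spec$target_offset, grid_size = 64L,
                         target_diameter = spec$target_diameter) {
  R <- spec$boundary_diameter / 2
  n <- as.integer(grid_size)
  px <- 2 * R / n
  cx <- -R + (seq_len(n) - 0.5) * px
  ctr <- target_center(spec, offset)
  gx <- matrix(cx, n, n); gy <- matrix(cx, n, n, byrow = TRUE)
  pixset <- (gx - ctr[1])^2 + (gy - ctr[2])^2 <= (target_diameter / 2)^2
  structure(list(center = ctr, radius = target_diameter / 2,
                 pixels = pixset,
                 contrast = spec$conductivities[["blood"]] -
                   spec$conductivities[["background"]],
                 grid_size = n, pixel_size = px, x = cx, y = cx),
            class = "eit_truth")
}

#' Figures of merit of a reconstruction against its ground truth
#'
#' Computes, on the quarter-amplitude set Q of the image:
#' amplitude response `AR` = (sum of image amplitude over Q) / (true contrast
#' times true-target pixel count); position error `PE` = distance between the
#' amplitude-weighted centre of gravity of Q and the true target centre
#' (model units); resolution `RES` = |Q| / |mask|; shape deformation `SD` =
#' |Q outside the true target| / |true target|; ringing `RNG` = ratio of
#' opposite-sign amplitude in the annulus around Q (out to twice the
#' equivalent radius of Q) to the amplitude in Q.
#'
#' @param image An `eit_image`.
#' @param truth An `eit_truth` on the same raster.
#' @param lcurve Optional `eit_lcurve`; its corner lambda is copied into the
#'   report.
#' @return An `eit_merit` list: `AR`, `PE`, `RES`, `SD`, `RNG`,
#'   `lambda_corner`, `flag_empty`.
#' @export
merit_report <- function(image, truth, lcurve = NULL) {
  if (truth$grid_size != image$grid_size)
    stop("truth raster does not match the image raster")
  qs <- quarter_amplitude_set(image)
  lam <- if (is.null(lcurve)) NA_real_ else lcurve$lambda_corner
  if (isTRUE(attr(qs, "empty")))
    return(structure(list(AR = NA_real_, PE = NA_real_, RES = NA_real_,
                          SD = NA_real_, RNG = NA_real_, lambda_corner = lam,
                          flag_empty = TRUE), class = "eit_merit"))
  s <- attr(qs, "sign")
  v <- image$values
  amp_q <- s * v[qs]                       # amplitudes in target-sign direction
  n <- image$grid_size
  gx <- matrix(image$x, n, n); gy <- matrix(image$y, n, n, byrow = TRUE)
  cog <- c(sum(gx[qs] * amp_q), sum(gy[qs] * amp_q)) / sum(amp_q)

  AR <- sum(v[qs]) / (truth$contrast * sum(truth$pixels))
  PE <- sqrt(sum((cog - truth$center)^2))
  RES <- sum(qs) / sum(image$mask)
  SD <- sum(qs & !truth$pixels) / sum(truth$pixels)

  r_q <- sqrt(sum(qs) * image$pixel_size^2 / pi)
  ann <- image$mask & !qs &
    ((gx - cog[1])^2 + (gy - cog[2])^2 <= (2 * r_q)^2)
  opp <- ann & !is.na(v) & (s * v < 0)
  RNG <- -sum(s * v[opp]) / sum(amp_q)

  structure(list(AR = AR, PE = PE, RES = RES, SD = SD, RNG = RNG,
                 lambda_corner = lam, flag_empty = FALSE),
            class = "eit_merit")
}

#' @export
print.eit_merit <- function(x, ...) {
  cat(sprintf("AR %.4g  PE %.4g  RES %.4g  SD %.4g  RNG %.4g  L-corner %.4g\n",
              x$AR, x$PE, x$RES, x$SD, x$RNG, x$lambda_corner))
  invisible(x)
}
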