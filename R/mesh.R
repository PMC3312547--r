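# Deterministic graded tetrahedral mesher for the cylindrical phantom.
#
# Construction: a set of concentric node rings in the (x, y) plane, each ring
# carrying its own angle list (fine near the oesophageal channel, the target
# corridor along -y, and -- on the outermost rings -- the electrode centres);
# consecutive rings are triangulated with an advancing-front "zipper"; the
# resulting disc (or annulus, when the channel is present) triangulation is
# extruded through a graded stack of z-layers and every triangular prism is
# split into three tetrahedra with the smallest-global-index diagonal rule,
# which makes the split conforming across neighbouring prisms.

# ---- angle / radius generation ------------------------------------------

# Fill cyclic gaps between mandatory angles with near-uniform steps of target
# angular size dth. Mandatory angles are kept exactly.
fill_angles <- function(mandatory, dth) {
  dth <- min(dth, pi / 3)   # cap gaps: keeps centre fans and zips non-degenerate
  if (length(mandatory) == 0L) {
    n <- max(8L, ceiling(2 * pi / dth))
    return(2 * pi * (seq_len(n) - 1L) / n)
  }
  m <- sort(unique(mandatory %% (2 * pi)))
  out <- vector("list", length(m))
  for (i in seq_along(m)) {
    a <- m[i]
    b <- if (i < length(m)) m[i + 1L] else m[1L] + 2 * pi
    k <- max(1L, ceiling((b - a) / dth - 1e-9))
    out[[i]] <- a + (b - a) * (seq_len(k) - 1L) / k
  }
  sort(unlist(out) %% (2 * pi))
}

# Drop angles closer than tol to their cyclic predecessor (keeps the first of
# each cluster).
dedup_angles <- function(th, tol) {
  th <- sort(unique(th %% (2 * pi)))
  if (length(th) < 2L) return(th)
  keep <- c(TRUE, diff(th) > tol)
  th <- th[keep]
  if (length(th) > 1L && (2 * pi - (th[length(th)] - th[1L])) <= tol)
    th <- th[-length(th)]
  th
}

# Subdivide [a, b] with local step h(r); mandatory breakpoints are preserved.
fill_interval <- function(breaks, hfun) {
  breaks <- sort(unique(breaks))
  out <- breaks[1L]
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    h <- hfun((a + b) / 2)
    k <- max(1L, round((b - a) / h))
    out <- c(out, a + (b - a) * seq_len(k) / k)
  }
  out
}

# ---- annulus zipper ------------------------------------------------------

# Triangulate the annulus between an inner ring (angles th_in, global node ids
# id_in) and an outer ring (th_out, id_out). Returns an (n_in + n_out) x 3
# matrix of node ids. Vertex orientation is not normalized here; tetrahedra
# are orientation-fixed after extrusion.
zip_rings <- function(th_in, id_in, th_out, id_out) {
  n_i <- length(th_in); n_o <- length(th_out)
  stopifnot(n_i >= 3L || n_o >= 3L)
  a_ang <- function(k) th_in[(k - 1L) %% n_i + 1L] + 2 * pi * ((k - 1L) %/% n_i)
  a_id  <- function(k) id_in[(k - 1L) %% n_i + 1L]
  # align outer start with the inner start angle
  d0 <- (th_out - th_in[1L]) %% (2 * pi)
  j0 <- which.min(pmin(d0, 2 * pi - d0))
  off <- th_in[1L] + ifelse(d0[j0] <= pi, d0[j0], d0[j0] - 2 * pi) - th_out[j0]
  b_ang <- function(k) {
    j <- (j0 + k - 2L) %% n_o + 1L
    th_out[j] + off + 2 * pi * (((j0 + k - 2L) %/% n_o))
  }
  b_id <- function(k) id_out[(j0 + k - 2L) %% n_o + 1L]
  tris <- matrix(0L, n_i + n_o, 3L)
  ki <- 1L; kj <- 1L; t <- 0L
  while (ki <= n_i || kj <= n_o) {
    adv_in <- if (ki <= n_i) a_ang(ki + 1L) else Inf
    adv_out <- if (kj <= n_o) b_ang(kj + 1L) else Inf
    t <- t + 1L
    if (adv_in <= adv_out) {
      tris[t, ] <- c(a_id(ki), a_id(ki + 1L), b_id(kj))
      ki <- ki + 1L
    } else {
      tris[t, ] <- c(b_id(kj), b_id(kj + 1L), a_id(ki))
      kj <- kj + 1L
    }
  }
  tris[seq_len(t), , drop = FALSE]
}

# ---- mesh sizing presets -------------------------------------------------

# Mesh sizing parameters for a density request. "forward" and "inverse" are
# deliberately distinct discretizations (different bulk sizes, z-stacks and
# ring layouts) so that simulated data and reconstruction never share a mesh.
mesh_params <- function(spec, density) {
  base <- list(
    h_bulk_r = 0.095, h_bulk_arc = 0.135,
    h_corr = 0.037, corr_margin = 0.06,
    h_elec_arc = 0.027, elec_halfwidth = 0.068, r_elec_zone = 0.90,
    h_outer_r = 0.058,
    h_chan = 0.017, grade = 1.2,
    z_band = c(0.35, 0.45), n_band = 3L, h_z = 0.145,
    corridor = TRUE
  )
  if (is.character(density)) {
    density <- match.arg(density, c("forward", "inverse"))
    if (density == "inverse") {
      # coarser bulk, different band split and ring layout than forward
      base$h_bulk_r <- 0.105; base$h_bulk_arc <- 0.145
      base$h_corr <- 0.040; base$h_outer_r <- 0.065
      base$h_elec_arc <- 0.031; base$elec_halfwidth <- 0.062
      base$n_band <- 5L; base$h_z <- 0.155
      # deliberately coarse around the oesophageal channel: avoids tiny
      # high-sensitivity elements at the internal electrode dominating the
      # regularized solution
      base$h_chan <- 0.085
    }
    return(base)
  }
  stopifnot(is.numeric(density), density > 0)
  s <- (37500 / density)^(1 / 3)
  for (f in c("h_bulk_r", "h_bulk_arc", "h_corr", "h_outer_r", "h_z"))
    base[[f]] <- base[[f]] * s
  # electrode-zone and channel resolution stay fixed so that the effective
  # electrode geometry is density-independent (frames then converge under
  # bulk refinement)
  base$n_band <- if (s > 1.4) 1L else 3L
  base
}

# ---- 2D disc / annulus triangulation ------------------------------------

build_disc2d <- function(spec, p) {
  R <- spec$boundary_diameter / 2
  internal <- spec$arrangement == "internal"
  r_chan <- spec$internal_channel_diameter / 2
  r_t <- spec$target_diameter / 2
  corr_dir <- electrode_angle(spec, spec$target_direction_electrode)
  # radial corridor zone covered by the target sweep (0.2..0.8) plus margin
  corr_zone <- if (isTRUE(p$corridor))
    c(max(0.2 - r_t - p$corr_margin, if (internal) r_chan + 0.02 else 0.06),
      min(0.8 + r_t + p$corr_margin, R - 0.04))
  else c(-2, -1)                         # empty zone: uniform sizing
  corr_w <- r_t + p$corr_margin          # corridor half-width, length units

  hrad <- function(r) {
    h <- p$h_bulk_r
    if (r > corr_zone[1] - 0.02 && r < corr_zone[2] + 0.02) h <- min(h, p$h_corr * 1.6)
    if (r > p$r_elec_zone - 0.05) h <- min(h, p$h_outer_r)
    if (internal) h <- min(h, p$h_chan + p$grade * (r - r_chan))
    h
  }
  r_in <- if (internal) r_chan else 0
  mand_r <- c(r_in, corr_zone, p$r_elec_zone, R)
  mand_r <- mand_r[mand_r >= r_in & mand_r <= R]
  radii <- fill_interval(mand_r, hrad)
  if (!internal) radii <- radii[-1L]     # centre node handled separately

  # per-ring angle lists
  elec_l <- if (internal) seq_len(spec$n_electrodes - 1L) else seq_len(spec$n_electrodes)
  elec_th <- vapply(elec_l, function(l) electrode_angle(spec, l), 0) %% (2 * pi)
  rings <- vector("list", length(radii))
  for (i in seq_along(radii)) {
    r <- radii[i]
    mand <- numeric(0)
    h_loc_arc <- min(p$h_bulk_arc,
                     if (internal) p$h_chan + p$grade * (r - r_chan) else Inf)
    if (r >= corr_zone[1] - 1e-9 && r <= corr_zone[2] + 1e-9) {
      w <- asin(min(1, corr_w / r))
      k <- max(1L, ceiling(w / (p$h_corr / r)))
      mand <- c(mand, corr_dir + w * seq(-k, k) / k)
    }
    if (r >= p$r_elec_zone - 1e-9) {
      w <- p$elec_halfwidth / r
      k <- max(1L, ceiling(w / (p$h_elec_arc / r)))
      mand <- c(mand, as.vector(outer(w * seq(-k, k) / k, elec_th, "+")))
    }
    mand <- dedup_angles(mand, 0.35 * min(p$h_corr, p$h_elec_arc, h_loc_arc) / r)
    rings[[i]] <- fill_angles(mand, h_loc_arc / r)
  }

  # node table: optional centre node, then rings in order
  nn <- vapply(rings, length, 0L)
  ids <- vector("list", length(rings))
  nxt <- 1L
  xy <- NULL
  center_id <- NULL
  if (!internal) { center_id <- nxt; nxt <- nxt + 1L; xy <- rbind(xy, c(0, 0)) }
  for (i in seq_along(rings)) {
    ids[[i]] <- nxt:(nxt + nn[i] - 1L)
    nxt <- nxt + nn[i]
    xy <- rbind(xy, cbind(radii[i] * cos(rings[[i]]), radii[i] * sin(rings[[i]])))
  }

  tris <- NULL
  if (!internal) {
    k <- ids[[1L]]
    tris <- cbind(center_id, k, c(k[-1L], k[1L]))
  }
  for (i in seq_len(length(rings) - 1L)) {
    tris <- rbind(tris, zip_rings(rings[[i]], ids[[i]],
                                  rings[[i + 1L]], ids[[i + 1L]]))
  }
  colnames(tris) <- NULL
  list(xy = xy, tris = tris, radii = radii,
       outer_ids = ids[[length(ids)]], inner_ids = if (internal) ids[[1L]])
}

# ---- extrusion to tetrahedra --------------------------------------------

z_breaks <- function(spec, p) {
  H <- spec$boundary_height
  zb <- sort(unique(c(0, p$z_band, H)))
  out <- zb[1L]
  for (i in seq_len(length(zb) - 1L)) {
    a <- zb[i]; b <- zb[i + 1L]
    k <- if (isTRUE(all.equal(c(a, b), p$z_band))) p$n_band
         else max(1L, round((b - a) / p$h_z))
    out <- c(out, a + (b - a) * seq_len(k) / k)
  }
  out
}

# Split every prism (bottom triangle ids B, top = B + nv2d) into 3 tets with
# the smallest-index diagonal rule; conforming across prisms by construction.
split_prisms <- function(tris, n2d, nlayer) {
  P <- nrow(tris) * nlayer
  B <- tris[rep(seq_len(nrow(tris)), nlayer), , drop = FALSE] +
    rep((seq_len(nlayer) - 1L) * n2d, each = nrow(tris))
  # rotate so the smallest id is first
  k <- max.col(-B, ties.method = "first")
  i1 <- cbind(seq_len(P), k)
  i2 <- cbind(seq_len(P), k %% 3L + 1L)
  i3 <- cbind(seq_len(P), (k + 1L) %% 3L + 1L)
  V1 <- B[i1]; V2 <- B[i2]; V3 <- B[i3]
  V4 <- V1 + n2d; V5 <- V2 + n2d; V6 <- V3 + n2d
  case1 <- pmin(V2, V6) < pmin(V3, V5)
  tets <- matrix(0L, 3L * P, 4L)
  idx <- 3L * (seq_len(P) - 1L)
  tets[idx + 1L, ] <- cbind(V1, V2, V3, ifelse(case1, V6, V5))
  tets[idx + 2L, ] <- cbind(V1, ifelse(case1, V2, V5), ifelse(case1, V6, V3), ifelse(case1, V5, V6))
  tets[idx + 3L, ] <- cbind(V1, V5, V6, V4)
  list(tets = tets,
       tri2d = rep(rep(seq_len(nrow(tris)), nlayer), each = 3L),
       layer = rep(rep(seq_len(nlayer), each = nrow(tris)), each = 3L))
}

tet_volumes_signed <- function(vertices, tets) {
  p1 <- vertices[tets[, 1L], , drop = FALSE]
  a <- vertices[tets[, 2L], , drop = FALSE] - p1
  b <- vertices[tets[, 3L], , drop = FALSE] - p1
  c_ <- vertices[tets[, 4L], , drop = FALSE] - p1
  (a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
   a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
   a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

# Boundary facets: faces referenced by exactly one tetrahedron.
boundary_faces <- function(tets) {
  m <- nrow(tets)
  faces <- rbind(tets[, c(2L, 3L, 4L)], tets[, c(1L, 3L, 4L)],
                 tets[, c(1L, 2L, 4L)], tets[, c(1L, 2L, 3L)])
  key <- t(apply(faces, 1L, sort.int))
  ord <- order(key[, 1L], key[, 2L], key[, 3L])
  ks <- key[ord, , drop = FALSE]
  same_next <- c(rowSums(ks[-nrow(ks), , drop = FALSE] ==
                           ks[-1L, , drop = FALSE]) == 3L, FALSE)
  same_prev <- c(FALSE, same_next[-length(same_next)])
  bnd <- ord[!(same_next | same_prev)]
  list(faces = faces[bnd, , drop = FALSE],
       element = (bnd - 1L) %% m + 1L)
}

tri_area3 <- function(vertices, faces) {
  a <- vertices[faces[, 2L], , drop = FALSE] - vertices[faces[, 1L], , drop = FALSE]
  b <- vertices[faces[, 3L], , drop = FALSE] - vertices[faces[, 1L], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

# ---- electrode facet selection ------------------------------------------

# Pick the wall facets forming electrode patch l: facets sorted by geodesic
# distance (on the cylinder of radius R_wall) from the electrode centre; the
# patch size k is chosen so the summed facet area best matches the analytic
# disc area pi (d/2)^2, starting from the centroids-within-radius set.
select_electrode_facets <- function(vertices, faces, areas, center_angle,
                                    center_z, R_wall, radius_e) {
  cen <- (vertices[faces[, 1L], , drop = FALSE] +
          vertices[faces[, 2L], , drop = FALSE] +
          vertices[faces[, 3L], , drop = FALSE]) / 3
  th <- atan2(cen[, 2L], cen[, 1L])
  dth <- (th - center_angle + pi) %% (2 * pi) - pi
  d <- sqrt((R_wall * dth)^2 + (cen[, 3L] - center_z)^2)
  ord <- order(d)
  A_target <- pi * radius_e^2
  cum <- cumsum(areas[ord])
  kmax <- sum(d[ord] <= 2.5 * radius_e)
  k <- which.min(abs(cum[seq_len(kmax)] - A_target))
  ord[seq_len(k)]
}

# ---- main build ----------------------------------------------------------

#' Build a tetrahedral mesh of the phantom with its electrode set
#'
#' Generates the graded tetrahedral discretization of the boundary cylinder
#' (minus the axial channel in the internal arrangement), labels lung /
#' background regions by element centroid, extracts labelled boundary facets
#' and assembles the 16 electrode patches. The `"forward"` and `"inverse"`
#' densities are distinct discretizations, so simulated data and
#' reconstruction never share a mesh.
#'
#' @param spec An [phantom_spec()] object.
#' @param density `"forward"` (about 37k elements), `"inverse"` (about 28k),
#'   or a numeric target element count.
#' @return A list with components `mesh` (class `eit_mesh`) and `electrodes`
#'   (class `eit_electrodes`).
#' @export
build_phantom <- function(spec, density = "forward") {
  validate_phantom_spec(spec)
  p <- mesh_params(spec, density)
  disc <- build_disc2d(spec, p)
  zb <- z_breaks(spec, p)
  n2d <- nrow(disc$xy)
  nlayer <- length(zb) - 1L

  vertices <- cbind(disc$xy[rep(seq_len(n2d), length(zb)), , drop = FALSE],
                    rep(zb, each = n2d))
  sp <- split_prisms(disc$tris, n2d, nlayer)
  tets <- sp$tets
  vol <- tet_volumes_signed(vertices, tets)
  flip <- vol < 0
  if (any(flip)) tets[flip, c(3L, 4L)] <- tets[flip, c(4L, 3L)]
  vol <- abs(vol)
  if (any(vol <= 0)) stop("degenerate (zero-volume) tetrahedra produced")

  centroids <- (vertices[tets[, 1L], ] + vertices[tets[, 2L], ] +
                vertices[tets[, 3L], ] + vertices[tets[, 4L], ]) / 4
  if (spec$include_lungs) {
    lc <- lung_centers(spec)
    r_l <- spec$lung_diameter / 2
    in_lung <- (sqrt((centroids[, 1] - lc[1, 1])^2 + (centroids[, 2] - lc[1, 2])^2) <= r_l) |
               (sqrt((centroids[, 1] - lc[2, 1])^2 + (centroids[, 2] - lc[2, 2])^2) <= r_l)
    region <- ifelse(in_lung, "lung", "background")
  } else {
    region <- rep("background", nrow(tets))
  }

  bf <- boundary_faces(tets)
  fcen <- (vertices[bf$faces[, 1L], , drop = FALSE] +
           vertices[bf$faces[, 2L], , drop = FALSE] +
           vertices[bf$faces[, 3L], , drop = FALSE]) / 3
  frad <- sqrt(fcen[, 1]^2 + fcen[, 2]^2)
  H <- spec$boundary_height
  R <- spec$boundary_diameter / 2
  r_chan <- spec$internal_channel_diameter / 2
  lab <- rep("outer_wall", nrow(bf$faces))
  lab[fcen[, 3] < 1e-9] <- "bottom"
  lab[fcen[, 3] > H - 1e-9] <- "top"
  if (spec$arrangement == "internal")
    lab[frad < r_chan * 1.8 & fcen[, 3] > 1e-9 & fcen[, 3] < H - 1e-9] <- "channel_wall"
  lab[lab == "outer_wall" & frad < R * 0.98] <- "outer_wall" # (wall facets are vertical)

  areas <- tri_area3(vertices, bf$faces)
  r_e <- spec$electrode_diameter / 2
  electrodes <- vector("list", spec$n_electrodes)
  for (l in seq_len(spec$n_electrodes)) {
    on_channel <- spec$arrangement == "internal" && l == spec$n_electrodes
    wall <- if (on_channel) "channel_wall" else "outer_wall"
    R_wall <- if (on_channel) r_chan else R
    idx <- which(lab == wall)
    ang <- electrode_angle(spec, l)
    pick <- select_electrode_facets(vertices, bf$faces[idx, , drop = FALSE],
                                    areas[idx], ang, spec$electrode_center_z,
                                    R_wall, r_e)
    sel <- idx[pick]
    lab[sel] <- paste0("electrode_", l)
    electrodes[[l]] <- list(
      index = l,
      faces = bf$faces[sel, , drop = FALSE],
      areas = areas[sel],
      center = c(R_wall * cos(ang), R_wall * sin(ang), spec$electrode_center_z),
      wall = wall,
      z_c = spec$contact_impedance)
  }

  mesh <- structure(list(
    vertices = vertices,
    elements = tets,
    element_region = region,
    volumes = vol,
    centroids = centroids,
    boundary = list(faces = bf$faces, element = bf$element,
                    label = lab, areas = areas),
    spec = spec,
    grid = list(xy = disc$xy, tris = disc$tris, zbreaks = zb,
                tri2d = sp$tri2d, layer = sp$layer)
  ), class = "eit_mesh")
  electrodes <- structure(electrodes, class = "eit_electrodes")
  list(mesh = mesh, electrodes = electrodes)
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat("EIT tetrahedral mesh:", nrow(x$elements), "elements,",
      nrow(x$vertices), "vertices\n")
  cat("  total volume", format(sum(x$volumes), digits = 6),
      "; regions:", paste(names(table(x$element_region)),
                          table(x$element_region), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.eit_electrodes <- function(x, ...) {
  cat("EIT electrode set:", length(x), "electrodes; z_c =",
      x[[1L]]$z_c, "Ohm m^2\n")
  for (e in x)
    cat(sprintf("  %2d: %-12s %3d facets, area %.5f\n", e$index, e$wall,
                nrow(e$faces), sum(e$areas)))
  invisible(x)
}

#' Assign tissue conductivities to mesh elements
#'
#' Sets each element's conductivity by its centroid: blood inside the target
#' cylinder (when `include_target`), lung inside either lung cylinder, else
#' background. With `include_target = FALSE` the target volume keeps the
#' background value, giving the reference state for difference imaging.
#'
#' @param mesh An `eit_mesh`.
#' @param spec The phantom spec the mesh was built from.
#' @param target_offset Radial offset of the target centre.
#' @param include_target Include the blood target?
#' @param target_diameter Target cylinder diameter (defaults to the spec's).
#' @return An `eit_sigma` object (per-element conductivity in S/m).
#' @export
assign_conductivity <- function(mesh, spec = mesh$spec,
                                target_offset = spec$target_offset,
                                include_target = TRUE,
                                target_diameter = spec$target_diameter) {
  validate_phantom_spec(spec, target_offset)
  sig <- ifelse(mesh$element_region == "lung",
                spec$conductivities[["lung"]],
                spec$conductivities[["background"]])
  in_target <- rep(FALSE, nrow(mesh$elements))
  if (include_target) {
    tc <- target_center(spec, target_offset)
    r_t <- target_diameter / 2
    in_target <- (mesh$centroids[, 1] - tc[1])^2 +
                 (mesh$centroids[, 2] - tc[2])^2 <= r_t^2
    sig[in_target] <- spec$conductivities[["blood"]]
  }
  structure(list(values = unname(sig), in_target = in_target,
                 target_offset = target_offset,
                 include_target = include_target),
            class = "eit_sigma")
}

#' @export
print.eit_sigma <- function(x, ...) {
  cat("EIT conductivity field:", length(x$values), "elements; values",
      paste(sort(unique(x$values)), collapse = ", "), "S/m\n")
  invisible(x)
}
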