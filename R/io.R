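# Plain-text interchange: Gmsh MSH v2.2 and legacy VTK for meshes and
# reconstructions, CSV for measurement frames and L-curves.

#' Write a mesh in Gmsh MSH v2.2 ASCII format
#'
#' Tetrahedra carry their region as a physical tag (1 background, 2 lung);
#' boundary triangles carry facet labels (electrode patches get physical tag
#' 100 + electrode index; walls/top/bottom tags 1-4).
#'
#' @param mesh An `eit_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mesh_msh <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat"), con)
  nv <- nrow(mesh$vertices)
  writeLines(c("$Nodes", as.character(nv)), con)
  writeLines(sprintf("%d %.16g %.16g %.16g", seq_len(nv),
                     mesh$vertices[, 1], mesh$vertices[, 2],
                     mesh$vertices[, 3]), con)
  writeLines("$EndNodes", con)
  reg <- match(mesh$element_region, c("background", "lung"))
  blab <- mesh$boundary$label
  btag <- integer(length(blab))
  btag[blab == "outer_wall"] <- 1L
  btag[blab == "bottom"] <- 2L
  btag[blab == "top"] <- 3L
  btag[blab == "channel_wall"] <- 4L
  el <- grepl("^electrode_", blab)
  btag[el] <- 100L + as.integer(sub("^electrode_", "", blab[el]))
  ne <- nrow(mesh$elements); nb <- nrow(mesh$boundary$faces)
  writeLines(c("$Elements", as.character(ne + nb)), con)
  writeLines(sprintf("%d 2 2 %d %d %d %d %d", seq_len(nb), btag, btag,
                     mesh$boundary$faces[, 1], mesh$boundary$faces[, 2],
                     mesh$boundary$faces[, 3]), con)
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", nb + seq_len(ne), reg, reg,
                     mesh$elements[, 1], mesh$elements[, 2],
                     mesh$elements[, 3], mesh$elements[, 4]), con)
  writeLines("$EndElements", con)
  invisible(path)
}

#' Read a Gmsh MSH v2.2 ASCII mesh
#'
#' Reads files produced by [write_mesh_msh()]: vertices, tetrahedra with
#' region tags, and labelled boundary triangles.
#'
#' @param path MSH file path.
#' @return List with `vertices`, `elements`, `element_region`,
#'   `boundary_faces`, `boundary_tag`.
#' @export
read_mesh_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stop("missing section ", name)
    lines[(i0 + 2L):(i1 - 1L)]
  }
  nodes <- matrix(scan(text = sec("Nodes"), quiet = TRUE), ncol = 4,
                  byrow = TRUE)
  el_lines <- sec("Elements")
  parts <- strsplit(el_lines, " ", fixed = TRUE)
  type <- vapply(parts, function(p) as.integer(p[2]), 0L)
  tags <- vapply(parts, function(p) as.integer(p[4]), 0L)
  tri <- t(vapply(parts[type == 2L],
                  function(p) as.integer(p[6:8]), integer(3)))
  tet <- t(vapply(parts[type == 4L],
                  function(p) as.integer(p[6:9]), integer(4)))
  list(vertices = nodes[, 2:4, drop = FALSE], elements = tet,
       element_region = c("background", "lung")[tags[type == 4L]],
       boundary_faces = tri, boundary_tag = tags[type == 2L])
}

#' Write a mesh (optionally with cell data) as legacy VTK ASCII
#'
#' @param mesh An `eit_mesh`.
#' @param path Output file path.
#' @param cell_data Optional named list of numeric per-element vectors
#'   (e.g. a reconstruction's `delta_sigma`).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, cell_data = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); ne <- nrow(mesh$elements)
  writeLines(c("# vtk DataFile Version 3.0",
               "oesoEIT phantom mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nv)), con)
  writeLines(sprintf("%.16g %.16g %.16g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("CELLS %d %d", ne, 5L * ne), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L,
                     mesh$elements[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", ne), con)
  writeLines(rep("10", ne), con)
  writeLines(sprintf("CELL_DATA %d", ne), con)
  writeLines(c("SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(match(mesh$element_region,
                                c("background", "lung"))), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm),
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.16g", cell_data[[nm]]), con)
  }
  invisible(path)
}

#' Write a reconstruction as VTK cell data on its inverse mesh
#'
#' @param recon An `eit_recon`.
#' @param mesh The inverse `eit_mesh`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_recon_vtk <- function(recon, mesh, path) {
  write_mesh_vtk(mesh, path, cell_data = list(delta_sigma = recon$delta_sigma))
}

#' Write / read a measurement frame as CSV
#'
#' One row per measurement: injection index, measurement electrode pair and
#' voltage. Protocol metadata (electrode count, amplitude, noise seed) goes
#' into a comment header.
#'
#' @param frame An `eit_frame`.
#' @param path CSV path.
#' @return `path`, invisibly (writer); an `eit_frame` (reader).
#' @export
write_frame_csv <- function(frame, path) {
  tab <- frame$protocol$table
  hdr <- sprintf("# n_el=%d amplitude_mA=%g noise_level=%g noise_seed=%d",
                 frame$protocol$n_el, frame$protocol$amplitude_mA,
                 if (is.null(frame$noise)) 0 else frame$noise$relative_level,
                 if (is.null(frame$noise)) -1L else frame$noise$seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(injection = tab[, "injection"],
                              m_pos = tab[, "m_pos"], m_neg = tab[, "m_neg"],
                              voltage = frame$values),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_csv
#' @export
read_frame_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- strsplit(sub("^# ", "", hdr), " ")[[1]]
  meta <- stats::setNames(
    as.numeric(sub("^[a-z_A-Z]+=", "", kv)),
    sub("=.*$", "", kv))
  df <- utils::read.csv(path, comment.char = "#")
  protocol <- adjacent_protocol(meta[["n_el"]], meta[["amplitude_mA"]])
  noise <- if (meta[["noise_seed"]] >= 0)
    list(relative_level = meta[["noise_level"]],
         seed = as.integer(meta[["noise_seed"]]))
  structure(list(values = df$voltage, protocol = protocol, noise = noise),
            class = "eit_frame")
}

#' Write an L-curve as CSV
#'
#' Columns: lambda, residual norm, solution seminorm, is_corner flag.
#'
#' @param lcurve An `eit_lcurve`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_lcurve_csv <- function(lcurve, path) {
  utils::write.csv(data.frame(
    lambda = lcurve$lambdas,
    residual_norm = lcurve$residual_norms,
    solution_seminorm = lcurve$solution_seminorms,
    is_corner = seq_along(lcurve$lambdas) == lcurve$corner_index),
    path, row.names = FALSE)
  invisible(path)
}
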