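analytic_volume <- function(arrangement) {
  pi * 1^2 * 0.8 - if (arrangement == "internal") pi * 0.05^2 * 0.8 else 0
}

test_that("evaluation-grade meshes hit their element budgets and volumes", {
  for (arr in c("external", "internal")) {
    fwd <- build_phantom(phantom_spec(arr), "forward")$mesh
    inv <- build_phantom(phantom_spec(arr), "inverse")$mesh
    expect_gt(nrow(fwd$elements), 30000)
    expect_lt(nrow(fwd$elements), 45000)
    expect_gt(nrow(inv$elements), 25000)
    va <- analytic_volume(arr)
    expect_lt(abs(sum(fwd$volumes) - va) / va, 0.005)
    expect_lt(abs(sum(inv$volumes) - va) / va, 0.01)
    # distinct discretizations (inverse-crime guard)
    expect_false(nrow(fwd$elements) == nrow(inv$elements))
  }
})

test_that("meshes are conforming with positive volumes", {
  for (arr in c("external", "internal")) {
    m <- cached_phantom(arr)$mesh
    expect_true(all(m$volumes > 0))
    faces <- rbind(m$elements[, c(2, 3, 4)], m$elements[, c(1, 3, 4)],
                   m$elements[, c(1, 2, 4)], m$elements[, c(1, 2, 3)])
    key <- t(apply(faces, 1, sort.int))
    cnt <- table(paste(key[, 1], key[, 2], key[, 3]))
    # every facet belongs to one (boundary) or two (interior) tetrahedra
    expect_true(all(cnt %in% c(1L, 2L)))
    expect_equal(sum(cnt == 1L), nrow(m$boundary$faces))
  }
})

test_that("electrode patches match the disc area and sit on the right wall", {
  A_disc <- pi * 0.05^2
  for (arr in c("external", "internal")) {
    ph <- build_phantom(phantom_spec(arr), "inverse")
    areas <- vapply(ph$electrodes, function(e) sum(e$areas), 0)
    expect_true(all(abs(areas - A_disc) / A_disc < 0.2))
    walls <- vapply(ph$electrodes, function(e) e$wall, "")
    if (arr == "internal") {
      expect_equal(walls, c(rep("outer_wall", 15), "channel_wall"))
    } else {
      expect_equal(walls, rep("outer_wall", 16))
    }
    # each patch is edge-connected
    for (e in ph$electrodes) {
      f <- e$faces
      comp <- seq_len(nrow(f))
      repeat {
        changed <- FALSE
        for (i in seq_len(nrow(f))) for (j in seq_len(nrow(f))) {
          if (comp[j] < comp[i] && length(intersect(f[i, ], f[j, ])) >= 2) {
            comp[i] <- comp[j]; changed <- TRUE
          }
        }
        if (!changed) break
      }
      expect_equal(length(unique(comp)), 1L)
    }
  }
})

test_that("region volumes match the analytic cylinders", {
  inv <- build_phantom(phantom_spec("external"), "inverse")$mesh
  lung_vol <- sum(inv$volumes[inv$element_region == "lung"])
  expect_lt(abs(lung_vol - 2 * pi * 0.4^2 * 0.8) / (2 * pi * 0.4^2 * 0.8),
            0.05)
  sig <- assign_conductivity(inv, target_offset = 0.5)
  tv <- sum(inv$volumes[sig$in_target])
  expect_lt(abs(tv - pi * 0.05^2 * 0.8) / (pi * 0.05^2 * 0.8), 0.05)
})

test_that("conductivity assignment uses the tabulated tissue values", {
  inv <- cached_phantom("external")$mesh
  ref <- assign_conductivity(inv, include_target = FALSE)
  expect_setequal(unique(ref$values), c(0.13, 0.48))
  tgt <- assign_conductivity(inv, target_offset = 0.5)
  expect_setequal(unique(tgt$values), c(0.13, 0.48, 0.7))
  # volume-weighted mean over target elements is exactly the blood value
  w <- inv$volumes[tgt$in_target]
  expect_equal(sum(tgt$values[tgt$in_target] * w) / sum(w), 0.7)
  # reference state leaves the target volume at background
  expect_equal(unique(ref$values[tgt$in_target]), 0.48)
})

test_that("mesh generation is deterministic and arrangements differ only as
           designed", {
  a <- build_phantom(phantom_spec("internal"), 3000)
  b <- build_phantom(phantom_spec("internal"), 3000)
  expect_identical(a$mesh$vertices, b$mesh$vertices)
  expect_identical(a$mesh$elements, b$mesh$elements)
  ext <- cached_phantom("external")
  int <- cached_phantom("internal")
  # electrodes 1..15 share nominal centres; 16 moves to the channel wall
  for (l in 1:15)
    expect_equal(ext$electrodes[[l]]$center, int$electrodes[[l]]$center)
  expect_equal(int$electrodes[[16]]$center[1:2], c(0.05 * cos(pi / 2 - 2 * pi * 15 / 16),
                                                   0.05 * sin(pi / 2 - 2 * pi * 15 / 16)),
               tolerance = 1e-12)
  expect_false(any(ext$mesh$boundary$label == "channel_wall"))
  expect_gt(sum(int$mesh$boundary$label == "channel_wall"), 0)
})

test_that("MSH round trip preserves the mesh and VTK export is well formed", {
  m <- cached_phantom("external", 2000)$mesh
  p <- withr::local_tempfile(fileext = ".msh")
  write_mesh_msh(m, p)
  back <- read_mesh_msh(p)
  expect_equal(back$vertices, unname(m$vertices))
  expect_equal(back$elements, unname(m$elements))
  expect_equal(back$element_region, m$element_region)
  v <- withr::local_tempfile(fileext = ".vtk")
  write_mesh_vtk(m, v, cell_data = list(delta_sigma = m$volumes))
  out <- readLines(v)
  expect_equal(out[1], "# vtk DataFile Version 3.0")
  expect_true(any(grepl("SCALARS delta_sigma double 1", out)))
})
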