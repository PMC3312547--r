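test_that("quarter-amplitude thresholding follows the 1/4-peak rule", {
  # disc indicator reproduces itself
  v <- matrix(0, 8, 8); v[3:5, 3:5] <- 1
  qs <- quarter_amplitude_set(make_image(v))
  expect_equal(unclass(qs)[,], v == 1)
  # single hot pixel: 0.2 < 0.25 stays out
  v2 <- matrix(0.2, 8, 8); v2[4, 4] <- 1
  qs2 <- quarter_amplitude_set(make_image(v2))
  expect_equal(sum(qs2), 1L)
  expect_true(qs2[4, 4])
  # all-zero image is flagged empty
  qs3 <- quarter_amplitude_set(make_image(matrix(0, 8, 8)))
  expect_true(attr(qs3, "empty"))
  expect_equal(sum(qs3), 0L)
  # negative-contrast images threshold in the image's own sign direction
  qs4 <- quarter_amplitude_set(make_image(-v))
  expect_equal(attr(qs4, "sign"), -1)
  expect_equal(sum(qs4), 9L)
})

test_that("Gaussian blob quarter set matches the analytic level set", {
  n <- 64
  cx <- seq_len(n) - (n + 1) / 2
  sg <- 6
  v <- exp(-outer(cx^2, cx^2, "+") / (2 * sg^2))
  qs <- quarter_amplitude_set(make_image(v))
  analytic <- pi * (sg * sqrt(2 * log(4)))^2
  expect_lt(abs(sum(qs) - analytic) / analytic, 0.1)
})

test_that("perfect reconstruction scores AR 1, PE 0, SD 0", {
  n <- 16
  # centre on a pixel centre so the discretized disc is symmetric and its
  # centre of gravity coincides with the true centre
  px <- 2 / n
  ctr <- c(-1 + 5.5 * px, -1 + 10.5 * px)
  truth <- make_truth(ctr, 0.25, n = n, contrast = 0.22)
  v <- matrix(0, n, n); v[truth$pixels] <- 0.22
  rep <- merit_report(make_image(v), truth)
  expect_equal(rep$AR, 1)
  expect_equal(rep$PE, 0)
  expect_equal(rep$SD, 0)
  expect_equal(rep$RES, sum(truth$pixels) / n^2)
  expect_equal(rep$RNG, 0)
})

test_that("a rigid two-pixel shift gives PE of two pixel widths", {
  n <- 16
  truth <- make_truth(c(0, 0), 0.2, n = n, contrast = 1)
  v <- matrix(0, n, n)
  shifted <- which(truth$pixels, arr.ind = TRUE)
  shifted[, 1] <- shifted[, 1] + 2L
  v[shifted] <- 1
  rep <- merit_report(make_image(v), truth)
  px <- 2 / n
  expect_equal(rep$PE, 2 * px, tolerance = 1e-12)
})

test_that("hand-worked 4x4 toy image scores as enumerated", {
  v <- rbind(c(0, 0, 0, 0),
             c(0, 1, .3, 0),
             c(0, .3, .1, 0),
             c(0, 0, 0, 0))
  img <- make_image(v)
  truth <- make_truth(c(img$x[2], img$y[2]), 0.2, n = 4, contrast = 1)
  expect_equal(sum(truth$pixels), 1L)        # single true pixel at (2,2)
  qs <- quarter_amplitude_set(img)
  expect_equal(sum(qs), 3L)                  # 1.0 and the two 0.3s
  rep <- merit_report(img, truth)
  expect_equal(rep$RES, 3 / 16)
  expect_equal(rep$SD, 2)                    # two spill pixels / one true
  expect_equal(rep$AR, 1.6)                  # (1 + .3 + .3) / (1 * 1)
  # amplitude-weighted COG against the true centre, by hand
  cog <- c(1 * img$x[2] + .3 * img$x[2] + .3 * img$x[3],
           1 * img$y[2] + .3 * img$y[3] + .3 * img$y[2]) / 1.6
  expect_equal(rep$PE, sqrt(sum((cog - truth$center)^2)), tolerance = 1e-12)
})

test_that("metrics are scale invariant except AR which is linear", {
  set.seed(8)
  n <- 32
  cx <- seq_len(n) - 10
  v <- exp(-outer(cx^2, (seq_len(n) - 20)^2, "+") / 50) -
    0.1 * exp(-outer((cx - 8)^2, (seq_len(n) - 20)^2, "+") / 80)
  img1 <- make_image(v); img5 <- make_image(5 * v)
  truth <- make_truth(c(img1$x[10], img1$y[20]), 0.15, n = n, contrast = 1)
  r1 <- merit_report(img1, truth); r5 <- merit_report(img5, truth)
  expect_equal(r5$AR, 5 * r1$AR)
  expect_equal(r5$PE, r1$PE)
  expect_equal(r5$RES, r1$RES)
  expect_equal(r5$SD, r1$SD)
  expect_equal(r5$RNG, r1$RNG)
})

test_that("rotating image and truth together leaves the metrics unchanged", {
  n <- 32
  cx <- seq_len(n)
  v <- exp(-(outer((cx - 12)^2, (cx - 18)^2, "+")) / 40)
  rot90 <- function(m) t(m)[, rev(seq_len(ncol(m)))]
  img <- make_image(v)
  imgr <- make_image(rot90(v))
  truth <- make_truth(c(img$x[12], img$y[18]), 0.2, n = n, contrast = 1)
  # (x, y) -> (y, -x) under this matrix rotation
  truthr <- make_truth(c(truth$center[2], -truth$center[1]), 0.2, n = n,
                       contrast = 1)
  r <- merit_report(img, truth); rr <- merit_report(imgr, truthr)
  expect_equal(rr$AR, r$AR, tolerance = 1e-12)
  expect_equal(rr$PE, r$PE, tolerance = 1e-12)
  expect_equal(rr$RES, r$RES, tolerance = 1e-12)
  expect_equal(rr$SD, r$SD, tolerance = 1e-12)
})

test_that("rasterization masks the boundary disc and samples elements", {
  ph <- cached_phantom("external", 2000)
  m <- ph$mesh
  img <- rasterize(rep(2.5, nrow(m$elements)), m)
  expect_lt(abs(sum(img$mask) / 64^2 - pi / 4), 0.03 * pi / 4)
  expect_true(all(img$values[img$mask] == 2.5))
  expect_true(all(is.na(img$values[!img$mask])))
  # oesophageal channel pixels are masked out in the internal arrangement
  mi <- cached_phantom("internal", 2000)$mesh
  imgi <- rasterize(rep(1, nrow(mi$elements)), mi)
  ctr <- imgi$values[abs(imgi$x) < 0.03, abs(imgi$y) < 0.03]
  expect_true(all(is.na(ctr)))
  expect_error(rasterize(rep(1, 5), m), "does not match")
})

test_that("smooth images give raster-resolution-independent AR", {
  ph <- cached_phantom("external", 2000)
  m <- ph$mesh
  vals <- exp(-((m$centroids[, 1])^2 + (m$centroids[, 2] + 0.4)^2) / 0.1)
  spec <- phantom_spec("external")
  r64 <- merit_report(rasterize(vals, m, 64), target_truth(spec, 0.4, 64))
  r128 <- merit_report(rasterize(vals, m, 128), target_truth(spec, 0.4, 128))
  expect_lt(abs(r64$AR - r128$AR) / abs(r64$AR), 0.02)
})

test_that("resampling conserves the disc-mean amplitude of a smooth field", {
  ph <- cached_phantom("external", 2000)
  m <- ph$mesh
  vals <- 1 + 0.5 * sin(2 * m$centroids[, 1]) * cos(m$centroids[, 2])
  img <- rasterize(vals, m)
  mid <- abs(m$centroids[, 3] - 0.4) < 0.05
  mesh_mean <- sum((vals * m$volumes)[mid]) / sum(m$volumes[mid])
  expect_lt(abs(mean(img$values[img$mask]) - mesh_mean) / mesh_mean, 0.02)
})
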