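# Shared phantom/mesh fixtures, built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

cached_phantom <- function(arrangement = "external", density = 3000,
                           include_lungs = TRUE) {
  key <- paste(arrangement, density, include_lungs)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- build_phantom(
      phantom_spec(arrangement, include_lungs = include_lungs), density)
  .fixture_cache[[key]]
}

# Minimal eit_image for metric tests: full square mask unless given.
make_image <- function(values, mask = NULL, half_width = 1) {
  n <- nrow(values)
  px <- 2 * half_width / n
  cx <- -half_width + (seq_len(n) - 0.5) * px
  if (is.null(mask)) mask <- matrix(TRUE, n, n)
  values[!mask] <- NA_real_
  structure(list(values = values, mask = mask, x = cx, y = cx,
                 pixel_size = px, grid_size = n), class = "eit_image")
}

make_truth <- function(center, radius, n = 4L, half_width = 1, contrast = 1) {
  px <- 2 * half_width / n
  cx <- -half_width + (seq_len(n) - 0.5) * px
  gx <- matrix(cx, n, n); gy <- matrix(cx, n, n, byrow = TRUE)
  structure(list(center = center, radius = radius,
                 pixels = (gx - center[1])^2 + (gy - center[2])^2 <= radius^2,
                 contrast = contrast, grid_size = n, pixel_size = px,
                 x = cx, y = cx), class = "eit_truth")
}
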