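protocol16 <- adjacent_protocol(16)

test_that("forward solution satisfies gauge, passivity and reciprocity", {
  for (arr in c("external", "internal")) {
    ph <- cached_phantom(arr)
    sig <- assign_conductivity(ph$mesh, include_target = FALSE)
    fw <- solve_forward(assemble_cem(ph$mesh, sig, ph$electrodes), protocol16)
    U <- fw$solution$U
    expect_lt(max(abs(colSums(U))), 1e-10 * max(abs(U)))
    for (l in 1:16) {
      I <- rep(0, 16)
      I[protocol16$drive[l, 1]] <- 1e-3; I[protocol16$drive[l, 2]] <- -1e-3
      expect_gt(sum(U[, l] * I), 0)      # dissipated power
    }
    Tz <- matrix(0, 16, 16)
    for (d in 1:16) for (m in 1:16)
      Tz[d, m] <- U[protocol16$drive[m, 1], d] - U[protocol16$drive[m, 2], d]
    expect_lt(max(abs(Tz - t(Tz))) / max(abs(Tz)), 1e-8)
  }
})

test_that("voltages scale linearly with conductivity", {
  ph <- cached_phantom("external")
  sig <- assign_conductivity(ph$mesh, include_target = FALSE)
  f1 <- solve_forward(assemble_cem(ph$mesh, sig, ph$electrodes),
                      protocol16)$frame$values
  sig2 <- sig; sig2$values <- 2 * sig$values
  # exact halving when the contact drop is co-scaled
  el2 <- ph$electrodes
  for (l in seq_along(el2)) el2[[l]]$z_c <- el2[[l]]$z_c / 2
  f2 <- solve_forward(assemble_cem(ph$mesh, sig2, el2),
                      protocol16)$frame$values
  expect_lt(max(abs(f2 - f1 / 2)) / max(abs(f1)), 1e-10)
  # with fixed z_c, electrode shunting leaves a small residual
  f3 <- solve_forward(assemble_cem(ph$mesh, sig2, ph$electrodes),
                      protocol16)$frame$values
  expect_lt(max(abs(f3 - f1 / 2)) / max(abs(f1)), 0.02)
})

test_that("homogeneous frames show the per-injection U-shaped profile", {
  ph <- cached_phantom("external", include_lungs = FALSE)
  sig <- assign_conductivity(ph$mesh, include_target = FALSE)
  v <- solve_forward(assemble_cem(ph$mesh, sig, ph$electrodes),
                     protocol16)$frame$values
  for (l in 1:16) {
    a <- abs(v[(l - 1) * 13 + 1:13])
    expect_true(which.max(a) %in% c(1L, 13L))
    expect_true(which.min(a) %in% 2:12)
    # both endpoints exceed the interior minimum by a wide margin
    expect_gt(min(a[1], a[13]), 3 * min(a))
  }
})

test_that("difference frames are gauge invariant", {
  ph <- cached_phantom("external")
  sig0 <- assign_conductivity(ph$mesh, include_target = FALSE)
  sig1 <- assign_conductivity(ph$mesh, target_offset = 0.5)
  d <- list()
  for (g in c("sum", "node")) {
    f0 <- solve_forward(assemble_cem(ph$mesh, sig0, ph$electrodes, g),
                        protocol16)$frame
    f1 <- solve_forward(assemble_cem(ph$mesh, sig1, ph$electrodes, g),
                        protocol16)$frame
    d[[g]] <- difference_frame(f1, f0)$values
  }
  expect_lt(max(abs(d$sum - d$node)) / max(abs(d$sum)), 1e-8)
})

test_that("contact impedance raises drive voltages, barely moves far pairs", {
  ph <- cached_phantom("external")
  sig <- assign_conductivity(ph$mesh, include_target = FALSE)
  s1 <- solve_forward(assemble_cem(ph$mesh, sig, ph$electrodes), protocol16)
  el10 <- ph$electrodes
  for (l in seq_along(el10)) el10[[l]]$z_c <- el10[[l]]$z_c * 10
  s2 <- solve_forward(assemble_cem(ph$mesh, sig, el10), protocol16)
  dr1 <- abs(s1$solution$U[cbind(protocol16$drive[, 1], 1:16)])
  dr2 <- abs(s2$solution$U[cbind(protocol16$drive[, 1], 1:16)])
  expect_true(all(dr2 > dr1))
  expect_lt(max(abs(s2$frame$values - s1$frame$values)) /
              max(abs(s1$frame$values)), 0.05)
})

test_that("frames converge under bulk mesh refinement", {
  spec <- phantom_spec("external", include_lungs = FALSE)
  f <- lapply(c(3000, 9000, 25000), function(d) {
    ph <- build_phantom(spec, d)
    sig <- assign_conductivity(ph$mesh, spec, include_target = FALSE)
    solve_forward(assemble_cem(ph$mesh, sig, ph$electrodes),
                  protocol16)$frame$values
  })
  r1 <- sqrt(sum((f[[2]] - f[[1]])^2) / sum(f[[1]]^2))
  r2 <- sqrt(sum((f[[3]] - f[[2]])^2) / sum(f[[2]]^2))
  expect_lt(r2, r1)              # Cauchy decrease
  expect_lt(r2, 0.05)
})

test_that("assembly rejects degenerate inputs", {
  ph <- cached_phantom("external", 2000)
  sig <- assign_conductivity(ph$mesh, include_target = FALSE)
  bad_el <- ph$electrodes
  bad_el[[3]]$faces <- bad_el[[3]]$faces[0, , drop = FALSE]
  bad_el[[3]]$areas <- numeric(0)
  expect_error(assemble_cem(ph$mesh, sig, bad_el), "zero area")
  bad_sig <- sig; bad_sig$values[1] <- -1
  expect_error(assemble_cem(ph$mesh, bad_sig, ph$electrodes), "positive")
})

test_that("measurement noise respects its contract", {
  frame <- structure(list(values = rep(2e-4, 10000), protocol = protocol16,
                          noise = NULL), class = "eit_frame")
  # zero level: identity
  expect_identical(apply_noise(frame, noise_model(0, 1)), frame)
  # frame-max scaling: sample sd within 3% of level * max|V|
  n1 <- apply_noise(frame, noise_model(5e-4, 42, scaling = "frame_max"))
  expect_lt(abs(sd(n1$values - frame$values) - 5e-4 * 2e-4) / (5e-4 * 2e-4),
            0.03)
  # proportional scaling on a constant frame gives the same law
  n2 <- apply_noise(frame, noise_model(5e-4, 43))
  expect_lt(abs(sd(n2$values - frame$values) - 5e-4 * 2e-4) / (5e-4 * 2e-4),
            0.03)
  # determinism: same seed, same draw; different seed differs
  expect_identical(apply_noise(frame, noise_model(5e-4, 42))$values,
                   apply_noise(frame, noise_model(5e-4, 42))$values)
  expect_false(identical(n1$values, n2$values))
  expect_error(noise_model(-1), "non-negative")
})

test_that("difference frames subtract element-wise and check protocols", {
  ph <- cached_phantom("external", 2000)
  sig <- assign_conductivity(ph$mesh, include_target = FALSE)
  f <- solve_forward(assemble_cem(ph$mesh, sig, ph$electrodes),
                     protocol16)$frame
  expect_equal(difference_frame(f, f)$values, rep(0, 208))
  f8 <- structure(list(values = rep(0, 40), protocol = adjacent_protocol(8),
                       noise = NULL), class = "eit_frame")
  expect_error(difference_frame(f, f8), "protocol")
})
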