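# Synthetic fibrous-tissue generator and the NA-dependent degradation model.

test_that("fiber maps are seeded, bounded and scale with fiber count", {
  z <- generate_fiber_map(60, 60, n_fibers = 0, seed = 1)
  expect_equal(max(z$density), 0)
  a <- generate_fiber_map(60, 60, n_fibers = 10, seed = 2)
  b <- generate_fiber_map(60, 60, n_fibers = 10, seed = 2)
  expect_identical(a$density, b$density)
  expect_identical(a$orientation, b$orientation)
  expect_true(all(a$density >= 0 & a$density <= 1))
  expect_true(all(a$orientation >= 0 & a$orientation < pi))
  means <- vapply(c(3, 10, 30), function(nf) {
    mean(generate_fiber_map(60, 60, n_fibers = nf, seed = 7)$density)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("per-pixel composition matches explicit matrix products", {
  set.seed(14)
  h <- 3; w <- 2
  D <- matrix(runif(h * w, 0, 0.5), h, w)
  delta <- matrix(runif(h * w, 0, 2), h, w)
  Delta <- matrix(runif(h * w, 0, 0.6), h, w)
  axis <- matrix(runif(h * w, 0, pi), h, w)
  arr <- muellerscope:::compose_mueller_maps(D, delta, Delta, axis)
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      ref <- mueller_depolarizer(Delta[i, j]) %*%
        mueller_retarder(delta[i, j], axis[i, j] * 180 / pi) %*%
        mueller_diattenuator(D[i, j], axis[i, j] * 180 / pi)
      expect_mueller_equal(arr[i, j, , ], ref, 1e-12)
    }
  }
})

test_that("rendered images decompose back to the ground truth", {
  fm <- generate_fiber_map(48, 48, n_fibers = 8, seed = 21)
  img <- fiber_map_to_mueller(fm)
  truth <- attr(img, "truth")
  maps <- decompose_image(img)
  expect_lt(max(abs(maps$D_map - truth$D)), 1e-6)
  expect_lt(max(abs(maps$delta_map - truth$delta)), 1e-6)
  expect_lt(max(abs(maps$Delta_map - truth$Delta)), 1e-6)

  # zero-density map renders the identity everywhere
  z <- generate_fiber_map(8, 8, n_fibers = 0, seed = 1)
  zi <- fiber_map_to_mueller(z)
  zm <- decompose_image(zi)
  # acos near its endpoint leaves O(sqrt(eps)) round-off
  expect_lt(max(abs(zm$delta_map)), 1e-6)
  # background depolarization floor remains
  expect_equal(zm$Delta_map[1, 1], fiber_optics()$Delta_floor,
               tolerance = 1e-9)
})

test_that("rotating the orientation field leaves the magnitudes unchanged", {
  fm <- generate_fiber_map(20, 20, n_fibers = 5, seed = 33)
  rot <- fm
  rot$orientation <- (fm$orientation + pi / 2) %% pi
  m1 <- decompose_image(fiber_map_to_mueller(fm))
  m2 <- decompose_image(fiber_map_to_mueller(rot))
  expect_equal(m1$D_map, m2$D_map, tolerance = 1e-9)
  expect_equal(m1$delta_map, m2$delta_map, tolerance = 1e-9)
  expect_equal(m1$Delta_map, m2$Delta_map, tolerance = 1e-9)
})

test_that("degradation behaves like the documented PSF + area averaging", {
  # constant image passes through unchanged
  Mconst <- mueller_depolarizer(0.3) %*% mueller_retarder(0.8, 30)
  arr <- array(0, c(60, 60, 4, 4))
  for (i in 1:4) for (j in 1:4) arr[, , i, j] <- Mconst[i, j]
  img <- mueller_image(arr, pixel_pitch_um = 3.45 / 60)
  low <- degrade_resolution(img, magnification_configs("10x"))
  # 60 native pixels, pitch ratio (3.45/10)/(3.45/60) = 6 -> 10 x 10 output
  expect_equal(dim(low)[1:2], c(10, 10))
  for (i in 1:4) for (j in 1:4) {
    expect_equal(max(abs(low[, , i, j] - Mconst[i, j])), 0,
                 tolerance = 1e-9)
  }

  # near-identity limit: target pitch = native pitch, PSF << pitch
  fm <- generate_fiber_map(40, 40, n_fibers = 6, seed = 12)
  nat <- fiber_map_to_mueller(fm)
  hi <- tibble::tibble(label = "hi", mag = 60, na = 12,
                       glcm_d = 1L, camera_pitch_um = 3.45)
  out <- degrade_resolution(nat, hi)
  expect_equal(dim(out)[1:2], dim(nat)[1:2])
  expect_lt(max(abs(unclass(out) - unclass(nat))), 0.02)

  # physicality closure: degraded pixels still map physical to physical
  low10 <- degrade_resolution(nat, magnification_configs("10x"))
  set.seed(5)
  probes <- list(c(1, 1, 0, 0), c(1, 0, 1, 0), c(1, 0, 0, 1),
                 c(1, -0.4, 0.5, 0.3))
  for (k in 1:10) {
    i <- sample(dim(low10)[1], 1); j <- sample(dim(low10)[2], 1)
    M <- low10[i, j, , ]
    for (S in probes) {
      expect_true(stokes_is_physical(as.numeric(M %*% S), tol = 1e-9))
    }
  }

  # target pitch finer than native is rejected
  toofine <- tibble::tibble(label = "x", mag = 120, na = 0.9,
                            glcm_d = 1L, camera_pitch_um = 3.45)
  expect_error(degrade_resolution(low10, toofine), "finer")
})

test_that("lower magnification never sharpens the retardance texture", {
  # compare at the FOV-matched displacements of the study configuration
  # (d = 15 at 60x and d = 1 at 4x span the same physical distance)
  fm <- generate_fiber_map(120, 120, n_fibers = 15, seed = 19)
  nat <- fiber_map_to_mueller(fm)
  cfs <- magnification_configs(c("60x", "4x"))
  contrasts <- vapply(1:2, function(k) {
    maps <- decompose_image(degrade_resolution(nat, cfs[k, ]))
    g <- normalize_to_gray(maps$delta_map, 0, pi)
    glcm_features(compute_glcm(g, d = cfs$glcm_d[k], Ng = 64))$contrast
  }, numeric(1))
  expect_lte(contrasts[2], contrasts[1])
})

test_that("region sets are reproducible and pairwise distinct", {
  r1 <- generate_region_set(3, seed = 5, height = 30, width = 30)
  r2 <- generate_region_set(3, seed = 5, height = 30, width = 30)
  expect_equal(length(r1), 3)
  sig <- function(img) sum(unclass(img) * seq_along(unclass(img)))
  expect_equal(vapply(r1, sig, numeric(1)), vapply(r2, sig, numeric(1)))
  expect_equal(length(unique(vapply(r1, sig, numeric(1)))), 3)
  single <- generate_region_set(1, seed = 2, height = 20, width = 20)
  expect_equal(length(single), 1)
})
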