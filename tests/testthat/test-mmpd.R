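# Lu-Chipman polar decomposition and the per-pixel parameter maps.

test_that("diattenuation handles the canonical cases", {
  expect_equal(diattenuation(diag(4)), 0)
  expect_equal(diattenuation(mueller_of_polarizer(0)), 1)
  M <- diag(4); M[1, 2] <- 0.3; M[1, 3] <- 0.4
  expect_equal(diattenuation(M), 0.5)
  # scale invariance through M11 normalization
  expect_equal(diattenuation(3 * M), 0.5)
  Mbad <- diag(4); Mbad[1, 1] <- 0
  expect_error(diattenuation(Mbad), "M11")
})

test_that("retardance and depolarization scalar extractions are exact", {
  expect_equal(linear_retardance(diag(4)), 0)
  expect_equal(linear_retardance(mueller_retarder(pi / 2, 35)), pi / 2,
               tolerance = 1e-12)
  expect_equal(linear_retardance(mueller_retarder(pi, 10)), pi,
               tolerance = 1e-6)
  expect_equal(depolarization(diag(4)), 0)
  expect_equal(depolarization(diag(c(1, 0, 0, 0))), 1)
  expect_equal(depolarization(diag(c(1, 0.7, 0.6, 0.5))), 0.4)
})

test_that("lu_chipman inverts a constructed depolarizer-retarder-diattenuator", {
  expect_mueller_equal(lu_chipman(diag(4))$M_D, diag(4), 1e-12)
  expect_mueller_equal(lu_chipman(diag(4))$M_R, diag(4), 1e-12)
  expect_mueller_equal(lu_chipman(diag(4))$M_Delta, diag(4), 1e-12)

  M <- mueller_depolarizer(factors = c(0.7, 0.6, 0.5)) %*%
    mueller_retarder(1.0, 20) %*% mueller_diattenuator(0.2, 0)
  r <- lu_chipman(M)
  expect_equal(r$D, 0.2, tolerance = 1e-6)
  expect_equal(r$delta, 1.0, tolerance = 1e-6)
  expect_equal(r$Delta, 0.4, tolerance = 1e-6)
  expect_equal(r$axis, 20 * pi / 180, tolerance = 1e-6)
  expect_lt(r$resid, 1e-8)
})

test_that("parameter recovery holds over 500 random products", {
  set.seed(101)
  worst <- 0
  for (k in 1:500) {
    M <- random_physical_mueller(D_max = 0.9, delta_max = pi,
                                 Delta_max = 0.9)
    p <- attr(M, "params")
    r <- lu_chipman(M)
    worst <- max(worst, abs(r$D - p["D"]), abs(r$delta - p["delta"]),
                 abs(r$Delta - p["Delta"]))
    expect_lt(r$resid, 1e-8)
    expect_true(r$D >= 0 && r$D <= 1)
    expect_true(r$Delta >= 0 && r$Delta <= 1)
    expect_true(r$delta >= 0 && r$delta <= pi)
  }
  expect_lt(worst, 1e-6)
})

test_that("ideal polarizer takes the pseudo-inverse branch", {
  r <- lu_chipman(mueller_of_polarizer(0))
  expect_equal(r$D, 1, tolerance = 1e-12)
  expect_match(r$flag, "D~1")
})

test_that("decompose_image lifts the scalar case and is local", {
  # identity everywhere -> all-zero maps
  arr <- array(0, c(3, 4, 4, 4))
  for (i in 1:4) arr[, , i, i] <- 1
  img <- mueller_image(arr, pixel_pitch_um = 1)
  maps <- decompose_image(img)
  expect_equal(max(abs(maps$D_map)), 0)
  expect_equal(max(abs(maps$delta_map)), 0)
  expect_equal(max(abs(maps$Delta_map)), 0)
  expect_true(all(maps$valid))

  # single pixel of the constructed product
  M <- mueller_depolarizer(factors = rep(0.6, 3)) %*%
    mueller_retarder(1.0, 40) %*% mueller_diattenuator(0.2, 40)
  arr1 <- array(M, c(1, 1, 4, 4))
  m1 <- decompose_image(mueller_image(arr1, 1))
  expect_equal(m1$D_map[1, 1], 0.2, tolerance = 1e-6)
  expect_equal(m1$delta_map[1, 1], 1.0, tolerance = 1e-6)
  expect_equal(m1$Delta_map[1, 1], 0.4, tolerance = 1e-6)

  # per-pixel locality: permuting pixels permutes the maps
  set.seed(5)
  arr2 <- array(0, c(2, 3, 4, 4))
  for (a in 1:2) for (b in 1:3) {
    arr2[a, b, , ] <- random_physical_mueller()
  }
  base <- decompose_image(mueller_image(arr2, 1))
  perm <- arr2[2:1, c(3, 1, 2), , , drop = FALSE]
  mp <- decompose_image(mueller_image(perm, 1))
  expect_equal(mp$D_map, base$D_map[2:1, c(3, 1, 2)])
  expect_equal(mp$delta_map, base$delta_map[2:1, c(3, 1, 2)])

  expect_error(decompose_image(mueller_image(array(1, c(0, 0, 4, 4)), 1)),
               "empty")
})

test_that("compiled per-pixel kernel agrees with the scalar R reference", {
  set.seed(77)
  for (k in 1:50) {
    M <- random_physical_mueller()
    r <- lu_chipman(M)
    px <- mmpd_pixels_ref <- muellerscope:::mmpd_pixels(matrix(as.numeric(M), 16, 1))
    expect_equal(px[1, 1], r$D, tolerance = 1e-10)
    expect_equal(px[2, 1], r$delta, tolerance = 1e-8)
    expect_equal(px[3, 1], r$Delta, tolerance = 1e-10)
  }
})
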