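# Infinite-cylinder scattering series, phase functions and derived angles.

med0 <- medium_spec()

test_that("thin-cylinder amplitudes match the Rayleigh-wire closed form", {
  sp <- cylinder_spec(5)   # x ~ 0.067
  x <- size_parameter(sp, med0)
  m <- sp$n_cyl / med0$n_med
  rw <- rayleigh_wire(x, m)
  th <- seq(-180, 180, by = 15)
  amp <- cylinder_amplitudes(sp, med0, 90, th)
  # parallel channel isotropic, equal to b0 to O(x^2)
  expect_lt(max(Mod(amp$T1 - rw$b0I)) / Mod(rw$b0I), 0.01)
  # perpendicular channel is a dipole pattern 2 a1 cos(Theta)
  expect_lt(max(Mod(amp$T2 - 2 * rw$a1II * cos(th * pi / 180))) /
              Mod(2 * rw$a1II), 0.01)
  # channel amplitude ratio (m^2+1)/2
  expect_equal(Mod(amp$T1[th == 0] / amp$T2[th == 0]),
               (m^2 + 1) / 2, tolerance = 0.01)
  # cross terms vanish at normal incidence
  expect_lt(max(Mod(amp$T3)), 1e-15)
  expect_lt(max(Mod(amp$T4)), 1e-15)
})

test_that("mirror symmetry holds: co-terms even, cross-terms odd in Theta", {
  sp <- cylinder_spec(300)
  for (zeta in c(90, 60)) {
    a_p <- cylinder_amplitudes(sp, med0, zeta, c(25, 110))
    a_m <- cylinder_amplitudes(sp, med0, zeta, c(-25, -110))
    expect_equal(a_p$T1, a_m$T1, tolerance = 1e-12)
    expect_equal(a_p$T2, a_m$T2, tolerance = 1e-12)
    expect_equal(a_p$T3, -a_m$T3, tolerance = 1e-12)
    expect_equal(a_p$T4, -a_m$T4, tolerance = 1e-12)
    expect_equal(Mod(a_p$T3), Mod(a_m$T3), tolerance = 1e-12)
  }
  # oblique incidence has genuine cross-polarization
  ao <- cylinder_amplitudes(sp, med0, 60, 40)
  expect_gt(Mod(ao$T3), 1e-8)
})

test_that("series truncation is converged at the standard order", {
  for (r_nm in c(100, 1500)) {
    sp <- cylinder_spec(r_nm)
    co <- cylinder_coefficients(sp, med0, 75)
    x <- co$x
    N0 <- ceiling(x + 4 * x^(1 / 3) + 2)
    # truncating at the standard order vs the (longer) kept series
    short <- lapply(co[c("aI", "bI", "aII", "bII")],
                    function(v) v[seq_len(min(length(v), N0 + 1))])
    short$N <- min(co$N, N0)
    th <- seq(-180, 180, by = 5) * pi / 180
    a_full <- muellerscope:::amplitudes_from_coefficients(co, th)
    a_short <- muellerscope:::amplitudes_from_coefficients(short, th)
    scale <- max(Mod(a_full$T1), Mod(a_full$T2))
    err <- max(Mod(a_full$T1 - a_short$T1), Mod(a_full$T2 - a_short$T2),
               Mod(a_full$T3 - a_short$T3), Mod(a_full$T4 - a_short$T4))
    expect_lt(err / scale, 1e-10)
  }
})

test_that("phase functions normalize and concentrate forward with radius", {
  radii <- c(100, 200, 1000, 1500)
  ff <- vapply(radii, function(r) {
    pf <- phase_function(cylinder_spec(r), med0, 90)
    w <- rep(1, nrow(pf)); w[c(1, nrow(pf))] <- 0.5
    expect_equal(sum(pf$density * w), 1, tolerance = 1e-6)
    expect_true(all(pf$density >= 0))
    forward_fraction(pf, 15)
  }, numeric(1))
  # strictly increasing forward concentration across the four study radii
  expect_true(all(diff(ff) > 0))
  # coarse fibers scatter mostly within the 10x acceptance cone
  expect_gt(ff[4], ff[1])
  # monotone in the half angle, and 1 at 180 degrees
  pf <- phase_function(cylinder_spec(200), med0)
  hh <- vapply(c(5, 15, 45, 90, 180), function(h) forward_fraction(pf, h),
               numeric(1))
  expect_true(all(diff(hh) > 0))
  expect_equal(hh[length(hh)], 1, tolerance = 1e-9)
})

test_that("single-scattering Mueller matrices are pure and physical", {
  probes <- list(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, -1, 0, 0),
                 c(1, 0, 1, 0), c(1, 0, 0, -1),
                 c(1, 0.4, -0.5, 0.3))
  for (zeta in c(90, 55)) {
    for (Th in c(0, 35, 120)) {
      M <- single_scatter_mueller(cylinder_spec(400), med0, zeta, Th)
      expect_gte(M[1, 1], 0)
      for (S in probes) {
        expect_true(stokes_is_physical(as.numeric(M %*% S), tol = 1e-9))
      }
      # purity (Gil-Bernabeu depolarization index equals 1; the
      # corresponding depolarization is 0 for a single event)
      purity <- sqrt((sum(M^2) - M[1, 1]^2) / (3 * M[1, 1]^2))
      expect_equal(purity, 1, tolerance = 1e-9)
    }
  }
  # forward direction: cross terms vanish, block-diagonal matrix
  M0 <- single_scatter_mueller(cylinder_spec(400), med0, 70, 0)
  expect_lt(max(abs(M0[1:2, 3:4])), 1e-12 * M0[1, 1])
  expect_lt(max(abs(M0[3:4, 1:2])), 1e-12 * M0[1, 1])
})

test_that("acceptance half-angle matches arcsin(NA/n)", {
  expect_equal(acceptance_half_angle(0.25), 14.4775, tolerance = 1e-4)
  # the 10x objective acceptance rounds to the stated 15 degrees
  expect_equal(round(acceptance_half_angle(0.25) / 5) * 5, 15)
  expect_equal(acceptance_half_angle(0.80), 53.13, tolerance = 1e-2)
  expect_lt(acceptance_half_angle(1e-6), 1e-3)
  expect_error(acceptance_half_angle(1.2), "NA")
  expect_error(acceptance_half_angle(1.4, 1.33), "NA")
})

test_that("the first-row shortcut agrees with the full coherency transform", {
  set.seed(8)
  for (k in 1:20) {
    Tv <- complex(real = rnorm(4), imaginary = rnorm(4))
    J <- matrix(c(Tv[1], Tv[3], Tv[4], Tv[2]), 2, 2)
    M <- jones_to_mueller(J)
    r1 <- muellerscope:::mueller_first_row(Tv[1], Tv[2], Tv[3], Tv[4])
    expect_equal(c(r1$M11, r1$M12, r1$M13, r1$M14), M[1, ],
                 tolerance = 1e-12)
  }
})
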