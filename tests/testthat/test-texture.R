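# Gray normalization, first-order moments and GLCM features.

test_that("gray normalization maps ranges as documented", {
  m <- matrix(c(0, 1), 1, 2)
  g <- normalize_to_gray(m, 0, 1)
  expect_equal(as.integer(g), c(0L, 255L))
  expect_equal(as.integer(normalize_to_gray(matrix(0.5), 0, 1)), 128L)
  # constant map with automatic range: all zeros by convention
  expect_equal(as.integer(normalize_to_gray(matrix(3.7, 2, 2))),
               rep(0L, 4))
  expect_error(normalize_to_gray(m, 1, 0), "greater")
  # clipping outside an explicit range
  expect_equal(as.integer(normalize_to_gray(matrix(c(-1, 2), 1, 2), 0, 1)),
               c(0L, 255L))
})

test_that("first-order moments match hand values", {
  expect_equal(first_order_moments(matrix(7L, 3, 3)),
               c(mean = 7, entropy = 0))
  img <- matrix(c(0L, 255L), 2, 2)
  expect_equal(first_order_moments(img),
               c(mean = 127.5, entropy = 1))
  expect_equal(unname(first_order_moments(matrix(0:255, 16, 16))["entropy"]),
               8)
})

test_that("GLCM reproduces the hand-counted 2x2 example", {
  img <- normalize_to_gray(matrix(c(0, 255, 0, 255), 2, 2), 0, 255)
  # rows are (0,0) and (255,255): two horizontal pairs
  P <- compute_glcm(img, d = 1, Ng = 2, angles = 0)
  expect_equal(P[1, 1], 0.5)
  expect_equal(P[2, 2], 0.5)
  expect_equal(P[1, 2] + P[2, 1], 0)
  f <- glcm_features(P)
  expect_equal(f$energy, 0.5)
  expect_equal(f$contrast, 0)
  expect_equal(f$homogeneity, 1)
  expect_equal(f$correlation, 1)
})

test_that("GLCM degenerate and symmetry properties hold", {
  const <- normalize_to_gray(matrix(100, 4, 4), 0, 255)
  P <- compute_glcm(const, 1, Ng = 64)
  expect_equal(sum(P != 0), 1)
  k <- (100L * 64L) %/% 256L + 1L
  expect_equal(P[k, k], 1)
  f <- glcm_features(P)
  expect_equal(f$contrast, 0)
  expect_equal(f$energy, 1)
  expect_equal(f$homogeneity, 1)
  expect_true(is.na(f$correlation))

  set.seed(9)
  img <- normalize_to_gray(matrix(runif(64), 8, 8), 0, 1)
  rot <- img[8:1, 8:1]
  class(rot) <- class(img)
  for (ang in c(0, 45, 90, 135)) {
    P1 <- compute_glcm(img, 2, 16, ang)
    P2 <- compute_glcm(rot, 2, 16, ang)
    expect_equal(unclass(P1), unclass(P2), ignore_attr = TRUE)
    expect_equal(sum(rowSums(P1)), 1, tolerance = 1e-12)
    expect_equal(sum(colSums(P1)), 1, tolerance = 1e-12)
  }
  expect_error(compute_glcm(img, d = 20), "too small")
})

test_that("uniform GLCM energy is 1/Ng^2", {
  Ng <- 8
  P <- matrix(1 / Ng^2, Ng, Ng)
  expect_equal(glcm_features(P)$energy, 1 / Ng^2)
})

test_that("features match the brute-force pair-enumeration oracle", {
  set.seed(31)
  for (k in 1:8) {
    h <- sample(2:4, 1); w <- sample(2:4, 1)
    img <- normalize_to_gray(matrix(runif(h * w), h, w), 0, 1)
    d <- sample(1:2, 1)
    for (ang in c(0, 45, 90, 135)) {
      ok <- tryCatch({
        P <- compute_glcm(img, d, Ng = 8, angles = ang)
        TRUE
      }, error = function(e) FALSE)
      oo <- tryCatch(oracle_glcm_features(img, d, 8, ang),
                     error = function(e) NULL)
      expect_equal(ok, !is.null(oo))
      if (!ok) next
      expect_equal(unclass(P), oo$P, ignore_attr = TRUE)
      f <- glcm_features(P)
      expect_equal(f$contrast, oo$contrast, tolerance = 1e-12)
      expect_equal(f$energy, oo$energy, tolerance = 1e-12)
      expect_equal(f$homogeneity, oo$homogeneity, tolerance = 1e-12)
      if (is.na(f$correlation)) {
        expect_true(is.na(oo$correlation))
      } else {
        expect_equal(f$correlation, oo$correlation, tolerance = 1e-12)
      }
    }
  }
})

test_that("local averaging does not increase contrast on a fixed test set", {
  blur3 <- function(m) {
    h <- nrow(m); w <- ncol(m)
    out <- m
    for (r in seq_len(h)) {
      for (cc in seq_len(w)) {
        rs <- max(1, r - 1):min(h, r + 1)
        cs <- max(1, cc - 1):min(w, cc + 1)
        out[r, cc] <- mean(m[rs, cs])
      }
    }
    out
  }
  set.seed(12)
  for (k in 1:5) {
    m <- matrix(runif(400), 20, 20)
    g1 <- normalize_to_gray(m, 0, 1)
    g2 <- normalize_to_gray(blur3(m), 0, 1)
    c1 <- glcm_features(compute_glcm(g1, 1, 64))$contrast
    c2 <- glcm_features(compute_glcm(g2, 1, 64))$contrast
    expect_lte(c2, c1)
  }
})

test_that("texture_summary returns the six statistics", {
  set.seed(4)
  ts <- texture_summary(matrix(runif(100), 10, 10), d = 1, lo = 0, hi = 1)
  expect_equal(ts$statistic,
               c("mean", "entropy", "contrast", "correlation", "energy",
                 "homogeneity"))
  expect_true(all(is.finite(ts$value)))
})
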