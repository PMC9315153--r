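# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (textbook formulas, explicit pair
# enumeration) without calling the package's own implementations.

# --- Stokes propagation oracle for the dual-rotating-retarder train --------

oracle_rotator <- function(theta_deg) {
  a <- 2 * theta_deg * pi / 180
  matrix(c(1, 0, 0, 0,
           0, cos(a), -sin(a), 0,
           0, sin(a), cos(a), 0,
           0, 0, 0, 1), 4, 4, byrow = TRUE)
}

oracle_polarizer <- function(theta_deg) {
  P0 <- 0.5 * matrix(c(1, 1, 0, 0,
                       1, 1, 0, 0,
                       0, 0, 0, 0,
                       0, 0, 0, 0), 4, 4, byrow = TRUE)
  oracle_rotator(theta_deg) %*% P0 %*% oracle_rotator(-theta_deg)
}

oracle_qwp <- function(theta_deg) {
  W0 <- matrix(c(1, 0, 0, 0,
                 0, 1, 0, 0,
                 0, 0, 0, 1,
                 0, 0, -1, 0), 4, 4, byrow = TRUE)
  oracle_rotator(theta_deg) %*% W0 %*% oracle_rotator(-theta_deg)
}

# element-by-element Stokes propagation through the full train
oracle_drr_intensity <- function(sample, theta_deg) {
  S <- c(1, 0, 0, 0)
  S <- oracle_polarizer(0) %*% S
  S <- oracle_qwp(theta_deg) %*% S
  S <- sample %*% S
  S <- oracle_qwp(5 * theta_deg) %*% S
  S <- oracle_polarizer(0) %*% S
  S[1]
}

# --- Brute-force GLCM oracle ----------------------------------------------

oracle_glcm_features <- function(img, d, Ng, angle) {
  q <- (matrix(as.integer(img), nrow(img), ncol(img)) * Ng) %/% 256L + 1L
  off <- switch(as.character(angle),
                "0" = c(0, d), "45" = c(-d, d),
                "90" = c(-d, 0), "135" = c(-d, -d))
  P <- matrix(0, Ng, Ng)
  for (r in seq_len(nrow(q))) {
    for (cc in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        P[q[r, cc], q[r2, c2]] <- P[q[r, cc], q[r2, c2]] + 1
        P[q[r2, c2], q[r, cc]] <- P[q[r2, c2], q[r, cc]] + 1
      }
    }
  }
  if (sum(P) == 0) stop("no pairs")
  P <- P / sum(P)
  contrast <- 0; energy <- 0; homog <- 0; sij <- 0
  for (i in seq_len(Ng)) {
    for (j in seq_len(Ng)) {
      contrast <- contrast + (i - j)^2 * P[i, j]
      energy <- energy + P[i, j]^2
      homog <- homog + P[i, j] / (1 + (i - j)^2)
      sij <- sij + i * j * P[i, j]
    }
  }
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(seq_len(Ng) * px); muy <- sum(seq_len(Ng) * py)
  sx <- sqrt(sum((seq_len(Ng) - mux)^2 * px))
  sy <- sqrt(sum((seq_len(Ng) - muy)^2 * py))
  corr <- if (sx * sy > 0) (sij - mux * muy) / (sx * sy) else NA_real_
  list(P = P, contrast = contrast, correlation = corr, energy = energy,
       homogeneity = homog)
}

# --- Rayleigh thin-wire closed forms (two-term small-argument series) ------

rayleigh_wire <- function(x, m) {
  list(b0I = -1i * pi * x^2 * (m^2 - 1) / 4,
       a1II = -1i * pi * x^2 * (m^2 - 1) / (4 * (m^2 + 1)))
}

expect_mueller_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}
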