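# Independent brute-force oracles, deliberately written with plain loops
# and base arithmetic so they share no code path with the package.

# power-iteration principal eigenvector of a positive matrix
oracle_eigen_weights <- function(A, iters = 10000, tol = 1e-14) {
  w <- rep(1 / nrow(A), nrow(A))
  for (i in seq_len(iters)) {
    w2 <- as.numeric(A %*% w)
    w2 <- w2 / sum(w2)
    if (max(abs(w2 - w)) < tol) break
    w <- w2
  }
  w
}

oracle_lambda_max <- function(A, w) {
  ratios <- numeric(nrow(A))
  for (i in seq_len(nrow(A))) {
    ratios[i] <- sum(A[i, ] * w) / w[i]
  }
  mean(ratios)
}

# full single-indicator benchmark TOPSIS column, by hand
oracle_panel <- function(city, pi, ni, weight, orientation) {
  x <- c(city, pi, ni)
  nrm <- sqrt(x[1]^2 + x[2]^2 + x[3]^2)
  r <- x / nrm
  v <- weight * r
  if (orientation == "MAX") {
    ap <- max(v[1], v[2], v[3])
    an <- min(v[1], v[2], v[3])
  } else {
    ap <- min(v[1], v[2], v[3])
    an <- max(v[1], v[2], v[3])
  }
  list(r = r, v = v, a_plus = ap, a_minus = an,
       dev_plus_sq = (v[1] - ap)^2, dev_minus_sq = (v[1] - an)^2)
}

oracle_closeness <- function(dev_plus, dev_minus) {
  sp <- sqrt(sum(dev_plus))
  sm <- sqrt(sum(dev_minus))
  sm / (sp + sm)
}

# rounding convention of the printed tables (half away from zero)
rhu <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d

# a deliberately contradictory (cyclic) judgment matrix
cyclic_pcm <- function() {
  pcm(rbind(c(1, 9, 1 / 9), c(1 / 9, 1, 9), c(9, 1 / 9, 1)),
      c("A", "B", "C"))
}

# minimal two-level framework used across tests: one dimension,
# two elements, two MAX + two MIN indicators with distinct ideals
tiny_framework <- function() {
  framework(
    dimensions = tibble::tibble(code = "D1", name = "Dim"),
    elements = tibble::tibble(code = c("E1", "E2"), name = c("El 1", "El 2"),
                              dimension = "D1"),
    indicators = tibble::tibble(
      code = c("I1", "I2", "I3", "I4"),
      name = paste("ind", 1:4), unit = "index",
      orientation = c("MAX", "MIN", "MAX", "MIN"),
      positive_ideal = c(10, 2, 50, 1),
      negative_ideal = c(2, 8, 10, 9),
      element = c("E1", "E1", "E2", "E2")
    ),
    pcms = list(
      E1 = pcm(rbind(c(1, 3), c(1 / 3, 1)), c("I1", "I2")),
      E2 = pcm(rbind(c(1, 2), c(1 / 2, 1)), c("I3", "I4"))
    )
  )
}

tiny_observation <- function(fw, values = c(I1 = 6, I2 = 5, I3 = 30, I4 = 4)) {
  city_observation(values, fw, city_id = "tinytown", year = 2020)
}

# published reference values used by several test files
published_weight_vectors <- list(
  HS = c(0.48, 0.13, 0.21, 0.09, 0.09),
  CDC = c(0.53, 0.27, 0.12, 0.08),
  NCDs = c(0.33, 0.06, 0.15, 0.33, 0.06, 0.06),
  HR = c(0.29, 0.12, 0.10, 0.28, 0.05, 0.04, 0.12),
  ENDm = c(0.08, 0.21, 0.48, 0.23),
  HSS = c(0.41, 0.26, 0.06, 0.06, 0.12, 0.10),
  SS = c(0.07, 0.15, 0.39, 0.39),
  HP = c(0.32, 0.24, 0.19, 0.12, 0.12),
  ECDm = c(0.21, 0.09, 0.18, 0.52)
)
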