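# independent oracles and small utilities shared across tests

# brute-force term-by-term Fourier summation, independent of eval_fourier
fourier_oracle <- function(a0, a, b, omega, t) {
  vapply(t, function(ti) {
    s <- a0
    for (n in seq_along(a)) {
      s <- s + a[n] * cos(n * omega * ti) + b[n] * sin(n * omega * ti)
    }
    s
  }, numeric(1))
}

# random rotation matrix via Rodrigues' formula, seeded by the caller
random_rotation <- function() {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  th <- stats::runif(1, 0.1, pi)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# a straight-tube "aorta" (no arch): the cardinal side is geometrically
# undefined for it
straight_aorta <- function(length = 120, lumen_radius = 12.5) {
  m <- aorta_model(ascending_length = length)
  n <- 49L
  m$centerline <- cbind(0, 0, seq(0, length, length.out = n))
  m$radius <- rep(lumen_radius, n)
  m$segment <- rep("ascending", n)
  m
}
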