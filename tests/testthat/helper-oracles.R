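# Shared fixtures and independent oracles, all built in code at test time.

random_image <- function(n, m = n, seed = 1) {
  set.seed(seed)
  matrix(runif(n * m), n, m)
}

# Reference reflection of an index into 1:n (edge repeated), by stepping.
reflect_ref <- function(k, n) {
  while (k < 1 || k > n) {
    if (k < 1) k <- 1 - k
    if (k > n) k <- 2 * n + 1 - k
  }
  k
}

pad_ref <- function(x, p) {
  n <- nrow(x)
  m <- ncol(x)
  out <- matrix(0, n + 2 * p, m + 2 * p)
  for (r in seq_len(n + 2 * p)) {
    for (c in seq_len(m + 2 * p)) {
      out[r, c] <- x[reflect_ref(r - p, n), reflect_ref(c - p, m)]
    }
  }
  out
}

# Direct per-pixel median filter (independent of the package's C++ path).
median_direct <- function(x, r) {
  p <- pad_ref(x, r)
  out <- x
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      v <- as.numeric(p[i:(i + 2 * r), j:(j + 2 * r)])
      out[i, j] <- sort(v)[(length(v) + 1) / 2]
    }
  }
  out
}

# Direct per-pixel adaptive Wiener (independent of the box-filter path).
wiener_direct <- function(x, r, nu = NULL) {
  p <- pad_ref(x, r)
  mu <- x
  s2 <- x
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      v <- as.numeric(p[i:(i + 2 * r), j:(j + 2 * r)])
      mu[i, j] <- mean(v)
      s2[i, j] <- mean(v^2) - mean(v)^2
    }
  }
  s2 <- pmax(s2, 0)
  if (is.null(nu)) nu <- mean(s2)
  denom <- pmax(s2, nu)
  gain <- ifelse(denom > 0, pmax(s2 - nu, 0) / denom, 0)
  pmin(pmax(mu + gain * (x - mu), 0), 1)
}

# Closed-form moments of speckle clipped at 1 for a constant clean level s:
# output = min(s * R / E[R], 1), R ~ Rayleigh(1).
clipped_speckle_moments <- function(s) {
  er <- sqrt(pi / 2)
  cc <- er / s # clip threshold in Rayleigh units
  m1 <- er - sqrt(2 * pi) * (1 - pnorm(cc)) # E[min(R, c)]
  m2 <- 2 - 2 * exp(-cc^2 / 2) # E[min(R, c)^2]
  mean_out <- s * m1 / er
  sd_out <- s * sqrt(m2 - m1^2) / er
  list(mean = mean_out, sd = sd_out, cv = sd_out / mean_out)
}

# Delta-method standard error of the sample cv of n draws whose skewness and
# excess kurtosis are those of the Rayleigh distribution.
rayleigh_cv_se <- function(cv, n) {
  g1 <- 2 * sqrt(pi) * (pi - 3) / (4 - pi)^1.5
  g2 <- -(6 * pi^2 - 24 * pi + 16) / (4 - pi)^2
  sqrt(cv^2 * ((g2 + 2) / 4 + cv^2 - g1 * cv) / n)
}

as_pixel_matrix_test <- function(img) {
  matrix(as.numeric(img), nrow(img), ncol(img))
}
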