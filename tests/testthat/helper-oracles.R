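# Independent brute-force oracles and small fixture builders.

# circular (periodic) autocorrelation by direct lag sums, zero lag centred
ac3_bruteforce <- function(v) {
  d <- dim(v)
  out <- array(0, d)
  cc <- floor(d / 2) + 1
  for (a in seq_len(d[1])) for (b in seq_len(d[2])) for (cz in seq_len(d[3])) {
    la <- a - cc[1]; lb <- b - cc[2]; lc <- cz - cc[3]
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
      s <- s + v[i, j, k] *
        v[(i - 1 + la) %% d[1] + 1, (j - 1 + lb) %% d[2] + 1,
          (k - 1 + lc) %% d[3] + 1]
    }
    out[a, b, cz] <- s
  }
  out
}

# lagged central-moment products by explicit loops
cumulant_bruteforce <- function(x, order, lag) {
  dx <- x - mean(x)
  n <- length(x) - (order - 1) * lag
  s <- 0
  for (t in seq_len(n)) {
    s <- s + if (order == 2) dx[t] * dx[t + lag]
             else dx[t] * dx[t + lag] * dx[t + 2 * lag]
  }
  s / n
}

# count of frequency-grid samples inside the NA disk by explicit enumeration
na_disk_count <- function(ny, nx, spacing, wavelength, na) {
  k0 <- 2 * pi / wavelength
  cnt <- 0L
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    fy <- (if (i - 1 <= ny / 2 - (ny %% 2 == 0)) i - 1 else i - 1 - ny) / (ny * spacing)
    fx <- (if (j - 1 <= nx / 2 - (nx %% 2 == 0)) j - 1 else j - 1 - nx) / (nx * spacing)
    if ((2 * pi)^2 * (fy^2 + fx^2) <= (na * k0)^2) cnt <- cnt + 1L
  }
  cnt
}

# band-limit a white-noise image at a radial cutoff (Nyquist units)
lowpass_noise <- function(n, cutoff, seed) {
  set.seed(seed)
  img <- matrix(rnorm(n * n), n)
  F <- stats::fft(img)
  f <- c(seq.int(0, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1)) / (n / 2)
  r <- sqrt(outer(f^2, f^2, `+`))
  F[r > cutoff] <- 0i
  Re(stats::fft(F, inverse = TRUE)) / (n * n)
}

small_optics <- function(nz = 16L, ny = 32L, nx = 32L, ...) {
  optical_config(grid_shape = c(nz, ny, nx), ...)
}

# a smooth high-SNR test image for registration
smooth_test_image <- function(n = 64, seed = 1) {
  set.seed(seed)
  lowpass_noise(n, 0.4, seed) + outer(exp(-((1:n) - n / 3)^2 / 60),
                                      exp(-((1:n) - n / 2)^2 / 80))
}
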