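# Internal numerical helpers: FFT wrappers, frequency grids, seeding,
# sub-voxel shifting and cubic resampling. All FFT-based operations use
# periodic boundary conditions.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

fftn <- function(x) stats::fft(x)

ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' @noRd
fft_freq <- function(n, d = 1) {
  # cycles per physical unit, standard FFT ordering
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

# circular shift of an array along one dimension
circshift_dim <- function(x, shift, dim) {
  n <- dim(x)[dim]
  shift <- ((shift %% n) + n) %% n
  if (shift == 0) return(x)
  idx <- c(seq.int(n - shift + 1, n), seq.int(1, n - shift))
  args <- rep(list(quote(expr = )), length(dim(x)))
  args[[dim]] <- idx
  do.call(`[`, c(list(x), args, list(drop = FALSE)))
}

fftshift_nd <- function(x) {
  for (d in seq_along(dim(x))) x <- circshift_dim(x, floor(dim(x)[d] / 2), d)
  x
}

ifftshift_nd <- function(x) {
  for (d in seq_along(dim(x))) x <- circshift_dim(x, ceiling(dim(x)[d] / 2), d)
  x
}

# centre index of a length-n axis (zero coordinate / zero lag position)
centre_index <- function(n) floor(n / 2) + 1L

axis_coords <- function(n, spacing) (seq_len(n) - centre_index(n)) * spacing

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so that seeded operations do
#' not perturb the global random stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed and integer indices
#'
#' Deterministic mixing keeps every stochastic stage independently seeded
#' while a single master seed reproduces a whole run. Result is in
#' [1, 2^31 - 2].
#' @noRd
derive_seed <- function(master, ...) {
  idx <- c(...)
  m <- 2147483647                      # 2^31 - 1 (prime)
  h <- as.numeric(master) %% m
  for (v in idx) {
    h <- (h * 48271 + as.numeric(v) * 16807 + 12345) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# sub-pixel shift of a 2-D image by (dy, dx) pixels via Fourier phase ramp;
# out(y, x) = in(y - dy, x - dx) with periodic wrap-around
fourier_shift2 <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  fy <- fft_freq(ny); fx <- fft_freq(nx)
  ph <- exp(-2i * pi * (outer(fy * dy, fx * dx, `+`)))
  Re(ifft2(fft2(img) * ph))
}

# Keys cubic-convolution interpolation weights (a = -0.5)
keys_weight <- function(s) {
  s <- abs(s)
  w <- numeric(length(s))
  i1 <- s < 1
  i2 <- !i1 & s < 2
  w[i1] <- 1.5 * s[i1]^3 - 2.5 * s[i1]^2 + 1
  w[i2] <- -0.5 * s[i2]^3 + 2.5 * s[i2]^2 - 4 * s[i2] + 2
  w
}

# sparse-ish interpolation matrix mapping samples at integer positions
# 1..n_old onto arbitrary positions `at` (same units); out-of-range rows are 0
cubic_interp_matrix <- function(n_old, at) {
  W <- matrix(0, length(at), n_old)
  for (i in seq_along(at)) {
    p <- at[i]
    if (p < 1 - 1e-9 || p > n_old + 1e-9) next
    j0 <- floor(p)
    js <- (j0 - 1):(j0 + 2)
    w <- keys_weight(p - js)
    keep <- js >= 1 & js <= n_old
    # clamp boundary support so edge values are extended, not lost
    jc <- pmin(pmax(js, 1), n_old)
    for (k in seq_along(js)) W[i, jc[k]] <- W[i, jc[k]] + w[k]
  }
  W
}

# apply a (n_new x n_old) resampling matrix along the 3rd (z) axis of a volume
apply_along_z <- function(vol, W) {
  d <- dim(vol)
  m <- matrix(aperm(vol, c(3, 1, 2)), nrow = d[3])
  out <- W %*% m
  aperm(array(out, c(nrow(W), d[1], d[2])), c(2, 3, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar", name), call. = FALSE)
}
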