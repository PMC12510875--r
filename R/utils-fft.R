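# FFT helpers shared by the simulator and the reconstruction code.
# Conventions: even/odd-safe fftshift moves DC to index floor(n/2)+1 (1-based);
# frequencies from fft_freq() are in cycles per unit length.

fft2 <- function(x) stats::fft(x)

ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

fft_freq <- function(n, d = 1) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / (n * d)
}

fftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[c((floor(n1 / 2) + 1):n1, 1:floor(n1 / 2)),
    c((floor(n2 / 2) + 1):n2, 1:floor(n2 / 2))]
}

ifftshift2 <- function(x) {
  n1 <- nrow(x); n2 <- ncol(x)
  x[c((n1 - floor(n1 / 2) + 1):n1, 1:(n1 - floor(n1 / 2))),
    c((n2 - floor(n2 / 2) + 1):n2, 1:(n2 - floor(n2 / 2)))]
}

# Circular integer roll of a matrix by (dy, dx): positive moves content down/right.
roll2 <- function(x, dy, dx) {
  n1 <- nrow(x); n2 <- ncol(x)
  dy <- ((dy %% n1) + n1) %% n1
  dx <- ((dx %% n2) + n2) %% n2
  if (dy > 0) x <- x[c((n1 - dy + 1):n1, 1:(n1 - dy)), , drop = FALSE]
  if (dx > 0) x <- x[, c((n2 - dx + 1):n2, 1:(n2 - dx)), drop = FALSE]
  x
}

# Subpixel circular translation by (dy, dx) pixels via a Fourier phase ramp.
fourier_shift <- function(x, dy, dx) {
  n1 <- nrow(x); n2 <- ncol(x)
  fy <- fft_freq(n1); fx <- fft_freq(n2)
  ramp <- exp(-2i * pi * (outer(fy, rep(1, n2)) * dy +
                          outer(rep(1, n1), fx) * dx))
  Re(ifft2(fft2(x) * ramp))
}

# Periodic Gaussian blur of a matrix, sigma in pixels.
gauss_blur2 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n1 <- nrow(x); n2 <- ncol(x)
  fy <- fft_freq(n1); fx <- fft_freq(n2)
  h <- exp(-2 * pi^2 * sigma^2 * (outer(fy^2, rep(1, n2)) +
                                  outer(rep(1, n1), fx^2)))
  Re(ifft2(fft2(x) * h))
}

# Box-bin a matrix by integer factor b in both axes.
bin2 <- function(x, b) {
  if (b == 1) return(x)
  n1 <- nrow(x) %/% b; n2 <- ncol(x) %/% b
  x <- x[seq_len(n1 * b), seq_len(n2 * b), drop = FALSE]
  dim(x) <- c(b, n1, b, n2)
  colSums(colSums(aperm(x, c(1, 3, 2, 4))))
}

# Zero-padded Fourier upsampling of a real matrix by integer factor s.
fourier_upsample <- function(x, s) {
  if (s == 1) return(x)
  n1 <- nrow(x); n2 <- ncol(x)
  X <- fftshift2(fft2(x))
  big <- matrix(0i, n1 * s, n2 * s)
  r0 <- floor(n1 * s / 2) - floor(n1 / 2)
  c0 <- floor(n2 * s / 2) - floor(n2 / 2)
  big[r0 + seq_len(n1), c0 + seq_len(n2)] <- X
  Re(ifft2(ifftshift2(big))) * s^2
}
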