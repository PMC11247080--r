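# 2-D convolution with reflect padding, for the small odd kernels the
# sharpening stage uses. Returns an unclipped signed field.
conv2_reflect <- function(m, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  stopifnot(kh %% 2 == 1, kw %% 2 == 1)
  ry <- (kh - 1L) %/% 2L
  rx <- (kw - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  # reflect indices (edge pixel not repeated): 2,1 | 1..n | n, n-1 — folded
  # periodically so kernels wider than the image remain defined
  refl <- function(idx, n) {
    if (n == 1L) return(rep(1L, length(idx)))
    p <- 2L * n - 2L
    j <- (idx - 1L) %% p
    ifelse(j < n, j + 1L, 2L * n - 1L - j)
  }
  rows <- refl(seq.int(1L - ry, h + ry), h)
  cols <- refl(seq.int(1L - rx, w + rx), w)
  pad <- m[rows, cols, drop = FALSE]
  out <- matrix(0, h, w)
  # convolution flips the kernel relative to correlation
  kflip <- kernel[kh:1, kw:1, drop = FALSE]
  for (dy in seq_len(kh)) {
    for (dx in seq_len(kw)) {
      out <- out + kflip[dy, dx] *
        pad[(dy - 1L) + seq_len(h), (dx - 1L) + seq_len(w), drop = FALSE]
    }
  }
  out
}

gaussian_kernel <- function(sigma) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- seq.int(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}
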