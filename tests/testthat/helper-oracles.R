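# Independent brute-force oracles used to validate the compiled kernels.

# half-sample symmetric reflection, 1-based
reflectIndex <- function(i, n) {
  while (i < 1L || i > n) {
    if (i < 1L) i <- 1L - i else i <- 2L * n + 1L - i
  }
  i
}

# per-pixel histogram entropy oracle: explicit loop over disk offsets
bruteEntropy <- function(px, radius) {
  off <- diskOffsets(radius)
  H <- nrow(px); W <- ncol(px)
  out <- matrix(0, H, W)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    vals <- integer(nrow(off))
    for (k in seq_len(nrow(off)))
      vals[k] <- px[reflectIndex(y + off[k, 1L], H),
                    reflectIndex(x + off[k, 2L], W)]
    counts <- tabulate(vals + 1L, nbins = 256L)
    p <- counts[counts > 0L] / nrow(off)
    out[y, x] <- -sum(p * log2(p))
  }
  out
}

# closed-form lattice count of a disk: sum over dy of the row extent
diskCountOracle <- function(radius) {
  dy <- seq.int(-radius, radius)
  sum(2L * floor(sqrt(radius^2 - dy^2)) + 1L)
}

randomGrayImage <- function(h, w, seed) {
  set.seed(seed)
  grayImage(matrix(sample(0:255, h * w, replace = TRUE), h, w))
}

flipH <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
flipV <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
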