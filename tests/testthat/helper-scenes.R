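# Shared fixture builders and independent oracles.

noiseless_spec <- function(...) {
  scene_spec(read_sigma = 0, shot_scale = 0, ...)
}

# Random scene at a given crystal SNR (Inf = noiseless); seeded.
random_spec <- function(seed, snr = Inf, max_offset_um = 40, ...) {
  set.seed(seed)
  off <- stats::runif(3, -max_offset_um, max_offset_um)
  scene_spec(crystal_offset_um = off, seed = seed,
             shot_scale = if (is.finite(snr)) sqrt(0.9) / snr else 0,
             read_sigma = if (is.finite(snr)) 0.01 else 0, ...)
}

# Brute-force normalized cross-correlation at a single placement
# (1-based top-left indices); the independent oracle for match_pattern.
ncc_oracle <- function(f, tmpl, i, j) {
  win <- f[i:(i + nrow(tmpl) - 1), j:(j + ncol(tmpl) - 1)]
  wv <- win - mean(win); tv <- tmpl - mean(tmpl)
  den <- sqrt(sum(wv^2)) * sqrt(sum(tv^2))
  if (den == 0) return(0)
  sum(wv * tv) / den
}

# Brute-force dense correlation with symmetric (mirror) padding; the
# independent oracle for the LoG convolution.
conv_oracle <- function(px, k) {
  K <- nrow(k); h <- (K - 1) / 2
  nr <- nrow(px); nc <- ncol(px)
  mirror <- function(i, n) {
    i <- ((i - 1) %% (2 * n) + 2 * n) %% (2 * n) + 1
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    acc <- 0
    for (a in -h:h) for (b in -h:h)
      acc <- acc + k[a + h + 1, b + h + 1] *
        px[mirror(i + a, nr), mirror(j + b, nc)]
    out[i, j] <- acc
  }
  out
}

expect_no_error <- function(expr) {
  expect_error(expr, NA)
}
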