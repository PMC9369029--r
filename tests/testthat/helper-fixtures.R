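# Shared fixtures: sequences are built in code, never stored.

# 90-bp promoter with the plant TATA consensus planted at 1-based offset 43
# (flanked so the default 15-bp PWM window aligns with its consensus core).
consensus_promoter <- function(offset = 43L, length = 90L) {
  cons <- "TCACTATATATAG"
  left <- strrep("GC", 30L)
  seqc <- strsplit(strrep("GC", 45L), "")[[1]]
  seqc[offset:(offset + nchar(cons) - 1L)] <- strsplit(cons, "")[[1]]
  paste(seqc, collapse = "")
}

# Random DNA string; assumes the caller fixed the RNG seed.
rand_dna <- function(n = 90L) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

quiet_promoter <- function(seq, id = "p") {
  suppressWarnings(validate_promoter(seq, id = id, expected_length = NULL))
}

# Brute-force window scorer independent of the package implementation:
# per-position PWM lookup-and-sum plus explicit dinucleotide sums.
oracle_windows <- function(seq, m) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  w <- m$window_w
  t(vapply(0:(L - w), function(s) {
    win <- chars[(s + 1):(s + w)]
    stop_score <- 0
    for (j in seq_len(w)) stop_score <- stop_score + m$pwm[win[j], j]
    dn <- paste0(win[-w], win[-1])
    c(start = s, stop_score = stop_score,
      slide_score = sum(m$slide_scale[dn]),
      bend_score = sum(m$bend_scale[dn]))
  }, c(start = 0, stop_score = 0, slide_score = 0, bend_score = 0)))
}

# O(n^2) concordant/discordant pair enumeration, independent of the
# package's vectorized counting.
oracle_pairs <- function(x, y) {
  n <- length(x)
  C <- 0L; D <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) C <- C + 1L else if (s < 0) D <- D + 1L
    }
  }
  list(C = C, D = D)
}

oracle_gamma <- function(x, y) {
  p <- oracle_pairs(x, y)
  (p$C - p$D) / (p$C + p$D)
}

oracle_tau_b <- function(x, y) {
  p <- oracle_pairs(x, y)
  n0 <- length(x) * (length(x) - 1) / 2
  tx <- table(x); ty <- table(y)
  (p$C - p$D) / sqrt((n0 - sum(tx * (tx - 1)) / 2) *
                       (n0 - sum(ty * (ty - 1)) / 2))
}
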