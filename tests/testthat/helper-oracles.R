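# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation it checks.

# Two-sided Fisher p by explicit enumeration with log-factorial arithmetic
# (the package uses dhyper; this uses lchoose directly).
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; n <- m1 + m2
  ks <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, ks) + lchoose(m2, k - ks) - lchoose(n, k)
  p_obs <- logp[ks == a]
  min(1, sum(exp(logp[logp <= p_obs + log(1 + 1e-7)])))
}

# Weir-Cockerham components by the nested ANOVA on allele indicator
# variables (expanded per-individual data; mean squares -> a, b, c).
wc_anova_oracle <- function(gc1, gc2) {
  expand <- function(gc) {
    rbind(matrix(1, gc[1], 2),
          if (gc[2] > 0) matrix(rep(c(1, 0), gc[2]), gc[2], 2, byrow = TRUE),
          matrix(0, gc[3], 2))
  }
  pops <- list(expand(gc1), expand(gc2))
  n <- vapply(pops, nrow, integer(1)); r <- 2
  xbar <- mean(unlist(pops))
  MSP <- sum(2 * n * (vapply(pops, mean, 0) - xbar)^2) / (r - 1)
  MSI <- sum(vapply(pops, function(x) sum(2 * (rowMeans(x) - mean(x))^2), 0)) /
    (sum(n) - r)
  MSG <- sum(vapply(pops, function(x) sum((x - rowMeans(x))^2), 0)) / sum(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  a <- (MSP - MSI) / (2 * nc)
  b <- (MSI - MSG) / 2
  c <- MSG
  list(a = a, b = b, c = c, theta = a / (a + b + c))
}

# pi by explicit all-pairs Hamming distance over haplotypes, averaged and
# divided by window length (package route: per-site heterozygosity sums).
pi_oracle <- function(h, window_length) {
  n <- ncol(h)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(h[, i] != h[, j])
  }
  tot / choose(n, 2) / window_length
}

# Tajima's D with constants written out directly from the 1989 definitions.
tajima_oracle <- function(h) {
  n <- ncol(h)
  dac <- rowSums(h)
  seg <- dac > 0 & dac < n
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    k <- k + sum(h[seg, i, drop = FALSE] != h[seg, j, drop = FALSE])
  }
  kbar <- k / choose(n, 2)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (kbar - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# small SV matrix fixture
make_sv_fixture <- function(dosages, chrom = "chr1",
                            start = seq(1000, by = 5000,
                                        length.out = nrow(dosages))) {
  n <- nrow(dosages)
  rec <- data.frame(id = sprintf("SV%03d", seq_len(n)), chrom = chrom,
                    start = start, end = start + 200, svtype = "DEL",
                    svlen = 200, stringsAsFactors = FALSE)
  sv_genotype_matrix(rec, sprintf("s%02d", seq_len(ncol(dosages))), dosages)
}
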