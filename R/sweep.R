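#' Nucleotide diversity per site over a window
#'
#' Per segregating site the unbiased heterozygosity
#' `2 p (1 - p) * n / (n - 1)` with `n` called haplotypes, summed over
#' sites and divided by the window length. Diploid dosage input counts 2n
#' haplotypes via allele frequencies (no phasing needed).
#'
#' @param x sites x haplotypes 0/1 matrix, or sites x samples dosage
#'   matrix with `ploidy = 2`. `NA` entries are excluded per site.
#' @param window_length window size in bp (> 0).
#' @param ploidy 1 for haplotypes (default), 2 for diploid dosages.
#' @return pi per bp.
#' @export
pi_per_site <- function(x, window_length, ploidy = 1) {
  if (window_length <= 0) stop("window length must be > 0", call. = FALSE)
  x <- as.matrix(x)
  if (nrow(x) == 0L) return(0)
  n_h <- ploidy * rowSums(!is.na(x))
  if (any(n_h < 2)) stop("need >= 2 called haplotypes at every site", call. = FALSE)
  p <- rowSums(x, na.rm = TRUE) / n_h
  sum(2 * p * (1 - p) * n_h / (n_h - 1)) / window_length
}

#' Tajima (1989) constants for n haplotypes
#'
#' @param n haplotype count (>= 4).
#' @return list a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  if (n < 4) stop("need n >= 4 haplotypes", call. = FALSE)
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2, e1 = e1, e2 = e2)
}

#' Tajima's D for a window of haplotypes
#'
#' `D = (kbar - S/a1) / sqrt(e1 S + e2 S (S - 1))` with `kbar` the mean
#' pairwise difference count and `S` the number of segregating sites.
#' Undefined (returned as `NA`) when `S = 0`.
#'
#' @param h sites x haplotypes 0/1 matrix (complete; no missing entries).
#' @return list: n, S, kbar, D, plus the Tajima constants.
#' @export
tajimas_d <- function(h) {
  h <- as.matrix(h)
  n <- ncol(h)
  if (n < 4) stop("need n >= 4 haplotypes", call. = FALSE)
  if (anyNA(h)) stop("haplotype matrix must be complete", call. = FALSE)
  dac <- rowSums(h)
  seg <- dac > 0 & dac < n
  S <- sum(seg)
  cst <- tajima_constants(n)
  if (S == 0L) {
    return(c(list(n = n, S = 0L, kbar = 0, D = NA_real_), cst))
  }
  j <- dac[seg]
  kbar <- sum(j * (n - j)) / choose(n, 2)
  D <- (kbar - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
  c(list(n = n, S = S, kbar = kbar, D = D), cst)
}

#' Expand diploid dosages to pseudo-haplotypes
#'
#' 0 -> (0,0), 1 -> (0,1), 2 -> (1,1). An unphased approximation: allele
#' counts are exact, within-individual phase is arbitrary.
#'
#' @param dos sites x samples dosage matrix in 0/1/2 (complete).
#' @return sites x 2*samples 0/1 matrix.
#' @export
genotypes_to_haplotypes <- function(dos) {
  dos <- as.matrix(dos)
  if (anyNA(dos)) stop("dosage matrix must be complete", call. = FALSE)
  h1 <- (dos >= 1) * 1L
  h2 <- (dos >= 2) * 1L
  h <- matrix(0L, nrow(dos), 2L * ncol(dos))
  h[, seq(1, 2 * ncol(dos), 2)] <- h2
  h[, seq(2, 2 * ncol(dos), 2)] <- h1
  h
}

#' Window/step presets for sweep scans
#'
#' 20 kb windows with 20 kb step for pi and windowed F_ST; 10 kb windows
#' with 5 kb step for Tajima's D.
#'
#' @param statistic "pi", "fst" or "tajima_d".
#' @return list with `window` and `step` in bp.
#' @export
sweep_preset <- function(statistic = c("pi", "fst", "tajima_d")) {
  statistic <- match.arg(statistic)
  if (statistic == "tajima_d") list(window = 10000L, step = 5000L)
  else list(window = 20000L, step = 20000L)
}

#' Sliding-window diversity scan
#'
#' Windows tile each chromosome at the given step (overlapping windows
#' allowed when step < window). Per window: `pi` (per bp), `tajima_d`
#' (genotypes expanded to 2n pseudo-haplotypes), or `fst` — the
#' Weir-Cockerham ratio-of-sums estimator `sum(a) / sum(a + b + c)` over
#' the window's sites for a two-group contrast (equal to the single-locus
#' theta-hat when the window holds one site). Windows with no usable sites
#' are reported with `NA`.
#'
#' @param mat an `sv_matrix` (SNP VCFs read with [read_sv_vcf()]'s
#'   conventions work the same; only positions and dosages are used). Sites
#'   are located at their interval start.
#' @param layout a [genome_layout()].
#' @param statistic "pi", "tajima_d" or "fst".
#' @param window,step window and step in bp; defaults from
#'   [sweep_preset()].
#' @param metadata,contrast required for `fst`: sample metadata and the
#'   two group labels.
#' @return data frame: chrom, start, end, n_sites, value.
#' @export
windowed_scan <- function(mat, layout, statistic = c("pi", "tajima_d", "fst"),
                          window = NULL, step = NULL,
                          metadata = NULL, contrast = NULL) {
  statistic <- match.arg(statistic)
  preset <- sweep_preset(statistic)
  window <- window %||% preset$window
  step <- step %||% preset$step
  if (step <= 0) stop("step must be > 0", call. = FALSE)
  pos <- mat$records$start
  chrom <- mat$records$chrom
  comp <- NULL
  if (statistic == "fst") {
    if (is.null(metadata) || is.null(contrast)) {
      stop("fst scan needs metadata and a contrast", call. = FALSE)
    }
    cnt <- group_allele_counts(mat, metadata, groups = contrast)
    A <- cnt[[contrast[1]]]; B <- cnt[[contrast[2]]]
    comp <- wc_fst(A$n, ifelse(A$m > 0, A$d / A$m, NA),
                   A$h / pmax(A$n, 1),
                   B$n, ifelse(B$m > 0, B$d / B$m, NA),
                   B$h / pmax(B$n, 1))
    usable <- A$n >= 2 & B$n >= 2 & is.finite(comp$a)
  } else {
    usable <- rep(TRUE, nrow(mat$records))
  }
  out <- list()
  for (k in seq_len(nrow(layout))) {
    ch <- layout$chrom[k]
    L <- layout$length[k]
    starts <- seq(0, max(0, L - 1), by = step)
    starts <- starts[starts < L]
    # full windows only; when tiling (step == window) keep the last partial
    full <- starts + window <= L
    if (step == window) full <- full | starts < L
    starts <- starts[full]
    ends <- pmin(starts + window, L)
    val <- rep(NA_real_, length(starts))
    nsit <- integer(length(starts))
    on_ch <- which(chrom == ch & usable)
    for (wi in seq_along(starts)) {
      ii <- on_ch[pos[on_ch] >= starts[wi] & pos[on_ch] < ends[wi]]
      nsit[wi] <- length(ii)
      if (!length(ii)) next
      if (statistic == "pi") {
        val[wi] <- pi_per_site(mat$dosages[ii, , drop = FALSE],
                               ends[wi] - starts[wi], ploidy = 2)
      } else if (statistic == "tajima_d") {
        h <- genotypes_to_haplotypes(mat$dosages[ii, , drop = FALSE])
        val[wi] <- tajimas_d(h)$D
      } else {
        denom <- sum(comp$a[ii] + comp$b[ii] + comp$c[ii])
        val[wi] <- if (denom == 0) NA_real_ else sum(comp$a[ii]) / denom
      }
    }
    out[[k]] <- data.frame(chrom = ch, start = starts, end = ends,
                           n_sites = nsit, value = val,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
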