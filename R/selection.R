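#' Per-group allele counts at every SV
#'
#' The ALT (non-reference) allele is counted as derived; missing dosages
#' are excluded from numerator and denominator alike.
#'
#' @param mat an `sv_matrix`.
#' @param metadata data frame with `sample`, `group`.
#' @param groups group labels to tabulate (default: all in metadata).
#' @return list of per-group data frames with columns `d` (derived allele
#'   count), `m` (called alleles), `h` (observed heterozygotes), `n`
#'   (called samples), one row per SV.
#' @export
group_allele_counts <- function(mat, metadata, groups = unique(metadata$group)) {
  missing_samples <- setdiff(mat$samples, metadata$sample)
  if (length(missing_samples)) {
    stop(sprintf("sample(s) without group assignment: %s",
                 paste(head(missing_samples, 3), collapse = ", ")), call. = FALSE)
  }
  grp <- setNames(metadata$group, metadata$sample)[mat$samples]
  out <- lapply(groups, function(g) {
    d <- mat$dosages[, grp == g, drop = FALSE]
    n <- rowSums(!is.na(d))
    data.frame(d = rowSums(d, na.rm = TRUE), m = 2L * n,
               h = rowSums(d == 1L, na.rm = TRUE), n = n)
  })
  names(out) <- groups
  out
}

#' Filter SVs on pooled minor-allele frequency
#'
#' @param mat an `sv_matrix` (biallelic by construction).
#' @param min_maf sites with pooled MAF < `min_maf` are removed
#'   (default 0.01).
#' @return filtered `sv_matrix`.
#' @export
maf_filter <- function(mat, min_maf = 0.01) {
  af <- allele_frequency(mat)
  maf <- pmin(af, 1 - af)
  keep <- !is.na(maf) & maf >= min_maf
  mat[keep, ]
}

#' Two-sided Fisher's exact p-value for 2x2 tables
#'
#' Exact hypergeometric enumeration: with margins fixed, p is the sum of
#' the probabilities of all tables whose probability does not exceed that
#' of the observed table (the minimum-likelihood two-sided convention of
#' mainstream statistical software). Vectorised over tables.
#'
#' @param a,b,c,d cell counts (`a b / c d`); vectors are recycled.
#' @return numeric p-values in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n); c <- rep_len(c, n); d <- rep_len(d, n)
  if (any(c(a, b, c, d) < 0)) stop("negative cell count", call. = FALSE)
  vapply(seq_len(n), function(i) {
    m1 <- a[i] + b[i]          # row 1 total ("white balls")
    m2 <- c[i] + d[i]
    k <- a[i] + c[i]           # column 1 total (draws)
    lo <- max(0L, k - m2); hi <- min(k, m1)
    probs <- dhyper(lo:hi, m1, m2, k)
    p_obs <- dhyper(a[i], m1, m2, k)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' @param p numeric p-values in \[0, 1\].
#' @return q-values (monotone step-up adjustment).
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]", call. = FALSE)
  p.adjust(p, method = "BH")
}

#' Weir-Cockerham single-locus F_ST for two groups
#'
#' The Weir & Cockerham (1984) moment estimator theta-hat = a / (a + b + c)
#' from per-group called sample sizes `n`, ALT allele frequencies `p` and
#' observed heterozygote proportions `h`. Vectorised over loci. Monomorphic
#' loci (a + b + c = 0) and loci where either group has fewer than 2 called
#' samples return `NA`.
#'
#' @param n1,p1,h1 group 1: called samples, allele frequency, heterozygote
#'   proportion.
#' @param n2,p2,h2 group 2 likewise.
#' @return data frame with components `a`, `b`, `c` and `theta`.
#' @export
wc_fst <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  c <- hbar / 2
  theta <- a / (a + b + c)
  bad <- (a + b + c) == 0 | n1 < 2 | n2 < 2
  theta[bad] <- NA_real_
  data.frame(a = a, b = b, c = c, theta = theta)
}

#' Scan SVs for selection between two groups
#'
#' Per SV: a two-sided Fisher's exact test on the derived-vs-other allele
#' counts of the two groups, BH adjustment over all tested SVs, and the
#' Weir-Cockerham theta-hat. An SV is selected when q <= `fdr` AND
#' theta-hat is at or above the empirical `fst_quantile` of the contrast's
#' non-missing theta-hat values. Direction is `increased` when the second
#' (later) group's frequency is higher (domestication contrast: wild ->
#' native; improvement: native -> commercial), `decreased` when lower,
#' `none` when equal.
#'
#' @param mat an `sv_matrix` (apply [maf_filter()] first).
#' @param metadata data frame with `sample`, `group`.
#' @param contrast character vector `c(groupA, groupB)`, earlier group
#'   first.
#' @param fdr FDR threshold on q (default 0.001).
#' @param fst_quantile empirical quantile of theta-hat (default 0.99).
#' @param count_unit "alleles" (default) or "genotypes" for the Fisher
#'   table.
#' @return data frame, one row per SV: id, af_a, af_b, fisher_p, q, fst,
#'   fst_rank, selected, direction.
#' @export
scan_selection <- function(mat, metadata, contrast, fdr = 0.001,
                           fst_quantile = 0.99,
                           count_unit = c("alleles", "genotypes")) {
  count_unit <- match.arg(count_unit)
  if (length(contrast) != 2L || contrast[1] == contrast[2]) {
    stop("contrast must name two distinct groups", call. = FALSE)
  }
  if (!all(contrast %in% metadata$group)) {
    stop(sprintf("contrast group(s) absent from metadata: %s",
                 paste(setdiff(contrast, metadata$group), collapse = ", ")),
         call. = FALSE)
  }
  cnt <- group_allele_counts(mat, metadata, groups = contrast)
  A <- cnt[[contrast[1]]]; B <- cnt[[contrast[2]]]
  af_a <- ifelse(A$m > 0, A$d / A$m, NA_real_)
  af_b <- ifelse(B$m > 0, B$d / B$m, NA_real_)
  if (count_unit == "alleles") {
    p <- fisher_exact_two_sided(A$d, A$m - A$d, B$d, B$m - B$d)
  } else {
    carA <- A$h + (A$d - A$h) / 2   # carriers of >= 1 derived allele
    carB <- B$h + (B$d - B$h) / 2
    p <- fisher_exact_two_sided(round(carA), A$n - round(carA),
                                round(carB), B$n - round(carB))
  }
  q <- bh_adjust(p)
  w <- wc_fst(A$n, af_a, A$h / pmax(A$n, 1), B$n, af_b, B$h / pmax(B$n, 1))
  thr <- quantile(w$theta, fst_quantile, na.rm = TRUE, names = FALSE)
  selected <- !is.na(q) & q <= fdr & !is.na(w$theta) & w$theta >= thr
  direction <- ifelse(is.na(af_a) | is.na(af_b) | af_a == af_b, "none",
                      ifelse(af_b > af_a, "increased", "decreased"))
  data.frame(id = mat$records$id, af_a = af_a, af_b = af_b,
             fisher_p = p, q = q, fst = w$theta,
             fst_rank = rank(-w$theta, na.last = "keep"),
             selected = selected, direction = direction,
             stringsAsFactors = FALSE)
}

#' Absolute allele-frequency difference within a region
#'
#' Ranks variants in a genomic region by |AF(high group) - AF(low group)|,
#' descending; ties broken by ascending position for deterministic output.
#'
#' @param mat an `sv_matrix` (SNPs read through [read_sv_vcf()] work too).
#' @param metadata data frame with `sample`, `group`.
#' @param group_hi,group_lo group labels to compare.
#' @param region single-row [intervals()] frame, or `NULL` for all sites.
#' @return data frame: id, chrom, start, daf, rank.
#' @export
delta_af <- function(mat, metadata, group_hi, group_lo, region = NULL) {
  keep <- rep(TRUE, nrow(mat$records))
  if (!is.null(region)) {
    keep <- mat$records$chrom == region$chrom[1] &
      mat$records$start < region$end[1] & mat$records$end > region$start[1]
  }
  if (!any(keep)) {
    warning("no variants inside region")
    return(data.frame(id = character(), chrom = character(), start = numeric(),
                      daf = numeric(), rank = integer()))
  }
  sub <- mat[keep, ]
  hi <- metadata$sample[metadata$group == group_hi]
  lo <- metadata$sample[metadata$group == group_lo]
  daf <- abs(allele_frequency(sub, hi) - allele_frequency(sub, lo))
  ord <- order(-daf, sub$records$start)
  out <- data.frame(id = sub$records$id[ord], chrom = sub$records$chrom[ord],
                    start = sub$records$start[ord], daf = daf[ord],
                    stringsAsFactors = FALSE)
  out$rank <- seq_len(nrow(out))
  out
}
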