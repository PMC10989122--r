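#' Globally align the two LTRs of an element
#'
#' Needleman-Wunsch global alignment with the fixed scheme match +1,
#' mismatch -1, gap -2 (linear), computed with Biostrings. Returns the two
#' aligned strings (with `-` gap characters) for divergence estimation.
#'
#' @param seq_a,seq_b DNA strings (A/C/G/T/N).
#' @return list: `aligned_a`, `aligned_b`, `score`.
#' @export
align_ltr_pair <- function(seq_a, seq_b) {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L) {
    stop("empty sequence", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- function(...) Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2, ...)
  if (nchar(seq_a) == nchar(seq_b) &&
      !grepl("N", seq_a, fixed = TRUE) && !grepl("N", seq_b, fixed = TRUE)) {
    # exact shortcut: when the gapless score already attains the NW optimum
    # (the usual case for two LTR copies), skip the O(L^2) traceback
    mm <- sum(utf8ToInt(seq_a) != utf8ToInt(seq_b))
    gapless <- nchar(seq_a) - 2 * mm
    if (isTRUE(all.equal(gapless, pa(scoreOnly = TRUE)))) {
      return(list(aligned_a = seq_a, aligned_b = seq_b, score = gapless))
    }
  }
  aln <- pa()
  list(aligned_a = as.character(Biostrings::alignedPattern(aln)),
       aligned_b = as.character(Biostrings::alignedSubject(aln)),
       score = Biostrings::score(aln))
}

#' LTR-LTR divergence from an alignment
#'
#' Gap columns and columns containing N are excluded from both numerator
#' and denominator. `p` is the mismatch proportion over the remaining
#' columns; `K` is the model-corrected divergence: raw (`K = p`), JC69
#' (`K = -(3/4) ln(1 - 4p/3)`, undefined for p >= 0.75) or K2P (from the
#' transition/transversion split).
#'
#' @param alignment result of [align_ltr_pair()].
#' @param model "JC69" (default), "raw" or "K2P".
#' @param min_columns minimum ungapped columns (default 50).
#' @return list: `columns`, `mismatches`, `p`, `K`, `model`, `defined`.
#' @export
ltr_divergence <- function(alignment, model = c("JC69", "raw", "K2P"),
                           min_columns = 50L) {
  model <- match.arg(model)
  a <- strsplit(alignment$aligned_a, "")[[1]]
  b <- strsplit(alignment$aligned_b, "")[[1]]
  use <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[use]; b <- b[use]
  n_col <- length(a)
  if (n_col < min_columns) {
    stop(sprintf("only %d ungapped columns (< %d)", n_col, min_columns),
         call. = FALSE)
  }
  mm <- a != b
  p <- mean(mm)
  defined <- TRUE
  if (model == "raw") {
    K <- p
  } else if (model == "JC69") {
    if (p >= 0.75) {
      K <- NA_real_; defined <- FALSE
    } else {
      K <- -0.75 * log(1 - 4 * p / 3)
    }
  } else {
    purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
    ts <- mm & (purine[a] == purine[b])   # transition: same chemical class
    P <- mean(ts); Q <- mean(mm & !ts)
    if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
      K <- NA_real_; defined <- FALSE
    } else {
      K <- -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    }
  }
  list(columns = n_col, mismatches = sum(mm), p = p, K = K, model = model,
       defined = defined)
}

#' LTR insertion time
#'
#' `T = K / (2r)`: at insertion the two LTRs are identical, and each
#' accumulates substitutions at rate `r` per site per year, so their
#' divergence grows at `2r`. Default rate 1.91e-9 substitutions per site
#' per year (avian).
#'
#' @param K divergence (>= 0).
#' @param r substitution rate per site per year (> 0).
#' @return insertion time in years.
#' @export
insertion_time <- function(K, r = 1.91e-9) {
  if (any(K < 0, na.rm = TRUE)) stop("K must be >= 0", call. = FALSE)
  if (r <= 0) stop("r must be > 0", call. = FALSE)
  K / (2 * r)
}

#' Date a set of LTR pairs
#'
#' @param pairs named list of `list(seq_a, seq_b)`, or a named character
#'   vector of sequences with `_5LTR` / `_3LTR` name suffixes (as written
#'   by [write_cohort()]).
#' @param model distance model (see [ltr_divergence()]).
#' @param r substitution rate per site per year.
#' @return data frame: element, columns, mismatches, p, K, T_years.
#' @export
date_ltr_pairs <- function(pairs, model = "JC69", r = 1.91e-9) {
  if (is.character(pairs)) {
    base <- sub("_(5|3)LTR$", "", names(pairs))
    pairs <- lapply(split(seq_along(pairs), base), function(ii) {
      if (length(ii) != 2L) stop("unpaired LTR sequence", call. = FALSE)
      five <- ii[grepl("_5LTR$", names(pairs)[ii])]
      three <- setdiff(ii, five)
      list(seq_a = unname(pairs[five]), seq_b = unname(pairs[three]))
    })
  }
  do.call(rbind, lapply(names(pairs), function(nm) {
    aln <- align_ltr_pair(pairs[[nm]]$seq_a, pairs[[nm]]$seq_b)
    dv <- ltr_divergence(aln, model = model)
    data.frame(element = nm, columns = dv$columns, mismatches = dv$mismatches,
               p = dv$p, K = dv$K,
               T_years = if (dv$defined) insertion_time(dv$K, r) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}
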