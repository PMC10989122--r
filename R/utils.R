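#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' perturb the caller's RNG stream. All simulators in the package route
#' their randomness through this helper, which is what makes cohorts
#' byte-identical under a fixed seed.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genome layout
#'
#' Ordered chromosome names and lengths; the coordinate frame every other
#' object in the package is validated against.
#'
#' @param chrom character vector of unique chromosome names.
#' @param length integer vector of chromosome lengths in bp (>= 1).
#' @return a `genome_layout` data frame with columns `chrom`, `length`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(5e6, 3e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique", call. = FALSE)
  if (base::length(chrom) != base::length(length)) {
    stop("`chrom` and `length` must have equal length", call. = FALSE)
  }
  if (any(length < 1) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers", call. = FALSE)
  }
  out <- data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Genomic intervals (0-based half-open)
#'
#' @param chrom chromosome names.
#' @param start 0-based inclusive starts.
#' @param end exclusive ends; `end - start` is the interval length.
#' @param strand one of "+", "-", "*" (unknown); recycled.
#' @param label optional feature labels.
#' @param layout optional [genome_layout()] to validate bounds against.
#' @return an `intervals` data frame.
#' @export
intervals <- function(chrom, start, end, strand = "*", label = NA_character_,
                      layout = NULL) {
  n <- length(start)
  out <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = as.numeric(start),
    end = as.numeric(end),
    strand = rep_len(as.character(strand), n),
    label = rep_len(as.character(label), n),
    stringsAsFactors = FALSE
  )
  if (any(out$start < 0)) stop("interval start < 0", call. = FALSE)
  if (any(out$start >= out$end)) stop("interval start >= end", call. = FALSE)
  if (!all(out$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'", call. = FALSE)
  }
  if (!is.null(layout)) {
    len <- setNames(layout$length, layout$chrom)
    if (!all(out$chrom %in% layout$chrom)) {
      stop("interval chromosome absent from layout", call. = FALSE)
    }
    if (any(out$end > len[out$chrom])) {
      stop("interval end beyond chromosome length", call. = FALSE)
    }
  }
  class(out) <- c("intervals", "data.frame")
  out
}

# IRanges view of a 0-based half-open interval frame (1-based closed inside).
as_iranges0 <- function(df) {
  IRanges::IRanges(start = df$start + 1L, end = df$end)
}

# Merge possibly-overlapping intervals per chromosome; returns intervals df.
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df)
  parts <- split(seq_len(nrow(df)), df$chrom)
  out <- do.call(rbind, lapply(names(parts), function(ch) {
    red <- IRanges::reduce(as_iranges0(df[parts[[ch]], , drop = FALSE]))
    data.frame(chrom = ch, start = IRanges::start(red) - 1L,
               end = IRanges::end(red), strand = "*",
               label = NA_character_, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("intervals", "data.frame")
  out
}

stop_if_missing_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(miss, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}
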