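#' SV genotype matrix
#'
#' Container for SV loci with per-sample diploid dosages: a records table
#' (one row per SV, 0-based half-open coordinates) and a dosage matrix with
#' one row per SV and one column per sample, values in 0/1/2 (ALT allele
#' count) or `NA` for missing genotypes.
#'
#' @param records data frame with columns `id`, `chrom`, `start`, `end`,
#'   `svtype` (DEL/INS/INV/DUP), `svlen` (bp, >= 50). For INS the interval
#'   is the 1-bp anchor position and `svlen` holds the inserted length.
#' @param samples character vector of sample ids.
#' @param dosages integer matrix, `nrow(records)` x `length(samples)`.
#' @return an `sv_matrix` object.
#' @export
sv_genotype_matrix <- function(records, samples, dosages) {
  stop_if_missing_cols(records, c("id", "chrom", "start", "end", "svtype", "svlen"),
                       "SV records")
  samples <- as.character(samples)
  dosages <- as.matrix(dosages)
  if (nrow(dosages) != nrow(records) || ncol(dosages) != length(samples)) {
    stop("dosage matrix dimensions do not match records/samples", call. = FALSE)
  }
  if (anyDuplicated(records$id)) stop("duplicate SV ids", call. = FALSE)
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  if (!all(records$svtype %in% c("DEL", "INS", "INV", "DUP"))) {
    stop("svtype must be one of DEL, INS, INV, DUP", call. = FALSE)
  }
  if (any(records$svlen < 50)) stop("svlen must be >= 50 bp", call. = FALSE)
  if (any(records$start < 0) || any(records$start >= records$end)) {
    stop("invalid SV interval (need 0 <= start < end)", call. = FALSE)
  }
  bad <- !(dosages %in% c(0L, 1L, 2L) | is.na(dosages))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  dimnames(dosages) <- list(records$id, samples)
  structure(list(records = records, samples = samples,
                 dosages = dosages),
            class = "sv_matrix")
}

#' @exportS3Method base::print
print.sv_matrix <- function(x, ...) {
  cat(sprintf("sv_matrix: %d SVs x %d samples (%.1f%% missing)\n",
              nrow(x$records), length(x$samples),
              100 * mean(is.na(x$dosages))))
  print(table(x$records$svtype))
  invisible(x)
}

#' @export
`[.sv_matrix` <- function(x, i, j) {
  if (missing(i)) i <- seq_len(nrow(x$records))
  if (missing(j)) j <- seq_along(x$samples)
  sv_genotype_matrix(x$records[i, , drop = FALSE],
                     x$samples[j],
                     x$dosages[i, j, drop = FALSE])
}

#' ALT allele frequency per SV
#'
#' Missing dosages are excluded from both numerator and denominator.
#'
#' @param mat an `sv_matrix`.
#' @param samples optional subset of sample ids.
#' @return numeric vector of allele frequencies, `NA` where no calls.
#' @export
allele_frequency <- function(mat, samples = NULL) {
  d <- mat$dosages
  if (!is.null(samples)) d <- d[, samples, drop = FALSE]
  called <- rowSums(!is.na(d))
  af <- rowSums(d, na.rm = TRUE) / (2 * called)
  af[called == 0] <- NA_real_
  af
}

gt_to_dosage <- function(gt) {
  # "0/1", "1|1", "./.", ".", possibly with trailing FORMAT fields removed
  out <- rep(NA_integer_, length(gt))
  ok <- !is.na(gt) & gt != "." & gt != "./." & gt != ".|."
  alleles <- strsplit(gt[ok], "[/|]")
  bad <- vapply(alleles, function(a) any(!a %in% c("0", "1", ".")), logical(1))
  if (any(bad)) {
    stop(sprintf("malformed or multi-allelic GT value '%s'",
                 gt[ok][bad][1]), call. = FALSE)
  }
  out[ok] <- vapply(alleles, function(a) {
    if (any(a == ".")) return(NA_integer_)
    sum(a == "1")
  }, integer(1))
  out
}

#' Read an SV VCF into an `sv_matrix`
#'
#' Requires INFO keys `SVTYPE` and `SVLEN` and/or `END`, and a GT FORMAT
#' field. 1-based VCF positions are converted to the package's 0-based
#' half-open convention. Records without SVTYPE and multi-allelic records
#' are dropped with a warning ("." and multi-ALT sites cannot be assigned a
#' diploid ALT dosage). `./.` genotypes become `NA`; phased and unphased
#' genotypes are treated identically by allele count.
#'
#' @param path VCF file path.
#' @return an `sv_matrix`.
#' @export
read_sv_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(sv_genotype_matrix(
      data.frame(id = character(), chrom = character(), start = numeric(),
                 end = numeric(), svtype = character(), svlen = numeric(),
                 stringsAsFactors = FALSE),
      samples = colnames(v@gt)[-1] %||% character(),
      dosages = matrix(integer(), 0, max(0L, ncol(v@gt) - 1L))))
  }
  svtype <- vcfR::extract.info(v, "SVTYPE")
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(v, "SVLEN")))
  endpos <- suppressWarnings(as.numeric(vcfR::extract.info(v, "END")))
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  keep <- !is.na(svtype) & !multi
  if (any(is.na(svtype))) {
    warning(sprintf("%d record(s) without SVTYPE dropped", sum(is.na(svtype))))
  }
  if (any(multi & !is.na(svtype))) {
    warning(sprintf("%d multi-allelic record(s) dropped", sum(multi & !is.na(svtype))))
  }
  pos <- as.numeric(fix$POS)
  svlen <- abs(svlen)
  svtype <- svtype[keep]
  # interval: 0-based half-open; INS anchors at a single base
  start0 <- pos[keep] - 1
  # 1-based inclusive END equals the 0-based exclusive end; POS is the first
  # affected base, so a reference-footprint SV without END spans svlen bases.
  end0 <- ifelse(svtype == "INS", pos[keep],
                 ifelse(!is.na(endpos[keep]), endpos[keep],
                        pos[keep] - 1 + svlen[keep]))
  len <- ifelse(is.na(svlen[keep]), end0 - start0, svlen[keep])
  id <- fix$ID[keep]
  noid <- is.na(id) | id == "."
  id[noid] <- sprintf("SV%06d", which(keep)[noid])
  records <- data.frame(id = id, chrom = fix$CHROM[keep], start = start0,
                        end = end0, svtype = svtype, svlen = len,
                        stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  dos <- matrix(NA_integer_, nrow(records), length(samples),
                dimnames = list(records$id, samples))
  gtk <- gt[keep, , drop = FALSE]
  for (j in seq_along(samples)) dos[, j] <- gt_to_dosage(gtk[, j])
  sv_genotype_matrix(records, samples, dos)
}

#' Write an `sv_matrix` as VCF 4.2
#'
#' Emits SVTYPE, SVLEN and END INFO keys and GT genotypes; inverse of
#' [read_sv_vcf()] on the in-memory model.
#'
#' @param mat an `sv_matrix`.
#' @param path output path (plain-text `.vcf`).
#' @param layout optional [genome_layout()] for `##contig` header lines.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(mat, path, layout = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pansvkit",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Type of structural variant">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="Length of structural variant">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position (1-based inclusive)">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  if (!is.null(layout)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", layout$chrom,
                          as.integer(layout$length)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", mat$samples), collapse = "\t"))
  rec <- mat$records
  lines <- character(0)
  if (nrow(rec) > 0L) {
    alt <- paste0("<", rec$svtype, ">")
    info <- sprintf("SVTYPE=%s;SVLEN=%d;END=%d", rec$svtype,
                    as.integer(rec$svlen), as.integer(rec$end))
    gt <- matrix(c("0/0", "0/1", "1/1")[mat$dosages + 1L],
                 nrow = nrow(rec))
    gt[is.na(mat$dosages)] <- "./."
    gtcol <- apply(gt, 1L, paste, collapse = "\t")
    lines <- paste(rec$chrom, as.integer(rec$start) + 1L, rec$id, "N", alt,
                   ".", "PASS", info, "GT", gtcol, sep = "\t")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}
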