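#' Read genomic intervals from BED or GFF3
#'
#' Both formats are mapped onto the package's single internal convention,
#' 0-based half-open. BED is already 0-based half-open; GFF3 coordinates are
#' 1-based inclusive and are shifted at this boundary only. For GFF3, exon
#' features are grouped by their (grand)parent gene into [gene_model()]s.
#'
#' @param path file path.
#' @param format "BED" or "GFF3"; guessed from the extension by default.
#' @return for BED, an [intervals()] frame (the BED name column becomes
#'   `label`); for GFF3, a list of `gene_model` objects.
#' @export
read_intervals <- function(path, format = c("auto", "BED", "GFF3")) {
  format <- match.arg(toupper(format[1]), c("AUTO", "BED", "GFF3"))
  if (format == "AUTO") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "GFF3" else "BED"
  }
  if (format == "BED") {
    gr <- rtracklayer::import(path, format = "BED")
    if (length(gr) == 0L) {
      return(intervals(character(), numeric(), numeric())[0, ])
    }
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "?"] <- "*"
    lab <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
    intervals(as.character(GenomicRanges::seqnames(gr)),
              GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
              strand = strand, label = lab)
  } else {
    read_gff3_genes(path)
  }
}

#' Gene model
#'
#' A gene as a set of merged, non-overlapping exon intervals on one
#' chromosome, with a strand-aware transcription start site.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome.
#' @param strand "+" or "-".
#' @param exons [intervals()] frame (merged on construction).
#' @return a `gene_model` object.
#' @export
gene_model <- function(gene_id, chrom, strand, exons) {
  if (!strand %in% c("+", "-")) stop("gene strand must be '+' or '-'", call. = FALSE)
  if (length(unique(exons$chrom)) > 1L || any(exons$chrom != chrom)) {
    stop("all exons of a gene must lie on its chromosome", call. = FALSE)
  }
  exons <- merge_intervals(exons)
  exons <- exons[order(exons$start), , drop = FALSE]
  tss <- if (strand == "+") min(exons$start) else max(exons$end)
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, tss = tss,
                 span = c(min(exons$start), max(exons$end))),
            class = "gene_model")
}

#' @exportS3Method base::print
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%d-%d(%s), %d exon(s), tss=%d\n", x$gene_id,
              x$chrom, x$span[1], x$span[2], x$strand, nrow(x$exons),
              as.integer(x$tss)))
  invisible(x)
}

read_gff3_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  type <- as.character(gr$type)
  id <- as.character(gr$ID %||% rep(NA_character_, length(gr)))
  parent_of <- vapply(seq_along(gr), function(i) {
    p <- gr$Parent[[i]]
    if (length(p) == 0L) NA_character_ else as.character(p[1])
  }, character(1))
  # walk exon -> (mRNA ->) gene
  gene_idx <- which(type == "gene")
  gene_ids <- id[gene_idx]
  owner <- setNames(rep(NA_character_, length(gr)), id)
  resolve_gene <- function(i) {
    p <- parent_of[i]
    for (hop in 1:3) {
      if (is.na(p)) return(NA_character_)
      k <- match(p, id)
      if (is.na(k)) return(p)  # dangling parent: take it as the gene id
      if (type[k] == "gene") return(id[k])
      p <- parent_of[k]
    }
    NA_character_
  }
  exon_idx <- which(type == "exon")
  exon_gene <- vapply(exon_idx, resolve_gene, character(1))
  if (anyNA(exon_gene)) stop("GFF3 exon without a resolvable gene parent", call. = FALSE)
  strand_chr <- as.character(GenomicRanges::strand(gr))
  out <- lapply(unique(exon_gene), function(g) {
    ii <- exon_idx[exon_gene == g]
    ex <- intervals(as.character(GenomicRanges::seqnames(gr))[ii],
                    GenomicRanges::start(gr)[ii] - 1L,
                    GenomicRanges::end(gr)[ii])
    gi <- gene_idx[match(g, gene_ids)]
    st <- if (!is.na(gi)) strand_chr[gi] else strand_chr[ii[1]]
    if (!st %in% c("+", "-")) st <- "+"
    gene_model(g, ex$chrom[1], st, ex)
  })
  names(out) <- vapply(out, `[[`, character(1), "gene_id")
  out
}

#' Write intervals as BED
#'
#' @param x an [intervals()] frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  df <- data.frame(x$chrom, as.integer(x$start), as.integer(x$end),
                   ifelse(is.na(x$label), ".", x$label), 0L,
                   ifelse(x$strand == "*", ".", x$strand))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write gene models as GFF3 (gene + exon features)
#'
#' @param genes list of [gene_model()]s.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (g in genes) {
    lines <- c(lines,
               sprintf("%s\tpansvkit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, as.integer(g$span[1]) + 1L, as.integer(g$span[2]),
                       g$strand, g$gene_id),
               sprintf("%s\tpansvkit\texon\t%d\t%d\t.\t%s\t.\tID=%s.exon%d;Parent=%s",
                       g$chrom, as.integer(g$exons$start) + 1L,
                       as.integer(g$exons$end), g$strand, g$gene_id,
                       seq_len(nrow(g$exons)), g$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}
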