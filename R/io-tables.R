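.table_schemas <- list(
  coverage = c("sample", "gene", "exon_index", "bases_ge_min_depth", "exon_length"),
  phenotype = c("sample", "sex"),
  groups = c("sample", "group")
)

#' Read a schema-validated TSV table
#'
#' Supported schemas: `coverage` (per-exon coverage summaries, mosdepth
#' style: sample, gene, exon_index, bases_ge_min_depth, exon_length),
#' `phenotype` (sample, sex in 0/1, plus one numeric column per trait) and
#' `groups` (sample, group).
#'
#' @param path TSV file with a header row.
#' @param schema one of "coverage", "phenotype", "groups".
#' @return a data frame with validated, typed columns.
#' @export
read_table <- function(path, schema = c("coverage", "phenotype", "groups")) {
  schema <- match.arg(schema)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  stop_if_missing_cols(df, .table_schemas[[schema]], sprintf("%s table", schema))
  if (schema == "coverage") {
    for (cl in c("exon_index", "bases_ge_min_depth", "exon_length")) {
      df[[cl]] <- as.numeric(df[[cl]])
    }
    if (any(df$exon_length <= 0)) stop("exon_length must be > 0", call. = FALSE)
    if (any(df$bases_ge_min_depth > df$exon_length)) {
      stop("bases_ge_min_depth exceeds exon_length", call. = FALSE)
    }
  } else if (schema == "phenotype") {
    df$sex <- as.integer(df$sex)
    if (!all(df$sex %in% c(0L, 1L))) stop("sex must be coded 0/1", call. = FALSE)
    traits <- setdiff(names(df), c("sample", "sex"))
    for (tr in traits) df[[tr]] <- as.numeric(df[[tr]])
  }
  df$sample <- as.character(df$sample)
  df
}

#' Read sample metadata (group labels, optional sex and traits)
#'
#' @param path groups TSV (`sample`, `group`, optional `sex` and traits).
#' @param groups optional declared group specification; labels outside it
#'   are an error.
#' @return data frame with at least `sample` and `group`.
#' @export
read_metadata <- function(path, groups = NULL) {
  df <- read_table(path, "groups")
  if (!is.null(groups) && !all(df$group %in% groups)) {
    bad <- setdiff(unique(df$group), groups)
    stop(sprintf("undeclared group label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  df
}

#' Read a FASTA file as a named character vector
#'
#' Sequences are upper-cased; alphabet restricted to A/C/G/T/N; duplicate
#' names are an error.
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate FASTA name '%s'", nm[duplicated(nm)][1]), call. = FALSE)
  }
  seqs <- toupper(as.character(ss))
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("FASTA contains characters outside A/C/G/T/N", call. = FALSE)
  }
  setNames(seqs, nm)
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
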