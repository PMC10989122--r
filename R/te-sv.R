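#' TE annotation track
#'
#' @param x an [intervals()] frame of TE spans.
#' @param class TE class/superfamily labels (e.g. "LTR/Gypsy").
#' @param intact logical: element retains full structure (e.g. both LTRs).
#' @return a `te_track` data frame.
#' @export
te_track <- function(x, class = "TE", intact = FALSE) {
  out <- as.data.frame(x)
  out$class <- rep_len(as.character(class), nrow(out))
  out$intact <- rep_len(as.logical(intact), nrow(out))
  class(out) <- c("te_track", "intervals", "data.frame")
  out
}

#' Parse a TE BED track read through [read_intervals()]
#'
#' The BED name column is expected to carry the class label, with an
#' optional `;intact` suffix for structurally intact elements.
#'
#' @param x an [intervals()] frame (from a BED file).
#' @return a `te_track`.
#' @export
as_te_track <- function(x) {
  lab <- ifelse(is.na(x$label), "TE", x$label)
  intact <- grepl(";intact$", lab)
  te_track(x, class = sub(";intact$", "", lab), intact = intact)
}

sv_footprints <- function(mat) {
  rec <- mat$records
  rec[rec$svtype %in% c("DEL", "INV", "DUP"), , drop = FALSE]
}

#' TE overlap per SV
#'
#' For every SV with a reference footprint (DEL/INV/DUP; insertions have a
#' point footprint and are excluded), computes the TE-covered fraction of
#' the SV (TEs merged first, so fragmented annotations are not double
#' counted), the best single-TE reciprocal overlap
#' `overlap / max(len_sv, len_te)`, and the overlap class: `none`
#' (no overlap), `partial` (> 0), `high` (covered fraction >= 0.5),
#' `intact_derived` (reciprocal overlap > 0.95 with an intact TE). Class
#' statistics in the source study are restricted to SVs with svlen > 100
#' bp; the `min_svlen` filter reproduces that restriction.
#'
#' @param mat an `sv_matrix`.
#' @param tes a `te_track`.
#' @param min_svlen restrict to SVs longer than this (default 100; set 0
#'   to keep all).
#' @param reciprocal logical; when `FALSE` the intact rule only requires
#'   `overlap / len_sv > 0.95` (one-sided).
#' @return data frame: id, svlen, te_bases, fraction, best_reciprocal,
#'   class.
#' @export
sv_te_overlap <- function(mat, tes, min_svlen = 100, reciprocal = TRUE) {
  rec <- sv_footprints(mat)
  rec <- rec[rec$svlen > min_svlen, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(data.frame(id = character(), svlen = numeric(), te_bases = numeric(),
                      fraction = numeric(), best_reciprocal = numeric(),
                      class = character()))
  }
  merged <- merge_intervals(tes)
  te_bases <- overlap_bases(rec, merged)
  fraction <- te_bases / (rec$end - rec$start)
  best <- best_reciprocal(rec, tes, intact_only = FALSE)
  cls <- ifelse(te_bases == 0, "none",
                ifelse(fraction >= 0.5, "high", "partial"))
  intact_best <- best_reciprocal(rec, tes[tes$intact, , drop = FALSE],
                                 intact_only = FALSE, reciprocal = reciprocal)
  cls[intact_best > 0.95] <- "intact_derived"
  data.frame(id = rec$id, svlen = rec$svlen, te_bases = te_bases,
             fraction = fraction, best_reciprocal = best, class = cls,
             stringsAsFactors = FALSE)
}

# total bases of `features` overlapping each row of `query` (same chrom)
overlap_bases <- function(query, features) {
  out <- numeric(nrow(query))
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    fi <- which(features$chrom == ch)
    if (!length(fi)) next
    qr <- as_iranges0(query[qi, , drop = FALSE])
    fr <- as_iranges0(features[fi, , drop = FALSE])
    hits <- IRanges::findOverlaps(qr, fr)
    if (length(hits) == 0L) next
    ov <- IRanges::width(IRanges::pintersect(qr[S4Vectors::queryHits(hits)],
                                             fr[S4Vectors::subjectHits(hits)]))
    agg <- tapply(ov, S4Vectors::queryHits(hits), sum)
    out[qi[as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}

# per query row, the best overlap / max(len_query, len_feature)
# (or overlap / len_query when reciprocal = FALSE)
best_reciprocal <- function(query, features, intact_only = TRUE,
                            reciprocal = TRUE) {
  out <- numeric(nrow(query))
  if (nrow(features) == 0L) return(out)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    fi <- which(features$chrom == ch)
    if (!length(fi)) next
    qr <- as_iranges0(query[qi, , drop = FALSE])
    fr <- as_iranges0(features[fi, , drop = FALSE])
    hits <- IRanges::findOverlaps(qr, fr)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- IRanges::width(IRanges::pintersect(qr[qh], fr[sh]))
    denom <- if (reciprocal) pmax(IRanges::width(qr[qh]), IRanges::width(fr[sh])) else
      IRanges::width(qr[qh])
    frac <- ov / denom
    agg <- tapply(frac, qh, max)
    out[qi[as.integer(names(agg))]] <- pmax(out[qi[as.integer(names(agg))]],
                                            as.numeric(agg))
  }
  out
}

#' Intact-TE-derived SV ids
#'
#' An SV is intact-TE-derived when some intact TE has reciprocal overlap
#' strictly greater than 0.95 with it (both `overlap/len_sv` and
#' `overlap/len_te` above 0.95; near-coincident spans).
#'
#' @param mat an `sv_matrix`.
#' @param tes a `te_track` with `intact` flags.
#' @param threshold reciprocal overlap threshold (default 0.95, strict).
#' @param reciprocal when `FALSE`, only `overlap/len_sv` is required.
#' @return character vector of SV ids.
#' @export
match_intact_derived <- function(mat, tes, threshold = 0.95, reciprocal = TRUE) {
  rec <- sv_footprints(mat)
  if (nrow(rec) == 0L) return(character(0))
  best <- best_reciprocal(rec, tes[tes$intact, , drop = FALSE],
                          reciprocal = reciprocal)
  rec$id[best > threshold]
}

#' Windowed TE/SV occupancy counts
#'
#' Tiles each chromosome with non-overlapping windows of `window_size` bp
#' (the last, partial window is kept). With `assign = "overlap"` (default)
#' a window has a feature when at least one bp of the feature overlaps it,
#' so a boundary-spanning feature marks every window it touches. With
#' `assign = "midpoint"` each feature marks only the window holding its
#' midpoint; this keeps window occupancies exchangeable when features are
#' placed independently, which is the mode the chi-square calibration
#' properties are stated for (any-overlap marking of multi-window features
#' autocorrelates neighbouring windows and makes the chi-square mildly
#' anti-conservative at window sizes comparable to feature length).
#'
#' @param mat an `sv_matrix` (reference-footprint SVs are used).
#' @param tes a `te_track`.
#' @param layout a [genome_layout()].
#' @param window_size window size in bp (2000/5000/10000 in the standard
#'   scan).
#' @param assign "overlap" (any-overlap, default) or "midpoint".
#' @return 2x2 integer matrix, rows TE yes/no, columns SV yes/no.
#' @export
window_occupancy <- function(mat, tes, layout, window_size,
                             assign = c("overlap", "midpoint")) {
  assign <- match.arg(assign)
  if (window_size <= 0) stop("window_size must be > 0", call. = FALSE)
  svs <- sv_footprints(mat)
  te_yes <- sv_yes <- logical(0)
  for (k in seq_len(nrow(layout))) {
    ch <- layout$chrom[k]
    nw <- ceiling(layout$length[k] / window_size)
    win <- IRanges::IRanges(start = (seq_len(nw) - 1L) * window_size + 1L,
                            end = pmin(seq_len(nw) * window_size,
                                       layout$length[k]))
    mark <- function(df) {
      ii <- which(df$chrom == ch)
      if (!length(ii)) return(rep(FALSE, nw))
      if (assign == "midpoint") {
        wi <- floor((df$start[ii] + df$end[ii]) / 2 / window_size) + 1L
        out <- rep(FALSE, nw)
        out[wi[wi >= 1 & wi <= nw]] <- TRUE
        return(out)
      }
      IRanges::overlapsAny(win, as_iranges0(df[ii, , drop = FALSE]))
    }
    te_yes <- c(te_yes, mark(tes))
    sv_yes <- c(sv_yes, mark(svs))
  }
  tab <- matrix(c(sum(te_yes & sv_yes), sum(te_yes & !sv_yes),
                  sum(!te_yes & sv_yes), sum(!te_yes & !sv_yes)),
                nrow = 2, byrow = TRUE,
                dimnames = list(TE = c("yes", "no"), SV = c("yes", "no")))
  tab
}

#' Pearson chi-square test on a 2x2 occupancy table
#'
#' No continuity correction by default (window counts are large). The odds
#' ratio uses the Haldane 0.5 correction when any cell is zero. A zero row
#' or column margin makes the test undefined; the result is flagged.
#'
#' @param tab 2x2 matrix of counts.
#' @param correct apply Yates continuity correction.
#' @return list: `chisq`, `p`, `odds_ratio`, `defined`.
#' @export
chi_square_2x2 <- function(tab, correct = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (sum(tab) < 1) stop("empty table", call. = FALSE)
  or_tab <- if (any(tab == 0)) tab + 0.5 else tab
  or <- (or_tab[1, 1] * or_tab[2, 2]) / (or_tab[1, 2] * or_tab[2, 1])
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chisq = NA_real_, p = NA_real_, odds_ratio = or,
                defined = FALSE))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = correct))
  list(chisq = unname(ct$statistic), p = unname(ct$p.value), odds_ratio = or,
       defined = TRUE)
}

#' TE/SV co-occurrence tests at several window sizes
#'
#' @param mat an `sv_matrix`.
#' @param tes a `te_track`.
#' @param layout a [genome_layout()].
#' @param window_sizes window sizes in bp (default 2/5/10 kb).
#' @param assign window assignment mode (see [window_occupancy()]).
#' @return data frame: window_size, the four cell counts, chisq, p,
#'   odds_ratio.
#' @export
te_sv_cooccurrence <- function(mat, tes, layout,
                               window_sizes = c(2000L, 5000L, 10000L),
                               assign = c("overlap", "midpoint")) {
  assign <- match.arg(assign)
  do.call(rbind, lapply(window_sizes, function(w) {
    tab <- window_occupancy(mat, tes, layout, w, assign = assign)
    ct <- chi_square_2x2(tab)
    data.frame(window_size = w, te_sv = tab[1, 1], te_only = tab[1, 2],
               sv_only = tab[2, 1], neither = tab[2, 2],
               chisq = ct$chisq, p = ct$p, odds_ratio = ct$odds_ratio)
  }))
}

#' Genomic context of SVs relative to gene models
#'
#' `gene_body` when the SV overlaps a gene's span (min exon start to max
#' exon end); otherwise `upstream5k` when it lies within `upstream_bp` 5'
#' of some gene's TSS on that gene's strand; otherwise `intergenic`.
#' Precedence: gene_body > upstream5k.
#'
#' @param mat an `sv_matrix`.
#' @param genes list of [gene_model()]s.
#' @param upstream_bp upstream window (default 5000).
#' @return data frame: id, context, gene (the gene justifying the call, NA
#'   for intergenic).
#' @export
classify_context <- function(mat, genes, upstream_bp = 5000) {
  rec <- sv_footprints(mat)
  gs <- gene_span_frame(genes)
  up <- upstream_frame(genes, upstream_bp)
  in_body <- overlap_bases(rec, gs) > 0
  body_gene <- first_overlap_label(rec, gs)
  in_up <- overlap_bases(rec, up) > 0
  up_gene <- first_overlap_label(rec, up)
  ctx <- ifelse(in_body, "gene_body", ifelse(in_up, "upstream5k", "intergenic"))
  data.frame(id = rec$id, context = ctx,
             gene = ifelse(in_body, body_gene, ifelse(in_up, up_gene, NA)),
             stringsAsFactors = FALSE)
}

gene_span_frame <- function(genes) {
  do.call(rbind, lapply(genes, function(g) {
    data.frame(chrom = g$chrom, start = g$span[1], end = g$span[2],
               strand = g$strand, label = g$gene_id, stringsAsFactors = FALSE)
  }))
}

upstream_frame <- function(genes, upstream_bp) {
  out <- do.call(rbind, lapply(genes, function(g) {
    if (g$strand == "+") {
      s <- max(0, g$span[1] - upstream_bp); e <- g$span[1]
    } else {
      s <- g$span[2]; e <- g$span[2] + upstream_bp
    }
    data.frame(chrom = g$chrom, start = s, end = e, strand = g$strand,
               label = g$gene_id, stringsAsFactors = FALSE)
  }))
  out[out$end > out$start, , drop = FALSE]
}

first_overlap_label <- function(query, features) {
  out <- rep(NA_character_, nrow(query))
  if (is.null(features) || nrow(features) == 0L) return(out)
  for (ch in unique(query$chrom)) {
    qi <- which(query$chrom == ch)
    fi <- which(features$chrom == ch)
    if (!length(fi)) next
    hits <- IRanges::findOverlaps(as_iranges0(query[qi, , drop = FALSE]),
                                  as_iranges0(features[fi, , drop = FALSE]),
                                  select = "first")
    out[qi] <- features$label[fi][hits]
  }
  out
}

#' Nearest gene per SV
#'
#' Minimal edge-to-edge distance; overlap gives distance 0. The sign is
#' positive when the gene starts at or beyond the SV end (downstream in
#' reference orientation), negative when it ends before the SV start. Ties
#' are broken by ascending gene start. SVs on chromosomes without genes get
#' `NA`.
#'
#' @param mat an `sv_matrix`.
#' @param genes list of [gene_model()]s.
#' @return data frame: id, gene, distance.
#' @export
nearest_gene <- function(mat, genes) {
  rec <- sv_footprints(mat)
  gs <- gene_span_frame(genes)
  gs <- gs[order(gs$chrom, gs$start), , drop = FALSE]
  gene <- rep(NA_character_, nrow(rec))
  dist <- rep(NA_real_, nrow(rec))
  for (i in seq_len(nrow(rec))) {
    cand <- gs[gs$chrom == rec$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    d <- ifelse(cand$start >= rec$end[i], cand$start - rec$end[i],
                ifelse(cand$end <= rec$start[i], -(rec$start[i] - cand$end), 0))
    d[cand$start < rec$end[i] & cand$end > rec$start[i]] <- 0
    best <- which(abs(d) == min(abs(d)))[1]  # cand sorted by start => tie rule
    gene[i] <- cand$label[best]
    dist[i] <- d[best]
  }
  data.frame(id = rec$id, gene = gene, distance = dist, stringsAsFactors = FALSE)
}
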