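#' Call gene presence from exon coverage
#'
#' A gene is present in a sample when the pooled fraction of its exonic
#' bases covered by at least `min_depth` reads exceeds `min_exon_fraction`
#' (strictly; a gene sitting exactly on the threshold is absent). The
#' alternative `per_exon` rule counts whole exons that individually clear
#' the fraction.
#'
#' @param bases_ge_min_depth per-exon counts of bases at depth >=
#'   `min_depth`.
#' @param exon_length per-exon lengths (bp).
#' @param min_exon_fraction presence threshold (default 0.05).
#' @param rule "pooled_bases" (default) or "per_exon".
#' @return logical scalar.
#' @export
call_gene_presence <- function(bases_ge_min_depth, exon_length,
                               min_exon_fraction = 0.05,
                               rule = c("pooled_bases", "per_exon")) {
  rule <- match.arg(rule)
  if (any(exon_length <= 0)) stop("exon lengths must be > 0", call. = FALSE)
  if (any(bases_ge_min_depth > exon_length)) {
    stop("bases_ge_min_depth exceeds exon_length", call. = FALSE)
  }
  if (rule == "pooled_bases") {
    sum(bases_ge_min_depth) / sum(exon_length) > min_exon_fraction
  } else {
    mean(bases_ge_min_depth / exon_length > min_exon_fraction) > min_exon_fraction
  }
}

#' Build a PAV matrix from a coverage table
#'
#' @param coverage coverage table (see [read_table()] schema `coverage`).
#' @param min_exon_fraction presence threshold (default 0.05).
#' @param exclude_genes gene ids to drop (e.g. genes on sex chromosomes).
#' @param rule see [call_gene_presence()].
#' @return logical gene x sample matrix of class `pav_matrix`.
#' @export
pav_call_matrix <- function(coverage, min_exon_fraction = 0.05,
                            exclude_genes = NULL,
                            rule = c("pooled_bases", "per_exon")) {
  rule <- match.arg(rule)
  stop_if_missing_cols(coverage, .table_schemas$coverage, "coverage table")
  if (!is.null(exclude_genes)) {
    coverage <- coverage[!coverage$gene %in% exclude_genes, , drop = FALSE]
  }
  genes <- sort(unique(coverage$gene))
  samples <- unique(coverage$sample)
  if (rule == "pooled_bases") {
    cov_sum <- stats::aggregate(cbind(bases_ge_min_depth, exon_length) ~ gene + sample,
                                data = coverage, FUN = sum)
    val <- cov_sum$bases_ge_min_depth / cov_sum$exon_length > min_exon_fraction
    m <- matrix(NA, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(cov_sum$gene, genes), match(cov_sum$sample, samples))] <- val
  } else {
    key <- paste(coverage$gene, coverage$sample, sep = "\r")
    pres <- tapply(seq_len(nrow(coverage)), key, function(ii) {
      call_gene_presence(coverage$bases_ge_min_depth[ii],
                         coverage$exon_length[ii], min_exon_fraction, rule)
    })
    parts <- strsplit(names(pres), "\r", fixed = TRUE)
    m <- matrix(NA, length(genes), length(samples),
                dimnames = list(genes, samples))
    m[cbind(match(vapply(parts, `[`, "", 1), genes),
            match(vapply(parts, `[`, "", 2), samples))] <- pres
  }
  if (anyNA(m)) stop("coverage table does not cover every gene x sample cell",
                     call. = FALSE)
  class(m) <- c("pav_matrix", class(m))
  m
}

#' Classify genes into core / softcore / shell / cloud occupancy classes
#'
#' Presence frequency f across samples maps to: core (f = 1), softcore
#' (0.99 < f < 1), shell (0.01 <= f <= 0.99), cloud (f < 0.01). The
#' thresholds are strict, so boundary frequencies fall to the lower class.
#'
#' @param pav logical gene x sample matrix.
#' @return data frame (gene, frequency, class) plus a `counts` attribute
#'   with per-class totals.
#' @export
classify_pav <- function(pav) {
  if (is.null(dim(pav)) || ncol(pav) < 2L) stop("need >= 2 samples", call. = FALSE)
  if (nrow(pav) == 0L) stop("empty PAV matrix", call. = FALSE)
  f <- rowMeans(pav)
  cls <- ifelse(f == 1, "core",
                ifelse(f > 0.99, "softcore",
                       ifelse(f >= 0.01, "shell", "cloud")))
  out <- data.frame(gene = rownames(pav) %||% as.character(seq_len(nrow(pav))),
                    frequency = f, class = cls, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counts") <- vapply(c("core", "softcore", "shell", "cloud"),
                                function(k) sum(cls == k), integer(1))
  out
}

#' Pan and core growth trajectories over random genome orderings
#'
#' For x = 1..S samples, the mean over `n_orders` random orderings of the
#' union (pan) and intersection (core) gene counts of the first x samples.
#'
#' @param pav logical gene x sample matrix.
#' @param n_orders number of random orderings (default 100).
#' @param seed RNG seed for the orderings.
#' @return data frame (x, y, kind) with kind in pan/core; per-ordering
#'   trajectories in attribute `orders` (arrays x x n_orders).
#' @export
pan_core_trajectories <- function(pav, n_orders = 100L, seed = 1L) {
  if (n_orders < 1) stop("n_orders must be >= 1", call. = FALSE)
  S <- ncol(pav)
  pan_mat <- core_mat <- matrix(0, S, n_orders)
  with_seed(seed, {
    for (o in seq_len(n_orders)) {
      ord <- sample.int(S)
      un <- rep(FALSE, nrow(pav)); int <- rep(TRUE, nrow(pav))
      for (x in seq_len(S)) {
        un <- un | pav[, ord[x]]
        int <- int & pav[, ord[x]]
        pan_mat[x, o] <- sum(un)
        core_mat[x, o] <- sum(int)
      }
    }
  })
  out <- rbind(
    data.frame(x = seq_len(S), y = rowMeans(pan_mat), kind = "pan"),
    data.frame(x = seq_len(S), y = rowMeans(core_mat), kind = "core")
  )
  attr(out, "orders") <- list(pan = pan_mat, core = core_mat)
  out
}

#' Fit a pan/core growth curve
#'
#' Power law `y = A * x^B + C` for the pan curve; exponential
#' `y = A * exp(B * x) + C` for the core curve. Fitting is bounded
#' Levenberg-Marquardt least squares over a deterministic multi-start grid
#' (B in \[-5, 5\], C >= 0), keeping the best residual sum of squares, so
#' fits are reproducible. When B < 0 the curve is closed and C estimates
#' the asymptote (total pan genes, or the core floor).
#'
#' @param points data frame with columns `x`, `y` (>= 4 distinct x).
#' @param model "power" or "exponential".
#' @return list: `model`, `A`, `B`, `C`, `rss`, `closed`, `asymptote`,
#'   `converged`.
#' @export
fit_growth_curve <- function(points, model = c("power", "exponential")) {
  model <- match.arg(model)
  x <- points$x; y <- points$y
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(unique(x)) < 4L) stop("need >= 4 distinct x values", call. = FALSE)
  form <- if (model == "power") y ~ A * x^B + C else y ~ A * exp(B * x) + C
  b_grid <- c(-2, -1, -0.5, -0.1, 0.1, 0.5, 1)
  best <- NULL
  for (b0 in b_grid) {
    basis <- if (model == "power") x^b0 else exp(b0 * x)
    # linear profile for A, C at fixed B gives an informed start
    cf <- tryCatch(stats::coef(stats::lm(y ~ basis)), error = function(e) c(mean(y), 0))
    start <- list(A = unname(cf[2]), B = b0, C = max(0, unname(cf[1])))
    if (!is.finite(start$A) || start$A == 0) start$A <- diff(range(y)) * sign(b0 + 1e-9)
    fit <- tryCatch(
      minpack.lm::nlsLM(form, data = data.frame(x = x, y = y), start = start,
                        lower = c(A = -Inf, B = -5, C = 0),
                        upper = c(A = Inf, B = 5, C = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- stats::coef(fit)
      best <- list(model = model, A = unname(cf["A"]), B = unname(cf["B"]),
                   C = unname(cf["C"]), rss = rss,
                   closed = unname(cf["B"]) < 0,
                   asymptote = if (unname(cf["B"]) < 0) unname(cf["C"]) else NA_real_,
                   converged = TRUE)
    }
  }
  if (is.null(best)) {
    return(list(model = model, A = NA_real_, B = NA_real_, C = NA_real_,
                rss = NA_real_, closed = NA, asymptote = NA_real_,
                converged = FALSE))
  }
  best
}
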