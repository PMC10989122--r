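#' Single-marker association with sex as a fixed effect
#'
#' Ordinary least squares `y = mu + b_sex * sex + b_g * g`, with the
#' marker coded additively (0/1/2). The marker p-value is the F-test of
#' the full model against the sex-only model, and the marker R-squared is
#' the marker sum of squares after fitting all other terms divided by the
#' total sum of squares: `(RSS_reduced - RSS_full) / TSS`. A 2-df
#' genotype-class coding is available via `coding = "genotype"`.
#'
#' @param phenotypes data frame with `sex` and the trait column.
#' @param trait trait column name.
#' @param marker dosage vector in 0/1/2, aligned with `phenotypes` rows.
#' @param coding "additive" (default) or "genotype" (factor, 2 df).
#' @return list: trait, n, effect (additive estimate; NA for genotype
#'   coding), p, r2.
#' @export
single_marker_glm <- function(phenotypes, trait, marker,
                              coding = c("additive", "genotype")) {
  coding <- match.arg(coding)
  y <- phenotypes[[trait]]
  if (is.null(y)) stop(sprintf("trait '%s' not found", trait), call. = FALSE)
  sex <- phenotypes$sex
  keep <- complete.cases(y, sex, marker)
  y <- y[keep]; sex <- sex[keep]
  g <- if (coding == "additive") marker[keep] else factor(marker[keep])
  n <- length(y)
  if (n < 10) stop("need >= 10 complete observations", call. = FALSE)
  if (length(unique(marker[keep])) < 2L) stop("marker is constant", call. = FALSE)
  full <- lm(y ~ sex + g)
  red <- lm(y ~ sex)
  if (full$rank < length(stats::coef(full))) {
    warning("marker collinear with sex; estimates unreliable")
  }
  cmp <- anova(red, full)
  tss <- sum((y - mean(y))^2)
  rss_red <- sum(stats::residuals(red)^2)
  rss_full <- sum(stats::residuals(full)^2)
  list(trait = trait, n = n,
       effect = if (coding == "additive") unname(stats::coef(full)["g"]) else NA_real_,
       p = cmp$`Pr(>F)`[2],
       r2 = (rss_red - rss_full) / tss)
}
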