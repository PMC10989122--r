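#' Simulation configuration
#'
#' Defaults encode the cohort structure the analyses assume: a three-group
#' cohort of 131 ducks (wild = 20, native = 70, commercial = 41 — only the
#' 41 commercial is fixed by the study design; the 20/70 split of the
#' remaining 90 is a simulation choice), SV allele frequencies drawn from a
#' U-shaped Beta(0.5, 0.5) site-frequency spectrum shared across groups
#' under the null, planted selected SVs with per-group frequency triples
#' including a near-fixed difference (0.05, 0.89, 0.012), a TE landscape
#' with tunable SV co-localisation, intact-TE-derived SVs with <= 2%
#' endpoint jitter, LTR pairs at known divergence K, ~45x exon coverage
#' with gene dropout, and an F2 phenotype with a marker of known variance
#' fraction (default 0.2761).
#'
#' @param seed integer master seed; fixed seed gives byte-identical cohorts.
#' @param layout [genome_layout()]; default two 5-Mb autosomes.
#' @param group_sizes named integer vector (wild, native, commercial).
#' @param n_sv number of SV loci.
#' @param af_beta length-2 shape parameters of the baseline allele-frequency
#'   Beta distribution.
#' @param planted data frame with columns `wild`, `native`, `commercial`:
#'   per-group allele frequencies of planted selected SVs.
#' @param te_density TEs per Mb.
#' @param te_len_range min/max TE length in bp.
#' @param rho probability that an SV is placed inside a TE-occupied window
#'   (of `placement_window` bp) instead of uniformly.
#' @param placement_window window size (bp) used for enriched SV placement.
#' @param intact_fraction fraction of SVs copied from intact TE spans.
#' @param jitter maximum endpoint jitter for intact-derived SVs, as a
#'   fraction of element length per endpoint (default 0.01, keeping
#'   reciprocal overlap > 0.95).
#' @param K_list LTR divergences to simulate.
#' @param ltr_length simulated LTR length in bp.
#' @param depth mean sequencing depth (fold).
#' @param n_genes number of gene models.
#' @param mismap_frac fraction of exonic bases of an *absent* gene that
#'   still attract mismapped reads at full depth (background signal the
#'   presence threshold must reject).
#' @param pav_dropout fraction of genes that are dispensable; dispensable
#'   genes get per-sample presence probability drawn from Uniform(0.1, 0.9).
#' @param f2 list: `n`, `v` (marker variance fraction), `sex_effect`,
#'   `resid_sd`, `mu`.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              layout = genome_layout(c("chr1", "chr2"), c(5e6, 5e6)),
                              group_sizes = c(wild = 20L, native = 70L, commercial = 41L),
                              n_sv = 1000L,
                              af_beta = c(0.5, 0.5),
                              planted = data.frame(wild = 0.05, native = 0.89,
                                                   commercial = 0.012),
                              te_density = 50,
                              te_len_range = c(500, 8000),
                              rho = 0.3,
                              placement_window = 2000L,
                              intact_fraction = 0.05,
                              jitter = 0.01,
                              K_list = c(0.001, 0.005, 0.02),
                              ltr_length = 10000L,
                              depth = 45,
                              n_genes = 200L,
                              mismap_frac = 0.03,
                              pav_dropout = 0.1,
                              f2 = list(n = 500L, v = 0.2761, sex_effect = 1,
                                        resid_sd = 1, mu = 10)) {
  stopifnot(all(group_sizes >= 2), n_sv >= 1, te_density > 0,
            rho >= 0, rho <= 1, intact_fraction >= 0, intact_fraction <= 1,
            jitter >= 0, jitter <= 0.02, depth >= 0,
            mismap_frac >= 0, mismap_frac <= 1)
  if (!is.null(planted) && nrow(planted)) {
    stop_if_missing_cols(planted, c("wild", "native", "commercial"), "planted AFs")
    if (any(unlist(planted) < 0 | unlist(planted) > 1)) {
      stop("planted allele frequencies must be in [0, 1]", call. = FALSE)
    }
  }
  if (f2$v < 0 || f2$v >= 1) stop("f2 variance fraction must be in [0, 1)", call. = FALSE)
  cfg <- list(seed = as.integer(seed), layout = layout,
              group_sizes = group_sizes, n_sv = as.integer(n_sv),
              af_beta = af_beta, planted = planted,
              te_density = te_density, te_len_range = te_len_range,
              rho = rho, placement_window = as.integer(placement_window),
              intact_fraction = intact_fraction, jitter = jitter,
              K_list = K_list, ltr_length = as.integer(ltr_length),
              depth = depth, n_genes = as.integer(n_genes),
              mismap_frac = mismap_frac, pav_dropout = pav_dropout, f2 = f2)
  class(cfg) <- "sim_config"
  cfg
}

sample_ids <- function(group_sizes) {
  grp <- rep(names(group_sizes), group_sizes)
  data.frame(sample = sprintf("%s%03d", toupper(substr(grp, 1, 1)),
                              seq_along(grp)),
             group = grp, stringsAsFactors = FALSE)
}

#' Simulate cohort SV genotypes
#'
#' Null SVs share one Beta-drawn allele frequency across all groups; planted
#' SVs use their per-group frequency triples. Dosages are Binomial(2, AF)
#' per sample (Hardy-Weinberg within groups, no linkage between SVs).
#'
#' @param config a [simulation_config()].
#' @param positions optional `intervals` frame of SV positions (e.g. from
#'   [simulate_te_sv_landscape()]); generated uniformly when `NULL`.
#' @return list: `matrix` (an `sv_matrix`), `metadata`, `truth` (ids and
#'   per-group true AFs of planted SVs).
#' @export
simulate_cohort_genotypes <- function(config, positions = NULL) {
  with_seed(config$seed, {
    meta <- sample_ids(config$group_sizes)
    n <- config$n_sv
    n_planted <- if (is.null(config$planted)) 0L else nrow(config$planted)
    if (n_planted > n) stop("more planted SVs than n_sv", call. = FALSE)
    af <- matrix(rbeta(n, config$af_beta[1], config$af_beta[2]),
                 nrow = n, ncol = 3,
                 dimnames = list(NULL, c("wild", "native", "commercial")))
    planted_idx <- integer(0)
    if (n_planted > 0L) {
      # planted sites spread deterministically across the locus list
      planted_idx <- unique(as.integer(round(seq(1, n, length.out = n_planted))))
      af[planted_idx, ] <- as.matrix(config$planted[, c("wild", "native", "commercial")])
    }
    if (is.null(positions)) positions <- uniform_sv_positions(config)
    records <- data.frame(id = sprintf("SV%05d", seq_len(n)),
                          chrom = positions$chrom[seq_len(n)],
                          start = positions$start[seq_len(n)],
                          end = positions$end[seq_len(n)],
                          svtype = positions$svtype %||% rep("DEL", n),
                          svlen = positions$end[seq_len(n)] - positions$start[seq_len(n)],
                          stringsAsFactors = FALSE)
    dos <- matrix(NA_integer_, n, nrow(meta))
    for (g in colnames(af)) {
      cols <- which(meta$group == g)
      dos[, cols] <- rbinom(n * length(cols), 2L, rep(af[, g], length(cols)))
    }
    mat <- sv_genotype_matrix(records, meta$sample, dos)
    list(matrix = mat, metadata = meta,
         truth = list(planted_ids = records$id[planted_idx],
                      planted_af = af[planted_idx, , drop = FALSE]))
  })
}

uniform_sv_positions <- function(config, n = config$n_sv,
                                 len_range = c(50, 10000)) {
  tot <- sum(config$layout$length)
  pos <- sort(runif(n, 0, tot))
  cum <- c(0, cumsum(config$layout$length))
  ci <- findInterval(pos, cum, rightmost.closed = TRUE)
  start <- floor(pos - cum[ci])
  len <- floor(exp(runif(n, log(len_range[1]), log(len_range[2]))))
  end <- pmin(start + len, config$layout$length[ci] - 1)
  start <- pmin(start, end - 50)  # keep svlen >= 50 at chromosome edges
  data.frame(chrom = config$layout$chrom[ci], start = start, end = end,
             svtype = "DEL", stringsAsFactors = FALSE)
}

#' Simulate a TE track and SV positions with tunable co-occurrence
#'
#' TEs are placed uniformly. With probability `rho` an SV start falls inside
#' a TE-occupied window of `placement_window` bp; otherwise uniformly. A
#' fraction `intact_fraction` of SVs instead copies an intact TE span with
#' per-endpoint jitter of at most `jitter` x length, which keeps reciprocal
#' overlap above 95%.
#'
#' @param config a [simulation_config()].
#' @return list: `tes` (a `te_track`), `sv_positions` (intervals frame with
#'   `svtype`), `truth` (row indices and ids of intact-derived SVs).
#' @export
simulate_te_sv_landscape <- function(config) {
  with_seed(config$seed + 1L, {
    lay <- config$layout
    n_te <- max(1L, round(config$te_density * sum(lay$length) / 1e6))
    te_len <- floor(exp(runif(n_te, log(config$te_len_range[1]),
                              log(config$te_len_range[2]))))
    if (max(te_len) >= min(lay$length)) {
      stop("layout too small for the requested TE density/length", call. = FALSE)
    }
    tot <- sum(lay$length)
    cum <- c(0, cumsum(lay$length))
    pos <- runif(n_te, 0, tot)
    ci <- findInterval(pos, cum, rightmost.closed = TRUE)
    te_start <- pmin(floor(pos - cum[ci]), lay$length[ci] - te_len - 1)
    te_start <- pmax(te_start, 0)
    classes <- sample(c("LTR/Gypsy", "LTR/ERVL", "LINE/CR1", "DNA/hAT"),
                      n_te, replace = TRUE, prob = c(0.35, 0.15, 0.4, 0.1))
    intact <- grepl("^LTR", classes) & runif(n_te) < 0.5
    tes <- te_track(intervals(lay$chrom[ci], te_start, te_start + te_len),
                    class = classes, intact = intact)

    n <- config$n_sv
    n_intact_sv <- round(config$intact_fraction * n)
    n_free <- n - n_intact_sv
    # TE-occupied windows for enriched placement
    w <- config$placement_window
    occ <- lapply(seq_len(nrow(lay)), function(k) {
      nw <- ceiling(lay$length[k] / w)
      wi <- unique(c(floor(tes$start[tes$chrom == lay$chrom[k]] / w),
                     floor((tes$end[tes$chrom == lay$chrom[k]] - 1) / w)))
      wi[wi < nw]
    })
    n_occ <- vapply(occ, length, integer(1))
    free <- uniform_sv_positions(config, n = n_free)
    enr <- runif(n_free) < config$rho
    if (any(enr) && sum(n_occ) > 0) {
      k <- sample.int(nrow(lay), sum(enr), replace = TRUE, prob = n_occ)
      wi <- vapply(k, function(kk) occ[[kk]][sample.int(n_occ[kk], 1L)], numeric(1))
      st <- floor(wi * w + runif(sum(enr), 0, w))
      len <- free$end[enr] - free$start[enr]
      st <- pmin(st, lay$length[k] - len - 1)
      free$chrom[enr] <- lay$chrom[k]
      free$start[enr] <- st
      free$end[enr] <- st + len
    }
    # ground-truth guarantee: a free SV must not coincide with an intact TE
    # span (reciprocal overlap > 0.9), or the truth id set would be ambiguous
    intact_tes <- tes[tes$intact, , drop = FALSE]
    for (tries in 1:50) {
      clash <- which(best_reciprocal(free, intact_tes) > 0.9)
      if (!length(clash)) break
      redraw <- uniform_sv_positions(config, n = length(clash))
      free[clash, c("chrom", "start", "end")] <-
        redraw[, c("chrom", "start", "end")]
    }
    truth_idx <- integer(0)
    if (n_intact_sv > 0L) {
      cand <- which(tes$intact)
      if (length(cand) < n_intact_sv) {
        stop("not enough intact TEs for requested intact_fraction", call. = FALSE)
      }
      pick <- sample(cand, n_intact_sv)
      len <- tes$end[pick] - tes$start[pick]
      j1 <- round(runif(n_intact_sv, -1, 1) * config$jitter * len)
      j2 <- round(runif(n_intact_sv, -1, 1) * config$jitter * len)
      derived <- data.frame(chrom = tes$chrom[pick],
                            start = pmax(0, tes$start[pick] + j1),
                            end = tes$end[pick] + j2,
                            svtype = "DEL", stringsAsFactors = FALSE)
      sv_pos <- rbind(free, derived)
      truth_idx <- n_free + seq_len(n_intact_sv)
    } else {
      sv_pos <- free
    }
    list(tes = tes, sv_positions = sv_pos,
         truth = list(intact_idx = truth_idx,
                      intact_ids = sprintf("SV%05d", truth_idx)))
  })
}

#' Simulate one LTR pair at known divergence
#'
#' Each of the two copies of `seed_seq` receives substitutions independently
#' at per-site probability `K/2` (uniform choice among the three other
#' bases), so the expected pairwise divergence of the two copies is ~`K`
#' for small `K`, consistent with the Jukes-Cantor clock the dating step
#' inverts.
#'
#' @param seed_seq DNA string (>= 100 bp).
#' @param K target divergence; must be < 0.75 (JC69 validity).
#' @return list: `seq_a`, `seq_b`.
#' @export
simulate_ltr_pair <- function(seed_seq, K) {
  if (K < 0) stop("K must be >= 0", call. = FALSE)
  if (K > 0.75) stop("K > 0.75 is outside JC69 validity", call. = FALSE)
  if (nchar(seed_seq) < 100) stop("seed sequence must be >= 100 bp", call. = FALSE)
  mutate <- function(s) {
    x <- strsplit(s, "")[[1]]
    hit <- which(runif(length(x)) < K / 2)
    if (length(hit)) {
      x[hit] <- vapply(x[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      }, character(1))
    }
    paste(x, collapse = "")
  }
  list(seq_a = mutate(seed_seq), seq_b = mutate(seed_seq))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate LTR pairs for every divergence in `K_list`
#'
#' @param config a [simulation_config()].
#' @return list: `pairs` (named list of `seq_a`/`seq_b`), `truth`
#'   (data frame element, K).
#' @export
simulate_ltr_pairs <- function(config) {
  with_seed(config$seed + 2L, {
    pairs <- list()
    truth <- data.frame(element = character(), K = numeric())
    for (i in seq_along(config$K_list)) {
      K <- config$K_list[i]
      nm <- sprintf("LTRelem%02d", i)
      seed_seq <- random_dna(config$ltr_length)
      pairs[[nm]] <- simulate_ltr_pair(seed_seq, K)
      truth <- rbind(truth, data.frame(element = nm, K = K))
    }
    list(pairs = pairs, truth = truth)
  })
}

#' Simulate per-exon coverage and the true PAV matrix
#'
#' Gene models (2-5 exons, 200-800 bp each) are laid down uniformly. A
#' fraction `pav_dropout` of genes is dispensable with per-sample presence
#' probability ~ Uniform(0.1, 0.9); the rest are present in everyone.
#' Present genes get exonic bases covered >= 2 reads with probability
#' P(Poisson(depth) >= 2) (~1 at 45x); absent genes attract mismapped reads
#' on a `mismap_frac` fraction of bases, so their covered fraction sits
#' below the 5% presence threshold but is not zero.
#'
#' @param config a [simulation_config()].
#' @return list: `coverage` (coverage table), `genes` (gene models),
#'   `truth_pav` (logical gene x sample matrix).
#' @export
simulate_pav_coverage <- function(config) {
  with_seed(config$seed + 3L, {
    meta <- sample_ids(config$group_sizes)
    lay <- config$layout
    ng <- config$n_genes
    genes <- vector("list", ng)
    for (i in seq_len(ng)) {
      k <- sample.int(nrow(lay), 1L)
      n_ex <- sample(2:5, 1L)
      ex_len <- sample(200:800, n_ex, replace = TRUE)
      gaps <- sample(100:2000, n_ex, replace = TRUE)
      gstart <- floor(runif(1, 0, lay$length[k] - sum(ex_len) - sum(gaps) - 1))
      starts <- gstart + cumsum(c(0, head(ex_len + gaps, -1)))
      genes[[i]] <- gene_model(sprintf("gene%04d", i), lay$chrom[k],
                               sample(c("+", "-"), 1L),
                               intervals(lay$chrom[k], starts, starts + ex_len))
    }
    names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
    dispensable <- runif(ng) < config$pav_dropout
    pres_prob <- ifelse(dispensable, runif(ng, 0.1, 0.9), 1)
    truth <- matrix(runif(ng * nrow(meta)) < pres_prob, ng, nrow(meta),
                    dimnames = list(names(genes), meta$sample))
    p_cov <- 1 - stats::ppois(1, config$depth)        # P(depth >= 2) per base
    rows <- vector("list", ng)
    for (i in seq_len(ng)) {
      ex_len <- genes[[i]]$exons$end - genes[[i]]$exons$start
      n_ex <- length(ex_len)
      ns <- nrow(meta)
      p <- ifelse(truth[i, ], p_cov, config$mismap_frac * p_cov)
      bases <- rbinom(n_ex * ns, size = rep(ex_len, ns), prob = rep(p, each = n_ex))
      rows[[i]] <- data.frame(sample = rep(meta$sample, each = n_ex),
                              gene = names(genes)[i],
                              exon_index = rep(seq_len(n_ex), ns),
                              bases_ge_min_depth = bases,
                              exon_length = rep(ex_len, ns),
                              stringsAsFactors = FALSE)
    }
    list(coverage = do.call(rbind, rows), genes = genes, truth_pav = truth,
         metadata = meta)
  })
}

#' Simulate an F2 phenotype with a marker of known variance fraction
#'
#' Marker genotypes follow F2 ratios (1/4, 1/2, 1/4); phenotype
#' `y = mu + s * sex + a * g + e`, with the additive effect `a` chosen so
#' the marker explains fraction `v` of Var(y) in expectation:
#' `a = sqrt(v * (s^2/4 + sigma^2) / (0.5 * (1 - v)))` (Var(g) = 1/2 in an
#' F2, sexes balanced).
#'
#' @param config a [simulation_config()].
#' @return list: `phenotypes` (sample, sex, trait), `marker` (dosage
#'   vector), `truth` (v, a).
#' @export
simulate_f2 <- function(config) {
  f2 <- config$f2
  with_seed(config$seed + 4L, {
    n <- f2$n
    g <- sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25))
    sex <- rep_len(c(0L, 1L), n)
    a <- if (f2$v == 0) 0 else {
      sqrt(f2$v * (f2$sex_effect^2 / 4 + f2$resid_sd^2) / (0.5 * (1 - f2$v)))
    }
    y <- f2$mu + f2$sex_effect * sex + a * g + rnorm(n, 0, f2$resid_sd)
    ph <- data.frame(sample = sprintf("F2_%04d", seq_len(n)), sex = sex,
                     trait = y, stringsAsFactors = FALSE)
    list(phenotypes = ph, marker = g, truth = list(v = f2$v, a = a))
  })
}

#' Simulate window haplotypes with a neutral frequency spectrum
#'
#' Segregating sites get derived-allele counts i drawn with probability
#' proportional to 1/i (the standard neutral site-frequency spectrum) and
#' uniform positions in the window.
#'
#' @param n_hap number of haplotypes (>= 4).
#' @param n_sites segregating sites (0 allowed).
#' @param window_length window size in bp.
#' @param seed integer seed.
#' @return list: `haplotypes` (sites x haplotypes 0/1 matrix), `positions`.
#' @export
simulate_window_haplotypes <- function(n_hap, n_sites, window_length = 10000L,
                                       seed = 1L) {
  if (n_hap < 4) stop("need >= 4 haplotypes", call. = FALSE)
  with_seed(seed, {
    h <- matrix(0L, n_sites, n_hap)
    if (n_sites > 0L) {
      i <- sample.int(n_hap - 1L, n_sites, replace = TRUE,
                      prob = 1 / seq_len(n_hap - 1L))
      for (s in seq_len(n_sites)) h[s, sample.int(n_hap, i[s])] <- 1L
    }
    pos <- sort(floor(runif(n_sites, 0, window_length)))
    list(haplotypes = h, positions = pos, window_length = window_length)
  })
}

#' Simulate a complete cohort
#'
#' Runs every generator under one master seed and assembles the result with
#' a ground-truth record for each stage.
#'
#' @param config a [simulation_config()].
#' @return a `simulated_cohort` list: `sv`, `metadata`, `tes`, `genes`,
#'   `coverage`, `ltr`, `f2`, `truth`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  land <- simulate_te_sv_landscape(config)
  geno <- simulate_cohort_genotypes(config, positions = land$sv_positions)
  pav <- simulate_pav_coverage(config)
  ltr <- simulate_ltr_pairs(config)
  f2 <- simulate_f2(config)
  structure(list(
    sv = geno$matrix, metadata = geno$metadata, tes = land$tes,
    genes = pav$genes, coverage = pav$coverage,
    ltr = ltr$pairs, f2 = f2,
    truth = list(planted_ids = geno$truth$planted_ids,
                 planted_af = geno$truth$planted_af,
                 intact_ids = land$truth$intact_ids,
                 pav = pav$truth_pav,
                 ltr_K = ltr$truth,
                 marker_v = f2$truth$v)
  ), class = "simulated_cohort")
}

#' Write a simulated cohort to standard formats
#'
#' Emits `svs.vcf`, `tes.bed`, `genes.gff3`, `coverage.tsv`,
#' `ltr_pairs.fasta` (paired `_5LTR`/`_3LTR` entries), `phenotypes.tsv`,
#' `groups.tsv`, `layout.tsv` and a machine-readable `truth.json`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param config the [simulation_config()] used (for the layout).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_sv_vcf(cohort$sv, p("svs.vcf"), layout = config$layout)
  te_df <- cohort$tes
  te_df$label <- paste0(te_df$class, ifelse(te_df$intact, ";intact", ""))
  write_bed(te_df, p("tes.bed"))
  write_gff3(cohort$genes, p("genes.gff3"))
  write.table(cohort$coverage, p("coverage.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  seqs <- unlist(lapply(names(cohort$ltr), function(nm) {
    setNames(c(cohort$ltr[[nm]]$seq_a, cohort$ltr[[nm]]$seq_b),
             paste0(nm, c("_5LTR", "_3LTR")))
  }))
  write_fasta(seqs, p("ltr_pairs.fasta"))
  ph <- cohort$f2$phenotypes
  ph$marker <- cohort$f2$marker
  write.table(ph, p("phenotypes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$metadata, p("groups.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(config$layout, p("layout.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- cohort$truth
  truth$pav <- NULL
  write.table(data.frame(gene = rownames(cohort$truth$pav),
                         cohort$truth$pav, check.names = FALSE),
              p("truth_pav.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  truth$planted_af <- as.data.frame(truth$planted_af)
  jsonlite::write_json(truth, p("truth.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(dir)
}
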