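make_sv_at <- function(start, end, chrom = "chr1") {
  rec <- data.frame(id = sprintf("SV%03d", seq_along(start)), chrom = chrom,
                    start = start, end = end, svtype = "DEL",
                    svlen = end - start, stringsAsFactors = FALSE)
  sv_genotype_matrix(rec, "s1", matrix(1L, length(start), 1))
}

test_that("TE-covered fraction merges TEs and classifies overlap", {
  sv <- make_sv_at(100, 300)  # svlen 200 > 100
  te1 <- te_track(intervals("chr1", 200, 400))
  ov <- sv_te_overlap(sv, te1)
  expect_equal(ov$fraction, 0.5)
  expect_identical(ov$class, "high")
  # fragmented TEs merge before counting: [100,140)+[130,160) -> 60 bp of 200
  te2 <- te_track(intervals("chr1", c(100, 130), c(140, 160)))
  ov2 <- sv_te_overlap(make_sv_at(100, 300), te2)
  expect_equal(ov2$fraction, 0.3)
  expect_identical(ov2$class, "partial")
  none <- sv_te_overlap(sv, te_track(intervals("chr2", 0, 1000)))
  expect_identical(none$class, "none")
})

test_that("coverage fraction is invariant to TE fragmentation", {
  set.seed(12)
  sv <- make_sv_at(seq(0, 90000, 10000), seq(0, 90000, 10000) + 5000)
  whole <- te_track(intervals("chr1", seq(2000, 92000, 10000),
                              seq(2000, 92000, 10000) + 4000))
  # split every TE into two adjacent pieces
  s <- whole$start; e <- whole$end; mid <- (s + e) %/% 2
  split_te <- te_track(intervals("chr1", c(s, mid), c(mid, e)))
  expect_equal(sv_te_overlap(sv, whole)$fraction,
               sv_te_overlap(sv, split_te)$fraction)
})

test_that("intact-derived matching is reciprocal with a strict 0.95 boundary", {
  tes <- te_track(intervals("chr1", c(1001, 5000, 9000),
                            c(1099, 5095, 9300)), intact = TRUE)
  sv <- make_sv_at(c(1000, 5000, 9000), c(1100, 5100, 9100))
  got <- match_intact_derived(sv, tes)
  # 98/100 = 0.98 reciprocal -> matched; 95/100 = 0.95 not > 0.95 -> out;
  # one-sided 100/100 but 100/300 reciprocal -> out
  expect_identical(got, "SV001")
  one_sided <- match_intact_derived(sv, tes, reciprocal = FALSE)
  expect_identical(one_sided, c("SV001", "SV003"))
  # non-intact TEs never match
  frag <- te_track(intervals("chr1", 1001, 1099), intact = FALSE)
  expect_length(match_intact_derived(sv, frag), 0)
})

test_that("window occupancy tiles chromosomes and marks any-overlap", {
  lay <- genome_layout("chr1", 10000)
  sv <- make_sv_at(100, 200)
  te <- te_track(intervals("chr1", 1900, 2100))  # spans windows 1 and 2
  tab <- window_occupancy(sv, te, lay, 2000)
  expect_equal(sum(tab), 5)                       # 5 windows of 2 kb
  expect_equal(unname(tab["yes", "yes"]), 1)      # window 1: TE + SV
  expect_equal(unname(tab["yes", "no"]), 1)       # window 2: TE only
  expect_equal(unname(tab["no", "no"]), 3)
  empty <- window_occupancy(make_sv_at(100, 200)[0, ], te[0, ], lay, 2000)
  expect_equal(unname(empty["no", "no"]), 5)
})

test_that("chi-square on 2x2 occupancy matches the closed form", {
  ct <- chi_square_2x2(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(ct$chisq, 20)  # n(ad-bc)^2 / prod(margins)
  ind <- chi_square_2x2(matrix(c(25, 25, 25, 25), 2))
  expect_equal(ind$chisq, 0)
  expect_equal(ind$p, 1)
  zm <- chi_square_2x2(matrix(c(0, 0, 10, 10), 2, byrow = TRUE))
  expect_false(zm$defined)
  expect_true(is.na(zm$p))
  expect_error(chi_square_2x2(matrix(0, 2, 2)), "empty")
})

test_that("SV context is strand-aware with gene_body precedence", {
  genes <- list(
    gplus = gene_model("gplus", "chr1", "+",
                       intervals("chr1", 20000, 26000)),
    gminus = gene_model("gminus", "chr1", "-",
                        intervals("chr1", 50000, 56000)))
  sv <- make_sv_at(c(21000, 17000, 29000, 57000, 43000, 80000),
                   c(21200, 17200, 29200, 57200, 43200, 80200))
  ctx <- classify_context(sv, genes)
  expect_identical(ctx$context,
                   c("gene_body",   # inside gplus
                     "upstream5k",  # 3 kb 5' of + strand tss
                     "intergenic",  # 3 kb 3' of gplus
                     "upstream5k",  # 1-1.2 kb 5' of - strand tss (right side)
                     "intergenic",  # 7 kb upstream: outside 5 kb
                     "intergenic"))
  expect_identical(ctx$gene[1], "gplus")
  expect_identical(ctx$gene[4], "gminus")
})

test_that("nearest gene minimises edge distance with start tie-breaks", {
  genes <- list(
    left = gene_model("left", "chr1", "+", intervals("chr1", 1000, 1500)),
    right = gene_model("right", "chr1", "+", intervals("chr1", 2300, 2800)))
  sv <- make_sv_at(1950, 2000)  # left gap 450, right gap 300
  ng <- nearest_gene(sv, genes)
  expect_identical(ng$gene, "right")
  expect_equal(ng$distance, 300)
  over <- nearest_gene(make_sv_at(1200, 1300), genes)
  expect_identical(over$gene, "left")
  expect_equal(over$distance, 0)
  tie <- nearest_gene(make_sv_at(1800, 2000), genes)  # both gaps 300
  expect_identical(tie$gene, "left")  # lower start wins
  nochr <- nearest_gene(make_sv_at(100, 200, chrom = "chrZ"), genes)
  expect_true(is.na(nochr$gene))
})

test_that("co-occurrence enrichment is detected when planted", {
  cfg <- simulation_config(seed = 77, rho = 0.9, intact_fraction = 0,
                           n_sv = 300)
  land <- simulate_te_sv_landscape(cfg)
  geno <- simulate_cohort_genotypes(cfg, positions = land$sv_positions)
  cc <- te_sv_cooccurrence(geno$matrix, land$tes, cfg$layout)
  expect_equal(cc$window_size, c(2000, 5000, 10000))
  expect_true(all(cc$p < 1e-6))
  expect_true(all(cc$odds_ratio > 1))
})
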