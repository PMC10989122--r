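test_that("pi reproduces the unbiased per-site heterozygosity", {
  h <- matrix(0L, 1, 4); h[1, 1:2] <- 1L
  expect_equal(pi_per_site(h, 100), 2 * 0.5 * 0.5 * (4 / 3) / 100)
  expect_equal(pi_per_site(matrix(0L, 0, 4), 100), 0)
  ident <- matrix(1L, 3, 2)
  expect_equal(pi_per_site(ident, 50), 0)
  expect_error(pi_per_site(h, 0), "> 0")
})

test_that("Tajima's D reproduces the n=4 single-site worked value", {
  h <- matrix(0L, 1, 4); h[1, 1:2] <- 1L
  td <- tajimas_d(h)
  expect_equal(td$kbar, 2 / 3)
  expect_equal(td$a1, 11 / 6)
  expect_equal(td$D, 1.632993, tolerance = 1e-6)
  empty <- tajimas_d(matrix(0L, 0, 4))
  expect_true(is.na(empty$D))
  expect_error(tajimas_d(matrix(0L, 1, 3)), "n >= 4")
})

test_that("D is invariant to derived/ancestral relabeling", {
  set.seed(5)
  h <- simulate_window_haplotypes(8, 30, seed = 5)$haplotypes
  flip <- h
  flip[7, ] <- 1L - flip[7, ]
  expect_equal(tajimas_d(h)$D, tajimas_d(flip)$D)
})

test_that("pi and D match brute-force all-pairs oracles on random windows", {
  for (s in 1:10) {
    h <- simulate_window_haplotypes(n_hap = 12, n_sites = 50,
                                    window_length = 5000, seed = s)$haplotypes
    expect_equal(pi_per_site(h, 5000), pi_oracle(h, 5000), tolerance = 1e-12)
    expect_equal(tajimas_d(h)$D, tajima_oracle(h), tolerance = 1e-12)
  }
})

test_that("diploid dosages give the same pi via frequencies as via expansion", {
  set.seed(8)
  dos <- matrix(sample(0:2, 60, replace = TRUE), 6, 10)
  h <- genotypes_to_haplotypes(dos)
  expect_equal(pi_per_site(dos, 1000, ploidy = 2), pi_per_site(h, 1000))
  expect_equal(rowSums(h), rowSums(dos))
})

test_that("windowed scan tiles and slides with the documented window counts", {
  lay <- genome_layout("chr1", 100000)
  dos <- matrix(sample(0:2, 50 * 8, replace = TRUE), 50)
  rec <- data.frame(id = sprintf("S%03d", 1:50), chrom = "chr1",
                    start = seq(500, 99000, length.out = 50), svtype = "DEL")
  rec$start <- floor(rec$start); rec$end <- rec$start + 100; rec$svlen <- 100
  m <- sv_genotype_matrix(rec, sprintf("s%d", 1:8), dos)
  tiled <- windowed_scan(m, lay, "pi", window = 20000, step = 20000)
  expect_equal(nrow(tiled), 5)
  slid <- windowed_scan(m, lay, "tajima_d", window = 10000, step = 5000)
  expect_equal(nrow(slid), 19)  # (100 - 10)/5 + 1 full windows
  # empty windows are reported missing
  rec2 <- rec; rec2$start <- rec2$start %% 10000; rec2$end <- rec2$start + 100
  m2 <- sv_genotype_matrix(rec2, sprintf("s%d", 1:8), dos)
  sc2 <- windowed_scan(m2, lay, "pi", window = 20000, step = 20000)
  expect_true(all(is.na(sc2$value[sc2$n_sites == 0])))
  expect_true(any(sc2$n_sites == 0))
})

test_that("windowed F_ST with one site equals the single-locus estimator", {
  dos <- matrix(c(2L, 2L, 1L, 2L, 0L, 0L, 1L, 0L), 1)
  m <- make_sv_fixture(dos)
  m$records$start <- 100; m$records$end <- 200
  meta <- data.frame(sample = m$samples,
                     group = rep(c("native", "commercial"), each = 4))
  lay <- genome_layout("chr1", 20000)
  sc <- windowed_scan(m, lay, "fst", window = 20000, step = 20000,
                      metadata = meta, contrast = c("native", "commercial"))
  cnt <- group_allele_counts(m, meta)
  single <- wc_fst(cnt$native$n, cnt$native$d / cnt$native$m,
                   cnt$native$h / cnt$native$n,
                   cnt$commercial$n, cnt$commercial$d / cnt$commercial$m,
                   cnt$commercial$h / cnt$commercial$n)$theta
  expect_equal(sc$value, single)
})

test_that("windowed F_ST peaks at a planted near-fixed difference", {
  hits <- 0
  for (s in 1:10) {
    cfg <- simulation_config(seed = 400 + s, n_sv = 300,
                             layout = genome_layout("chr1", 3e6),
                             planted = data.frame(wild = 0.5, native = 0.95,
                                                  commercial = 0.02))
    sim <- simulate_cohort_genotypes(cfg)
    sc <- windowed_scan(sim$matrix, cfg$layout, "fst", metadata = sim$metadata,
                        contrast = c("native", "commercial"))
    planted_pos <- sim$matrix$records$start[sim$matrix$records$id ==
                                              sim$truth$planted_ids]
    top <- sc[which.max(sc$value), ]
    if (planted_pos >= top$start && planted_pos < top$end) hits <- hits + 1
  }
  expect_gte(hits, 9)
})
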