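test_that("cohort genotypes are deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 5, n_sv = 100)
  a <- simulate_cohort_genotypes(cfg)
  b <- simulate_cohort_genotypes(cfg)
  expect_identical(a$matrix$dosages, b$matrix$dosages)
  expect_identical(a$matrix$records, b$matrix$records)
})

test_that("planted allele frequencies are realised within binomial error", {
  cfg <- simulation_config(seed = 21, n_sv = 500)
  sim <- simulate_cohort_genotypes(cfg)
  native <- sim$metadata$sample[sim$metadata$group == "native"]
  af <- allele_frequency(sim$matrix[sim$matrix$records$id %in%
                                      sim$truth$planted_ids, ], native)
  # n = 70 ducks -> 140 alleles; 0.06 ~ 2.3 binomial SE at p = 0.89
  expect_lt(abs(af - 0.89), 0.06)
})

test_that("null SVs share frequencies across groups in expectation", {
  cfg <- simulation_config(seed = 9, n_sv = 2000, planted = NULL)
  sim <- simulate_cohort_genotypes(cfg)
  wild <- sim$metadata$sample[sim$metadata$group == "wild"]
  comm <- sim$metadata$sample[sim$metadata$group == "commercial"]
  d <- allele_frequency(sim$matrix, wild) - allele_frequency(sim$matrix, comm)
  expect_lt(abs(mean(d)), 0.01)
})

test_that("intact_fraction yields exactly the requested intact-derived truth set", {
  cfg <- simulation_config(seed = 2, n_sv = 100, intact_fraction = 0.1)
  land <- simulate_te_sv_landscape(cfg)
  expect_length(land$truth$intact_ids, 10)
  expect_equal(nrow(land$sv_positions), 100)
})

test_that("LTR pair generator hits the target divergence and honours guards", {
  s <- paste(rep("ACGT", 2500), collapse = "")
  set.seed(33)
  pair <- simulate_ltr_pair(s, 0.01)
  mm <- mean(strsplit(pair$seq_a, "")[[1]] != strsplit(pair$seq_b, "")[[1]])
  expect_lt(abs(mm - 0.01), 0.003)
  set.seed(34)
  same <- simulate_ltr_pair(s, 0)
  expect_identical(same$seq_a, same$seq_b)
  expect_error(simulate_ltr_pair(s, 0.8), "JC69")
  expect_error(simulate_ltr_pair("ACGT", 0.01), "100 bp")
})

test_that("coverage generator separates present and absent genes at 45x", {
  cfg <- simulation_config(seed = 4, n_genes = 50,
                           group_sizes = c(wild = 3, native = 3, commercial = 3))
  sim <- simulate_pav_coverage(cfg)
  cov <- sim$coverage
  frac <- tapply(seq_len(nrow(cov)), paste(cov$gene, cov$sample), function(ii) {
    sum(cov$bases_ge_min_depth[ii]) / sum(cov$exon_length[ii])
  })
  gene <- sub(" .*", "", names(frac))
  samp <- sub(".* ", "", names(frac))
  truth <- sim$truth_pav[cbind(gene, samp)]
  expect_gt(min(frac[truth]), 0.5)       # present genes nearly fully covered
  expect_lt(max(frac[!truth]), 0.05)     # absent genes below the threshold
  expect_gt(mean(frac[!truth] > 0), 0.9) # but background is nonzero
})

test_that("F2 generator encodes the requested marker variance fraction", {
  cfg <- simulation_config(seed = 6)
  f2 <- simulate_f2(cfg)
  expect_equal(f2$truth$v, 0.2761)
  g <- f2$marker
  expect_gt(mean(g == 1), 0.4)  # F2 heterozygote class near 1/2
  cfg0 <- simulation_config(seed = 6, f2 = list(n = 100, v = 0, sex_effect = 1,
                                                resid_sd = 1, mu = 0))
  expect_equal(simulate_f2(cfg0)$truth$a, 0)
})

test_that("window haplotypes follow the 1/i neutral frequency spectrum", {
  h <- simulate_window_haplotypes(n_hap = 10, n_sites = 0, seed = 1)
  expect_equal(nrow(h$haplotypes), 0)
  h <- simulate_window_haplotypes(n_hap = 10, n_sites = 5000, seed = 2)
  dac <- rowSums(h$haplotypes)
  expect_true(all(dac >= 1 & dac <= 9))
  obs <- tabulate(dac, 9) / 5000
  expected <- (1 / 1:9) / sum(1 / 1:9)
  expect_lt(max(abs(obs - expected)), 0.02)
  again <- simulate_window_haplotypes(n_hap = 10, n_sites = 5000, seed = 2)
  expect_identical(h$haplotypes, again$haplotypes)
})

test_that("a full cohort is internally consistent with its truth record", {
  cfg <- simulation_config(seed = 13, n_sv = 200, n_genes = 40)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$planted_ids %in% co$sv$records$id))
  expect_true(all(co$truth$intact_ids %in% co$sv$records$id))
  expect_identical(sort(rownames(co$truth$pav)), sort(names(co$genes)))
  expect_setequal(co$truth$ltr_K$element, names(co$ltr))
  expect_equal(ncol(co$sv$dosages), sum(cfg$group_sizes))
})
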