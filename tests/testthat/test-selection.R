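test_that("group allele counts exclude missing dosages", {
  dos <- matrix(1L, 1, 10)
  m <- make_sv_fixture(dos)
  meta <- data.frame(sample = m$samples, group = "native")
  cnt <- group_allele_counts(m, meta)$native
  expect_equal(cnt$d, 10)
  expect_equal(cnt$m, 20)
  expect_equal(cnt$h, 10)
  dos[1, 1] <- NA
  m2 <- make_sv_fixture(dos)
  cnt2 <- group_allele_counts(m2, meta)$native
  expect_equal(cnt2$m, 18)
  expect_equal(cnt2$n, 9)
  expect_error(group_allele_counts(m, meta[-1, ]), "without group")
})

test_that("MAF filter removes rare sites on either tail", {
  # 100 samples: AF 0.005, 0.5, 0.995
  dos <- rbind(c(1L, rep(0L, 99)), rep(1L, 100), c(1L, rep(2L, 99)))
  m <- make_sv_fixture(dos)
  kept <- maf_filter(m, 0.01)
  expect_equal(kept$records$id, "SV002")
})

test_that("Fisher two-sided p matches hand-enumerated values", {
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1)
  expect_equal(fisher_exact_two_sided(3, 1, 1, 3), 34 / 70)
  expect_equal(fisher_exact_two_sided(10, 0, 0, 10), 2 / choose(20, 10))
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "negative")
})

test_that("Fisher p equals stats::fisher.test over random tables", {
  set.seed(101)
  for (i in 1:200) {
    tb <- matrix(sample(0:25, 4, replace = TRUE), 2)
    if (sum(tb) == 0) next
    expect_equal(fisher_exact_two_sided(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2]),
                 stats::fisher.test(tb)$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(c(0.001, 0.01, 0.02, 0.8)),
               c(0.004, 0.02, 0.8 / 30, 0.8))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in sorted p
  expect_true(all(q <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("Weir-Cockerham theta matches the ANOVA oracle to 1e-12", {
  set.seed(2024)
  for (i in 1:300) {
    gc1 <- as.vector(stats::rmultinom(1, sample(2:40, 1), runif(3) + 0.05))
    gc2 <- as.vector(stats::rmultinom(1, sample(2:40, 1), runif(3) + 0.05))
    n1 <- sum(gc1); n2 <- sum(gc2)
    p1 <- (2 * gc1[1] + gc1[2]) / (2 * n1)
    p2 <- (2 * gc2[1] + gc2[2]) / (2 * n2)
    mine <- wc_fst(n1, p1, gc1[2] / n1, n2, p2, gc2[2] / n2)
    orc <- wc_anova_oracle(gc1, gc2)
    expect_equal(mine$a, orc$a, tolerance = 1e-12)
    expect_equal(mine$b, orc$b, tolerance = 1e-12)
    expect_equal(mine$c, orc$c, tolerance = 1e-12)
  }
})

test_that("theta is 1 at a fixed difference and symmetric/invariant", {
  expect_equal(wc_fst(10, 1, 0, 10, 0, 0)$theta, 1)
  th_ab <- wc_fst(12, 0.3, 0.4, 30, 0.8, 0.2)$theta
  th_ba <- wc_fst(30, 0.8, 0.2, 12, 0.3, 0.4)$theta
  expect_equal(th_ab, th_ba)                               # group swap
  th_flip <- wc_fst(12, 0.7, 0.4, 30, 0.2, 0.2)$theta      # allele relabel
  expect_equal(th_ab, th_flip)
  expect_true(is.na(wc_fst(10, 0, 0, 10, 0, 0)$theta))     # monomorphic
  expect_true(is.na(wc_fst(1, 0.5, 0.5, 10, 0.5, 0.5)$theta))  # n < 2
})

test_that("selection scan flags planted frequency shifts with correct direction", {
  cfg <- simulation_config(seed = 301, n_sv = 400,
                           planted = data.frame(wild = 0.05, native = 0.89,
                                                commercial = 0.012))
  sim <- simulate_cohort_genotypes(cfg)
  res <- scan_selection(maf_filter(sim$matrix), sim$metadata,
                        c("native", "commercial"))
  hit <- res[res$id == sim$truth$planted_ids, ]
  expect_true(hit$selected)
  expect_identical(hit$direction, "decreased")
  dom <- scan_selection(maf_filter(sim$matrix), sim$metadata,
                        c("wild", "native"))
  expect_identical(dom$direction[dom$id == sim$truth$planted_ids], "increased")
  expect_error(scan_selection(sim$matrix, sim$metadata, c("wild", "feral")),
               "absent")
})

test_that("equal group frequencies give direction 'none'", {
  dos <- matrix(rep(c(0L, 2L), 10), 1)
  m <- make_sv_fixture(dos)
  meta <- data.frame(sample = m$samples,
                     group = rep(c("wild", "native"), each = 10))
  res <- scan_selection(m, meta, c("wild", "native"))
  expect_identical(res$direction, "none")
})

test_that("delta_af ranks |AF| differences with positional tie-breaks", {
  dos <- rbind(c(rep(2L, 5), rep(0L, 5)),  # dAF 1 at pos 1000
               rep(1L, 10),                # dAF 0
               c(rep(2L, 5), rep(0L, 5)))  # dAF 1 at pos 11000
  m <- make_sv_fixture(dos)
  meta <- data.frame(sample = m$samples,
                     group = rep(c("high", "low"), each = 5))
  res <- delta_af(m, meta, "high", "low")
  expect_equal(res$daf, c(1, 1, 0))
  expect_equal(res$id, c("SV001", "SV003", "SV002"))  # tie by position
  expect_equal(res$rank, 1:3)
  region <- intervals("chr1", 0, 2000)
  inside <- delta_af(m, meta, "high", "low", region = region)
  expect_equal(inside$id, "SV001")
  empty <- intervals("chr9", 0, 100)
  expect_warning(none <- delta_af(m, meta, "high", "low", region = empty),
                 "no variants")
  expect_equal(nrow(none), 0)
})
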