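test_that("maf and call_rate follow their counting definitions", {
  expect_equal(maf(rep(1L, 10)), 0.5)            # all heterozygotes
  expect_equal(maf(rep(0L, 6)), 0)               # monomorphic
  expect_equal(maf(c(2L, 1L, 1L, 1L, rep(0L, 8))), 5 / 24)
  expect_equal(maf(c(2L, 2L, NA, 2L)), 0)        # missing excluded
  expect_error(maf(c(NA_integer_, NA_integer_)), "all genotypes missing")

  expect_equal(call_rate(c(0L, 1L, 2L)), 1)
  expect_equal(call_rate(rep(NA_integer_, 4)), 0)
  expect_equal(call_rate(c(rep(0L, 54), rep(NA_integer_, 6))), 0.9)
  # the rule is strict "<": exactly 90% is retained
  expect_false(0.9 < qc_thresholds()$call_rate_min)
})

test_that("HWE exact p matches the enumeration oracle and its symmetries", {
  expect_equal(hwe_exact_p(10, 0, 0), 1)  # monomorphic
  expect_equal(hwe_exact_p(3, 5, 2), hwe_oracle(3, 5, 2), tolerance = 1e-12)
  # allele-label symmetry
  for (cfg in list(c(3, 5, 2), c(0, 10, 0), c(7, 1, 4), c(12, 0, 3))) {
    expect_equal(hwe_exact_p(cfg[1], cfg[2], cfg[3]),
                 hwe_exact_p(cfg[3], cfg[2], cfg[1]), tolerance = 1e-12)
  }
  # p is a valid probability over a scattering of configurations
  set.seed(5)
  for (i in 1:50) {
    cfg <- as.vector(rmultinom(1, sample(2:40, 1), c(1, 1, 1)))
    p <- hwe_exact_p(cfg[1], cfg[2], cfg[3])
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(p, hwe_oracle(cfg[1], cfg[2], cfg[3]), tolerance = 1e-12)
  }
  expect_error(hwe_exact_p(0, 0, 0), "no genotypes")
})

test_that("QC cascade at extreme thresholds is the identity", {
  set.seed(8)
  panel <- random_panel(n = 10, m = 20)
  res <- apply_qc(panel, qc_thresholds(
    hwe_p_min = 0, maf_min = 0, call_rate_min = 0,
    autosomes = unique(panel$variants$chrom)
  ))
  expect_equal(res$report$n_retained, 20)
  expect_equal(res$report$n_removed_hwe, 0)
  expect_equal(res$report$n_removed_nonautosomal, 0)
  expect_equal(res$report$n_removed_callrate_or_maf, 0)
  expect_identical(panel_dosages(res$panel), panel_dosages(panel))
})

test_that("planted violations are charged to the correct cascade stage", {
  cfg <- sim_config(
    n_populations = 3, n_samples_per_pop = 12, n_loci = 300,
    n_chromosomes = 3, chrom_length_bp = 5e6,
    maf_range = c(0.2, 0.5), low_maf_frac = 0, missing_rate = 0,
    n_hwe_violations = 7, n_maf_violations = 5, n_lowcall_violations = 4,
    n_nonautosomal = 6, seed = 31
  )
  sim <- simulate_panel(cfg)
  res <- apply_qc(sim$panel)
  rep <- res$report
  expect_equal(rep$n_removed_nonautosomal, 6)
  expect_equal(rep$n_removed_hwe, 7)
  expect_equal(rep$n_removed_callrate_or_maf, 9)
  # partition identity
  expect_equal(rep$n_input,
               rep$n_removed_nonautosomal + rep$n_removed_hwe +
                 rep$n_removed_callrate_or_maf + rep$n_retained)
  # removed ids match the planted truth, stage by stage
  truth <- sim$truth$planted
  expect_setequal(rep$removed$vid[rep$removed$stage == "hwe"],
                  truth$vid[truth$label == "hwe"])
  expect_setequal(rep$removed$vid[rep$removed$stage == "callrate_or_maf"],
                  truth$vid[truth$label %in% c("maf", "callrate")])
})

test_that("a non-autosomal locus violating HWE is charged to stage one", {
  d <- matrix(1L, 30, 2)          # all heterozygous at both loci
  panel <- make_panel(d, chrom = c("X", "1"))
  expect_warning(
    res <- apply_qc(panel, qc_thresholds(hwe_p_min = 0.9)),
    "no loci retained"
  )
  expect_equal(res$report$n_removed_nonautosomal, 1)
  expect_equal(res$report$n_removed_hwe, 1)
  expect_equal(res$report$removed$stage[res$report$removed$vid == "v001"],
               "nonautosomal")
})

test_that("QC partition identity holds on random panels", {
  set.seed(99)
  for (i in 1:8) {
    panel <- random_panel(n = 6 + i, m = 15 + i, missing_rate = 0.25)
    rep <- apply_qc(panel)$report
    expect_equal(rep$n_input,
                 rep$n_removed_nonautosomal + rep$n_removed_hwe +
                   rep$n_removed_callrate_or_maf + rep$n_retained)
    expect_equal(nrow(rep$removed), rep$n_input - rep$n_retained)
    expect_false(anyDuplicated(rep$removed$vid) > 0)
  }
})

test_that("MAF histogram uses half-open bins with a closed last bin", {
  panel <- make_panel(matrix(0L, 6, 4))            # all MAF 0
  h <- maf_histogram(panel)
  expect_equal(h$n_loci[h$lo == 0], 4)
  expect_equal(sum(h$n_loci), 4)

  panel2 <- make_panel(matrix(1L, 6, 3))           # all MAF exactly 0.5
  h2 <- maf_histogram(panel2)
  expect_equal(h2$n_loci[h2$hi == 0.5], 3)

  expect_error(maf_histogram(panel, population = "nope"), "unknown population")
})

test_that("MAF histogram matches a direct tabulation oracle", {
  set.seed(21)
  sim <- simulate_panel(sim_config(
    n_populations = 2, n_samples_per_pop = 12, n_loci = 400,
    n_chromosomes = 2, chrom_length_bp = 5e6, seed = 21
  ))
  h <- maf_histogram(sim$panel)
  tab <- maf_table(sim$panel)
  for (p in unique(tab$population)) {
    mafs <- tab$maf[tab$population == p]
    edges <- seq(0, 0.5, by = 0.1)
    oracle <- as.vector(table(cut(mafs, edges, right = FALSE,
                                  include.lowest = FALSE)))
    # cut(right = FALSE) puts 0.5 out of range; fold it into the last bin
    oracle[5] <- oracle[5] + sum(mafs == 0.5)
    got <- h$n_loci[h$population == p][order(h$lo[h$population == p])]
    expect_equal(got, oracle)
    expect_equal(sum(got), length(mafs))
  }
})

test_that("monomorphic overlap matches planted sets", {
  cfg <- sim_config(
    n_populations = 3, n_samples_per_pop = 12, n_loci = 300,
    n_chromosomes = 2, chrom_length_bp = 5e6,
    maf_range = c(0.35, 0.5), low_maf_frac = 0, missing_rate = 0,
    monomorphic_plan = list(
      list(pops = c("pop1", "pop2", "pop3"), n = 30),
      list(pops = "pop1", n = 10)
    ),
    seed = 17
  )
  sim <- simulate_panel(cfg)
  # the planted sets are exactly the realized monomorphic sets
  for (p in c("pop1", "pop2", "pop3"))
    expect_setequal(monomorphic_loci(sim$panel, p),
                    sim$truth$monomorphic_sets[[p]])
  expect_equal(monomorphic_overlap(sim$panel, "pop1", c("pop2", "pop3")),
               30 / 40)
  expect_equal(monomorphic_overlap(sim$panel, "pop1", "pop1"), 1)
  expect_equal(monomorphic_overlap(sim$panel, "pop2", "pop3"), 1)
  no_mono <- make_panel(matrix(1L, 6, 3))
  expect_error(monomorphic_overlap(no_mono, "pop1", "pop1"),
               "no monomorphic loci")
})
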