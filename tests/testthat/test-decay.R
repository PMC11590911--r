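scan_panel <- function(seed = 9, n_loci = 120, n_chrom = 2, n = 40,
                       len = 4e6) {
  sim <- simulate_panel(sim_config(
    n_populations = 1, n_samples_per_pop = n, n_loci = n_loci,
    n_chromosomes = n_chrom, chrom_length_bp = len, low_maf_frac = 0,
    maf_range = c(0.15, 0.5), missing_rate = 0.02, seed = seed
  ))
  sim$panel
}

test_that("the syntenic scan gates pairs by distance", {
  set.seed(2)
  d <- matrix(sample(0:1, 60, replace = TRUE) + sample(0:1, 60, replace = TRUE),
              20, 3)
  storage.mode(d) <- "integer"
  panel <- make_panel(d, pos = c(1e3, 40e3, 2e6))
  est <- pairwise_syntenic_ld(panel, max_distance_bp = 1e6)
  expect_equal(nrow(est) + sum(attr(est, "skipped")), 1)  # only 1kb-40kb pair
  expect_equal(attr(est, "n_enumerated"), 1)

  # L loci all within the ceiling -> L(L-1)/2 pairs enumerated
  panel2 <- scan_panel(seed = 4, n_loci = 30, n_chrom = 1, len = 9e5)
  est2 <- pairwise_syntenic_ld(panel2, max_distance_bp = 1e6)
  expect_equal(attr(est2, "n_enumerated"), 30 * 29 / 2)
})

test_that("pair enumeration matches a brute-force double loop", {
  panel <- scan_panel(seed = 14)
  est <- pairwise_syntenic_ld(panel, max_distance_bp = 5e5)
  v <- panel_variants(panel)
  brute <- 0L
  for (i in seq_len(nrow(v) - 1)) for (j in (i + 1):nrow(v)) {
    if (v$chrom[i] == v$chrom[j] &&
        abs(v$pos[j] - v$pos[i]) <= 5e5 && v$pos[i] != v$pos[j])
      brute <- brute + 1L
  }
  expect_equal(attr(est, "n_enumerated"), brute)
  expect_equal(nrow(est) + sum(attr(est, "skipped")),
               attr(est, "n_enumerated"))
})

test_that("distance-class binning follows the (lo, hi] convention", {
  est <- tibble::tibble(
    chrom = "1", vid_i = "a", vid_j = "b",
    distance_bp = c(1, 50000, 50001, 100000, 500000, 1000000),
    n_alleles = 24L, D = 0.1, Dprime = 0.5,
    r2 = c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05),
    r2_corrected = c(0.5, 0.4, 0.3, 0.2, 0.1, 0.05), converged = TRUE
  )
  b <- bin_by_distance(est, statistic = "r2")
  expect_equal(b$n_pairs, c(2L, 2L, 1L, 1L))
  # a pair at exactly 50 kb is in the first class
  expect_equal(b$mean[1], mean(c(0.5, 0.4)))
  expect_equal(b$mean[4], 0.05)

  # all pairs in one bin -> plain arithmetic mean
  one <- bin_by_distance(est[1:2, ], distance_bins(c(1, 50000)),
                         statistic = "r2")
  expect_equal(one$mean, 0.45)
  expect_equal(one$sd, sqrt(mean((c(0.5, 0.4) - 0.45)^2)))

  # empty bin reported with zero pairs and NA moments
  empty <- bin_by_distance(est[0, ], statistic = "r2")
  expect_equal(empty$n_pairs, rep(0L, 4))
  expect_true(all(is.na(empty$mean)))
})

test_that("binned means and SDs equal an independent tabulation", {
  panel <- scan_panel(seed = 25)
  est <- pairwise_syntenic_ld(panel)
  b <- bin_by_distance(est, statistic = "r2")
  for (k in seq_len(nrow(b))) {
    inb <- if (k == 1) est$distance_bp >= b$lo[k] & est$distance_bp <= b$hi[k]
           else est$distance_bp > b$lo[k] & est$distance_bp <= b$hi[k]
    x <- est$r2[inb]
    if (!length(x)) next
    expect_equal(b$mean[k], sum(x) / length(x), tolerance = 1e-12)
    expect_equal(b$sd[k], sqrt(sum((x - mean(x))^2) / length(x)),
                 tolerance = 1e-12)
  }
  # conservation: bins + out-of-range + skipped = enumerated
  expect_equal(sum(b$n_pairs) + sum(est$distance_bp > max(b$hi)) +
                 sum(attr(est, "skipped")),
               attr(est, "n_enumerated"))
})

test_that("point-distance windows equal a brute-force filter", {
  panel <- scan_panel(seed = 33, n_loci = 150, n_chrom = 1, len = 2e6)
  est <- pairwise_syntenic_ld(panel)
  pt <- point_distance_summary(est, centers = c(1e3, 1e4, 1e5),
                               statistic = "r2")
  for (k in seq_len(nrow(pt))) {
    w <- est$r2[est$distance_bp >= pt$lo[k] & est$distance_bp <= pt$hi[k]]
    if (pt$n_pairs[k] == 0) expect_true(is.na(pt$mean[k]))
    else expect_equal(pt$mean[k], mean(w), tolerance = 1e-12)
    expect_equal(pt$n_pairs[k], length(w))
  }
  # the 1 kb window floors at the 1 bp minimum distance
  expect_equal(pt$lo[1], 900)
  expect_equal(point_distance_summary(est, centers = 1,
                                      statistic = "r2")$lo, 1)
  # a single pair at exactly the centre reports its own value
  single <- est[which.min(abs(est$distance_bp - 1e4))[1], ]
  pt1 <- point_distance_summary(single, centers = single$distance_bp,
                                statistic = "r2")
  expect_equal(pt1$mean, single$r2)
  expect_equal(pt1$n_pairs, 1L)
})

test_that("per-chromosome summary equals grouped tabulation", {
  est <- tibble::tibble(
    chrom = rep(c("1", "2"), c(3, 2)), vid_i = "a", vid_j = "b",
    distance_bp = 1000, n_alleles = 24L, D = 0, Dprime = 0,
    r2 = c(0.2, 0.2, 0.2, 0.7, 0.7),
    r2_corrected = c(0.2, 0.2, 0.2, 0.7, 0.7), converged = TRUE
  )
  s <- per_chromosome_summary(est, statistic = "r2")
  expect_equal(s$mean[s$chrom == "1"], 0.2)
  expect_equal(s$mean[s$chrom == "2"], 0.7)
  expect_equal(s$n_pairs, c(3L, 2L))

  panel <- scan_panel(seed = 41)
  est2 <- pairwise_syntenic_ld(panel)
  s2 <- per_chromosome_summary(est2, statistic = "r2")
  for (ch in s2$chrom) {
    x <- est2$r2[est2$chrom == ch]
    expect_equal(s2$mean[s2$chrom == ch], mean(x), tolerance = 1e-12)
    expect_equal(s2$n_pairs[s2$chrom == ch], length(x))
  }
  # single-chromosome input reproduces the global mean
  one <- per_chromosome_summary(dplyr::filter(est2, chrom == est2$chrom[1]),
                                statistic = "r2")
  expect_equal(one$mean, mean(est2$r2[est2$chrom == est2$chrom[1]]))
})

test_that("adjacent-marker summary equals the rank-adjacent filtered scan", {
  panel <- scan_panel(seed = 52, n_loci = 60, n_chrom = 2, len = 3e6)
  adj <- adjacent_snp_summary(panel)
  est <- pairwise_syntenic_ld(panel, max_distance_bp = Inf)
  v <- panel_variants(panel)
  for (ch in unique(v$chrom)) {
    ids <- v$vid[v$chrom == ch]
    pairs <- tibble::tibble(vid_i = ids[-length(ids)], vid_j = ids[-1])
    sub <- dplyr::inner_join(est, pairs, by = c("vid_i", "vid_j"))
    got <- adj$mean[adj$chrom == ch]
    if (nrow(sub)) expect_equal(got, mean(sub$r2), tolerance = 1e-12)
  }

  # two loci on one chromosome: the single pair's r2
  d <- cbind(c(0L, 1L, 2L, 1L, 0L, 2L), c(0L, 1L, 2L, 2L, 0L, 1L))
  p2 <- make_panel(d)
  adj2 <- adjacent_snp_summary(p2)
  expect_equal(adj2$mean, ld_pair(p2, 1, 2)$r2)

  # an all-monomorphic chromosome yields no mean and a skip count
  d3 <- cbind(d, matrix(0L, 6, 2))
  p3 <- make_panel(d3, chrom = c("1", "1", "2", "2"))
  adj3 <- adjacent_snp_summary(p3)
  expect_true(is.na(adj3$mean[adj3$chrom == "2"]))
  expect_equal(adj3$n_skipped[adj3$chrom == "2"], 1L)
})

test_that("decay curve agrees with equivalent explicit bins", {
  panel <- scan_panel(seed = 61)
  est <- pairwise_syntenic_ld(panel)
  dc <- decay_curve(est, n_log_bins = 6, statistic = "r2")
  expect_equal(sum(dc$n_pairs), nrow(est))
  eq <- bin_by_distance(
    est,
    structure(tibble::tibble(bin = as.character(1:6), lo = dc$lo, hi = dc$hi),
              class = c("distance_bins", "tbl_df", "tbl", "data.frame")),
    statistic = "r2"
  )
  expect_equal(dc$mean, eq$mean)

  one <- decay_curve(est, n_log_bins = 1, statistic = "r2")
  expect_equal(one$mean, mean(est$r2))

  expect_equal(nrow(decay_curve(est[0, ], 4)), 0)
})

test_that("autoplot methods return ggplot objects", {
  panel <- scan_panel(seed = 71, n_loci = 60)
  est <- pairwise_syntenic_ld(panel)
  expect_s3_class(autoplot(decay_curve(est, 5)), "ggplot")
  expect_s3_class(autoplot(bin_by_distance(est)), "ggplot")
  expect_s3_class(autoplot(per_chromosome_summary(est)), "ggplot")
  expect_s3_class(autoplot(maf_histogram(panel)), "ggplot")
})
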