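#' Configuration for the synthetic genotype-panel generator
#'
#' Defaults emulate a multi-breed SNP-chip study at desk scale: five
#' populations of twelve diploids each, a few thousand autosomal markers with
#' base-pair positions, an allele-frequency spectrum enriched for rare
#' alleles, LD that decays with physical distance on a ~100 kb length scale,
#' and light random missingness. Planted features (Hardy-Weinberg violations,
#' sub-threshold MAF loci, low-call-rate loci, non-autosomal loci, designed
#' within-population monomorphic sets) are disjoint and recorded in the truth
#' record, so QC bookkeeping can be checked exactly.
#'
#' @param n_populations number of populations.
#' @param n_samples_per_pop diploid individuals per population.
#' @param n_loci total marker count (including planted non-autosomal loci).
#' @param n_chromosomes autosomes to spread the markers over (labels "1",
#'   "2", ...).
#' @param chrom_length_bp length of each chromosome in bp.
#' @param decay_lambda_bp length scale of the latent-correlation decay
#'   `exp(-d / lambda)`.
#' @param maf_range range of the common-allele frequency component.
#' @param low_maf_frac fraction of loci drawn from the rare component.
#' @param low_maf_range frequency range of the rare component.
#' @param missing_rate per-call missing probability at unplanted loci.
#' @param n_hwe_violations loci overwritten with an extreme heterozygote
#'   excess (every individual heterozygous). The exact-test p-value of an
#'   all-heterozygote locus falls with sample size: about 1.9e-3 at 12
#'   individuals, 1.8e-10 at 36 and 4.9e-14 at 48, so panels of at least 36
#'   individuals are needed for the planted loci to breach a 1e-7 screen.
#' @param n_maf_violations loci overwritten so the pooled minor allele count
#'   is 1 (needs at least 11 individuals for MAF < 0.05).
#' @param n_lowcall_violations loci with just over 10% of calls forced
#'   missing.
#' @param n_nonautosomal loci assigned to chromosome "X".
#' @param monomorphic_plan list of `list(pops = <labels>, n = <count>)`
#'   entries; each entry plants `n` loci fixed (dosage 0) in every population
#'   in `pops` while guaranteed polymorphic in the remaining populations.
#' @param duplicate_error_rate default per-call error rate used by
#'   [simulate_duplicates()].
#' @param seed integer seed fixing the whole output stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 5, n_samples_per_pop = 12,
                       n_loci = 2000, n_chromosomes = 5,
                       chrom_length_bp = 2e7, decay_lambda_bp = 1e5,
                       maf_range = c(0.05, 0.5), low_maf_frac = 0.2,
                       low_maf_range = c(0.01, 0.05), missing_rate = 0.01,
                       n_hwe_violations = 0, n_maf_violations = 0,
                       n_lowcall_violations = 0, n_nonautosomal = 0,
                       monomorphic_plan = list(),
                       duplicate_error_rate = 0.02, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    n_populations >= 1, n_samples_per_pop >= 1, n_loci >= 1,
    n_chromosomes >= 1, chrom_length_bp > n_loci,
    decay_lambda_bp >= 0, missing_rate >= 0, missing_rate <= 1,
    low_maf_frac >= 0, low_maf_frac <= 1,
    duplicate_error_rate >= 0, duplicate_error_rate <= 1
  )
  n_mono <- sum(vapply(monomorphic_plan, function(e) e$n, numeric(1)))
  n_special <- n_hwe_violations + n_maf_violations + n_lowcall_violations +
    n_nonautosomal + n_mono
  if (n_special > n_loci)
    stop("infeasible config: planted loci exceed n_loci")
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-population genotype panel with distance-decaying LD
#'
#' Haplotypes are generated from a latent stationary first-order
#' autoregressive Gaussian process along each chromosome with inter-locus
#' correlation `exp(-d / decay_lambda_bp)`, thresholded at each locus's
#' target allele-frequency quantile (a Gaussian copula). Diploids are formed
#' by random union of two independent haplotypes, so Hardy-Weinberg
#' equilibrium holds everywhere except at planted violations. Missingness is
#' applied independently per call; planted loci are then overwritten as
#' described in [sim_config()]. Output is deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return A list with elements `panel` (a [genotype_panel()]) and `truth`,
#'   a list carrying `target_freq` (tibble `vid`, `freq`), `planted` (tibble
#'   `vid`, `label` in hwe/maf/callrate/nonautosomal/monomorphic/none),
#'   `monomorphic_sets` (named list population -> planted vids) and the
#'   config echo.
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n_pop <- config$n_populations
  n_per <- config$n_samples_per_pop
  n_ind <- n_pop * n_per
  pops <- sprintf("pop%d", seq_len(n_pop))
  samples <- tibble::tibble(
    sample_id = sprintf("%s_s%02d", rep(pops, each = n_per),
                        rep(seq_len(n_per), n_pop)),
    population = rep(pops, each = n_per)
  )

  n_auto <- config$n_loci - config$n_nonautosomal
  per_chr <- diff(round(seq(0, n_auto, length.out = config$n_chromosomes + 1)))
  variants <- purrr::map_dfr(seq_len(config$n_chromosomes), function(ch) {
    k <- per_chr[ch]
    if (k == 0) return(NULL)
    tibble::tibble(
      chrom = as.character(ch),
      pos = sort(sample.int(config$chrom_length_bp, k))
    )
  })
  if (config$n_nonautosomal > 0)
    variants <- dplyr::bind_rows(variants, tibble::tibble(
      chrom = "X",
      pos = sort(sample.int(config$chrom_length_bp, config$n_nonautosomal))
    ))
  m <- nrow(variants)
  variants$vid <- sprintf("snp_%s_%07d", variants$chrom, variants$pos)
  variants$allele_a <- "A"
  variants$allele_b <- "B"

  freq <- ifelse(
    stats::runif(m) < config$low_maf_frac,
    stats::runif(m, config$low_maf_range[1], config$low_maf_range[2]),
    stats::runif(m, config$maf_range[1], config$maf_range[2])
  )
  flip <- stats::runif(m) < 0.5  # counted allele is minor or major at random
  freq <- ifelse(flip, 1 - freq, freq)

  # latent AR(1) haplotypes, one chromosome at a time
  n_hap <- 2L * n_ind
  dos <- matrix(0L, n_ind, m)
  thr <- stats::qnorm(freq)
  for (ch in unique(variants$chrom)) {
    idx <- which(variants$chrom == ch)
    z <- matrix(0, n_hap, length(idx))
    z[, 1] <- stats::rnorm(n_hap)
    if (length(idx) > 1) {
      rho <- exp(-diff(variants$pos[idx]) / config$decay_lambda_bp)
      if (config$decay_lambda_bp == 0) rho[] <- 0
      for (k in 2:length(idx))
        z[, k] <- rho[k - 1] * z[, k - 1] +
          sqrt(1 - rho[k - 1]^2) * stats::rnorm(n_hap)
    }
    hap <- z < matrix(thr[idx], n_hap, length(idx), byrow = TRUE)
    dos[, idx] <- hap[seq_len(n_ind) * 2L - 1L, , drop = FALSE] +
      hap[seq_len(n_ind) * 2L, , drop = FALSE]
  }
  storage.mode(dos) <- "integer"

  # missingness on unplanted calls
  miss <- matrix(stats::runif(n_ind * m) < config$missing_rate, n_ind, m)

  # disjoint planted loci, all autosomal except the non-autosomal block
  planted <- rep("none", m)
  planted[variants$chrom == "X"] <- "nonautosomal"
  pool <- which(planted == "none")
  take <- function(n) {
    if (n == 0) return(integer(0))
    if (n > length(pool)) stop("infeasible config: planted loci exceed pool")
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  pool <- sample(pool)
  hwe_idx <- take(config$n_hwe_violations)
  maf_idx <- take(config$n_maf_violations)
  low_idx <- take(config$n_lowcall_violations)
  planted[hwe_idx] <- "hwe"
  planted[maf_idx] <- "maf"
  planted[low_idx] <- "callrate"

  dos[, hwe_idx] <- 1L                     # total heterozygote excess
  if (length(maf_idx)) {
    dos[, maf_idx] <- 0L
    dos[1L, maf_idx] <- 1L                 # pooled minor allele count of 1
  }
  miss[, c(hwe_idx, maf_idx)] <- FALSE
  if (length(low_idx)) {
    miss[, low_idx] <- FALSE
    n_miss <- floor(0.1 * n_ind) + 1L      # strictly below 90% call rate
    for (j in low_idx) miss[sample.int(n_ind, n_miss), j] <- TRUE
  }

  mono_sets <- stats::setNames(vector("list", n_pop), pops)
  for (entry in config$monomorphic_plan) {
    idx <- take(entry$n)
    planted[idx] <- "monomorphic"
    miss[, idx] <- FALSE
    in_pops <- match(entry$pops, pops)
    if (anyNA(in_pops)) stop("monomorphic_plan names unknown population")
    for (p in seq_len(n_pop)) {
      rows <- which(samples$population == pops[p])
      if (p %in% in_pops) {
        dos[rows, idx] <- 0L
        mono_sets[[p]] <- c(mono_sets[[p]], idx)
      } else {
        for (j in idx) if (all(dos[rows, j] == dos[rows[1], j]))
          dos[rows[1], j] <- if (dos[rows[1], j] == 1L) 2L else 1L
      }
    }
  }

  dos[miss] <- NA_integer_
  panel <- genotype_panel(dos, samples, variants)
  truth <- list(
    target_freq = tibble::tibble(vid = variants$vid, freq = freq),
    planted = tibble::tibble(vid = variants$vid, label = planted),
    monomorphic_sets = purrr::map(mono_sets, ~ variants$vid[.x]),
    config = config
  )
  list(panel = panel, truth = truth)
}

#' Duplicate samples with a known genotyping error rate
#'
#' Copies the chosen samples and perturbs each non-missing call to one of the
#' other two dosage classes (chosen uniformly) with probability
#' `error_rate`; the duplicates model re-genotyped individuals for
#' concordance scoring.
#'
#' @param panel a [genotype_panel()].
#' @param sample_ids samples to duplicate.
#' @param error_rate per-call perturbation probability.
#' @param seed integer seed.
#' @return A `genotype_panel` of the duplicated samples (ids suffixed
#'   `"_dup"`), same variants as `panel`.
#' @export
simulate_duplicates <- function(panel, sample_ids,
                                error_rate = 0.02, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  if (!is.null(seed)) set.seed(seed)
  sub <- subset_panel(panel, samples = sample_ids)
  d <- sub$dosages
  hit <- !is.na(d) & matrix(stats::runif(length(d)) < error_rate,
                            nrow(d), ncol(d))
  shift <- matrix(sample(1:2, length(d), replace = TRUE), nrow(d), ncol(d))
  d[hit] <- (d[hit] + shift[hit]) %% 3L
  s <- sub$samples
  s$sample_id <- paste0(s$sample_id, "_dup")
  genotype_panel(d, s, sub$variants)
}

#' Two-locus Wright-Fisher simulation of sample r-squared
#'
#' Evolves the four gamete frequencies of a two-locus biallelic system in a
#' population of `Ne` diploids by multinomial resampling of `2 Ne` gametes
#' per generation, applying recombination at fraction `c` to the expected
#' gamete frequencies before each draw. Replicates start at linkage
#' equilibrium with both allele frequencies 0.5; replicates in which either
#' locus fixes before the end are dropped and regenerated. At the end of each
#' replicate, `2 * n_sample` gametes are drawn from the final frequencies,
#' paired into diploids, and the raw sample r-squared is estimated by EM
#' exactly as in the analysis pipeline. At drift-recombination equilibrium
#' the expected value follows Sved's approximation
#' `E[r2] ~ 1 / (1 + 4 Ne c)` plus the `1/n` sampling inflation.
#'
#' @param Ne effective population size (diploids, >= 2).
#' @param c recombination fraction in `[0, 0.5]`.
#' @param n_generations generations to evolve (4 Ne is ample for
#'   equilibrium).
#' @param n_sample diploids genotyped per replicate.
#' @param n_replicates retained replicates.
#' @param seed integer seed.
#' @return Numeric vector of `n_replicates` raw sample r-squared values,
#'   with attribute `n_regenerated` counting discarded fixed replicates.
#' @export
simulate_two_locus_wf <- function(Ne, c, n_generations, n_sample,
                                  n_replicates, seed = 1L) {
  stopifnot(Ne >= 2, c >= 0, c <= 0.5, n_sample >= 2, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  res <- wf_r2_cpp(as.integer(Ne), as.numeric(c), as.integer(n_generations),
                   as.integer(n_sample), as.integer(n_replicates),
                   1e-10, 1000L)
  out <- res$r2
  attr(out, "n_regenerated") <- res$n_regenerated
  out
}
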