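#' Minor allele frequency of a dosage vector
#'
#' @param dosage_column integer vector of allele-B dosages (0/1/2, `NA`
#'   missing).
#' @return `min(f, 1 - f)` where `f` is the sample frequency of allele B over
#'   non-missing calls; always in `[0, 0.5]`.
#' @export
maf <- function(dosage_column) {
  x <- dosage_column[!is.na(dosage_column)]
  if (!length(x)) stop("MAF undefined: all genotypes missing")
  f <- sum(x) / (2 * length(x))
  min(f, 1 - f)
}

#' Call rate of a dosage vector
#'
#' @inheritParams maf
#' @return Fraction of samples with a non-missing genotype.
#' @export
call_rate <- function(dosage_column) {
  if (!length(dosage_column)) stop("call rate undefined: no samples")
  mean(!is.na(dosage_column))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: given the observed allele counts, the probability
#' of each attainable heterozygote count is computed under the null of
#' random union of gametes, and the two-sided p-value is the total mass of
#' configurations whose probability does not exceed that of the observed
#' count (no mid-p adjustment). Probabilities are accumulated by the stable
#' ratio recurrence between adjacent heterozygote counts; a relative slack of
#' 1e-12 guards the inclusion comparison against round-off at exact ties.
#'
#' @param n_AA,n_Aa,n_aa nonnegative genotype counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("HWE test undefined: no genotypes")
  n_A <- 2 * n_AA + n_Aa
  n_a <- 2 * n_aa + n_Aa
  rare <- min(n_A, n_a)
  if (rare == 0) return(1)  # monomorphic: single attainable configuration

  # attainable het counts share the parity of the rare-allele count
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hets))
  mid <- which.min(abs(hets - rare * n_a / (2 * n)))  # start near the mode
  probs[mid] <- 1
  # P(h+2)/P(h) = [ (rare-h)(2n-rare-h) ] / [ (h+2)(h+1) ] ... derived from
  # the conditional likelihood n! 2^h / (nAA! h! naa!) with fixed margins
  if (mid < length(hets)) {
    for (k in mid:(length(hets) - 1L)) {
      h <- hets[k]
      probs[k + 1L] <- probs[k] *
        ((rare - h) * (2 * n - rare - h)) / ((h + 2) * (h + 1))
    }
  }
  if (mid > 1L) {
    for (k in mid:2L) {
      h <- hets[k]
      probs[k - 1L] <- probs[k] *
        (h * (h - 1)) / ((rare - h + 2) * (2 * n - rare - h + 2))
    }
  }
  probs <- probs / sum(probs)
  p_obs <- probs[match(n_Aa, hets)]
  if (is.na(p_obs)) stop("observed heterozygote count incompatible with margins")
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

#' QC threshold set
#'
#' Defaults implement the standard locus-level cascade for dense bovine SNP
#' panels: drop loci off the 29 autosomes, then loci failing an exact
#' Hardy-Weinberg test at p < 1e-7, then loci with call rate below 90% or
#' minor allele frequency below 0.05. All inequalities are strict, so
#' boundary values are retained.
#'
#' @param hwe_p_min exclusion threshold on the HWE exact p-value.
#' @param maf_min exclusion threshold on pooled MAF.
#' @param call_rate_min exclusion threshold on call rate.
#' @param autosomes chromosome labels to keep.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(hwe_p_min = 1e-7, maf_min = 0.05,
                          call_rate_min = 0.90,
                          autosomes = as.character(1:29)) {
  stopifnot(
    hwe_p_min >= 0, hwe_p_min <= 1, maf_min >= 0, maf_min <= 1,
    call_rate_min >= 0, call_rate_min <= 1
  )
  structure(
    list(hwe_p_min = hwe_p_min, maf_min = maf_min,
         call_rate_min = call_rate_min, autosomes = as.character(autosomes)),
    class = "qc_thresholds"
  )
}

#' Apply the locus QC cascade to a pooled panel
#'
#' Stages are applied in order: (1) non-autosomal loci removed; (2) loci
#' failing the Hardy-Weinberg exact test on pooled genotype counts removed;
#' (3) loci with low call rate or low pooled MAF removed (one merged stage).
#' Each locus is charged to exactly the first stage that removes it, so the
#' stage counts partition the input. All statistics are computed on the panel
#' pooled across populations; pooling induces a Wahlund heterozygote deficit
#' in structured data, which biases the HWE stage toward removing strongly
#' differentiated loci -- retained here as the conventional across-breed
#' protocol, with the caveat documented.
#'
#' @param panel a [genotype_panel()].
#' @param thresholds a [qc_thresholds()] object.
#' @return A list with elements `panel` (retained loci, order preserved) and
#'   `report` (class `qc_report`).
#' @export
apply_qc <- function(panel, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  v <- panel$variants
  d <- panel$dosages
  m <- n_loci(panel)
  stage <- rep(NA_character_, m)

  stage[!(v$chrom %in% thresholds$autosomes)] <- "nonautosomal"

  for (j in which(is.na(stage))) {
    x <- d[, j]
    x <- x[!is.na(x)]
    if (!length(x)) next  # all-missing: caught by call-rate stage
    p <- hwe_exact_p(sum(x == 2L), sum(x == 1L), sum(x == 0L))
    if (p < thresholds$hwe_p_min) stage[j] <- "hwe"
  }

  for (j in which(is.na(stage))) {
    x <- d[, j]
    cr <- call_rate(x)
    low_maf <- if (all(is.na(x))) thresholds$maf_min > 0 else
      maf(x) < thresholds$maf_min
    if (cr < thresholds$call_rate_min || low_maf) stage[j] <- "callrate_or_maf"
  }

  keep <- is.na(stage)
  report <- structure(
    list(
      n_input = m,
      n_removed_nonautosomal = sum(stage == "nonautosomal", na.rm = TRUE),
      n_removed_hwe = sum(stage == "hwe", na.rm = TRUE),
      n_removed_callrate_or_maf = sum(stage == "callrate_or_maf", na.rm = TRUE),
      n_retained = sum(keep),
      removed = tibble::tibble(vid = v$vid[!keep], stage = stage[!keep])
    ),
    class = "qc_report"
  )
  if (!any(keep)) warning("no loci retained by QC; returning empty panel")
  list(panel = subset_panel(panel, loci = keep), report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>\n")
  print(tidy(x))
  invisible(x)
}

#' Tidy and summarise a QC report
#'
#' `tidy()` returns one row per cascade stage with the loci removed;
#' `glance()` a one-row overview.
#'
#' @param x a `qc_report` from [apply_qc()].
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.qc_report <- function(x, ...) {
  tibble::tibble(
    stage = c("nonautosomal", "hwe", "callrate_or_maf", "retained"),
    n_loci = c(x$n_removed_nonautosomal, x$n_removed_hwe,
               x$n_removed_callrate_or_maf, x$n_retained)
  )
}

#' @rdname tidy.qc_report
#' @export
glance.qc_report <- function(x, ...) {
  tibble::tibble(
    n_input = x$n_input,
    n_removed_nonautosomal = x$n_removed_nonautosomal,
    n_removed_hwe = x$n_removed_hwe,
    n_removed_callrate_or_maf = x$n_removed_callrate_or_maf,
    n_retained = x$n_retained
  )
}

#' Per-population minor allele frequency table
#'
#' MAF is recomputed within each population; loci with no non-missing call in
#' a population are dropped for that population.
#'
#' @param panel a [genotype_panel()].
#' @param populations labels to include; `NULL` means all.
#' @return Tibble with columns `population`, `vid`, `chrom`, `maf`.
#' @export
maf_table <- function(panel, populations = NULL) {
  pops <- populations %||% unique(panel$samples$population)
  unknown <- setdiff(pops, panel$samples$population)
  if (length(unknown)) stop("unknown population label: ",
                            paste(unknown, collapse = ", "))
  purrr::map_dfr(pops, function(p) {
    sub <- panel_population(panel, p)
    d <- sub$dosages
    nonmiss <- colSums(!is.na(d))
    f <- colSums(d, na.rm = TRUE) / (2 * nonmiss)
    tibble::tibble(
      population = p,
      vid = sub$variants$vid,
      chrom = sub$variants$chrom,
      maf = pmin(f, 1 - f)
    ) |>
      dplyr::filter(nonmiss > 0)
  })
}

#' Binned MAF spectrum per population
#'
#' Bins are half-open `[lo, hi)` with the final bin closed at 0.5, so a locus
#' at exactly the upper edge lands in the last bin. Counts over each
#' population sum to the loci assessed there (loci with at least one
#' non-missing call).
#'
#' @param panel a [genotype_panel()].
#' @param population one population label, or `NULL` for every population.
#' @param bin_edges ascending numeric edges covering `[0, 0.5]`.
#' @return Tibble of class `maf_histogram` with columns `population`,
#'   `bin`, `lo`, `hi`, `n_loci`.
#' @export
maf_histogram <- function(panel, population = NULL,
                          bin_edges = seq(0, 0.5, by = 0.1)) {
  stopifnot(!is.unsorted(bin_edges, strictly = TRUE), length(bin_edges) >= 2)
  tab <- maf_table(panel, populations = population)
  nb <- length(bin_edges) - 1L
  out <- tab |>
    dplyr::mutate(
      bin_idx = pmin(findInterval(.data$maf, bin_edges,
                                  rightmost.closed = TRUE), nb)
    ) |>
    dplyr::count(.data$population, .data$bin_idx, name = "n_loci") |>
    tidyr::complete(
      population = unique(tab$population),
      bin_idx = seq_len(nb),
      fill = list(n_loci = 0L)
    ) |>
    dplyr::mutate(
      lo = bin_edges[.data$bin_idx],
      hi = bin_edges[.data$bin_idx + 1L],
      bin = sprintf("[%g,%g%s", .data$lo, .data$hi,
                    ifelse(.data$bin_idx == nb, "]", ")"))
    ) |>
    dplyr::select("population", "bin", "lo", "hi", "n_loci") |>
    dplyr::arrange(.data$population, .data$lo)
  class(out) <- c("maf_histogram", class(out))
  out
}

#' Within-population monomorphic loci
#'
#' @param panel a [genotype_panel()].
#' @param population population label.
#' @return Character vector of variant ids with within-population MAF equal
#'   to 0 (loci with no non-missing call in the population are excluded).
#' @export
monomorphic_loci <- function(panel, population) {
  tab <- maf_table(panel, populations = population)
  tab$vid[tab$maf == 0]
}

#' Cross-population monomorphic-marker overlap
#'
#' Fraction of the reference population's monomorphic loci that are also
#' monomorphic in every population of `pops_other`. Intended to be run on the
#' QC-retained panel, where pooled filtering leaves some loci fixed within
#' individual populations; a high overlap indicates shared fixation and hence
#' relatedness of the populations.
#'
#' @param panel a [genotype_panel()] (typically after [apply_qc()]).
#' @param pop_ref reference population label.
#' @param pops_other character vector of comparison population labels.
#' @return Fraction in `[0, 1]`.
#' @export
monomorphic_overlap <- function(panel, pop_ref, pops_other) {
  m_ref <- monomorphic_loci(panel, pop_ref)
  if (!length(m_ref))
    stop("monomorphic overlap undefined: no monomorphic loci in ", pop_ref)
  m_other <- purrr::map(pops_other, ~ monomorphic_loci(panel, .x))
  shared <- Reduce(intersect, m_other, m_ref)
  length(shared) / length(m_ref)
}
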