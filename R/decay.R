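#' Default physical-distance classes for LD decay
#'
#' The four classes conventionally reported for dense bovine panels:
#' 1-50 kb, 50-100 kb, 100-500 kb and 0.5-1 Mb. Intervals are `(lo, hi]`
#' half-open with the first bin closed at 1 bp, so a pair at exactly 50 kb
#' falls in the first class and no pair is double-counted.
#'
#' @param edges_bp ascending numeric vector of interval edges in bp; bin k
#'   is `(edges[k], edges[k+1]]` with the first bin including its lower edge.
#' @return A tibble of class `distance_bins` with columns `bin`, `lo`, `hi`.
#' @export
distance_bins <- function(edges_bp = c(1, 50e3, 100e3, 500e3, 1e6)) {
  stopifnot(length(edges_bp) >= 2, !is.unsorted(edges_bp, strictly = TRUE))
  lo <- edges_bp[-length(edges_bp)]
  hi <- edges_bp[-1]
  out <- tibble::tibble(
    bin = sprintf("%s-%s", format_bp(lo), format_bp(hi)),
    lo = lo, hi = hi
  )
  class(out) <- c("distance_bins", class(out))
  out
}

format_bp <- function(x) {
  dplyr::case_when(
    x >= 1e6 & x %% 1e5 == 0 ~ sprintf("%gMb", x / 1e6),
    x >= 1e3 & x %% 100 == 0 ~ sprintf("%gkb", x / 1e3),
    TRUE ~ sprintf("%gbp", x)
  )
}

#' All syntenic pairwise LD estimates within a distance ceiling
#'
#' Enumerates every within-chromosome marker pair whose separation is between
#' 1 bp and `max_distance_bp`, estimates haplotype frequencies by EM for each
#' pair using the named population's samples only, and returns one row per
#' successfully estimated pair. Pairs skipped because a locus is monomorphic
#' in the pairwise-complete subset, or because fewer than two individuals are
#' scored at both loci, are tallied by reason in the `skipped` attribute so
#' that `n_pairs + skipped` always equals the pairs enumerated.
#'
#' @param panel a QC-retained [genotype_panel()] (loci are sorted internally
#'   by chromosome and position).
#' @param population population label; `NULL` pools all samples.
#' @param max_distance_bp pair-distance ceiling in bp.
#' @param use_panel_n see [ld_pair()].
#' @return Tibble of class `ld_scan` with the [ld_pair()] columns; attributes
#'   `skipped` (named integer: monomorphic, insufficient) and `n_enumerated`.
#' @export
pairwise_syntenic_ld <- function(panel, population = NULL,
                                 max_distance_bp = 1e6,
                                 use_panel_n = FALSE) {
  sub <- if (is.null(population)) panel else panel_population(panel, population)
  ord <- order(sub$variants$chrom, sub$variants$pos)
  sub <- subset_panel(sub, loci = ord)
  v <- sub$variants
  d <- sub$dosages

  res <- ld_scan_cpp(d, as.character(v$chrom), as.integer(v$pos),
                     as.numeric(max_distance_bp), 1e-10, 1000L)
  ok <- res$status == 0L
  n_pair <- if (use_panel_n) rep(2L * n_samples(sub), sum(ok)) else
    res$n_alleles[ok]
  out <- tibble::tibble(
    chrom = v$chrom[res$i[ok]],
    vid_i = v$vid[res$i[ok]],
    vid_j = v$vid[res$j[ok]],
    distance_bp = v$pos[res$j[ok]] - v$pos[res$i[ok]],
    n_alleles = as.integer(n_pair),
    D = res$D[ok],
    Dprime = res$Dprime[ok],
    r2 = res$r2[ok],
    r2_corrected = correct_r2(res$r2[ok], n_pair),
    converged = res$converged[ok]
  )
  class(out) <- c("ld_scan", class(out))
  attr(out, "skipped") <- c(
    monomorphic = sum(res$status == 1L),
    insufficient = sum(res$status == 2L)
  )
  attr(out, "n_enumerated") <- length(res$status)
  attr(out, "population") <- population %||% "(pooled)"
  out
}

stat_column <- function(estimates, statistic) {
  statistic <- match.arg(statistic, c("r2_corrected", "r2", "D", "Dprime"))
  estimates[[statistic]]
}

#' Distance-class summary of pairwise LD
#'
#' Mean and population standard deviation (divisor n) of the chosen statistic
#' within each physical-distance class; pairs outside every class are
#' ignored. Empty classes are reported with `n_pairs = 0` and `NA` moments.
#'
#' @param estimates an `ld_scan` tibble from [pairwise_syntenic_ld()].
#' @param bins a [distance_bins()] tibble.
#' @param statistic one of `"r2_corrected"`, `"r2"`, `"D"`, `"Dprime"`.
#' @return Tibble of class `ld_bin_summary`: `bin`, `lo`, `hi`, `mean`, `sd`,
#'   `n_pairs`.
#' @export
bin_by_distance <- function(estimates, bins = distance_bins(),
                            statistic = "r2_corrected") {
  x <- stat_column(estimates, statistic)
  dist <- estimates$distance_bp
  out <- purrr::pmap_dfr(bins, function(bin, lo, hi) {
    inb <- if (lo == min(bins$lo)) dist >= lo & dist <= hi
           else dist > lo & dist <= hi
    xi <- x[inb]
    tibble::tibble(
      bin = bin, lo = lo, hi = hi,
      mean = if (length(xi)) mean(xi) else NA_real_,
      sd = if (length(xi)) sd_pop(xi) else NA_real_,
      n_pairs = length(xi)
    )
  })
  attr(out, "statistic") <- statistic
  class(out) <- c("ld_bin_summary", class(out))
  out
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Mean LD at nominal point distances
#'
#' Summarises the statistic over pairs whose separation lies within a
#' relative window around each nominal distance, `[c(1-tol), c(1+tol)]`,
#' floored at the 1 bp minimum pair distance. The window width is a
#' reporting convention, not an estimate; the default of +/-10% is tunable.
#'
#' @inheritParams bin_by_distance
#' @param centers nominal distances in bp.
#' @param tolerance_fraction half-width of the relative window.
#' @return Tibble: `center_bp`, `lo`, `hi`, `mean`, `sd`, `n_pairs`.
#' @export
point_distance_summary <- function(estimates, centers = c(1e3, 1e4, 1e5),
                                   tolerance_fraction = 0.10,
                                   statistic = "r2_corrected") {
  x <- stat_column(estimates, statistic)
  dist <- estimates$distance_bp
  purrr::map_dfr(centers, function(cc) {
    lo <- max(1, cc * (1 - tolerance_fraction))
    hi <- cc * (1 + tolerance_fraction)
    xi <- x[dist >= lo & dist <= hi]
    tibble::tibble(
      center_bp = cc, lo = lo, hi = hi,
      mean = if (length(xi)) mean(xi) else NA_real_,
      sd = if (length(xi)) sd_pop(xi) else NA_real_,
      n_pairs = length(xi)
    )
  })
}

#' Per-chromosome LD summary
#'
#' Groups all syntenic pairs (already distance-limited by the scan) by
#' chromosome and reports the mean, population SD and pair count of the
#' chosen statistic.
#'
#' @inheritParams bin_by_distance
#' @return Tibble of class `ld_chrom_summary`: `chrom`, `mean`, `sd`,
#'   `n_pairs`.
#' @export
per_chromosome_summary <- function(estimates, statistic = "r2_corrected") {
  x <- stat_column(estimates, statistic)
  out <- tibble::tibble(chrom = estimates$chrom, value = x) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = sd_pop(.data$value),
      n_pairs = dplyr::n(),
      .by = "chrom"
    ) |>
    dplyr::arrange(.data$chrom)
  attr(out, "statistic") <- statistic
  class(out) <- c("ld_chrom_summary", class(out))
  out
}

#' Mean r-squared between adjacent markers, per chromosome
#'
#' Restricts to consecutive-position pairs within each chromosome (no
#' distance ceiling), skipping pairs where either locus is monomorphic among
#' the population's pairwise-complete individuals.
#'
#' @param panel a [genotype_panel()].
#' @param population population label; `NULL` pools all samples.
#' @param statistic column to average, default raw `"r2"`.
#' @return Tibble: `chrom`, `mean`, `n_pairs`, `n_skipped`.
#' @export
adjacent_snp_summary <- function(panel, population = NULL,
                                 statistic = "r2") {
  sub <- if (is.null(population)) panel else panel_population(panel, population)
  ord <- order(sub$variants$chrom, sub$variants$pos)
  sub <- subset_panel(sub, loci = ord)
  v <- sub$variants
  purrr::map_dfr(unique(v$chrom), function(ch) {
    idx <- which(v$chrom == ch)
    if (length(idx) < 2)
      return(tibble::tibble(chrom = ch, mean = NA_real_, n_pairs = 0L,
                            n_skipped = 0L))
    vals <- numeric(0)
    skipped <- 0L
    for (k in seq_len(length(idx) - 1L)) {
      est <- tryCatch(
        ld_pair(sub, idx[k], idx[k + 1L]),
        error = function(e) NULL
      )
      if (is.null(est)) skipped <- skipped + 1L
      else vals <- c(vals, est[[statistic]])
    }
    tibble::tibble(
      chrom = ch,
      mean = if (length(vals)) mean(vals) else NA_real_,
      n_pairs = length(vals),
      n_skipped = skipped
    )
  })
}

#' Log-spaced LD decay curve
#'
#' Bins pair distances into `n_log_bins` logarithmically spaced intervals
#' between the minimum and maximum observed distance and averages the
#' statistic per bin; a compact summary for decay plots.
#'
#' @inheritParams bin_by_distance
#' @param n_log_bins number of bins (>= 1).
#' @return Tibble of class `ld_decay_curve`: `midpoint_bp`, `lo`, `hi`,
#'   `mean`, `n_pairs`.
#' @export
decay_curve <- function(estimates, n_log_bins = 20,
                        statistic = "r2_corrected") {
  stopifnot(n_log_bins >= 1)
  if (!nrow(estimates)) {
    out <- tibble::tibble(midpoint_bp = numeric(), lo = numeric(),
                          hi = numeric(), mean = numeric(),
                          n_pairs = integer())
    class(out) <- c("ld_decay_curve", class(out))
    return(out)
  }
  dist <- estimates$distance_bp
  edges <- exp(seq(log(min(dist)), log(max(dist)),
                   length.out = n_log_bins + 1L))
  edges[1] <- edges[1] - 0.5  # include the minimum-distance pair
  b <- bin_by_distance(
    estimates,
    structure(tibble::tibble(
      bin = as.character(seq_len(n_log_bins)),
      lo = edges[-length(edges)], hi = edges[-1]
    ), class = c("distance_bins", "tbl_df", "tbl", "data.frame")),
    statistic = statistic
  )
  out <- tibble::tibble(
    midpoint_bp = sqrt(b$lo * b$hi), lo = b$lo, hi = b$hi,
    mean = b$mean, n_pairs = b$n_pairs
  )
  attr(out, "statistic") <- statistic
  class(out) <- c("ld_decay_curve", class(out))
  out
}
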