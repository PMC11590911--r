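#' Two-locus genotype counts for a pair of loci
#'
#' The 3x3 cross-tabulation of dosages over individuals non-missing at both
#' loci is the sufficient statistic for two-locus haplotype-frequency
#' estimation from unphased genotypes: every cell determines its gametes
#' except the double heterozygote, whose phase is latent.
#'
#' @param x,y integer dosage vectors (0/1/2, `NA` missing) for the two loci,
#'   aligned by sample.
#' @return 3x3 integer matrix, rows = dosage at the first locus (0,1,2),
#'   columns = dosage at the second.
#' @export
two_locus_counts <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  tab <- table(factor(x[ok], levels = 0:2), factor(y[ok], levels = 0:2))
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(dosage1 = 0:2, dosage2 = 0:2))
  m
}

#' EM estimate of two-locus haplotype frequencies
#'
#' Maximises the multinomial likelihood of unphased two-locus genotypes in
#' the four gamete frequencies (p_AB, p_Ab, p_aB, p_ab). Only the double
#' heterozygote has ambiguous phase; each E-step splits that cell between the
#' coupling and repulsion configurations in proportion to p_AB*p_ab versus
#' p_Ab*p_aB. The allele-frequency marginals are preserved exactly at every
#' iteration. Three deterministic starts are run -- linkage equilibrium and
#' D offset to half its positive and negative bounds -- and the solution with
#' the highest final log-likelihood is kept, ties (within 1e-8 log units)
#' broken toward the smaller |D|; this avoids stalling at the symmetric
#' linkage-equilibrium fixed point.
#'
#' @param counts 3x3 matrix from [two_locus_counts()].
#' @param tol convergence threshold on the largest absolute frequency change
#'   per iteration.
#' @param max_iter iteration cap; if reached, `converged` is `FALSE` and the
#'   best iterate is returned.
#' @return A list of class `hap_freqs`: `p_AB`, `p_Ab`, `p_aB`, `p_ab`,
#'   `loglik`, `converged`, `n_iter`, `n_alleles`, `monomorphic`. When either
#'   locus is monomorphic the frequencies are the (fully determined) marginal
#'   products, `monomorphic` is `TRUE`, and downstream D'/r2 are undefined;
#'   [ld_pair()] converts the flag into a `monomorphic_pair` error.
#' @export
em_haplotype_freqs <- function(counts, tol = 1e-10, max_iter = 1000L) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(3, 3)), all(counts >= 0))
  if (sum(counts) < 1) stop("EM undefined: empty genotype table")
  fit <- em_haplotype_cpp(matrix(as.numeric(counts), 3, 3), tol,
                          as.integer(max_iter))
  out <- fit[c("p_AB", "p_Ab", "p_aB", "p_ab", "loglik", "converged",
               "n_iter", "n_alleles")]
  out$monomorphic <- fit$status == 1L
  structure(out, class = "hap_freqs")
}

monomorphic_pair_error <- function() {
  structure(
    class = c("monomorphic_pair", "error", "condition"),
    list(message = "monomorphic locus in pair: LD undefined", call = NULL)
  )
}

#' Per-iteration EM log-likelihood trace
#'
#' Runs the linkage-equilibrium start only and returns the log-likelihood
#' after each M-step; used to verify the EM monotonicity guarantee.
#'
#' @inheritParams em_haplotype_freqs
#' @return Numeric vector of log-likelihood values.
#' @export
em_loglik_trace <- function(counts, tol = 1e-10, max_iter = 1000L) {
  counts <- as.matrix(counts)
  em_trace_cpp(matrix(as.numeric(counts), 3, 3), tol, as.integer(max_iter))
}

#' Gametic disequilibrium statistics from haplotype frequencies
#'
#' `compute_D()` is the raw disequilibrium D = p_AB*p_ab - p_Ab*p_aB
#' (equivalently p_AB - p_A*p_B); its sign depends on allele orientation.
#' `compute_Dprime()` normalises D by its attainable bound at the observed
#' allele frequencies: Dmax = min(p_A*p_b, p_a*p_B) for D > 0 and
#' min(p_A*p_B, p_a*p_b) for D < 0, with D' defined as 0 at D = 0.
#' `compute_r2()` is the squared allelic correlation
#' D^2 / (p_A*p_a*p_B*p_b).
#'
#' @param hf a `hap_freqs` object or list with `p_AB`, `p_Ab`, `p_aB`,
#'   `p_ab`.
#' @return A single numeric value.
#' @export
compute_D <- function(hf) {
  hf$p_AB * hf$p_ab - hf$p_Ab * hf$p_aB
}

#' @rdname compute_D
#' @export
compute_Dprime <- function(hf) {
  pA <- hf$p_AB + hf$p_Ab
  pB <- hf$p_AB + hf$p_aB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("D' undefined for a monomorphic locus")
  D <- compute_D(hf)
  if (D == 0) return(0)
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else       min(pA * pB, (1 - pA) * (1 - pB))
  D / dmax
}

#' @rdname compute_D
#' @export
compute_r2 <- function(hf) {
  pA <- hf$p_AB + hf$p_Ab
  pB <- hf$p_AB + hf$p_aB
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("r2 undefined for a monomorphic locus")
  compute_D(hf)^2 / (pA * (1 - pA) * pB * (1 - pB))
}

#' Finite-sample correction of r-squared
#'
#' Under linkage equilibrium the expected sample r-squared is about 1/n,
#' where n is the number of sampled alleles (twice the number of diploids
#' scored for the pair). The correction removes this null expectation and
#' rescales: (r2 - 1/n) / (1 - 1/n). The raw formula is negative whenever
#' r2 < 1/n; since a negative squared correlation has no interpretation the
#' result is floored at 0 by default (`floor_at_zero = FALSE` gives the
#' uncensored value).
#'
#' @param r2_computed raw r-squared value(s).
#' @param n_alleles allele count(s), at least 2 (vectorised).
#' @param floor_at_zero censor negative corrected values at 0.
#' @return Corrected r-squared value(s).
#' @export
correct_r2 <- function(r2_computed, n_alleles, floor_at_zero = TRUE) {
  stopifnot(all(n_alleles >= 2))
  out <- (r2_computed - 1 / n_alleles) / (1 - 1 / n_alleles)
  if (floor_at_zero) out <- pmax(out, 0)
  out
}

#' LD estimate for one syntenic marker pair
#'
#' Builds the two-locus genotype table over individuals non-missing at both
#' loci, fits haplotype frequencies by EM, and returns the full set of pair
#' statistics. The allele count n is pair-specific (2 x pairwise-complete
#' individuals); `use_panel_n = TRUE` substitutes the panel-wide sample size
#' in the r-squared correction instead.
#'
#' @param panel a [genotype_panel()].
#' @param locus_i,locus_j variant ids or column indices; must lie on the same
#'   chromosome with `pos_j > pos_i`.
#' @param use_panel_n use 2 x panel samples as n in [correct_r2()].
#' @return One-row tibble: `chrom`, `vid_i`, `vid_j`, `distance_bp`,
#'   `n_alleles`, `D`, `Dprime`, `r2`, `r2_corrected`, `converged`.
#' @export
ld_pair <- function(panel, locus_i, locus_j, use_panel_n = FALSE) {
  ci <- if (is.character(locus_i)) match(locus_i, panel$variants$vid) else locus_i
  cj <- if (is.character(locus_j)) match(locus_j, panel$variants$vid) else locus_j
  if (is.na(ci) || is.na(cj)) stop("unknown locus id")
  vi <- panel$variants[ci, ]
  vj <- panel$variants[cj, ]
  if (vi$chrom != vj$chrom) stop("ld_pair requires syntenic loci")
  if (vj$pos <= vi$pos) stop("ld_pair requires pos_j > pos_i")
  cnt <- two_locus_counts(panel$dosages[, ci], panel$dosages[, cj])
  if (sum(cnt) < 2) stop("insufficient pairwise-complete individuals")
  hf <- em_haplotype_freqs(cnt)
  if (hf$monomorphic) stop(monomorphic_pair_error())
  n <- if (use_panel_n) 2L * n_samples(panel) else hf$n_alleles
  r2 <- compute_r2(hf)
  tibble::tibble(
    chrom = vi$chrom, vid_i = vi$vid, vid_j = vj$vid,
    distance_bp = vj$pos - vi$pos,
    n_alleles = as.integer(n),
    D = compute_D(hf),
    Dprime = compute_Dprime(hf),
    r2 = r2,
    r2_corrected = correct_r2(r2, n),
    converged = hf$converged
  )
}
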