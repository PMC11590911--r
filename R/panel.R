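#' Construct a genotype panel
#'
#' A `genotype_panel` bundles an integer dosage matrix (samples in rows, loci
#' in columns, entries 0/1/2 counting copies of `allele_b`, `NA` for a missing
#' call) with a sample table carrying population labels and a variant table
#' carrying marker coordinates. It is the common currency of the package:
#' quality control, LD estimation and the synthetic generator all consume and
#' produce panels, while every analysis result is returned as a tibble.
#'
#' @param dosages integer matrix, samples x loci, entries in \{0, 1, 2, NA\}.
#' @param samples data frame with columns `sample_id` (unique character) and
#'   `population` (character); one row per matrix row.
#' @param variants data frame with columns `chrom` (character), `pos`
#'   (integer, 1-based base pairs), `vid` (unique character), `allele_a`,
#'   `allele_b` (single-character allele codes); one row per matrix column.
#'
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, samples, variants) {
  samples <- tibble::as_tibble(samples)
  variants <- tibble::as_tibble(variants)
  stopifnot(
    is.matrix(dosages),
    all(c("sample_id", "population") %in% names(samples)),
    all(c("chrom", "pos", "vid", "allele_a", "allele_b") %in% names(variants)),
    nrow(samples) == nrow(dosages),
    nrow(variants) == ncol(dosages)
  )
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in panel")
  if (anyDuplicated(variants$vid)) stop("duplicate variant id in panel")
  if (any(variants$pos < 1L)) stop("variant positions must be >= 1")
  bad <- dosages[!is.na(dosages) & !(dosages %in% 0:2)]
  if (length(bad)) stop("dosages must be 0, 1, 2 or NA")
  storage.mode(dosages) <- "integer"
  dimnames(dosages) <- list(samples$sample_id, variants$vid)
  structure(
    list(dosages = dosages, samples = samples, variants = variants),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "<genotype_panel> %d samples x %d loci, %d population(s), %d chromosome(s)\n",
    n_samples(x), n_loci(x),
    dplyr::n_distinct(x$samples$population),
    dplyr::n_distinct(x$variants$chrom)
  ))
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing call rate: %.3f\n", miss))
  invisible(x)
}

#' Panel dimensions and accessors
#'
#' @param panel a [genotype_panel()].
#' @return `n_samples()` / `n_loci()` return counts; `panel_variants()` and
#'   `panel_samples()` return the corresponding tibbles; `panel_dosages()`
#'   the integer dosage matrix.
#' @export
n_samples <- function(panel) nrow(panel$dosages)

#' @rdname n_samples
#' @export
n_loci <- function(panel) ncol(panel$dosages)

#' @rdname n_samples
#' @export
panel_variants <- function(panel) panel$variants

#' @rdname n_samples
#' @export
panel_samples <- function(panel) panel$samples

#' @rdname n_samples
#' @export
panel_dosages <- function(panel) panel$dosages

#' Subset a panel by samples and/or loci
#'
#' @param panel a [genotype_panel()].
#' @param samples character sample ids or logical/integer row index; `NULL`
#'   keeps all.
#' @param loci character variant ids or logical/integer column index; `NULL`
#'   keeps all.
#' @return A `genotype_panel` with the requested rows/columns, order preserved
#'   as given.
#' @export
subset_panel <- function(panel, samples = NULL, loci = NULL) {
  ridx <- if (is.null(samples)) seq_len(n_samples(panel)) else {
    if (is.character(samples)) match(samples, panel$samples$sample_id) else
      seq_len(n_samples(panel))[samples]
  }
  cidx <- if (is.null(loci)) seq_len(n_loci(panel)) else {
    if (is.character(loci)) match(loci, panel$variants$vid) else
      seq_len(n_loci(panel))[loci]
  }
  if (anyNA(ridx)) stop("unknown sample id in subset")
  if (anyNA(cidx)) stop("unknown variant id in subset")
  genotype_panel(
    panel$dosages[ridx, cidx, drop = FALSE],
    panel$samples[ridx, , drop = FALSE],
    panel$variants[cidx, , drop = FALSE]
  )
}

#' Restrict a panel to the samples of one population
#'
#' @param panel a [genotype_panel()].
#' @param population population label present in the sample table.
#' @return A `genotype_panel` containing only that population's samples.
#' @export
panel_population <- function(panel, population) {
  keep <- panel$samples$population == population
  if (!any(keep)) stop("unknown population label: ", population)
  subset_panel(panel, samples = keep)
}

#' Put a panel into reader-canonical allele orientation
#'
#' Flips (via [flip_alleles()]) every locus whose first non-missing call is
#' homozygous for the counted allele, so that the first allele code observed
#' in sample order is `allele_a`. A panel in this form survives a
#' [write_ped_map()] / [read_ped_map()] round trip with its dosage matrix
#' bit-identical; panels read from PED are canonical by construction. The
#' relabelling changes no LD magnitude statistic.
#'
#' @param panel a [genotype_panel()].
#' @return The canonically oriented `genotype_panel`.
#' @export
canonical_orientation <- function(panel) {
  d <- panel$dosages
  flip <- vapply(seq_len(ncol(d)), function(j) {
    x <- d[, j]
    x <- x[!is.na(x)]
    length(x) > 0 && x[1] == 2L
  }, logical(1))
  if (!any(flip)) return(panel)
  flip_alleles(panel, loci = which(flip))
}

#' Flip the allele orientation of selected loci
#'
#' Swaps `allele_a`/`allele_b` and maps every dosage d to 2 - d. LD magnitude
#' statistics (r-squared, |D'|) are invariant under this relabelling; the sign
#' of D flips. Used mainly in invariance tests.
#'
#' @param panel a [genotype_panel()].
#' @param loci variant ids or column index to flip; `NULL` flips all.
#' @return The relabelled `genotype_panel`.
#' @export
flip_alleles <- function(panel, loci = NULL) {
  cidx <- if (is.null(loci)) seq_len(n_loci(panel)) else {
    if (is.character(loci)) match(loci, panel$variants$vid) else
      seq_len(n_loci(panel))[loci]
  }
  d <- panel$dosages
  d[, cidx] <- 2L - d[, cidx]
  v <- panel$variants
  tmp <- v$allele_a[cidx]
  v$allele_a[cidx] <- v$allele_b[cidx]
  v$allele_b[cidx] <- tmp
  genotype_panel(d, panel$samples, v)
}
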