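#' Genotype concordance cross-tabulation
#'
#' A K x K table of called genotype class (rows) against true genotype class
#' (columns); for biallelic dosage data K = 3 with classes 0/1/2.
#'
#' @param counts square nonnegative integer matrix with a positive total.
#' @return The matrix with class `concordance_table`.
#' @export
concordance_table <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == ncol(counts), all(counts >= 0))
  if (sum(counts) <= 0) stop("concordance table is empty")
  structure(counts, class = c("concordance_table", "matrix"))
}

#' Observed, chance, and quality-score agreement
#'
#' `observed_agreement()` (Po) is the fraction of individuals whose called
#' genotype matches the true genotype (the diagonal mass).
#' `chance_agreement()` (Pc) is the agreement expected if calls were assigned
#' independently with the observed marginal class frequencies,
#' sum_i(n_i. * n_.i) / n^2. `quality_score()` combines them in the
#' Cohen-kappa form Q = (Po - Pc) / (1 - Pc): the excess of observed over
#' chance agreement, rescaled so that perfect concordance gives 1 and
#' chance-level concordance gives 0.
#'
#' @param table a [concordance_table()] or plain square count matrix.
#' @return A single numeric value.
#' @export
observed_agreement <- function(table) {
  m <- as.matrix(table)
  sum(diag(m)) / sum(m)
}

#' @rdname observed_agreement
#' @export
chance_agreement <- function(table) {
  m <- as.matrix(table)
  n <- sum(m)
  sum(rowSums(m) * colSums(m)) / n^2
}

#' @rdname observed_agreement
#' @export
quality_score <- function(table) {
  po <- observed_agreement(table)
  pc <- chance_agreement(table)
  if (pc >= 1) stop("quality score undefined: chance agreement is 1")
  (po - pc) / (1 - pc)
}

#' Tidy and summarise a concordance table
#'
#' `tidy()` gives one row per (called, true) cell; `glance()` a one-row
#' summary with Po, Pc, Q and the total count.
#'
#' @param x a `concordance_table`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.concordance_table <- function(x, ...) {
  m <- as.matrix(x)
  k <- nrow(m)
  cls <- rownames(m) %||% as.character(seq_len(k) - 1L)
  tibble::tibble(
    called = rep(cls, times = k),
    true = rep(cls, each = k),
    n = as.vector(m)
  )
}

#' @rdname tidy.concordance_table
#' @export
glance.concordance_table <- function(x, ...) {
  tibble::tibble(
    Po = observed_agreement(x),
    Pc = chance_agreement(x),
    Q = quality_score(x),
    n = sum(as.matrix(x))
  )
}

#' Cross-tabulate called against true genotype panels
#'
#' For each (called, true) sample pair the dosage calls are compared locus by
#' locus over the shared locus set; loci where either call is missing are
#' excluded from the table and counted separately. Pairs are matched by
#' sample id, never by row order.
#'
#' @param panel_called,panel_true [genotype_panel()] objects sharing a locus
#'   set (matched by variant id).
#' @param sample_pairs data frame with columns `called` and `true` naming
#'   sample ids in the respective panels; defaults to pairing shared ids.
#' @return A `concordance_table` (3x3, pooled over pairs) with attributes
#'   `n_missing_excluded` and `per_pair` (tibble: `called`, `true`, `Po`,
#'   `Pc`, `Q`, `n_loci_used`).
#' @export
concordance_from_panels <- function(panel_called, panel_true,
                                    sample_pairs = NULL) {
  shared <- intersect(panel_called$variants$vid, panel_true$variants$vid)
  if (!length(shared)) stop("panels share no loci")
  if (is.null(sample_pairs)) {
    ids <- intersect(panel_called$samples$sample_id,
                     panel_true$samples$sample_id)
    sample_pairs <- tibble::tibble(called = ids, true = ids)
  }
  sample_pairs <- tibble::as_tibble(sample_pairs)
  dc <- panel_called$dosages[, shared, drop = FALSE]
  dt <- panel_true$dosages[, shared, drop = FALSE]

  pooled <- matrix(0L, 3, 3, dimnames = list(0:2, 0:2))
  n_missing <- 0L
  per_pair <- purrr::pmap_dfr(sample_pairs, function(called, true) {
    x <- dc[called, ]
    y <- dt[true, ]
    ok <- !is.na(x) & !is.na(y)
    n_missing <<- n_missing + sum(!ok)
    tab <- table(factor(x[ok], levels = 0:2), factor(y[ok], levels = 0:2))
    m <- matrix(as.integer(tab), 3, 3)
    pooled <<- pooled + m
    if (sum(m) == 0)
      return(tibble::tibble(called = called, true = true, Po = NA_real_,
                            Pc = NA_real_, Q = NA_real_, n_loci_used = 0L))
    ct <- concordance_table(m)
    tibble::tibble(
      called = called, true = true,
      Po = observed_agreement(ct), Pc = chance_agreement(ct),
      Q = tryCatch(quality_score(ct), error = function(e) NA_real_),
      n_loci_used = sum(m)
    )
  })
  if (sum(pooled) == 0) stop("no pairwise non-missing genotype calls")
  out <- concordance_table(pooled)
  attr(out, "n_missing_excluded") <- n_missing
  attr(out, "per_pair") <- per_pair
  out
}

#' Per-pair concordance summary
#'
#' @param table the result of [concordance_from_panels()].
#' @return Tibble with one row per sample pair: `called`, `true`, `Po`, `Pc`,
#'   `Q`, `n_loci_used`.
#' @export
concordance_summary <- function(table) {
  pp <- attr(table, "per_pair")
  if (is.null(pp)) stop("table carries no per-pair records")
  pp
}
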