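#' Read a PLINK text PED/MAP pair into a genotype panel
#'
#' Parses the classic whitespace-separated PLINK text formats: the MAP file
#' holds one marker per line (chromosome, id, genetic position in cM -- read
#' but ignored, physical position in bp) and the PED file one individual per
#' line (six pedigree columns, then two allele codes per marker). Allele "0"
#' is the missing code; a genotype with either allele missing becomes a
#' missing dosage. At each locus `allele_a` is the first non-missing allele
#' code observed scanning samples in file order and `allele_b` its partner, so
#' dosages count copies of the second-observed allele. This orientation is
#' arbitrary; all downstream magnitude statistics are orientation-invariant
#' and the sign of D is documented as orientation-dependent.
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @param pop_assignments either a data frame with columns `sample_id`,
#'   `population`, or the path of a two-column headerless TSV with those
#'   fields. Population labels are taken from here, not from the PED family
#'   id column. `NULL` assigns every sample to population `"pop1"`.
#'
#' @return A [genotype_panel()].
#' @export
read_ped_map <- function(ped_path, map_path, pop_assignments = NULL) {
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) != 4L)
    stop("MAP format error: expected 4 columns, found ", ncol(map))
  variants <- tibble::tibble(
    chrom = map[[1]], vid = map[[2]], pos = as.integer(map[[4]]),
    allele_a = NA_character_, allele_b = NA_character_
  )
  m <- nrow(variants)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  dos <- matrix(NA_integer_, nrow = n, ncol = m)
  sample_ids <- character(n)
  a1 <- matrix(NA_character_, nrow = n, ncol = m)
  a2 <- matrix(NA_character_, nrow = n, ncol = m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m)
      stop(sprintf(
        "PED format error: row %d has %d fields, expected %d (6 + 2 x %d loci)",
        i, length(f), 6L + 2L * m, m
      ))
    sample_ids[i] <- f[2]
    g <- f[-(1:6)]
    a1[i, ] <- g[seq(1L, 2L * m, by = 2L)]
    a2[i, ] <- g[seq(2L, 2L * m, by = 2L)]
  }
  if (anyDuplicated(sample_ids))
    sample_ids <- paste(vapply(
      strsplit(trimws(ped_lines), "[ \t]+"), `[`, "", 1L
    ), sample_ids, sep = "_")

  for (j in seq_len(m)) {
    obs <- c(rbind(a1[, j], a2[, j]))  # sample-major allele stream
    nonmiss <- obs[obs != "0"]
    codes <- unique(nonmiss)
    if (length(codes) > 2L)
      stop(sprintf(
        "non-biallelic locus '%s': allele codes %s",
        variants$vid[j], paste(codes, collapse = ", ")
      ))
    aa <- if (length(codes) >= 1L) codes[1] else "0"
    bb <- if (length(codes) == 2L) codes[2] else "0"
    variants$allele_a[j] <- aa
    variants$allele_b[j] <- bb
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dj <- (a1[, j] == bb) + (a2[, j] == bb)
    dj[miss] <- NA_integer_
    dos[, j] <- as.integer(dj)
  }

  pops <- resolve_pop_assignments(pop_assignments, sample_ids)
  genotype_panel(
    dos,
    tibble::tibble(sample_id = sample_ids, population = pops),
    variants
  )
}

resolve_pop_assignments <- function(pop_assignments, sample_ids) {
  if (is.null(pop_assignments))
    return(rep("pop1", length(sample_ids)))
  if (is.character(pop_assignments) && length(pop_assignments) == 1L) {
    tab <- utils::read.table(pop_assignments, header = FALSE,
                             colClasses = "character")
    pop_assignments <- tibble::tibble(sample_id = tab[[1]],
                                      population = tab[[2]])
  }
  pop_assignments <- tibble::as_tibble(pop_assignments)
  idx <- match(sample_ids, pop_assignments$sample_id)
  if (anyNA(idx))
    stop("population assignment missing for sample(s): ",
         paste(sample_ids[is.na(idx)], collapse = ", "))
  pop_assignments$population[idx]
}

#' Write a genotype panel as PLINK text PED/MAP
#'
#' Inverse of [read_ped_map()]: `read_ped_map(write_ped_map(panel))` recovers
#' the dosage matrix exactly. Heterozygotes are written `allele_a allele_b`,
#' missing calls as `0 0`. The family id column carries the population label
#' (informational only; reading takes populations from the separate map).
#'
#' Because PED files carry no allele metadata, orientation is only
#' recoverable when the panel is in reader-canonical orientation (the first
#' non-missing call at each locus is not homozygous for the counted allele);
#' [canonical_orientation()] puts any panel into that form by the
#' statistics-preserving relabelling d -> 2 - d. Panels produced by
#' [read_ped_map()] are always canonical.
#'
#' @param panel a [genotype_panel()].
#' @param ped_path,map_path output paths.
#' @param pop_path optional path for a two-column sample-to-population TSV.
#' @return Invisibly, the panel.
#' @export
write_ped_map <- function(panel, ped_path, map_path, pop_path = NULL) {
  v <- panel$variants
  writeLines(
    sprintf("%s\t%s\t0\t%d", v$chrom, v$vid, v$pos),
    map_path
  )
  d <- panel$dosages
  n <- n_samples(panel)
  lines <- character(n)
  g0 <- paste(v$allele_a, v$allele_a)
  g1 <- paste(v$allele_a, v$allele_b)
  g2 <- paste(v$allele_b, v$allele_b)
  gm <- rep("0 0", n_loci(panel))
  for (i in seq_len(n)) {
    di <- d[i, ]
    gt <- gm
    gt[!is.na(di) & di == 0L] <- g0[!is.na(di) & di == 0L]
    gt[!is.na(di) & di == 1L] <- g1[!is.na(di) & di == 1L]
    gt[!is.na(di) & di == 2L] <- g2[!is.na(di) & di == 2L]
    lines[i] <- paste(
      panel$samples$population[i], panel$samples$sample_id[i],
      "0 0 0 -9", paste(gt, collapse = " ")
    )
  }
  writeLines(lines, ped_path)
  if (!is.null(pop_path))
    writeLines(
      sprintf("%s\t%s", panel$samples$sample_id, panel$samples$population),
      pop_path
    )
  invisible(panel)
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; floating-point columns are formatted at 6
#' significant digits so written files are stable across platforms.
#'
#' @param rows data frame of results.
#' @param path output path.
#' @return Invisibly, `rows`.
#' @export
write_result_table <- function(rows, path) {
  out <- as.data.frame(rows)
  num <- vapply(out, is.double, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(rows)
}
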