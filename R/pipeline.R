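#' Pipeline configuration
#'
#' Collects every knob of an end-to-end run: input paths, QC thresholds,
#' distance classes, the statistic to summarise, the populations to analyse
#' and the output directory. A configuration can also be read from a flat
#' YAML file with [read_pipeline_config()]; explicit arguments override file
#' values.
#'
#' @param ped,map paths to the PLINK text PED and MAP files.
#' @param pop_map path to the two-column sample-to-population TSV, or `NULL`
#'   for a single pooled population.
#' @param out_dir output directory (created if absent).
#' @param thresholds a [qc_thresholds()].
#' @param bins a [distance_bins()].
#' @param statistic summary statistic for the decay tables.
#' @param max_distance_bp syntenic pair-distance ceiling.
#' @param populations labels to analyse; `NULL` means every population in
#'   the panel.
#' @param duplicate_pairs optional data frame (`called`, `true`) of sample id
#'   pairs for concordance scoring (e.g. re-genotyped duplicates).
#' @param seed integer seed recorded in the manifest.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(ped, map, pop_map = NULL, out_dir = ".",
                            thresholds = qc_thresholds(),
                            bins = distance_bins(),
                            statistic = "r2_corrected",
                            max_distance_bp = 1e6,
                            populations = NULL,
                            duplicate_pairs = NULL,
                            seed = 1L) {
  structure(
    list(ped = ped, map = map, pop_map = pop_map, out_dir = out_dir,
         thresholds = thresholds, bins = bins, statistic = statistic,
         max_distance_bp = max_distance_bp, populations = populations,
         duplicate_pairs = duplicate_pairs, seed = seed),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a flat YAML file
#'
#' Recognised keys: `ped`, `map`, `pop_map`, `out_dir`, `hwe_p_min`,
#' `maf_min`, `call_rate_min`, `autosomes`, `bin_edges_bp`, `statistic`,
#' `max_distance_bp`, `populations`, `seed`.
#'
#' @param path YAML file path.
#' @param ... overrides passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  thr <- qc_thresholds(
    hwe_p_min = y$hwe_p_min %||% 1e-7,
    maf_min = y$maf_min %||% 0.05,
    call_rate_min = y$call_rate_min %||% 0.90,
    autosomes = y$autosomes %||% as.character(1:29)
  )
  bins <- if (!is.null(y$bin_edges_bp)) distance_bins(as.numeric(y$bin_edges_bp))
          else distance_bins()
  args <- list(
    ped = y$ped, map = y$map, pop_map = y$pop_map, out_dir = y$out_dir %||% ".",
    thresholds = thr, bins = bins,
    statistic = y$statistic %||% "r2_corrected",
    max_distance_bp = y$max_distance_bp %||% 1e6,
    populations = y$populations, seed = y$seed %||% 1L
  )
  over <- list(...)
  args[names(over)] <- over
  do.call(pipeline_config, args)
}

#' Run the full LD-decay pipeline
#'
#' Reads the panel, applies the QC cascade once on the pooled panel, then for
#' each analysed population computes the syntenic pairwise LD scan, the
#' distance-class, point-distance, per-chromosome and adjacent-marker decay
#' summaries, the MAF histogram, and the cross-population monomorphic
#' overlap; scores concordance if duplicate pairs are supplied. Every result
#' is written as TSV under `out_dir` together with a JSON manifest (seed,
#' parameter echo, output list). Reruns with the same configuration are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`panel`,
#'   `qc_report`, `ld`, `bins`, `points`, `chromosomes`, `adjacent`,
#'   `maf_hist`, `mono_overlap`, `concordance`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  outputs <- character(0)
  emit <- function(rows, name) {
    write_result_table(rows, outp(name))
    outputs <<- c(outputs, name)
  }

  panel <- read_ped_map(config$ped, config$map, config$pop_map)
  qc <- apply_qc(panel, config$thresholds)
  emit(tidy(qc$report), "qc_report.tsv")
  kept <- qc$panel

  pops <- config$populations %||% unique(kept$samples$population)
  ld_all <- purrr::map(pops, function(p) {
    pairwise_syntenic_ld(kept, p, config$max_distance_bp)
  })
  names(ld_all) <- pops

  ld_tab <- purrr::imap_dfr(ld_all, ~ dplyr::mutate(.x, population = .y,
                                                    .before = 1))
  emit(ld_tab, "ld_pairs.tsv")

  bin_tab <- purrr::imap_dfr(ld_all, function(est, p)
    dplyr::mutate(bin_by_distance(est, config$bins, config$statistic),
                  population = p, .before = 1))
  emit(bin_tab, "ld_bins.tsv")

  pt_tab <- purrr::imap_dfr(ld_all, function(est, p)
    dplyr::mutate(point_distance_summary(est, statistic = config$statistic),
                  population = p, .before = 1))
  emit(pt_tab, "ld_points.tsv")

  chr_tab <- purrr::imap_dfr(ld_all, function(est, p)
    dplyr::mutate(per_chromosome_summary(est, config$statistic),
                  population = p, .before = 1))
  emit(chr_tab, "ld_chromosomes.tsv")

  adj_tab <- purrr::map_dfr(pops, function(p)
    dplyr::mutate(adjacent_snp_summary(kept, p), population = p,
                  .before = 1))
  emit(adj_tab, "ld_adjacent.tsv")

  maf_tab <- maf_histogram(kept)
  emit(maf_tab, "maf_histogram.tsv")

  mono_tab <- purrr::map_dfr(pops, function(p) {
    others <- setdiff(pops, p)
    ov <- if (length(others))
      tryCatch(monomorphic_overlap(kept, p, others), error = function(e) NA_real_)
    else NA_real_
    tibble::tibble(
      population = p,
      n_monomorphic = length(monomorphic_loci(kept, p)),
      overlap_with_others = ov
    )
  })
  emit(mono_tab, "monomorphic_overlap.tsv")

  conc <- NULL
  if (!is.null(config$duplicate_pairs)) {
    conc <- concordance_from_panels(panel, panel, config$duplicate_pairs)
    emit(concordance_summary(conc), "concordance.tsv")
  }

  manifest <- list(
    package = "lddecay",
    version = as.character(utils::packageVersion("lddecay")),
    seed = config$seed,
    statistic = config$statistic,
    max_distance_bp = config$max_distance_bp,
    thresholds = unclass(config$thresholds),
    bin_edges_bp = c(config$bins$lo, config$bins$hi[nrow(config$bins)]),
    populations = pops,
    n_input_loci = qc$report$n_input,
    n_retained_loci = qc$report$n_retained,
    outputs = outputs
  )
  jsonlite::write_json(manifest, outp("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    panel = kept, qc_report = qc$report, ld = ld_all, bins = bin_tab,
    points = pt_tab, chromosomes = chr_tab, adjacent = adj_tab,
    maf_hist = maf_tab, mono_overlap = mono_tab, concordance = conc,
    manifest = manifest
  ))
}
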