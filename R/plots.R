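#' Plot methods for decay-analysis results
#'
#' `autoplot()` methods return ggplot objects: a decay curve of mean LD
#' against log distance, per-population MAF spectra, distance-class bars,
#' and per-chromosome means.
#'
#' @param object a result object from this package.
#' @param ... unused.
#' @return A `ggplot`.
#' @name lddecay-plots
NULL

#' @rdname lddecay-plots
#' @export
autoplot.ld_decay_curve <- function(object, ...) {
  stat <- attr(object, "statistic") %||% "LD"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$midpoint_bp, y = .data$mean)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.6) +
    ggplot2::scale_x_log10(labels = function(x) format_bp(x)) +
    ggplot2::labs(x = "inter-marker distance", y = paste("mean", stat),
                  size = "pairs", title = "LD decay") +
    ggplot2::theme_minimal()
}

#' @rdname lddecay-plots
#' @export
autoplot.ld_bin_summary <- function(object, ...) {
  stat <- attr(object, "statistic") %||% "LD"
  df <- dplyr::mutate(object, bin = factor(.data$bin, levels = unique(.data$bin)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = .data$mean + .data$sd),
      width = 0.2
    ) +
    ggplot2::labs(x = "distance class", y = paste("mean", stat),
                  title = "LD by distance class") +
    ggplot2::theme_minimal()
}

#' @rdname lddecay-plots
#' @export
autoplot.ld_chrom_summary <- function(object, ...) {
  stat <- attr(object, "statistic") %||% "LD"
  df <- dplyr::mutate(
    object,
    chrom = factor(.data$chrom,
                   levels = unique(.data$chrom[order(suppressWarnings(
                     as.numeric(.data$chrom)))]))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom, y = .data$mean)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "chromosome", y = paste("mean", stat),
                  title = "Per-chromosome LD") +
    ggplot2::theme_minimal()
}

#' @rdname lddecay-plots
#' @export
autoplot.maf_histogram <- function(object, ...) {
  df <- dplyr::mutate(object, bin = factor(.data$bin, levels = unique(.data$bin)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin, y = .data$n_loci,
                                   fill = .data$population)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "minor allele frequency", y = "loci",
                  title = "MAF spectrum by population") +
    ggplot2::theme_minimal()
}
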