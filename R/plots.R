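#' Stacked-bar plot of taxon profiles
#'
#' @param profiles Named list of profile tibbles (`rank`, `taxon`,
#'   `abundance`) or a single profile tibble.
#' @param rank Rank to plot.
#' @return A ggplot object.
#' @export
plot_profile_bars <- function(profiles, rank = "genus") {
  if (is.data.frame(profiles)) profiles <- list(profile = profiles)
  long <- purrr::imap_dfr(profiles, function(p, nm) {
    dplyr::mutate(dplyr::filter(as_tibble(p), .data$rank == !!rank),
                  method = nm)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method,
                                     y = .data$abundance,
                                     fill = .data$taxon)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Relative abundance",
                  title = paste("Taxon profile at", rank, "level")) +
    ggplot2::theme_minimal()
}

#' Plot rank-wise assignment rates
#'
#' The fraction of reads carrying a name at each rank, superkingdom to
#' species; conservative rank degradation makes this non-increasing.
#'
#' @param assignments Tibble from [assign_reads()].
#' @return A ggplot object.
#' @export
plot_rank_assignment <- function(assignments) {
  rates <- rank_assignment_rates(assignments)
  rates$rank <- factor(rates$rank, levels = taxonomic_ranks())
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$rank,
                                      y = .data$fraction_assigned,
                                      group = 1)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "Fraction of reads assigned") +
    ggplot2::theme_minimal()
}

#' Autoplot method for accumulation curves
#'
#' @param object Tibble from [accumulation_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.operonkit_accum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n_reads,
                                       y = .data$mean_taxa)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_taxa - .data$sd_taxa,
      ymax = .data$mean_taxa + .data$sd_taxa), alpha = 0.2) +
    ggplot2::labs(x = "Reads sampled", y = "Distinct taxa observed") +
    ggplot2::theme_minimal()
}

#' Line plot of an accumulation curve
#' @inheritParams autoplot.operonkit_accum
#' @param curve Tibble from [accumulation_curve()].
#' @return A ggplot object.
#' @export
plot_accumulation <- function(curve) {
  class(curve) <- c("operonkit_accum", class(curve))
  ggplot2::autoplot(curve)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
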