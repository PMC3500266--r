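#' Plot the bootstrap null with the observed group averages
#'
#' Frequency histogram of the bootstrap distribution of group-average
#' similarities, with vertical marks for the observed group means.
#'
#' @param object A `coexpression_report` or `pcc_bootstrap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot coexpression_report
#' @export
autoplot.coexpression_report <- function(object, ...) {
  if (is.null(object$bootstrap)) {
    rlang::abort("report carries no bootstrap distribution")
  }
  p <- autoplot(object$bootstrap)
  marks <- dplyr::filter(object$groups, !is.na(.data$mean_pcc))
  p +
    ggplot2::geom_vline(
      data = marks,
      ggplot2::aes(xintercept = .data$mean_pcc, colour = .data$group),
      linewidth = 0.8
    ) +
    ggplot2::labs(
      title = paste0(object$regulon, ": group-average similarity vs random groupings"),
      colour = "observed group"
    )
}

#' @rdname autoplot.coexpression_report
#' @method autoplot pcc_bootstrap
#' @export
autoplot.pcc_bootstrap <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$mean_pcc)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", colour = "grey40") +
    ggplot2::labs(x = "bootstrap mean offset-PCC", y = "frequency") +
    ggplot2::theme_minimal()
}

#' Plot orientation counts of an adjacency summary
#'
#' @param object An `adjacency_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot adjacency_summary
#' @export
autoplot.adjacency_summary <- function(object, ...) {
  df <- tibble::tibble(
    orientation = factor(names(object$orientation_counts),
      levels = c("divergent", "tandem", "convergent")),
    n = as.integer(object$orientation_counts)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$orientation, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      title = sprintf("%s: %d adjacent pair(s), j = %d of M = %d",
        object$regulon, nrow(object$pairs), object$j, object$M),
      y = "adjacent pairs"
    ) +
    ggplot2::theme_minimal()
}

#' Heat-map style view of pair fates across a species panel
#'
#' Tiles pair (rows) by species (columns), coloured by fate — the
#' conservation fate matrix.
#'
#' @param object A `conservation_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot conservation_profile
#' @export
autoplot.conservation_profile <- function(object, ...) {
  ggplot2::ggplot(
    object$fates,
    ggplot2::aes(x = .data$species, y = .data$pair_id, fill = .data$fate)
  ) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = c(
      same_partner = "#1b7837",
      repaired_within_regulon = "#a6dba0",
      unpaired = "#f7f7f7",
      gene_absent = "#bdbdbd"
    )) +
    ggplot2::labs(x = NULL, y = NULL, fill = "fate") +
    ggplot2::theme_minimal()
}

#' Plot the synteny-maintenance bootstrap distribution
#'
#' @param object A `synteny_bootstrap`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot synteny_bootstrap
#' @export
autoplot.synteny_bootstrap <- function(object, ...) {
  p <- ggplot2::ggplot(tidy(object),
    ggplot2::aes(x = .data$maintained_fraction)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::labs(x = "maintained fraction per resample", y = "frequency") +
    ggplot2::theme_minimal()
  if (!is.na(object$observed_fraction)) {
    p <- p + ggplot2::geom_vline(xintercept = object$observed_fraction,
      colour = "firebrick", linewidth = 0.8)
  }
  p
}
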