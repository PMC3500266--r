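#' Tidy an adjacency summary into its pair table
#'
#' @param x An `adjacency_summary`.
#' @param ... Unused.
#' @return The pair tibble, one row per adjacent pair.
#' @method tidy adjacency_summary
#' @export
tidy.adjacency_summary <- function(x, ...) {
  dplyr::mutate(x$pairs, regulon = x$regulon, .before = 1)
}

#' @rdname tidy.adjacency_summary
#' @method glance adjacency_summary
#' @export
glance.adjacency_summary <- function(x, ...) {
  adjacency_table_row(x)
}

#' Tidy an adjacency enrichment test
#'
#' @param x An `adjacency_test` from [enrich_regulon()].
#' @param ... Unused.
#' @return `tidy()`: one row per adjacent pair with the test context;
#'   `glance()`: a one-row tibble in the enrichment report schema
#'   (`regulon`, `species`, `M`, `N`, `j`, `p_single`, `p_value`).
#' @method tidy adjacency_test
#' @export
tidy.adjacency_test <- function(x, ...) {
  tidy(x$summary)
}

#' @rdname tidy.adjacency_test
#' @method glance adjacency_test
#' @export
glance.adjacency_test <- function(x, ...) {
  tibble::tibble(
    regulon = x$regulon,
    go_id = x$go_id,
    species = x$species,
    M = x$M,
    N = x$N,
    j = x$j,
    pct_adjacent = round(100 * x$j / x$M),
    p_single = x$p_single,
    p_value = x$p_value
  )
}

#' Tidy a co-expression report
#'
#' @param x A `coexpression_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-group tibble (group, mean offset-PCC, comparison
#'   and skip counts); `glance()`: a one-row summary with the bootstrap
#'   p-value.
#' @method tidy coexpression_report
#' @export
tidy.coexpression_report <- function(x, ...) {
  dplyr::mutate(x$groups, regulon = x$regulon, .before = 1)
}

#' @rdname tidy.coexpression_report
#' @method glance coexpression_report
#' @export
glance.coexpression_report <- function(x, ...) {
  wide <- stats::setNames(x$groups$mean_pcc, paste0("mean_pcc_", x$groups$group))
  tibble::tibble(
    regulon = x$regulon,
    !!!as.list(wide),
    bootstrap_p = x$bootstrap_p,
    iterations = x$iterations,
    offset = x$offset,
    n_excluded = length(x$excluded),
    seed = x$seed %||% NA_integer_
  )
}

#' Tidy a bootstrap null distribution
#'
#' @param x A `pcc_bootstrap` or `synteny_bootstrap`.
#' @param ... Unused.
#' @return `tidy()`: one row per iteration; `glance()`: a one-row summary.
#' @method tidy pcc_bootstrap
#' @export
tidy.pcc_bootstrap <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$draws), mean_pcc = x$draws)
}

#' @rdname tidy.pcc_bootstrap
#' @method glance pcc_bootstrap
#' @export
glance.pcc_bootstrap <- function(x, ...) {
  tibble::tibble(
    observed = x$observed,
    p_value = x$p_value,
    boot_mean = mean(x$draws, na.rm = TRUE),
    boot_q975 = unname(x$quantiles[["97.5%"]]),
    iterations = x$iterations,
    group_size = x$group_size,
    seed = x$seed %||% NA_integer_
  )
}

#' @rdname tidy.pcc_bootstrap
#' @method tidy synteny_bootstrap
#' @export
tidy.synteny_bootstrap <- function(x, ...) {
  tibble::tibble(iteration = seq_along(x$fractions),
    maintained_fraction = x$fractions)
}

#' @rdname tidy.pcc_bootstrap
#' @method glance synteny_bootstrap
#' @export
glance.synteny_bootstrap <- function(x, ...) {
  tibble::tibble(
    mean_fraction = x$mean_fraction,
    observed_fraction = x$observed_fraction,
    p_value = x$p_value,
    S = x$S,
    n_pairs_sampled = x$n_pairs_sampled,
    iterations = x$iterations,
    seed = x$seed %||% NA_integer_
  )
}

#' Tidy a conservation profile
#'
#' @param x A `conservation_profile`.
#' @param ... Unused.
#' @return `tidy()`: the long fate tibble (pair x species); `glance()`: class
#'   counts in one row.
#' @method tidy conservation_profile
#' @export
tidy.conservation_profile <- function(x, ...) {
  dplyr::left_join(x$fates,
    dplyr::select(x$classes, "pair_id", "conservation_class"),
    by = "pair_id")
}

#' @rdname tidy.conservation_profile
#' @method glance conservation_profile
#' @export
glance.conservation_profile <- function(x, ...) {
  tibble::tibble(
    regulon = x$regulon,
    n_pairs = nrow(x$classes),
    n_minimal = x$class_counts[["minimal"]],
    n_intermediate = x$class_counts[["intermediate"]],
    n_wide = x$class_counts[["wide"]]
  )
}
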