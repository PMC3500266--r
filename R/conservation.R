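#' Assemble a species panel for conservation scoring
#'
#' A panel holds, for each non-reference species, its genome annotation, an
#' ortholog map from the reference, the regulon membership in that species,
#' and a clade tag. At most one species may be tagged `"outgroup"`; the
#' outgroup anchors the "wide" conservation class.
#'
#' @param reference The reference [genome_annotation()].
#' @param entries A list of entries, each a list with fields `species`,
#'   `annotation`, `orthologs` (an [ortholog_map()]), `regulon` (character
#'   vector of target-species regulon members) and `clade`.
#' @return A `species_panel` object.
#' @export
species_panel <- function(reference, entries) {
  stopifnot(inherits(reference, "genome_annotation"))
  for (e in entries) {
    if (!all(c("species", "annotation", "orthologs", "clade") %in% names(e))) {
      rlang::abort("panel entry needs species, annotation, orthologs, clade",
        class = "adjacentome_validation_error")
    }
  }
  clades <- vapply(entries, `[[`, character(1), "clade")
  if (sum(clades == "outgroup") > 1) {
    rlang::abort("at most one panel species may be the outgroup",
      class = "adjacentome_validation_error")
  }
  names(entries) <- vapply(entries, `[[`, character(1), "species")
  structure(list(reference = reference, entries = entries),
    class = "species_panel")
}

#' @export
print.species_panel <- function(x, ...) {
  cat(sprintf("<species_panel> reference %s + %d species: %s\n",
    species(x$reference), length(x$entries),
    paste(names(x$entries), collapse = ", ")))
  invisible(x)
}

# Neighbour lookup for one annotation: for each gene, the ids of the genes at
# the previous/next position on its chromosome.
neighbour_table <- function(annotation) {
  order_genes(annotation) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(
      prev = dplyr::lag(.data$gene_id),
      nxt = dplyr::lead(.data$gene_id)
    ) |>
    dplyr::ungroup() |>
    dplyr::select("gene_id", "prev", "nxt")
}

#' Fate of one adjacent gene pair in a target species
#'
#' For a reference-species adjacent pair (left, right) and a panel entry:
#' `gene_absent` if either gene has no ortholog in the target species;
#' `same_partner` if any ortholog of left is immediately adjacent to any
#' ortholog of right; otherwise `repaired_within_regulon` if either gene's
#' ortholog is immediately adjacent to any member of the target-species
#' regulon; otherwise `unpaired`. Orientation is not required to match.
#'
#' @param left,right Reference gene ids (left first in coordinate order).
#' @param entry One panel entry (see [species_panel()]).
#' @return One of `"same_partner"`, `"repaired_within_regulon"`,
#'   `"unpaired"`, `"gene_absent"`.
#' @export
pair_fate <- function(left, right, entry) {
  links <- entry$orthologs
  lo <- links$ortholog_id[links$gene_id == left]
  ro <- links$ortholog_id[links$gene_id == right]
  if (length(lo) == 0 || length(ro) == 0) {
    return("gene_absent")
  }
  nbr <- entry$.nbr %||% neighbour_table(entry$annotation)
  for (a in lo) {
    row <- nbr[match(a, nbr$gene_id), ]
    if (!is.na(row$gene_id[1]) && any(ro %in% c(row$prev, row$nxt))) {
      return("same_partner")
    }
  }
  reg <- entry$regulon %||% character(0)
  for (a in c(lo, ro)) {
    row <- nbr[match(a, nbr$gene_id), ]
    if (!is.na(row$gene_id[1]) &&
        any(setdiff(reg, a) %in% c(row$prev, row$nxt))) {
      return("repaired_within_regulon")
    }
  }
  "unpaired"
}

#' Fates of all adjacent pairs across a panel
#'
#' @param pairs A tibble with `left` and `right` columns (e.g.
#'   `summary$pairs` from [find_adjacent_pairs()]).
#' @param panel A [species_panel()].
#' @return A long tibble: `pair_id` (`left-right`), `left`, `right`,
#'   `species`, `clade`, `fate` — the per-pair fate matrix behind conservation
#'   heat-map style reports.
#' @export
pair_fates <- function(pairs, panel) {
  pairs <- tibble::as_tibble(pairs)
  purrr::map_dfr(panel$entries, function(entry) {
    entry$.nbr <- neighbour_table(entry$annotation)
    tibble::tibble(
      pair_id = paste(pairs$left, pairs$right, sep = "-"),
      left = pairs$left,
      right = pairs$right,
      species = entry$species,
      clade = entry$clade,
      fate = vapply(seq_len(nrow(pairs)), function(i) {
        pair_fate(pairs$left[i], pairs$right[i], entry)
      }, character(1))
    )
  })
}

#' Assign a conservation class to each pair
#'
#' Classes over the fate profile of a pair across the panel:
#' `wide` if, in the outgroup species, either gene remains paired
#' (`same_partner` or `repaired_within_regulon`); `minimal` if in every
#' non-reference species the fate is `unpaired` or `gene_absent`; otherwise
#' `intermediate`. The three classes partition the pair set.
#'
#' @param fates The long fate tibble from [pair_fates()].
#' @return A tibble `pair_id`, `left`, `right`, `conservation_class`.
#' @export
assign_conservation_class <- function(fates) {
  if (!any(fates$clade == "outgroup")) {
    rlang::abort("panel has no outgroup species; cannot assign classes",
      class = "adjacentome_config_error")
  }
  paired_fates <- c("same_partner", "repaired_within_regulon")
  fates |>
    dplyr::group_by(.data$pair_id, .data$left, .data$right) |>
    dplyr::summarise(
      conservation_class = dplyr::case_when(
        any(.data$fate[.data$clade == "outgroup"] %in% paired_fates) ~ "wide",
        all(!.data$fate %in% paired_fates) ~ "minimal",
        TRUE ~ "intermediate"
      ),
      .groups = "drop"
    )
}

#' Conservation profile of a regulon's adjacent pairs
#'
#' Runs [pair_fates()] and [assign_conservation_class()] for the adjacent
#' pairs of a regulon and tallies the class counts.
#'
#' @param summary An `adjacency_summary` for the reference species.
#' @param panel A [species_panel()].
#' @return A `conservation_profile`: `fates` (long tibble), `classes`
#'   (per-pair tibble) and `class_counts`.
#' @export
conservation_profile <- function(summary, panel) {
  stopifnot(inherits(summary, "adjacency_summary"))
  fates <- pair_fates(summary$pairs, panel)
  classes <- assign_conservation_class(fates)
  counts <- table(factor(classes$conservation_class,
    levels = c("minimal", "intermediate", "wide")))
  structure(
    list(
      regulon = summary$regulon,
      fates = fates,
      classes = classes,
      class_counts = stats::setNames(as.integer(counts), names(counts))
    ),
    class = "conservation_profile"
  )
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf(
    "<conservation_profile> %s: %d pair(s) — minimal %d, intermediate %d, wide %d\n",
    x$regulon, nrow(x$classes), x$class_counts[["minimal"]],
    x$class_counts[["intermediate"]], x$class_counts[["wide"]]
  ))
  invisible(x)
}

#' Background synteny maintenance by pair resampling
#'
#' Estimates how often a random adjacent gene pair of the reference genome is
#' maintained as an adjacent pair (orthologs immediately adjacent,
#' `same_partner`) in at least one panel species. Per iteration,
#' `round(S / 2)` of the reference genome's adjacent pairs are sampled
#' (distinct within an iteration, resampled across iterations — S genes make
#' about S/2 pairs) and the maintained fraction recorded. A query pair set
#' (e.g. a regulon's pairs) can be scored against this null: the upper-tail
#' frequency of bootstrap fractions at or above the query's observed fraction
#' is returned as a p-like statistic.
#'
#' @param reference The reference [genome_annotation()].
#' @param panel A [species_panel()] (all entries are used).
#' @param S Sample size in genes (e.g. the regulon size).
#' @param iterations Bootstrap iterations (>= 10000 for final figures).
#' @param seed RNG seed.
#' @param query_pairs Optional tibble with `left`/`right` columns.
#' @return A `synteny_bootstrap`: `fractions` per iteration, `mean_fraction`,
#'   `observed_fraction` and `p_value` for the query set (NA when absent),
#'   `S`, `n_pairs_sampled`, `iterations`, `seed`.
#' @export
synteny_maintenance_bootstrap <- function(reference, panel, S,
                                          iterations = 10000, seed = NULL,
                                          query_pairs = NULL) {
  N <- n_genes(reference)
  if (S > N) {
    rlang::abort("S exceeds the genome gene count",
      class = "adjacentome_domain_error")
  }
  all_pairs <- order_genes(reference) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::reframe(
      left = .data$gene_id[-dplyr::n()],
      right = .data$gene_id[-1]
    )
  maintained <- pair_maintained(all_pairs, panel)
  n_sample <- max(1L, round(S / 2))
  if (n_sample > nrow(all_pairs)) {
    rlang::abort("sample size exceeds the number of adjacent pairs",
      class = "adjacentome_domain_error")
  }
  fractions <- with_seed(seed, vapply(seq_len(iterations), function(i) {
    mean(maintained[sample.int(length(maintained), n_sample)])
  }, numeric(1)))

  observed <- NA_real_
  p_value <- NA_real_
  if (!is.null(query_pairs) && nrow(query_pairs) > 0) {
    q <- pair_maintained(tibble::as_tibble(query_pairs), panel)
    observed <- mean(q)
    p_value <- (1 + sum(fractions >= observed)) / (iterations + 1)
  }
  structure(
    list(
      fractions = fractions,
      mean_fraction = mean(fractions),
      observed_fraction = observed,
      p_value = p_value,
      S = S,
      n_pairs_sampled = n_sample,
      iterations = iterations,
      seed = seed
    ),
    class = "synteny_bootstrap"
  )
}

# logical vector: is each (left, right) pair adjacent (same_partner) in at
# least one panel species?
pair_maintained <- function(pairs, panel) {
  hit <- rep(FALSE, nrow(pairs))
  for (entry in panel$entries) {
    nbr <- neighbour_table(entry$annotation)
    links <- entry$orthologs
    lo <- split(links$ortholog_id, links$gene_id)
    todo <- which(!hit)
    for (i in todo) {
      a <- lo[[pairs$left[i]]]
      b <- lo[[pairs$right[i]]]
      if (is.null(a) || is.null(b)) next
      rows <- nbr[match(a, nbr$gene_id), , drop = FALSE]
      if (any(b %in% c(rows$prev, rows$nxt), na.rm = TRUE)) hit[i] <- TRUE
    }
  }
  hit
}

#' @export
print.synteny_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<synteny_bootstrap> %d iterations of %d pairs (S = %d genes): mean maintained fraction %.3f\n",
    x$iterations, x$n_pairs_sampled, x$S, x$mean_fraction
  ))
  if (!is.na(x$observed_fraction)) {
    cat(sprintf("  query set: %.3f maintained (upper-tail p = %.4g)\n",
      x$observed_fraction, x$p_value))
  }
  invisible(x)
}

#' Mean expression level per conservation class
#'
#' Averages a user-supplied per-gene expression level (absolute mRNA levels in
#' typical use) over all genes of all pairs in each conservation class.
#'
#' @param classes The per-pair class tibble from
#'   [assign_conservation_class()] or a [conservation_profile()].
#' @param levels A data frame with columns `gene_id` and `level`, or a named
#'   numeric vector.
#' @return A tibble `conservation_class`, `n_genes`, `mean_level` (NA for an
#'   empty class), with all three classes always present.
#' @export
expression_by_conservation_class <- function(classes, levels) {
  if (inherits(classes, "conservation_profile")) classes <- classes$classes
  if (!is.data.frame(levels)) {
    levels <- tibble::tibble(gene_id = names(levels), level = unname(levels))
  }
  genes <- classes |>
    tidyr::pivot_longer(c("left", "right"), values_to = "gene_id") |>
    dplyr::distinct(.data$conservation_class, .data$gene_id) |>
    dplyr::left_join(levels, by = "gene_id")
  genes |>
    dplyr::mutate(conservation_class = factor(.data$conservation_class,
      levels = c("minimal", "intermediate", "wide"))) |>
    dplyr::group_by(.data$conservation_class, .drop = FALSE) |>
    dplyr::summarise(
      n_genes = sum(!is.na(.data$level)),
      mean_level = if (all(is.na(.data$level))) NA_real_ else
        mean(.data$level, na.rm = TRUE),
      .groups = "drop"
    )
}
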