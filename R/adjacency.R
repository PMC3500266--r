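#' Order genes along each chromosome
#'
#' Produces the per-chromosome gene order that defines immediate adjacency:
#' genes are sorted by `(start, end, gene_id)` within each chromosome, giving a
#' deterministic total order even for overlapping or nested genes, and indexed
#' by `pos`. Two genes are immediately adjacent iff they sit on the same
#' chromosome at consecutive `pos`.
#'
#' @param annotation A [genome_annotation()].
#' @return A tibble with the annotation columns plus an integer `pos` column,
#'   ordered by chromosome then position.
#' @export
order_genes <- function(annotation) {
  tibble::as_tibble(annotation) |>
    dplyr::arrange(.data$chromosome, .data$start, .data$end, .data$gene_id) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(pos = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Classify the orientation of an adjacent gene pair
#'
#' With the left gene first in coordinate order: a `(-,+)` pair is transcribed
#' away from itself (divergent, candidate bidirectional promoter), same-strand
#' pairs are tandem, and `(+,-)` pairs are transcribed toward each other
#' (convergent).
#'
#' @param left_strand,right_strand Strand symbols (`"+"`/`"-"`), vectorized.
#' @return Character vector in `c("divergent", "tandem", "convergent")`.
#' @examples
#' classify_orientation("-", "+") # divergent
#' classify_orientation(c("+", "+"), c("+", "-"))
#' @export
classify_orientation <- function(left_strand, right_strand) {
  ok <- left_strand %in% c("+", "-") & right_strand %in% c("+", "-")
  if (!all(ok)) {
    rlang::abort("strand symbols must be '+' or '-'",
      class = "adjacentome_validation_error")
  }
  dplyr::case_when(
    left_strand == "-" & right_strand == "+" ~ "divergent",
    left_strand == right_strand ~ "tandem",
    TRUE ~ "convergent"
  )
}

#' Find immediately adjacent gene pairs within a regulon
#'
#' Scans each chromosome's ordered gene list for regulon members at consecutive
#' positions (no intervening annotated gene of any kind). Maximal streaks of
#' consecutive members form runs: a run of length L contributes L - 1 pairs and
#' L adjacent genes, so a triplet yields 2 pairs, a quadruplet 3. The adjacent
#' gene count `j` — the number of distinct regulon genes with at least one
#' immediately adjacent regulon neighbour — is the test statistic of
#' [adjacency_pvalue()].
#'
#' @param annotation A [genome_annotation()].
#' @param regulon A [regulon()] (or a character vector of gene ids).
#' @return An `adjacency_summary`: list with `regulon`, `M`, `j`, a `pairs`
#'   tibble (`left`, `right`, `chromosome`, strands, `orientation`, `run_id`),
#'   a `runs` tibble (`run_id`, `chromosome`, `genes`, `length`),
#'   `orientation_counts`, `missing_members` and `n_present`.
#' @export
find_adjacent_pairs <- function(annotation, regulon) {
  regulon <- as_regulon(regulon)
  ordered <- order_genes(annotation)
  present <- regulon$members[regulon$members %in% ordered$gene_id]
  missing_members <- setdiff(regulon$members, present)

  members <- ordered |>
    dplyr::filter(.data$gene_id %in% present) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(
      new_run = c(TRUE, diff(.data$pos) != 1L),
      run_key = cumsum(.data$new_run)
    ) |>
    dplyr::ungroup()

  if (nrow(members) == 0) {
    rlang::warn(paste0("no members of '", regulon$name, "' found in annotation"))
  }

  runs <- members |>
    dplyr::group_by(.data$chromosome, .data$run_key) |>
    dplyr::summarise(
      genes = list(.data$gene_id),
      length = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$length >= 2L) |>
    dplyr::mutate(run_id = dplyr::row_number()) |>
    dplyr::select("run_id", "chromosome", "genes", "length")

  pairs <- runs |>
    dplyr::mutate(pair = purrr::map(.data$genes, function(g) {
      tibble::tibble(left = g[-length(g)], right = g[-1])
    })) |>
    dplyr::select("run_id", "chromosome", "pair") |>
    tidyr::unnest("pair")

  strand_of <- stats::setNames(ordered$strand, ordered$gene_id)
  if (nrow(pairs) > 0) {
    pairs <- pairs |>
      dplyr::mutate(
        left_strand = unname(strand_of[.data$left]),
        right_strand = unname(strand_of[.data$right]),
        orientation = classify_orientation(.data$left_strand, .data$right_strand)
      ) |>
      dplyr::select("left", "right", "chromosome", "left_strand",
        "right_strand", "orientation", "run_id")
  } else {
    pairs <- tibble::tibble(
      left = character(), right = character(), chromosome = character(),
      left_strand = character(), right_strand = character(),
      orientation = character(), run_id = integer()
    )
  }

  counts <- table(factor(pairs$orientation,
    levels = c("divergent", "tandem", "convergent")))

  structure(
    list(
      regulon = regulon$name,
      go_id = regulon$go_id,
      M = regulon$M,
      j = sum(runs$length),
      pairs = pairs,
      runs = runs,
      orientation_counts = stats::setNames(as.integer(counts), names(counts)),
      missing_members = missing_members,
      present_members = present,
      n_present = length(present)
    ),
    class = "adjacency_summary"
  )
}

#' @export
print.adjacency_summary <- function(x, ...) {
  cat(sprintf(
    "<adjacency_summary> %s: M = %d, j = %d adjacent genes (%d%%), %d pair(s) in %d run(s)\n",
    x$regulon, x$M, x$j, round(100 * x$j / x$M), nrow(x$pairs), nrow(x$runs)
  ))
  if (nrow(x$pairs) > 0) {
    cnt <- x$orientation_counts
    cat(sprintf("  divergent %d | tandem %d | convergent %d\n",
      cnt[["divergent"]], cnt[["tandem"]], cnt[["convergent"]]))
  }
  if (length(x$missing_members) > 0) {
    cat(sprintf("  %d member(s) absent from annotation\n",
      length(x$missing_members)))
  }
  invisible(x)
}

#' Summarise adjacency as a one-row report table
#'
#' One row in the schema of the per-regulon summary tables: regulon name, GO
#' accession, regulon size M, adjacent gene count j, the rounded percentage
#' `100 j / M`, pair and orientation counts, semicolon-joined runs, and any
#' regulon members absent from the annotation.
#'
#' @param summary An `adjacency_summary` from [find_adjacent_pairs()].
#' @return A one-row tibble.
#' @export
adjacency_table_row <- function(summary) {
  stopifnot(inherits(summary, "adjacency_summary"))
  runs <- vapply(summary$runs$genes, paste, character(1), collapse = ",")
  tibble::tibble(
    regulon = summary$regulon,
    go_id = summary$go_id,
    M = summary$M,
    j = summary$j,
    pct_adjacent = round(100 * summary$j / summary$M),
    n_pairs = nrow(summary$pairs),
    n_divergent = summary$orientation_counts[["divergent"]],
    n_tandem = summary$orientation_counts[["tandem"]],
    n_convergent = summary$orientation_counts[["convergent"]],
    runs = paste(runs, collapse = ";"),
    missing_members = paste(summary$missing_members, collapse = ";")
  )
}
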