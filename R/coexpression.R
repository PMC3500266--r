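#' Offset-normalized Pearson similarity of two expression profiles
#'
#' Correlation relative to a reference expression state rather than the
#' profile mean: with residuals taken from an offset `G_offset`, the
#' similarity of profiles X and Y over N shared conditions is
#' \deqn{S_{X,Y} = \frac{1}{N}\sum_{i=1}^{N}
#'   \frac{X_i - X_{off}}{\phi_X}\,\frac{Y_i - Y_{off}}{\phi_Y},
#'   \qquad \phi_G = \sqrt{\tfrac{1}{N}\sum_i (G_i - G_{off})^2}.}
#' With `offset = "mean"` this is algebraically the classical (population)
#' Pearson correlation; with `offset = "first"` the reference state is the
#' pre-perturbation measurement, so S rewards profiles that move in the same
#' direction *away from baseline*, the natural choice for stress-response
#' time-courses. `|S| <= 1` by Cauchy-Schwarz.
#'
#' Conditions missing (`NA`) in either profile are dropped pairwise; fewer
#' than 3 shared conditions, or a constant profile (`phi = 0`), yields `NA`
#' (callers skip and count these).
#'
#' @param x,y Numeric expression profiles over the same conditions.
#' @param offset `"first"`, `"mean"`, or `"explicit"`.
#' @param x_offset,y_offset Reference values when `offset = "explicit"`.
#' @return The similarity in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' offset_pcc(c(0, 1, 2), c(0, 2, 1), offset = "explicit", x_offset = 0, y_offset = 0)
#' @export
offset_pcc <- function(x, y, offset = c("first", "mean", "explicit"),
                       x_offset = NULL, y_offset = NULL) {
  offset <- match.arg(offset)
  if (length(x) != length(y)) {
    rlang::abort("profiles differ in length", class = "adjacentome_validation_error")
  }
  shared <- !is.na(x) & !is.na(y)
  if (sum(shared) < 3) {
    return(NA_real_)
  }
  xs <- x[shared]
  ys <- y[shared]
  offs <- switch(offset,
    first = c(xs[1], ys[1]),
    mean = c(mean(xs), mean(ys)),
    explicit = {
      if (is.null(x_offset) || is.null(y_offset)) {
        rlang::abort("explicit offsets require x_offset and y_offset",
          class = "adjacentome_validation_error")
      }
      c(x_offset, y_offset)
    }
  )
  xr <- xs - offs[1]
  yr <- ys - offs[2]
  phi_x <- sqrt(mean(xr^2))
  phi_y <- sqrt(mean(yr^2))
  if (phi_x == 0 || phi_y == 0) {
    return(NA_real_)
  }
  s <- mean((xr / phi_x) * (yr / phi_y))
  min(max(s, -1), 1)
}

# Pairwise offset-PCC matrix for a set of genes. Without missing values the
# similarity is a cross-product of offset-normalized residual rows; with NAs
# each pair falls back to offset_pcc() on its shared conditions.
pcc_matrix <- function(exprs, genes, offset = "first") {
  stopifnot(inherits(exprs, "expression_matrix"))
  idx <- match(genes, exprs$gene_id)
  if (anyNA(idx)) {
    rlang::abort(paste0("gene absent from expression matrix: ",
      genes[which(is.na(idx))[1]]), class = "adjacentome_validation_error")
  }
  vals <- as.matrix(exprs[idx, -1, drop = FALSE])
  rownames(vals) <- genes
  n <- length(genes)
  if (!anyNA(vals)) {
    off <- switch(offset,
      first = vals[, 1],
      mean = rowMeans(vals),
      rlang::abort("explicit offsets are per-pair; use offset_pcc()",
        class = "adjacentome_validation_error")
    )
    res <- vals - off
    phi <- sqrt(rowMeans(res^2))
    u <- res / (phi * sqrt(ncol(vals)))
    s <- tcrossprod(u)
    s[!is.finite(s)] <- NA_real_
    s <- pmin(pmax(s, -1), 1)
  } else {
    s <- matrix(NA_real_, n, n, dimnames = list(genes, genes))
    for (i in seq_len(n)) {
      s[i, i] <- 1
      for (k in seq_len(i - 1L)) {
        s[i, k] <- s[k, i] <- offset_pcc(vals[i, ], vals[k, ], offset = offset)
      }
    }
  }
  diag(s) <- 1
  s
}

#' Classify a regulon's comparison groups
#'
#' Splits the regulon members (restricted to genes with expression data) into
#' the three comparison classes used for group-average correlations:
#' comparisons among *unpaired* genes, comparisons between the two genes of an
#' *adjacent pair*, and comparisons among paired genes excluding each gene's
#' own adjacent partner (*paired, not adjacent*).
#'
#' @param summary An `adjacency_summary` from [find_adjacent_pairs()].
#' @param exprs An [expression_matrix()], used to drop genes without data.
#' @return A `pair_class_groups` list: `unpaired` and `paired` gene-id
#'   vectors, `adjacent_pairs` tibble, `excluded` (members lacking expression
#'   data), and the comparison counts per class.
#' @export
classify_regulon_pairs <- function(summary, exprs) {
  stopifnot(inherits(summary, "adjacency_summary"))
  present <- summary$present_members
  with_data <- present[present %in% exprs$gene_id]
  excluded <- setdiff(present, with_data)

  paired_all <- unique(c(summary$pairs$left, summary$pairs$right))
  paired <- intersect(paired_all, with_data)
  unpaired <- setdiff(with_data, paired_all)
  adj <- summary$pairs |>
    dplyr::filter(.data$left %in% with_data & .data$right %in% with_data) |>
    dplyr::select("left", "right")

  n_paired_cmp <- choose(length(paired), 2) - nrow(adj)
  structure(
    list(
      unpaired = unpaired,
      paired = paired,
      adjacent_pairs = adj,
      excluded = excluded,
      n_comparisons = c(
        unpaired = choose(length(unpaired), 2),
        adjacent = nrow(adj),
        paired_not_adjacent = n_paired_cmp
      )
    ),
    class = "pair_class_groups"
  )
}

#' Mean offset-PCC over a comparison group
#'
#' @param comparisons Either a character vector of gene ids (all unordered
#'   pairs are compared) or a two-column data frame of explicit comparisons.
#' @param exprs An [expression_matrix()].
#' @param offset Offset mode passed to [offset_pcc()].
#' @param exclude Optional two-column data frame of comparisons to leave out
#'   (e.g. adjacent partners when averaging the paired set).
#' @return A list with `mean` (NA if no valid comparison), `n` (valid
#'   comparisons) and `n_skipped` (undefined similarities).
#' @export
mean_group_pcc <- function(comparisons, exprs, offset = "first", exclude = NULL) {
  if (is.data.frame(comparisons)) {
    pairs <- tibble::as_tibble(comparisons)[, 1:2]
    names(pairs) <- c("a", "b")
  } else {
    genes <- unique(comparisons)
    if (length(genes) < 2) {
      return(list(mean = NA_real_, n = 0L, n_skipped = 0L))
    }
    cmb <- utils::combn(genes, 2)
    pairs <- tibble::tibble(a = cmb[1, ], b = cmb[2, ])
  }
  if (!is.null(exclude) && nrow(pairs) > 0) {
    ex <- tibble::as_tibble(exclude)[, 1:2]
    key <- function(u, v) paste(pmin(u, v), pmax(u, v))
    pairs <- pairs[!key(pairs$a, pairs$b) %in% key(ex[[1]], ex[[2]]), ]
  }
  if (nrow(pairs) == 0) {
    return(list(mean = NA_real_, n = 0L, n_skipped = 0L))
  }
  genes <- unique(c(pairs$a, pairs$b))
  s <- pcc_matrix(exprs, genes, offset = offset)
  vals <- s[cbind(match(pairs$a, genes), match(pairs$b, genes))]
  list(
    mean = if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE),
    n = sum(!is.na(vals)),
    n_skipped = sum(is.na(vals))
  )
}

#' Bootstrap null for a group-average correlation
#'
#' Draws `iterations` random groupings of `group_size` distinct genes from
#' `members`, computes each grouping's mean pairwise offset-PCC, and returns
#' the one-sided upper-tail p-value
#' `p = (1 + #[boot >= observed]) / (iterations + 1)` together with the
#' bootstrap distribution. Groupings are resampled independently across
#' iterations (a gene can recur across, not within, groupings).
#'
#' @param exprs An [expression_matrix()].
#' @param members Gene ids to resample from (regulon members with data).
#' @param observed_mean The observed group-average similarity.
#' @param group_size Genes per random grouping (the paired-subset size).
#' @param offset Offset mode.
#' @param iterations Number of random groupings (>= 10000 for final figures;
#'   smaller values are fine for exploration).
#' @param seed RNG seed; recorded in the result.
#' @return A `pcc_bootstrap` list: `p_value`, `observed`, `draws`,
#'   `quantiles`, `iterations`, `group_size`, `seed`.
#' @export
bootstrap_mean_pcc_pvalue <- function(exprs, members, observed_mean, group_size,
                                      offset = "first", iterations = 10000,
                                      seed = NULL) {
  if (group_size > length(members)) {
    rlang::abort("group_size exceeds number of available genes",
      class = "adjacentome_domain_error")
  }
  if (iterations < 1) {
    rlang::abort("iterations must be >= 1", class = "adjacentome_domain_error")
  }
  s <- pcc_matrix(exprs, members, offset = offset)
  n <- length(members)
  draws <- with_seed(seed, vapply(seq_len(iterations), function(i) {
    g <- sample.int(n, group_size)
    sub <- s[g, g]
    mean(sub[upper.tri(sub)], na.rm = TRUE)
  }, numeric(1)))
  p <- (1 + sum(draws >= observed_mean, na.rm = TRUE)) / (iterations + 1)
  structure(
    list(
      p_value = p,
      observed = observed_mean,
      draws = draws,
      quantiles = stats::quantile(draws, c(0.025, 0.25, 0.5, 0.75, 0.975),
        na.rm = TRUE),
      iterations = iterations,
      group_size = group_size,
      seed = seed
    ),
    class = "pcc_bootstrap"
  )
}

#' @export
print.pcc_bootstrap <- function(x, ...) {
  cat(sprintf(
    "<pcc_bootstrap> observed mean S = %.3f vs %d random groupings of %d genes: p = %.4g\n",
    x$observed, x$iterations, x$group_size, x$p_value
  ))
  invisible(x)
}

#' Group-average co-expression report for a regulon
#'
#' The full co-expression stage: classifies the regulon's comparison groups,
#' averages the offset-PCC within each (unpaired, adjacent, paired-not-
#' adjacent), and bootstraps the significance of the paired subset's average
#' against random groupings of the same size drawn from the regulon.
#'
#' @param annotation A [genome_annotation()].
#' @param regulon A [regulon()] or character vector.
#' @param exprs An [expression_matrix()].
#' @param offset Offset mode (`"first"` for time-courses, `"mean"` for the
#'   classical Pearson correlation).
#' @param iterations Bootstrap iterations.
#' @param seed RNG seed, recorded in the report.
#' @return A `coexpression_report` with a per-group tibble, the bootstrap
#'   object and bookkeeping fields.
#' @export
coexpression_report <- function(annotation, regulon, exprs, offset = "first",
                                iterations = 10000, seed = NULL) {
  regulon <- as_regulon(regulon)
  summary <- find_adjacent_pairs(annotation, regulon)
  groups <- classify_regulon_pairs(summary, exprs)

  unp <- mean_group_pcc(groups$unpaired, exprs, offset = offset)
  adj <- mean_group_pcc(groups$adjacent_pairs, exprs, offset = offset)
  pna <- mean_group_pcc(groups$paired, exprs, offset = offset,
    exclude = groups$adjacent_pairs)

  group_tbl <- tibble::tibble(
    group = c("unpaired", "adjacent", "paired_not_adjacent"),
    mean_pcc = c(unp$mean, adj$mean, pna$mean),
    n_comparisons = c(unp$n, adj$n, pna$n),
    n_skipped = c(unp$n_skipped, adj$n_skipped, pna$n_skipped)
  )

  boot <- NULL
  members_with_data <- c(groups$unpaired, groups$paired)
  paired_mean <- mean_group_pcc(groups$paired, exprs, offset = offset)$mean
  if (length(groups$paired) >= 2 &&
      length(members_with_data) >= length(groups$paired) && !is.na(paired_mean)) {
    boot <- bootstrap_mean_pcc_pvalue(
      exprs, members_with_data,
      observed_mean = paired_mean,
      group_size = length(groups$paired),
      offset = offset, iterations = iterations, seed = seed
    )
  }

  structure(
    list(
      regulon = regulon$name,
      groups = group_tbl,
      observed_paired_mean = paired_mean,
      bootstrap = boot,
      bootstrap_p = if (is.null(boot)) NA_real_ else boot$p_value,
      excluded = groups$excluded,
      offset = offset,
      iterations = iterations,
      seed = seed
    ),
    class = "coexpression_report"
  )
}

#' @export
print.coexpression_report <- function(x, ...) {
  cat(sprintf("<coexpression_report> %s (offset = %s)\n", x$regulon, x$offset))
  print(x$groups)
  if (!is.na(x$bootstrap_p)) {
    cat(sprintf("paired subset vs %d random groupings: p = %.4g (seed %s)\n",
      x$iterations, x$bootstrap_p, x$seed %||% "none"))
  }
  invisible(x)
}
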