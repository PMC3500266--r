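#' Per-gene pairing probability
#'
#' The chance that a given gene has at least one of its two flanking
#' neighbours inside a regulon of M genes drawn from a genome of N genes:
#' by inclusion-exclusion, `p = 2(M/N) - (M/N)^2`. This is the success
#' probability of the binomial adjacency test.
#'
#' @param M Regulon size.
#' @param N Total number of protein-coding genes in the genome.
#' @return Probability in `[0, 1]`; vectorized over `M` and `N`.
#' @examples
#' pairing_probability(180, 5797)
#' @export
pairing_probability <- function(M, N) {
  if (any(N <= 0) || any(M < 1) || any(M > N)) {
    rlang::abort("need 1 <= M <= N and N > 0",
      class = "adjacentome_domain_error")
  }
  f <- M / N
  2 * f - f^2
}

#' Binomial tail significance of gene adjacency
#'
#' The chance probability of observing more than `j` adjacent genes in a
#' regulon of `M` genes within an `N`-gene genome, modelling each member
#' independently as adjacent to another member with probability
#' `p = 2(M/N) - (M/N)^2`:
#' \deqn{P = 1 - \sum_{k=0}^{j} \binom{M}{k} p^k (1-p)^{M-k}}
#' i.e. the strict upper tail `P(X > j)` of a Binomial(M, p). The sum is
#' evaluated in log space (log-gamma binomial coefficients, log-sum-exp over
#' the upper-tail terms), so values down to the smallest normal double are
#' exact to full precision; anything below is reported as 0.
#'
#' @param M Regulon size.
#' @param j Observed count of adjacent regulon genes.
#' @param N Genome gene count.
#' @param p Per-gene pairing probability; defaults to
#'   [pairing_probability()]`(M, N)`.
#' @return Tail probability in `[0, 1]`; vectorized over `M`, `j`, `N`.
#' @examples
#' adjacency_pvalue(18, 4, 5797) # heat-shock regulon scale
#' adjacency_pvalue(282, 44, 5797)
#' @export
adjacency_pvalue <- function(M, j, N, p = pairing_probability(M, N)) {
  args <- vctrs_recycle(M = M, j = j, N = N, p = p)
  if (any(args$j < 0) || any(args$j > args$M) || any(args$M > args$N)) {
    rlang::abort("need 0 <= j <= M <= N", class = "adjacentome_domain_error")
  }
  vapply(seq_along(args$M), function(i) {
    binom_upper_tail(args$M[i], args$j[i], args$p[i])
  }, numeric(1))
}

# P(X > j) for X ~ Binomial(M, prob), log-space summation of the upper tail.
binom_upper_tail <- function(M, j, prob) {
  if (j >= M) return(0)
  if (prob <= 0) return(0)
  if (prob >= 1) return(1)
  k <- seq.int(j + 1L, M)
  log_terms <- lchoose(M, k) + k * log(prob) + (M - k) * log1p(-prob)
  m <- max(log_terms)
  val <- exp(m) * sum(exp(log_terms - m))
  min(max(val, 0), 1)
}

vctrs_recycle <- function(...) {
  args <- list(...)
  n <- max(lengths(args))
  lapply(args, rep_len, length.out = n)
}

#' Test a regulon for adjacency enrichment
#'
#' Composes [find_adjacent_pairs()] with [adjacency_pvalue()], taking `N` from
#' the annotation. The result carries the adjacency summary so pair-level
#' detail stays available.
#'
#' @param annotation A [genome_annotation()].
#' @param regulon A [regulon()] or character vector of gene ids.
#' @return An `adjacency_test` object with fields `regulon`, `M`, `N`, `j`,
#'   `p_single` (per-gene pairing probability), `p_value`, and `summary`.
#' @export
enrich_regulon <- function(annotation, regulon) {
  regulon <- as_regulon(regulon)
  summary <- find_adjacent_pairs(annotation, regulon)
  N <- n_genes(annotation)
  if (regulon$M > N) {
    rlang::abort("regulon larger than genome", class = "adjacentome_domain_error")
  }
  p <- pairing_probability(regulon$M, N)
  structure(
    list(
      regulon = regulon$name,
      go_id = regulon$go_id,
      species = species(annotation),
      M = regulon$M,
      N = N,
      j = summary$j,
      p_single = p,
      p_value = adjacency_pvalue(regulon$M, summary$j, N, p),
      summary = summary
    ),
    class = "adjacency_test"
  )
}

#' @export
print.adjacency_test <- function(x, ...) {
  cat(sprintf(
    "<adjacency_test> %s in %s: j = %d of M = %d (N = %d), P = %s\n",
    x$regulon, x$species, x$j, x$M, x$N, format_pvalue(x$p_value)
  ))
  invisible(x)
}

#' Enrichment table for several regulons
#'
#' @param annotation A [genome_annotation()].
#' @param regulons A list of [regulon()] objects (e.g. from [read_gmt()]).
#' @return A tibble, one row per regulon, in the per-regulon report schema.
#' @export
enrich_regulons <- function(annotation, regulons) {
  if (inherits(regulons, "regulon")) regulons <- list(regulons)
  purrr::map_dfr(regulons, function(r) glance(enrich_regulon(annotation, r)))
}
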