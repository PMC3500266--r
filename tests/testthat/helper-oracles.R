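# Independent oracles and small fixture builders used across the suite.

# Brute-force adjacency oracle: for every unordered pair of regulon genes on
# one chromosome, count the genes strictly between them in the sorted order;
# the pair is adjacent iff nothing intervenes. Deliberately quadratic and
# independent of the package's run-scan implementation.
brute_force_pairs <- function(annotation, members) {
  ord <- tibble::as_tibble(annotation)
  ord <- ord[order(ord$chromosome, ord$start, ord$end, ord$gene_id), ]
  out <- list()
  for (chr in unique(ord$chromosome)) {
    genes <- ord$gene_id[ord$chromosome == chr]
    hits <- which(genes %in% members)
    if (length(hits) < 2) next
    for (a in seq_along(hits)[-length(hits)]) {
      for (b in (a + 1):length(hits)) {
        if (hits[b] - hits[a] == 1) {
          out[[length(out) + 1]] <- c(genes[hits[a]], genes[hits[b]], chr)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(left = character(), right = character(),
      chromosome = character()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(left = m[, 1], right = m[, 2], chromosome = m[, 3])
}

# Direct-summation binomial upper tail: exact term recursion in plain doubles,
# t_{k+1} = t_k * (M - k) / (k + 1) * p / (1 - p), started at t_0 = (1-p)^M.
# Accurate while the leading tail term stays above the underflow floor.
naive_binom_tail <- function(M, j, p) {
  t_k <- (1 - p)^M
  total <- 0
  for (k in 0:(M - 1)) {
    if (k > j) total <- total + t_k
    t_k <- t_k * (M - k) / (k + 1) * p / (1 - p)
  }
  if (M > j) total <- total + t_k
  total
}

# Offset-first residual scale of the default synthetic latent response; used
# to set noise levels that target specific expected correlations.
latent_scale <- function(n_conditions) {
  t <- seq(0, 1, length.out = n_conditions)
  latent <- -2 * (1 - exp(-5 * t))
  sqrt(mean((latent - latent[1])^2))
}

tiny_annotation <- function(starts, strands = NULL, chromosome = "chr1",
                            ids = NULL, width = 50L) {
  n <- length(starts)
  genome_annotation(tibble::tibble(
    gene_id = ids %||% paste0("g", seq_len(n)),
    chromosome = chromosome,
    start = as.integer(starts),
    end = as.integer(starts + width),
    strand = strands %||% rep("+", n)
  ), species = "toy")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A hand-built two-species panel where the target genome is the reference
# with renamed ids, so every reference pair is trivially maintained.
identity_panel <- function(annotation, members, clades = c("sensu_strictu", "outgroup")) {
  entries <- lapply(seq_along(clades), function(i) {
    sp <- paste0("id", i)
    genes <- tibble::as_tibble(annotation)
    genes$gene_id <- paste0(sp, "_", genes$gene_id)
    list(
      species = sp,
      annotation = genome_annotation(genes, species = sp),
      orthologs = ortholog_map(tibble::tibble(
        gene_id = annotation$gene_id,
        ortholog_id = paste0(sp, "_", annotation$gene_id)
      )),
      regulon = paste0(sp, "_", members),
      clade = clades[i]
    )
  })
  species_panel(annotation, entries)
}
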