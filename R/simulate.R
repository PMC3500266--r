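#' Generate a synthetic genome annotation
#'
#' Lays out `n_chromosomes` chromosomes of non-overlapping genes with lengths
#' and intergenic gaps drawn uniformly from the given ranges and strands drawn
#' independently. Output is fully deterministic under a seed and is a regular
#' [genome_annotation()], so it exercises the same code paths as real input.
#'
#' @param n_genes Total gene count N.
#' @param n_chromosomes Number of chromosomes (genes are split evenly).
#' @param gene_length,spacing Integer ranges `c(min, max)` in bp.
#' @param prob_plus Probability of the `+` strand.
#' @param species Species label.
#' @param seed RNG seed.
#' @return A [genome_annotation()].
#' @examples
#' gen <- generate_genome(100, n_chromosomes = 2, seed = 7)
#' n_genes(gen)
#' @export
generate_genome <- function(n_genes, n_chromosomes = 2,
                            gene_length = c(500L, 2000L),
                            spacing = c(100L, 1000L),
                            prob_plus = 0.5, species = "synthetica",
                            seed = NULL) {
  if (n_genes < n_chromosomes || n_chromosomes < 1) {
    rlang::abort("need n_genes >= n_chromosomes >= 1",
      class = "adjacentome_generation_error")
  }
  if (gene_length[1] < 1 || spacing[1] < 1) {
    rlang::abort("gene lengths and spacings must be positive",
      class = "adjacentome_generation_error")
  }
  with_seed(seed, {
    chrom <- sort(rep_len(seq_len(n_chromosomes), n_genes))
    width <- floor(stats::runif(n_genes, gene_length[1], gene_length[2] + 1))
    gap <- floor(stats::runif(n_genes, spacing[1], spacing[2] + 1))
    strand <- ifelse(stats::runif(n_genes) < prob_plus, "+", "-")
    genes <- tibble::tibble(
      gene_id = sprintf("g%05d", seq_len(n_genes)),
      chromosome = paste0("chr", chrom),
      width = as.integer(width),
      gap = as.integer(gap),
      strand = strand
    ) |>
      dplyr::group_by(.data$chromosome) |>
      dplyr::mutate(
        start = cumsum(dplyr::lag(.data$width + .data$gap, default = 1L)),
        end = .data$start + .data$width - 1L
      ) |>
      dplyr::ungroup() |>
      dplyr::select("gene_id", "chromosome", "start", "end", "strand")
    genome_annotation(genes, species = species)
  })
}

#' Plant a regulon with known adjacency structure
#'
#' Selects `M` regulon members so that the adjacent structure is exactly the
#' requested run-length multiset — e.g. `runs = c(2, 2, 3)` plants two pairs
#' and one triplet (j = 7) — and the remaining `M - sum(runs)` members are
#' singletons with no regulon neighbour. Placement is rejection-sampled (cap
#' `max_tries`) so no unplanned adjacency can arise, and strands inside the
#' planted runs are adjusted to satisfy the requested pair orientations. A
#' verification pass re-runs [find_adjacent_pairs()] and asserts the planted
#' structure was recovered rather than trusting construction.
#'
#' @param annotation A [genome_annotation()] (will be strand-adjusted).
#' @param M Regulon size.
#' @param runs Integer vector of planted run lengths (each >= 2); may be
#'   empty for a fully unpaired regulon.
#' @param orientations Optional character vector, one orientation per planted
#'   pair (`sum(runs - 1)` entries, in run order), from
#'   `c("divergent", "tandem", "convergent")`. Default: random strands.
#' @param name Regulon name.
#' @param seed RNG seed.
#' @param max_tries Rejection-sampling cap.
#' @return A `planted_regulon` list: `annotation` (strand-adjusted),
#'   `regulon`, and `planted` (the realised `j`, `run_lengths`,
#'   `orientations`).
#' @export
plant_regulon <- function(annotation, M, runs = integer(),
                          orientations = NULL, name = "planted",
                          seed = NULL, max_tries = 1000) {
  runs <- as.integer(runs)
  if (any(runs < 2)) {
    rlang::abort("planted runs must have length >= 2",
      class = "adjacentome_generation_error")
  }
  j <- sum(runs)
  if (j > M) {
    rlang::abort("sum of run lengths exceeds M",
      class = "adjacentome_generation_error")
  }
  n_pairs <- sum(pmax(runs - 1L, 0L))
  if (!is.null(orientations)) {
    if (length(orientations) != n_pairs) {
      rlang::abort("need one orientation per planted pair",
        class = "adjacentome_generation_error")
    }
    if (!all(orientations %in% c("divergent", "tandem", "convergent"))) {
      rlang::abort("unknown orientation", class = "adjacentome_generation_error")
    }
  }
  ordered <- order_genes(annotation)

  with_seed(seed, {
    placement <- NULL
    for (try in seq_len(max_tries)) {
      placement <- try_place_regulon(ordered, M, runs)
      if (!is.null(placement)) break
    }
    if (is.null(placement)) {
      rlang::abort(
        "could not place the regulon without unplanned adjacencies; increase genome size",
        class = "adjacentome_generation_error"
      )
    }
    ann <- annotation
    if (!is.null(orientations) && length(runs) > 0) {
      strands <- solve_run_strands(runs, orientations, max_tries)
      if (is.null(strands)) {
        rlang::abort("orientation quota is infeasible for the planted runs",
          class = "adjacentome_generation_error")
      }
      run_genes <- unlist(placement$run_genes)
      ann$strand[match(run_genes, ann$gene_id)] <- unlist(strands)
    }
    reg <- regulon(placement$members, name = name)

    # verification pass: the planted structure must be exactly recovered
    check <- find_adjacent_pairs(genome_annotation(ann, species(ann)), reg)
    ok <- check$j == j &&
      identical(sort(check$runs$length), sort(runs)) &&
      (is.null(orientations) ||
        identical(sort(check$pairs$orientation), sort(orientations)))
    if (!ok) {
      rlang::abort("planted regulon failed verification",
        class = "adjacentome_generation_error")
    }

    structure(
      list(
        annotation = genome_annotation(ann, species(ann)),
        regulon = reg,
        planted = list(
          j = j,
          run_lengths = runs,
          orientations = orientations,
          run_genes = placement$run_genes
        )
      ),
      class = "planted_regulon"
    )
  })
}

# One placement attempt: choose run anchor positions and singleton positions
# such that every planted block (run or singleton) is flanked by non-members.
# Returns NULL on collision.
try_place_regulon <- function(ordered, M, runs) {
  ordered <- dplyr::mutate(ordered, idx = dplyr::row_number())
  chrom_sizes <- table(ordered$chromosome)
  taken <- rep(FALSE, nrow(ordered)) # member or buffer positions
  run_genes <- vector("list", length(runs))

  place_block <- function(len) {
    # candidate start indices where the block fits within one chromosome
    cand <- which(!taken)
    cand <- cand[sample.int(length(cand))]
    for (s in cand) {
      block <- s:(s + len - 1L)
      if (max(block) > nrow(ordered)) next
      if (length(unique(ordered$chromosome[block])) != 1) next
      buffer <- unique(pmax(1L, min(block) - 1L):pmin(nrow(ordered), max(block) + 1L))
      if (any(taken[buffer])) next
      taken[buffer] <<- TRUE
      return(block)
    }
    NULL
  }

  for (i in order(runs, decreasing = TRUE)) {
    block <- place_block(runs[i])
    if (is.null(block)) return(NULL)
    run_genes[[i]] <- ordered$gene_id[block]
  }
  singles <- character(0)
  for (k in seq_len(M - sum(runs))) {
    block <- place_block(1L)
    if (is.null(block)) return(NULL)
    singles <- c(singles, ordered$gene_id[block])
  }
  list(members = c(unlist(run_genes), singles), run_genes = run_genes)
}

# Strand sequences realising the requested pair orientations, one per run.
# Orientations are permuted across pairs until every run's sequence is
# chain-consistent (divergent needs left "-", convergent left "+", and the
# right strand of one pair is the left strand of the next).
solve_run_strands <- function(runs, orientations, max_tries) {
  idx <- split(seq_along(orientations),
    rep(seq_along(runs), times = pmax(runs - 1L, 0L)))
  perm <- seq_along(orientations)
  for (try in seq_len(max_tries)) {
    assigned <- orientations[perm]
    strands <- purrr::map2(runs, idx, function(len, is) {
      run_strands(assigned[is])
    })
    if (!any(vapply(strands, is.null, logical(1)))) {
      return(strands)
    }
    perm <- sample(perm)
  }
  NULL
}

run_strands <- function(orients) {
  first <- switch(orients[1],
    divergent = c("-", "+"), convergent = c("+", "-"), tandem = c("+", "+"))
  strands <- first
  for (o in orients[-1]) {
    left <- strands[length(strands)]
    nxt <- switch(o,
      divergent = if (left == "-") "+" else return(NULL),
      convergent = if (left == "+") "-" else return(NULL),
      tandem = left
    )
    strands <- c(strands, nxt)
  }
  strands
}

#' Generate a time-course expression matrix with planted co-regulation
#'
#' Every regulon gene's profile is a shared latent response (by default a
#' heat-shock-like repression: a rapid monotone decline to a plateau, in log2
#' units) plus independent Gaussian noise whose standard deviation depends on
#' its class: genes in adjacent pairs get `sigma_paired` noise and
#' additionally share a pair-specific latent component of standard deviation
#' `pair_sd` with their partner (driving the expected ordering
#' adjacent >= paired >= unpaired of group-average similarities); unpaired
#' regulon genes get `sigma_unpaired`; background genes are pure noise with
#' `sigma_background` around a flat baseline and carry no shared signal.
#'
#' Defaults plant a clear pairing effect; setting `pair_sd = 0` and all
#' sigmas equal gives a null matrix with no pairing signal (for calibration).
#'
#' @param planted A `planted_regulon` from [plant_regulon()] (or a list with
#'   `annotation` and `regulon`).
#' @param n_conditions Number of conditions (time points), >= 3.
#' @param latent Optional numeric vector of length `n_conditions` overriding
#'   the default response shape.
#' @param sigma_paired,sigma_unpaired,sigma_background Noise standard
#'   deviations per gene class (log2 units).
#' @param pair_sd Standard deviation of the extra pair-shared component.
#' @param seed RNG seed.
#' @return An [expression_matrix()] covering every gene in the annotation.
#' @export
generate_expression <- function(planted, n_conditions = 20,
                                latent = NULL,
                                sigma_paired = 0.15,
                                sigma_unpaired = 0.8,
                                sigma_background = 1.0,
                                pair_sd = 0.25,
                                seed = NULL) {
  if (n_conditions < 3) {
    rlang::abort("need at least 3 conditions",
      class = "adjacentome_generation_error")
  }
  annotation <- planted$annotation
  reg <- planted$regulon
  summary <- find_adjacent_pairs(annotation, reg)
  paired_genes <- unique(c(summary$pairs$left, summary$pairs$right))
  members <- intersect(reg$members, annotation$gene_id)
  unpaired_genes <- setdiff(members, paired_genes)
  background <- setdiff(annotation$gene_id, members)

  if (is.null(latent)) {
    # heat-shock-like repression: fast decline from baseline 0 to -2 log2 units
    t <- seq(0, 1, length.out = n_conditions)
    latent <- -2 * (1 - exp(-5 * t))
  }
  if (length(latent) != n_conditions) {
    rlang::abort("latent shape must have n_conditions values",
      class = "adjacentome_generation_error")
  }

  with_seed(seed, {
    all_genes <- c(paired_genes, unpaired_genes, background)
    vals <- matrix(0, nrow = length(all_genes), ncol = n_conditions,
      dimnames = list(all_genes, NULL))
    noise <- function(sd) stats::rnorm(n_conditions, 0, sd)

    # pair-shared components, one per adjacency run so triplet members share
    pair_comp <- list()
    for (r in seq_len(nrow(summary$runs))) {
      comp <- stats::rnorm(n_conditions, 0, pair_sd)
      for (g in summary$runs$genes[[r]]) pair_comp[[g]] <- comp
    }
    for (g in paired_genes) {
      vals[g, ] <- latent + pair_comp[[g]] + noise(sigma_paired)
    }
    for (g in unpaired_genes) {
      vals[g, ] <- latent + noise(sigma_unpaired)
    }
    for (g in background) {
      vals[g, ] <- noise(sigma_background)
    }
    expression_matrix(tibble::tibble(
      gene_id = all_genes,
      !!!stats::setNames(
        as.data.frame(vals),
        sprintf("t%02d", seq_len(n_conditions))
      )
    ))
  })
}

#' Generate an ortholog panel with planted synteny maintenance
#'
#' Derives each panel species from the reference genome by breaking the
#' reference gene order into blocks — every link between two consecutive
#' reference genes is independently kept with probability `q` — shuffling the
#' blocks over the chromosomes and re-laying coordinates. Orthology is
#' one-to-one by construction (`<species>_<gene>`), with each gene lost
#' entirely with probability `loss`. The realised number of kept links per
#' species is recorded so recovery can be checked against a Binomial(n, q)
#' oracle.
#'
#' @param annotation The reference [genome_annotation()].
#' @param regulon The reference [regulon()]; each species' regulon is the set
#'   of orthologs of its members.
#' @param n_species Number of panel species.
#' @param q Per-link maintenance probability; scalar or one per species.
#' @param loss Per-gene loss probability.
#' @param clades Clade tags, one per species; defaults to `"sensu_strictu"`
#'   with the last species tagged `"outgroup"` when `outgroup = TRUE`.
#' @param outgroup Whether to tag the final species as the outgroup.
#' @param seed RNG seed.
#' @return A [species_panel()]; attribute `realized` is a tibble of kept-link
#'   counts per species.
#' @export
generate_ortholog_panel <- function(annotation, regulon, n_species = 3,
                                    q = 0.67, loss = 0,
                                    clades = NULL, outgroup = FALSE,
                                    seed = NULL) {
  regulon <- as_regulon(regulon)
  q <- rep_len(q, n_species)
  loss <- rep_len(loss, n_species)
  if (is.null(clades)) {
    clades <- rep("sensu_strictu", n_species)
    if (outgroup && n_species > 0) clades[n_species] <- "outgroup"
  }
  ordered <- order_genes(annotation)

  with_seed(seed, {
    realized <- tibble::tibble(species = character(), n_links = integer(),
      n_kept = integer())
    entries <- vector("list", n_species)
    for (sp in seq_len(n_species)) {
      name <- sprintf("sp%02d", sp)
      derived <- derive_species_genome(ordered, name, q[sp], loss[sp])
      entries[[sp]] <- list(
        species = name,
        annotation = derived$annotation,
        orthologs = derived$orthologs,
        regulon = derived$orthologs$ortholog_id[
          derived$orthologs$gene_id %in% regulon$members],
        clade = clades[sp]
      )
      realized <- dplyr::bind_rows(realized, tibble::tibble(
        species = name, n_links = derived$n_links, n_kept = derived$n_kept
      ))
    }
    panel <- species_panel(annotation, entries)
    attr(panel, "realized") <- realized
    panel
  })
}

# Shuffled blocks can, by chance, land so that a deliberately broken link is
# restored at a junction. Swap offending neighbours until no junction pair is
# reference-consecutive, so realized maintenance equals the kept-link set.
repair_block_junctions <- function(blocks, chrom_of_block, surviving) {
  pos_of <- stats::setNames(surviving$pos, surviving$gene_id)
  chr_of <- stats::setNames(surviving$chromosome, surviving$gene_id)
  ref_consecutive <- function(a, b) {
    chr_of[[a]] == chr_of[[b]] && abs(pos_of[[a]] - pos_of[[b]]) == 1L
  }
  n <- length(blocks)
  if (n < 3) return(blocks)
  for (attempt in seq_len(1000)) {
    offender <- 0L
    for (i in seq_len(n - 1L)) {
      if (chrom_of_block[i] != chrom_of_block[i + 1L]) next
      a <- blocks[[i]][length(blocks[[i]])]
      b <- blocks[[i + 1L]][1L]
      if (ref_consecutive(a, b)) {
        offender <- i + 1L
        break
      }
    }
    if (offender == 0L) return(blocks)
    other <- sample(setdiff(seq_len(n), offender), 1)
    blocks[c(offender, other)] <- blocks[c(other, offender)]
  }
  blocks
}

derive_species_genome <- function(ordered, name, q, loss) {
  kept_gene <- stats::runif(nrow(ordered)) >= loss
  surviving <- ordered[kept_gene, ]
  # candidate links: consecutive surviving genes that were consecutive in the
  # reference order (a lost gene breaks both of its links)
  same_chrom <- surviving$chromosome[-1] == surviving$chromosome[-nrow(surviving)]
  consecutive <- diff(surviving$pos) == 1L
  candidate <- same_chrom & consecutive
  keep_link <- candidate & (stats::runif(length(candidate)) < q)

  block_id <- cumsum(c(TRUE, !keep_link))
  blocks <- split(surviving$gene_id, block_id)
  blocks <- blocks[sample.int(length(blocks))]

  n_chrom <- length(unique(ordered$chromosome))
  chrom_of_block <- sort(rep_len(seq_len(n_chrom), length(blocks)))
  blocks <- repair_block_junctions(blocks, chrom_of_block, surviving)
  new_ids <- paste0(name, "_", unlist(blocks, use.names = FALSE))
  genes <- tibble::tibble(
    gene_id = new_ids,
    chromosome = paste0("chr", rep(chrom_of_block, lengths(blocks))),
    strand = surviving$strand[match(unlist(blocks), surviving$gene_id)]
  ) |>
    dplyr::group_by(.data$chromosome) |>
    dplyr::mutate(
      start = 1L + (dplyr::row_number() - 1L) * 2000L,
      end = .data$start + 999L
    ) |>
    dplyr::ungroup()

  list(
    annotation = genome_annotation(genes, species = name),
    orthologs = ortholog_map(
      tibble::tibble(
        gene_id = surviving$gene_id,
        ortholog_id = paste0(name, "_", surviving$gene_id)
      ),
      source_species = "reference", target_species = name
    ),
    n_links = sum(candidate),
    n_kept = sum(keep_link)
  )
}
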