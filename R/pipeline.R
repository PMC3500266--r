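#' Run the full adjacency analysis end to end
#'
#' Ties the stages together: read (or accept in-memory) inputs, compute the
#' adjacency and enrichment tables for every gene set, the co-expression
#' report when an expression matrix is supplied, and the conservation outputs
#' when a species panel is supplied. All result tables are written as TSV
#' under `out_dir` together with a run manifest (seeds, input checksums,
#' package version), and re-running with the same config and seed reproduces
#' byte-identical outputs.
#'
#' @param config A list with fields:
#'   \describe{
#'     \item{annotation}{A [genome_annotation()] or a path.}
#'     \item{format}{Annotation format when `annotation` is a path.}
#'     \item{gene_sets}{A [regulon()], list of regulons, or paths.}
#'     \item{expression}{Optional [expression_matrix()] or path.}
#'     \item{offset}{Offset mode for the co-expression stage (default
#'       `"first"`).}
#'     \item{panel}{Optional [species_panel()].}
#'     \item{expression_levels}{Optional per-gene levels (data frame
#'       `gene_id`/`level`) for the conservation-by-expression table.}
#'     \item{iterations}{Bootstrap iterations (default 10000).}
#'     \item{seed}{Seed for every stochastic stage.}
#'     \item{out_dir}{Output directory.}
#'   }
#' @return Invisibly, a named list of the result objects and tables.
#' @export
run_full_analysis <- function(config) {
  out_dir <- config$out_dir %||% rlang::abort("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  iterations <- config$iterations %||% 10000
  inputs <- character(0)

  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      rlang::abort(paste0(name, " stage failed: ", conditionMessage(e)),
        parent = e, class = "adjacentome_stage_error")
    })
  }

  annotation <- stage("annotation", {
    if (inherits(config$annotation, "genome_annotation")) {
      config$annotation
    } else {
      inputs <- c(inputs, config$annotation)
      read_gene_annotation(config$annotation,
        format = config$format %||% "tsv5",
        species = config$species %||% "unknown")
    }
  })

  regulons <- stage("gene_sets", {
    gs <- config$gene_sets
    if (inherits(gs, "regulon")) {
      list(gs)
    } else if (is.character(gs)) {
      inputs <- c(inputs, gs)
      lapply(gs, read_gene_set)
    } else {
      gs
    }
  })

  adjacency <- stage("adjacency", {
    summaries <- lapply(regulons, function(r) find_adjacent_pairs(annotation, r))
    tbl <- purrr::map_dfr(summaries, adjacency_table_row)
    write_report(tbl, file.path(out_dir, "adjacency.tsv"))
    list(summaries = summaries, table = tbl)
  })

  enrichment <- stage("enrichment", {
    tbl <- enrich_regulons(annotation, regulons)
    write_report(tbl, file.path(out_dir, "enrichment.tsv"))
    tbl
  })

  coexpression <- NULL
  if (!is.null(config$expression)) {
    coexpression <- stage("coexpression", {
      exprs <- if (inherits(config$expression, "expression_matrix")) {
        config$expression
      } else {
        inputs <- c(inputs, config$expression)
        read_expression_matrix(config$expression)
      }
      reports <- lapply(regulons, function(r) {
        coexpression_report(annotation, r, exprs,
          offset = config$offset %||% "first",
          iterations = iterations, seed = seed)
      })
      tbl <- purrr::map_dfr(reports, glance)
      write_report(tbl, file.path(out_dir, "coexpression.tsv"))
      list(reports = reports, table = tbl)
    })
  } else {
    rlang::inform("no expression matrix supplied; coexpression stage skipped")
  }

  conservation <- NULL
  if (!is.null(config$panel)) {
    conservation <- stage("conservation", {
      profiles <- lapply(adjacency$summaries, function(s) {
        conservation_profile(s, config$panel)
      })
      fates <- purrr::map_dfr(profiles, tidy)
      write_report(fates, file.path(out_dir, "conservation_fates.tsv"))
      classes <- purrr::map_dfr(profiles, glance)
      write_report(classes, file.path(out_dir, "conservation_classes.tsv"))

      boots <- lapply(seq_along(adjacency$summaries), function(i) {
        s <- adjacency$summaries[[i]]
        synteny_maintenance_bootstrap(annotation, config$panel, S = s$M,
          iterations = iterations, seed = seed, query_pairs = s$pairs)
      })
      boot_tbl <- purrr::map_dfr(seq_along(boots), function(i) {
        dplyr::mutate(glance(boots[[i]]),
          regulon = adjacency$summaries[[i]]$regulon, .before = 1)
      })
      write_report(boot_tbl, file.path(out_dir, "synteny_bootstrap.tsv"))

      levels_tbl <- NULL
      if (!is.null(config$expression_levels)) {
        levels_tbl <- purrr::map_dfr(seq_along(profiles), function(i) {
          dplyr::mutate(
            expression_by_conservation_class(profiles[[i]],
              config$expression_levels),
            regulon = profiles[[i]]$regulon, .before = 1)
        })
        write_report(levels_tbl,
          file.path(out_dir, "expression_by_conservation.tsv"))
      }
      list(profiles = profiles, bootstraps = boots, classes = classes,
        levels = levels_tbl)
    })
  }

  manifest <- list(
    package = "adjacentome",
    version = as.character(utils::packageVersion("adjacentome")),
    seed = seed,
    iterations = iterations,
    species = species(annotation),
    n_genes = n_genes(annotation),
    regulons = vapply(regulons, function(r) as_regulon(r)$name, character(1)),
    input_checksums = as.list(tools::md5sum(inputs[file.exists(inputs)]))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE)

  invisible(list(
    annotation = annotation,
    adjacency = adjacency,
    enrichment = enrichment,
    coexpression = coexpression,
    conservation = conservation,
    manifest = manifest
  ))
}
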