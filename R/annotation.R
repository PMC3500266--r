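#' Construct a genome annotation
#'
#' A genome annotation is a tibble of gene records — one row per protein-coding
#' gene — carrying `gene_id`, `chromosome`, `start`, `end` (1-based, inclusive)
#' and `strand` (`"+"` or `"-"`). The total gene count `N` of the genome is
#' simply the number of rows; it enters the binomial adjacency test via
#' [pairing_probability()].
#'
#' @param genes A data frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, `strand`.
#' @param species Species label attached to the annotation.
#' @return A tibble of class `genome_annotation` with a `species` attribute.
#' @examples
#' ann <- genome_annotation(
#'   tibble::tibble(
#'     gene_id = c("g1", "g2"), chromosome = "chr1",
#'     start = c(1L, 200L), end = c(100L, 300L), strand = c("+", "-")
#'   ),
#'   species = "example"
#' )
#' n_genes(ann)
#' @export
genome_annotation <- function(genes, species = "unknown") {
  genes <- tibble::as_tibble(genes)
  required <- c("gene_id", "chromosome", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0(
      "annotation is missing column(s): ", paste(missing_cols, collapse = ", ")
    ), class = "adjacentome_validation_error")
  }
  genes <- dplyr::mutate(
    genes,
    gene_id = as.character(.data$gene_id),
    chromosome = as.character(.data$chromosome),
    start = as.integer(.data$start),
    end = as.integer(.data$end),
    strand = as.character(.data$strand)
  )
  validate_gene_records(genes)
  genes <- genes[required]
  structure(
    genes,
    species = species,
    class = c("genome_annotation", class(tibble::tibble()))
  )
}

validate_gene_records <- function(genes) {
  if (nrow(genes) == 0) {
    rlang::abort("annotation contains no gene records",
      class = "adjacentome_validation_error")
  }
  if (anyNA(genes$start) || anyNA(genes$end)) {
    rlang::abort("non-integer gene coordinates",
      class = "adjacentome_parse_error")
  }
  bad <- which(genes$start > genes$end)
  if (length(bad) > 0) {
    rlang::abort(paste0("start > end for gene ", genes$gene_id[bad[1]]),
      class = "adjacentome_validation_error")
  }
  if (any(genes$gene_id == "" | is.na(genes$gene_id))) {
    rlang::abort("empty gene_id", class = "adjacentome_validation_error")
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup) > 0) {
    rlang::abort(paste0("duplicate gene_id: ", dup[1]),
      class = "adjacentome_validation_error")
  }
  bad_strand <- setdiff(unique(genes$strand), c("+", "-"))
  if (length(bad_strand) > 0) {
    rlang::abort(paste0("unknown strand symbol: ", bad_strand[1]),
      class = "adjacentome_validation_error")
  }
  invisible(genes)
}

#' @rdname genome_annotation
#' @param annotation A `genome_annotation`.
#' @export
n_genes <- function(annotation) nrow(annotation)

#' @rdname genome_annotation
#' @export
species <- function(annotation) attr(annotation, "species") %||% "unknown"

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "<genome_annotation> %s: %d genes on %d chromosome(s)\n",
    species(x), nrow(x), dplyr::n_distinct(x$chromosome)
  ))
  NextMethod()
}

#' Construct a regulon (named gene set)
#'
#' A regulon is a named set of gene identifiers assumed to be co-regulated as a
#' unit (a GO category, or a curated set such as the ribosome biogenesis
#' regulon). Its size `M` is the member count. Members need not all be present
#' in a given annotation; absent members are reported downstream, not dropped.
#'
#' @param members Character vector of gene identifiers (deduplicated).
#' @param name Regulon name.
#' @param go_id Optional gene-ontology accession.
#' @return An object of class `regulon` with fields `name`, `go_id`,
#'   `members` and `M`.
#' @export
regulon <- function(members, name = "regulon", go_id = NA_character_) {
  members <- unique(as.character(members))
  members <- members[!is.na(members) & members != ""]
  if (length(members) == 0) {
    rlang::abort("regulon has no members", class = "adjacentome_validation_error")
  }
  structure(
    list(name = name, go_id = go_id, members = members, M = length(members)),
    class = "regulon"
  )
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("<regulon> %s: M = %d genes\n", x$name, x$M))
  invisible(x)
}

#' Read a genome annotation from GFF3, BED6 or a 5-column TSV
#'
#' GFF3 and BED6 are parsed with `rtracklayer::import()`; BED's 0-based
#' half-open coordinates are converted to the 1-based inclusive convention used
#' throughout. For GFF3 only records whose type matches `feature_type` are
#' kept, with the `ID` attribute as `gene_id`. The `tsv5` dialect is a
#' headerless or headered tab file with columns
#' `gene_id, chromosome, start, end, strand` (1-based inclusive).
#'
#' @param path Input file.
#' @param format One of `"tsv5"`, `"gff3"`, `"bed6"`.
#' @param species Species label for the returned annotation.
#' @param feature_type GFF3 type filter (column 3); default `"gene"`.
#' @return A [genome_annotation()].
#' @export
read_gene_annotation <- function(path,
                                 format = c("tsv5", "gff3", "bed6"),
                                 species = "unknown",
                                 feature_type = "gene") {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "adjacentome_io_error")
  }
  genes <- switch(format,
    tsv5 = read_tsv5(path),
    gff3 = read_gff3_genes(path, feature_type),
    bed6 = read_bed6_genes(path)
  )
  genome_annotation(genes, species = species)
}

read_tsv5 <- function(path) {
  lines <- readr::read_lines(path)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0) {
    rlang::abort("empty tsv5 annotation", class = "adjacentome_validation_error")
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  # optional header row: recognised by non-numeric start column
  first <- fields[[1]]
  has_header <- length(first) >= 5 && is.na(suppressWarnings(as.integer(first[3])))
  if (has_header) {
    keep <- keep[-1]
    fields <- fields[-1]
  }
  bad <- which(lengths(fields) < 5)
  if (length(bad) > 0) {
    rlang::abort(
      paste0("malformed tsv5 line ", keep[bad[1]], ": expected 5 fields"),
      class = "adjacentome_parse_error"
    )
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:5))
  start <- suppressWarnings(as.integer(m[, 3]))
  end <- suppressWarnings(as.integer(m[, 4]))
  nonnum <- which(is.na(start) | is.na(end))
  if (length(nonnum) > 0) {
    rlang::abort(
      paste0("malformed tsv5 line ", keep[nonnum[1]], ": non-integer coordinates"),
      class = "adjacentome_parse_error"
    )
  }
  tibble::tibble(
    gene_id = m[, 1], chromosome = m[, 2],
    start = start, end = end, strand = m[, 5]
  )
}

read_gff3_genes <- function(path, feature_type) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% feature_type
  gr <- gr[keep]
  if (length(gr) == 0) {
    rlang::abort(paste0("no '", feature_type, "' records in GFF3"),
      class = "adjacentome_validation_error")
  }
  ids <- as.character(gr$ID)
  if (anyNA(ids)) {
    rlang::abort("GFF3 gene record without ID attribute",
      class = "adjacentome_parse_error")
  }
  tibble::tibble(
    gene_id = ids,
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

read_bed6_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  # rtracklayer already converts BED 0-based half-open to 1-based inclusive
  tibble::tibble(
    gene_id = as.character(gr$name),
    chromosome = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

#' Read a gene set (one id per line, or a GMT line)
#'
#' Plain lists carry one gene id per line; blank lines and `#` comments are
#' ignored. A GMT line (`name<TAB>description<TAB>gene1<TAB>gene2...`) is
#' recognised by containing tabs. Files with several GMT lines are read with
#' [read_gmt()].
#'
#' @param path Input file.
#' @param name Regulon name; defaults to the file name (or the GMT set name).
#' @param go_id Optional GO accession.
#' @return A [regulon()].
#' @export
read_gene_set <- function(path, name = NULL, go_id = NA_character_) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    rlang::abort("empty gene set", class = "adjacentome_validation_error")
  }
  if (any(grepl("\t", lines, fixed = TRUE))) {
    sets <- read_gmt(path)
    if (length(sets) > 1) {
      rlang::abort(
        "file contains several GMT sets; use read_gmt()",
        class = "adjacentome_validation_error"
      )
    }
    return(sets[[1]])
  }
  regulon(trimws(lines), name = name %||% basename(path), go_id = go_id)
}

#' @rdname read_gene_set
#' @return `read_gmt()` returns a named list of regulons.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    rlang::abort("empty GMT file", class = "adjacentome_validation_error")
  }
  sets <- lapply(lines, function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      rlang::abort("GMT line needs name, description and at least one gene",
        class = "adjacentome_parse_error")
    }
    go <- if (grepl("^(GO:)?\\d+$", fields[2])) fields[2] else NA_character_
    regulon(fields[-(1:2)], name = fields[1], go_id = go)
  })
  stats::setNames(sets, vapply(sets, `[[`, character(1), "name"))
}

#' Read an expression matrix (genes x conditions TSV)
#'
#' The first column holds gene identifiers; the header row holds condition
#' labels. Cells equal to `missing` (default `"NA"`) become `NA`. Any other
#' non-numeric cell is a parse error.
#'
#' @param path Input TSV.
#' @param missing Token denoting a missing value.
#' @return A tibble of class `expression_matrix` with a `gene_id` column and
#'   one numeric column per condition.
#' @export
read_expression_matrix <- function(path, missing = "NA") {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
    comment = "#", progress = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2) {
    rlang::abort("empty expression matrix", class = "adjacentome_validation_error")
  }
  gene_id <- as.character(df[[1]])
  vals <- lapply(df[-1], function(col) {
    col[col == missing] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad) > 0) {
      rlang::abort(paste0("non-numeric expression value '", col[bad[1]], "'"),
        class = "adjacentome_parse_error")
    }
    num
  })
  expression_matrix(tibble::tibble(gene_id = gene_id, !!!vals))
}

#' @rdname read_expression_matrix
#' @param x A data frame with a `gene_id` column and numeric condition columns.
#' @export
expression_matrix <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"gene_id" %in% names(x)) {
    names(x)[1] <- "gene_id"
  }
  if (ncol(x) < 3) {
    rlang::abort("expression matrix needs at least 2 conditions",
      class = "adjacentome_validation_error")
  }
  if (anyDuplicated(x$gene_id)) {
    rlang::abort("duplicate gene_id in expression matrix",
      class = "adjacentome_validation_error")
  }
  structure(x, class = c("expression_matrix", class(tibble::tibble())))
}

#' @rdname read_expression_matrix
#' @export
n_conditions <- function(x) ncol(x) - 1L

#' Read a two-column ortholog map
#'
#' Tab-separated `gene_id<TAB>ortholog_id` lines mapping reference-species
#' genes to target-species genes; one-to-many links are allowed as repeated
#' rows. Blank lines and `#` comments are ignored.
#'
#' @param path Input TSV.
#' @param source_species,target_species Species labels.
#' @return A tibble of class `ortholog_map` with columns `gene_id`,
#'   `ortholog_id`.
#' @export
read_ortholog_map <- function(path, source_species = "reference",
                              target_species = "target") {
  lines <- readr::read_lines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0) {
    rlang::abort("empty ortholog map", class = "adjacentome_validation_error")
  }
  fields <- strsplit(lines, "\t|\\s+")
  bad <- which(lengths(fields) < 2)
  if (length(bad) > 0) {
    rlang::abort(paste0("malformed ortholog line: '", lines[bad[1]], "'"),
      class = "adjacentome_parse_error")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:2))
  ortholog_map(tibble::tibble(gene_id = m[, 1], ortholog_id = m[, 2]),
    source_species, target_species)
}

#' @rdname read_ortholog_map
#' @param links A data frame with columns `gene_id`, `ortholog_id`.
#' @export
ortholog_map <- function(links, source_species = "reference",
                         target_species = "target") {
  links <- dplyr::distinct(tibble::as_tibble(links))
  if (!all(c("gene_id", "ortholog_id") %in% names(links))) {
    rlang::abort("ortholog map needs gene_id and ortholog_id columns",
      class = "adjacentome_validation_error")
  }
  structure(
    links,
    source_species = source_species,
    target_species = target_species,
    class = c("ortholog_map", class(tibble::tibble()))
  )
}

#' Write a tabular report as TSV
#'
#' Rows are sorted by the first column for deterministic output. Columns whose
#' name looks like a p-value (`p_value`, `bootstrap_p`, ...) are rendered in
#' scientific notation with 2 significant digits (`7.3e-08`); other numeric
#' columns keep full precision.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report <- function(rows, path) {
  rows <- tibble::as_tibble(rows)
  if (nrow(rows) > 0) {
    rows <- dplyr::arrange(rows, dplyr::across(1))
  }
  out <- dplyr::mutate(rows, dplyr::across(
    dplyr::matches("(^|_)p(_value)?$|^p_|pvalue|bootstrap_p", ignore.case = TRUE) &
      dplyr::where(is.numeric),
    format_pvalue
  ))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @param p Numeric vector of p-values.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), NA_character_, sprintf("%.1e", p))
}

#' Write an annotation back to the tsv5 dialect
#'
#' @param annotation A [genome_annotation()].
#' @param path Output path.
#' @export
write_gene_annotation <- function(annotation, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(tibble::as_tibble(annotation), path, col_names = FALSE,
    progress = FALSE)
  invisible(path)
}
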