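test_that("pair fates follow the same-partner / repaired / absent rules", {
  ann <- tiny_annotation(seq(100, 600, by = 100))
  members <- c("g1", "g2", "g5")
  panel <- identity_panel(ann, members)
  entry <- panel$entries[[1]]

  expect_equal(pair_fate("g1", "g2", entry), "same_partner")

  # no ortholog for either gene
  no_links <- entry
  no_links$orthologs <- ortholog_map(
    tibble::tibble(gene_id = "g9", ortholog_id = "id1_g9"))
  expect_equal(pair_fate("g1", "g2", no_links), "gene_absent")

  # pair split apart, but the left gene sits next to another regulon member
  genes <- tibble::as_tibble(ann)
  genes$gene_id <- paste0("t_", c("g1", "g5", "g3", "g4", "g2", "g6"))
  split_entry <- list(
    species = "t",
    annotation = genome_annotation(genes, species = "t"),
    orthologs = ortholog_map(tibble::tibble(
      gene_id = c("g1", "g2", "g5"),
      ortholog_id = c("t_g1", "t_g2", "t_g5")
    )),
    regulon = c("t_g1", "t_g2", "t_g5"),
    clade = "outgroup"
  )
  expect_equal(pair_fate("g1", "g2", split_entry), "repaired_within_regulon")

  # orthologs exist but nothing regulon-adjacent remains
  lone <- split_entry
  lone$regulon <- c("t_g1", "t_g2")
  genes2 <- genes
  genes2$gene_id <- paste0("t_", c("g1", "g9", "g3", "g4", "g2", "g6"))
  lone$annotation <- genome_annotation(genes2, species = "t")
  lone$orthologs <- ortholog_map(tibble::tibble(
    gene_id = c("g1", "g2"), ortholog_id = c("t_g1", "t_g2")))
  expect_equal(pair_fate("g1", "g2", lone), "unpaired")
})

test_that("adding ortholog links never downgrades a fate", {
  ann <- tiny_annotation(seq(100, 600, by = 100))
  panel <- identity_panel(ann, c("g1", "g2"))
  entry <- panel$entries[[1]]
  base_fate <- pair_fate("g1", "g2", entry)
  expect_equal(base_fate, "same_partner")
  richer <- entry
  richer$orthologs <- ortholog_map(dplyr::bind_rows(
    entry$orthologs,
    tibble::tibble(gene_id = "g1", ortholog_id = "id1_g4")
  ))
  expect_equal(pair_fate("g1", "g2", richer), "same_partner")
})

test_that("conservation classes partition pairs by clade evidence", {
  fates <- tibble::tibble(
    pair_id = rep(c("a-b", "c-d", "e-f"), each = 2),
    left = rep(c("a", "c", "e"), each = 2),
    right = rep(c("b", "d", "f"), each = 2),
    species = rep(c("near", "far"), 3),
    clade = rep(c("sensu_strictu", "outgroup"), 3),
    fate = c(
      "unpaired", "gene_absent", # minimal
      "same_partner", "unpaired", # intermediate
      "unpaired", "repaired_within_regulon" # wide
    )
  )
  classes <- assign_conservation_class(fates)
  got <- stats::setNames(classes$conservation_class, classes$pair_id)
  expect_equal(unname(got[c("a-b", "c-d", "e-f")]),
    c("minimal", "intermediate", "wide"))

  no_outgroup <- dplyr::mutate(fates, clade = "sensu_strictu")
  expect_error(assign_conservation_class(no_outgroup),
    class = "adjacentome_config_error")
})

test_that("profiles tally classes over a generated panel", {
  gen <- generate_genome(400, 2, seed = 41)
  planted <- plant_regulon(gen, M = 30, runs = c(2, 2, 2, 2), seed = 42)
  s <- find_adjacent_pairs(planted$annotation, planted$regulon)
  panel <- generate_ortholog_panel(planted$annotation, planted$regulon,
    n_species = 3, q = c(0.9, 0.9, 0.3), outgroup = TRUE, seed = 43)
  prof <- conservation_profile(s, panel)
  expect_equal(sum(prof$class_counts), nrow(s$pairs))
  expect_equal(sort(unique(prof$fates$species)), c("sp01", "sp02", "sp03"))
  g <- glance(prof)
  expect_equal(g$n_pairs, nrow(s$pairs))
})

test_that("synteny bootstrap is exact on degenerate panels", {
  ann <- tiny_annotation(seq(100, 1000, by = 100))
  members <- c("g1", "g2")
  ident <- identity_panel(ann, members)
  boot <- synteny_maintenance_bootstrap(ann, ident, S = 6,
    iterations = 50, seed = 1,
    query_pairs = tibble::tibble(left = "g1", right = "g2"))
  expect_true(all(boot$fractions == 1))
  expect_equal(boot$observed_fraction, 1)

  # a panel whose ortholog map misses every gene maintains nothing
  nowhere <- ident
  for (i in seq_along(nowhere$entries)) {
    nowhere$entries[[i]]$orthologs <- ortholog_map(
      tibble::tibble(gene_id = "ghost", ortholog_id = "id_ghost"))
  }
  boot0 <- synteny_maintenance_bootstrap(ann, nowhere, S = 6,
    iterations = 50, seed = 1)
  expect_true(all(boot0$fractions == 0))

  expect_error(
    synteny_maintenance_bootstrap(ann, ident, S = 100, iterations = 10, seed = 1),
    class = "adjacentome_domain_error"
  )
})

test_that("planted maintenance probability is recovered by the bootstrap", {
  gen <- generate_genome(600, 3, seed = 51)
  reg <- plant_regulon(gen, M = 20, runs = c(2, 2), seed = 52)
  for (q in c(0.2, 0.67, 0.9)) {
    panel <- generate_ortholog_panel(reg$annotation, reg$regulon,
      n_species = 1, q = q, outgroup = TRUE, seed = round(1000 * q))
    boot <- synteny_maintenance_bootstrap(reg$annotation, panel, S = 282,
      iterations = 2000, seed = 53)
    se <- sqrt(q * (1 - q) / 282)
    expect_lt(abs(boot$mean_fraction - q), 3 * se)
  }
})

test_that("expression levels group by conservation class", {
  classes <- tibble::tibble(
    pair_id = c("a-b", "c-d", "e-f"),
    left = c("a", "c", "e"),
    right = c("b", "d", "f"),
    conservation_class = c("minimal", "intermediate", "wide")
  )
  equal_levels <- stats::setNames(rep(5, 6), c("a", "b", "c", "d", "e", "f"))
  out <- expression_by_conservation_class(classes, equal_levels)
  expect_true(all(out$mean_level == 5))

  doubled <- stats::setNames(c(1, 1, 1.5, 1.5, 2, 2),
    c("a", "b", "c", "d", "e", "f"))
  out2 <- expression_by_conservation_class(classes, doubled)
  wide <- out2$mean_level[out2$conservation_class == "wide"]
  minimal <- out2$mean_level[out2$conservation_class == "minimal"]
  expect_equal(wide / minimal, 2)

  # empty class reported with count 0 and undefined mean
  out3 <- expression_by_conservation_class(classes[1:2, ], doubled)
  empty <- out3[out3$conservation_class == "wide", ]
  expect_equal(empty$n_genes, 0)
  expect_true(is.na(empty$mean_level))
})
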