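test_that("genome generation is deterministic under a seed", {
  a <- generate_genome(100, 2, seed = 7)
  b <- generate_genome(100, 2, seed = 7)
  c <- generate_genome(100, 2, seed = 8)
  expect_equal(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c)))
  expect_equal(n_genes(a), 100)

  single <- generate_genome(1, 1, seed = 1)
  expect_equal(n_genes(single), 1)

  plus_only <- generate_genome(50, 1, prob_plus = 1, seed = 2)
  expect_true(all(plus_only$strand == "+"))

  # genes never overlap within a chromosome
  ord <- order_genes(a)
  gaps <- ord |>
    dplyr::group_by(chromosome) |>
    dplyr::summarise(ok = all(diff(start) > 0 & start[-1] > end[-dplyr::n()]))
  expect_true(all(gaps$ok))

  expect_error(generate_genome(1, 2), class = "adjacentome_generation_error")
})

test_that("planted regulons are recovered exactly by the adjacency scan", {
  gen <- generate_genome(1000, 2, seed = 7)

  p1 <- plant_regulon(gen, M = 10, runs = c(2), seed = 1)
  s1 <- find_adjacent_pairs(p1$annotation, p1$regulon)
  expect_equal(s1$j, 2)
  expect_equal(nrow(s1$pairs), 1)

  p2 <- plant_regulon(gen, M = 50, runs = c(2, 2, 2, 2, 3), seed = 2)
  s2 <- find_adjacent_pairs(p2$annotation, p2$regulon)
  expect_equal(s2$j, 11)
  expect_equal(nrow(s2$pairs), 6)
  expect_equal(sort(s2$runs$length), c(2L, 2L, 2L, 2L, 3L))

  # orientation quotas are realised via local strand adjustment
  p3 <- plant_regulon(gen, M = 10, runs = c(2), orientations = "divergent",
    seed = 3)
  s3 <- find_adjacent_pairs(p3$annotation, p3$regulon)
  expect_equal(s3$pairs$orientation, "divergent")

  p4 <- plant_regulon(gen, M = 12, runs = c(3, 2),
    orientations = c("divergent", "tandem", "convergent"), seed = 4)
  s4 <- find_adjacent_pairs(p4$annotation, p4$regulon)
  expect_equal(sort(s4$pairs$orientation),
    c("convergent", "divergent", "tandem"))

  expect_error(plant_regulon(gen, M = 3, runs = c(2, 2)),
    class = "adjacentome_generation_error")
  # too dense to place without accidental adjacency
  small <- generate_genome(6, 1, seed = 5)
  expect_error(plant_regulon(small, M = 5, runs = c(2, 2), max_tries = 20),
    class = "adjacentome_generation_error")
})

test_that("plant-then-scan is the identity across random configurations", {
  withr::local_seed(99)
  for (i in 1:15) {
    gen <- generate_genome(sample(300:600, 1), sample(1:3, 1),
      seed = sample.int(1e6, 1))
    runs <- sample(2:4, sample(1:3, 1), replace = TRUE)
    M <- sum(runs) + sample(3:10, 1)
    planted <- plant_regulon(gen, M = M, runs = runs, seed = sample.int(1e6, 1))
    s <- find_adjacent_pairs(planted$annotation, planted$regulon)
    expect_equal(s$j, sum(runs))
    expect_equal(sort(s$runs$length), sort(as.integer(runs)))
    expect_equal(nrow(s$pairs), sum(runs - 1L))
  }
})

test_that("noise-free adjacent partners correlate perfectly", {
  gen <- generate_genome(200, 1, seed = 61)
  planted <- plant_regulon(gen, M = 10, runs = c(2), seed = 62)
  exprs <- generate_expression(planted, n_conditions = 10,
    sigma_paired = 0, pair_sd = 0, seed = 63)
  pair <- find_adjacent_pairs(planted$annotation, planted$regulon)$pairs
  left <- as.numeric(exprs[match(pair$left, exprs$gene_id), -1])
  right <- as.numeric(exprs[match(pair$right, exprs$gene_id), -1])
  expect_equal(offset_pcc(left, right, offset = "first"), 1.0)

  expect_equal(nrow(exprs), 200)
  expect_equal(n_conditions(exprs), 10)
  expect_error(generate_expression(planted, n_conditions = 2),
    class = "adjacentome_generation_error")
})

test_that("ortholog panels realise the planted maintenance probability", {
  gen <- generate_genome(500, 2, seed = 71)
  reg <- plant_regulon(gen, M = 20, runs = c(2, 2), seed = 72)

  panel1 <- generate_ortholog_panel(reg$annotation, reg$regulon,
    n_species = 1, q = 1, outgroup = TRUE, seed = 73)
  s <- find_adjacent_pairs(reg$annotation, reg$regulon)
  fates <- pair_fates(s$pairs, panel1)
  expect_true(all(fates$fate == "same_partner"))

  panel0 <- generate_ortholog_panel(reg$annotation, reg$regulon,
    n_species = 1, q = 0, outgroup = TRUE, seed = 74)
  fates0 <- pair_fates(s$pairs, panel0)
  expect_true(all(fates0$fate != "same_partner"))

  # realized kept-link counts agree with an explicit rescan of every
  # reference-adjacent pair, and sit inside the Binomial(n, q) 99.9% band
  q <- 0.67
  panelq <- generate_ortholog_panel(reg$annotation, reg$regulon,
    n_species = 1, q = q, outgroup = TRUE, seed = 75)
  realized <- attr(panelq, "realized")
  all_pairs <- order_genes(reg$annotation) |>
    dplyr::group_by(chromosome) |>
    dplyr::reframe(left = gene_id[-dplyr::n()], right = gene_id[-1])
  maintained <- sum(vapply(seq_len(nrow(all_pairs)), function(i) {
    pair_fate(all_pairs$left[i], all_pairs$right[i],
      panelq$entries[[1]]) == "same_partner"
  }, logical(1)))
  expect_equal(maintained, realized$n_kept)
  band <- stats::qbinom(c(5e-4, 1 - 5e-4), realized$n_links, q)
  expect_gte(realized$n_kept, band[1])
  expect_lte(realized$n_kept, band[2])
})

test_that("gene loss produces gene_absent fates", {
  gen <- generate_genome(300, 1, seed = 81)
  reg <- plant_regulon(gen, M = 16, runs = c(2, 2, 2, 2), seed = 82)
  panel <- generate_ortholog_panel(reg$annotation, reg$regulon,
    n_species = 1, q = 1, loss = 0.5, outgroup = TRUE, seed = 83)
  s <- find_adjacent_pairs(reg$annotation, reg$regulon)
  fates <- pair_fates(s$pairs, panel)
  expect_true(any(fates$fate == "gene_absent"))
})
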