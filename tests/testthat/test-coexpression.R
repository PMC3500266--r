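test_that("offset similarity matches hand calculations and identities", {
  x <- c(0, 1, 2)
  y <- c(0, 2, 1)
  expect_equal(offset_pcc(x, y, offset = "explicit", x_offset = 0, y_offset = 0),
    0.8)
  expect_equal(offset_pcc(x, x, offset = "first"), 1.0)
  expect_equal(offset_pcc(c(1, 2, 3), c(3, 2, 1), offset = "first"), -1.0)
  # symmetric
  expect_equal(offset_pcc(x, y, offset = "mean"), offset_pcc(y, x, offset = "mean"))
})

test_that("mean offsets reduce to the classical Pearson correlation", {
  withr::local_seed(7)
  for (i in 1:50) {
    x <- rnorm(12)
    y <- rnorm(12)
    expect_equal(offset_pcc(x, y, offset = "mean"), stats::cor(x, y),
      tolerance = 1e-12)
  }
})

test_that("similarity respects rescaling, sign flips and missing data", {
  withr::local_seed(11)
  x <- rnorm(10)
  y <- rnorm(10)
  s <- offset_pcc(x, y, offset = "mean")
  expect_equal(offset_pcc(3 * x, y, offset = "mean"), s, tolerance = 1e-12)
  expect_equal(offset_pcc(-x, y, offset = "mean"), -s, tolerance = 1e-12)

  # pairwise condition dropping
  y_na <- y
  y_na[c(2, 5)] <- NA
  keep <- !is.na(y_na)
  expect_equal(offset_pcc(x, y_na, offset = "mean"),
    stats::cor(x[keep], y[keep]), tolerance = 1e-12)

  # degenerate inputs are signalled as NA
  expect_true(is.na(offset_pcc(c(1, 1, 1, 1), y[1:4], offset = "mean")))
  expect_true(is.na(offset_pcc(c(1, NA, NA, NA, 2), c(1, 2, 3, 4, NA))))
})

test_that("comparison classes follow the three-group geometry", {
  ann <- tiny_annotation(seq(100, 1000, by = 100)[1:8])
  exprs <- expression_matrix(tibble::tibble(
    gene_id = paste0("g", 1:8),
    t0 = rnorm(8), t1 = rnorm(8), t2 = rnorm(8)
  ))

  # regulon of 6 with one adjacent pair: C(4,2)=6 unpaired comparisons
  s <- find_adjacent_pairs(ann, c("g1", "g2", "g4", "g6", "g8", "g5"))
  # g4,g5,g6 are consecutive: adjust to a cleaner configuration
  s <- find_adjacent_pairs(ann, c("g1", "g2", "g4", "g6", "g8"))
  expect_equal(nrow(s$pairs), 1)
  groups <- classify_regulon_pairs(s, exprs)
  expect_equal(length(groups$unpaired), 3)
  expect_equal(unname(groups$n_comparisons["unpaired"]), 3)
  expect_equal(unname(groups$n_comparisons["adjacent"]), 1)
  expect_equal(unname(groups$n_comparisons["paired_not_adjacent"]), 0)

  # two adjacent pairs: paired-not-adjacent comparisons = C(4,2) - 2 = 4
  s2 <- find_adjacent_pairs(ann, c("g1", "g2", "g5", "g6"))
  groups2 <- classify_regulon_pairs(s2, exprs)
  expect_equal(unname(groups2$n_comparisons["paired_not_adjacent"]), 4)

  # genes without expression data are excluded and counted
  exprs_small <- expression_matrix(tibble::tibble(
    gene_id = paste0("g", 1:6),
    t0 = rnorm(6), t1 = rnorm(6), t2 = rnorm(6)
  ))
  s3 <- find_adjacent_pairs(ann, c("g1", "g2", "g5", "g7", "g8"))
  groups3 <- classify_regulon_pairs(s3, exprs_small)
  expect_equal(sort(groups3$excluded), c("g7", "g8"))
  expect_equal(length(groups3$unpaired), 1)
})

test_that("group means average the pairwise similarities", {
  exprs <- expression_matrix(tibble::tibble(
    gene_id = c("a", "b", "c"),
    t0 = c(0, 0, 0), t1 = c(1, 1, -1), t2 = c(2, 2, -2)
  ))
  same <- mean_group_pcc(c("a", "b"), exprs, offset = "first")
  expect_equal(same$mean, 1)
  both <- mean_group_pcc(c("a", "b", "c"), exprs, offset = "first")
  # comparisons: (a,b)=1, (a,c)=-1, (b,c)=-1
  expect_equal(both$mean, -1 / 3)
  expect_equal(both$n, 3)

  excl <- mean_group_pcc(c("a", "b", "c"), exprs, offset = "first",
    exclude = tibble::tibble(left = "a", right = "b"))
  expect_equal(excl$mean, -1)
  expect_equal(excl$n, 2)
})

test_that("bootstrap p-values hit their finite-sample bounds", {
  withr::local_seed(5)
  exprs <- expression_matrix(tibble::tibble(
    gene_id = paste0("g", 1:10),
    !!!stats::setNames(as.data.frame(matrix(rnorm(60), 10)), paste0("t", 1:6))
  ))
  members <- paste0("g", 1:10)
  b_hi <- bootstrap_mean_pcc_pvalue(exprs, members, observed_mean = 2,
    group_size = 4, iterations = 999, seed = 1)
  expect_equal(b_hi$p_value, 1 / 1000)
  b_lo <- bootstrap_mean_pcc_pvalue(exprs, members, observed_mean = -1,
    group_size = 4, iterations = 999, seed = 1)
  expect_equal(b_lo$p_value, 1)
  expect_error(
    bootstrap_mean_pcc_pvalue(exprs, members, 0, group_size = 11, seed = 1),
    class = "adjacentome_domain_error"
  )
})

test_that("planted co-regulation orders the group averages", {
  gen <- generate_genome(300, 2, seed = 31)
  planted <- plant_regulon(gen, M = 30, runs = c(2, 2, 2), seed = 32)
  s <- latent_scale(20)
  exprs <- generate_expression(planted, n_conditions = 20,
    sigma_paired = 0.15 * s, pair_sd = 0.3 * s, sigma_unpaired = s,
    seed = 33)
  rep <- coexpression_report(planted$annotation, planted$regulon, exprs,
    iterations = 1000, seed = 34)
  m <- stats::setNames(rep$groups$mean_pcc, rep$groups$group)
  expect_gt(m["adjacent"], m["paired_not_adjacent"])
  expect_gte(m["paired_not_adjacent"], m["unpaired"])
  expect_lt(rep$bootstrap_p, 0.05)
})
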