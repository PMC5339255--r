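test_that("locus aggregation matches hand arithmetic and rejects bad input", {
  expect_equal(aggregate_locus_score(0.9, "mean"), 0.9)
  expect_equal(aggregate_locus_score(c(0.8, 0.2), "mean"), 0.5)
  expect_equal(aggregate_locus_score(c(0.8, 0.2), "range"), 0.6)
  expect_equal(aggregate_locus_score(0.9, "range"), 0)
  expect_error(aggregate_locus_score(numeric(0)), "non-empty")
  expect_error(aggregate_locus_score(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("variant score is the disease fraction of summed locus scores", {
  # all disease-associated -> numerator equals denominator
  expect_equal(normalize_variant_score(c(0.3, 0.9), c(TRUE, TRUE)), 1)
  # none associated -> empty numerator
  expect_equal(normalize_variant_score(c(0.3, 0.9), c(FALSE, FALSE)), 0)
  # {0.8 (disease), 0.2 (disease), 0.5, 0.5} -> 1/2
  expect_equal(
    normalize_variant_score(c(0.8, 0.2, 0.5, 0.5), c(1, 1, 0, 0)), 0.5
  )
  # scale invariance of the ratio
  s <- c(0.12, 0.4, 0.03, 0.9)
  d <- c(TRUE, FALSE, TRUE, FALSE)
  expect_equal(normalize_variant_score(s, d),
               normalize_variant_score(s * 0.37, d))
  # all-zero scores: undefined ratio
  expect_warning(r <- normalize_variant_score(c(0, 0), c(TRUE, FALSE)),
                 "undefined")
  expect_true(is.na(r))
})

test_that("gene scores are normalized by the maximum Z-score", {
  expect_equal(normalize_gene_scores(3.7), 1)
  expect_equal(normalize_gene_scores(c(2, 1, 0.5)), c(1, 0.5, 0.25))
  expect_error(normalize_gene_scores(numeric(0)), "empty")
  expect_error(normalize_gene_scores(c(-1, -2)), "positive")
  expect_error(normalize_gene_scores(c(1, NA)), "finite")
})

toy_genes <- data.frame(gene = c("A", "B", "C"), z_score = c(2, 1, 0.5))
toy_variants <- data.frame(
  variant_id = paste0("rs", 1:3), gene = c("A", "B", "C"),
  allele_scores = "1.0", disease_associated = 1
)

test_that("build_map composes the two normalizations", {
  m <- build_map(toy_genes, toy_variants)
  expect_s3_class(m, "gene_variant_map")
  pts <- m$points[order(match(m$points$gene, c("A", "B", "C"))), ]
  expect_equal(pts$x, c(1, 0.5, 0.25))
  expect_equal(pts$y, c(1, 1, 1))
  # coordinates always inside the unit square
  expect_true(all(pts$x >= 0 & pts$x <= 1 & pts$y >= 0 & pts$y <= 1))
})

test_that("build_map is invariant to input row order", {
  tt <- make_toy_tables(seed = 3)
  m1 <- build_map(tt$genes, tt$variants)
  set.seed(5)
  m2 <- build_map(tt$genes[sample(nrow(tt$genes)), ],
                  tt$variants[sample(nrow(tt$variants)), ])
  expect_equal(m1$points, m2$points)
})

test_that("build_map drops unknown-gene variants and zero-score genes with warnings", {
  v <- rbind(toy_variants,
             data.frame(variant_id = "rs9", gene = "ZZZ",
                        allele_scores = "0.5", disease_associated = 1))
  expect_warning(m <- build_map(toy_genes, v), "ZZZ")
  expect_setequal(m$points$gene, c("A", "B", "C"))

  v2 <- toy_variants
  v2$allele_scores[1] <- "0.0"   # gene A: all scores zero -> excluded
  w <- capture_warnings(m2 <- build_map(toy_genes, v2))
  expect_true(any(grepl("excluded", w)))
  expect_setequal(m2$points$gene, c("B", "C"))

  g3 <- rbind(toy_genes, data.frame(gene = "NOVAR", z_score = 1))
  expect_warning(m3 <- build_map(g3, toy_variants), "no variant records")
  expect_false("NOVAR" %in% m3$points$gene)
})

test_that("duplicate gene or variant rows are rejected", {
  expect_error(build_map(rbind(toy_genes, toy_genes[1, ]), toy_variants),
               "duplicate gene")
  expect_error(build_map(toy_genes, rbind(toy_variants, toy_variants[1, ])),
               "duplicate \\(variant_id, gene\\)")
})

test_that("the seeded toy tables reproduce the golden map file", {
  tt <- make_toy_tables(seed = 1)
  m <- build_map(tt$genes, tt$variants)
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_map(m, tmp)
  expect_identical(readLines(tmp), readLines(test_path("golden_toy_map.tsv")))
})

test_that("printed gene-variant scores round-trip through map TSV", {
  # CRYAB carries (S_G, S_V) = (0.46, 0.52); TINF2 (0.41, 0.04)
  m <- read_map(textConnection(
    "gene\tx\ty\nCRYAB\t0.46\t0.52\nTINF2\t0.41\t0.04\nOTHER\t1\t0.3"))
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_map(m, tmp)
  m2 <- read_map(tmp)
  expect_equal(m2$points, m$points)
  expect_equal(m2$points$x[m2$points$gene == "CRYAB"], 0.46)
  expect_equal(m2$points$y[m2$points$gene == "CRYAB"], 0.52)
})
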