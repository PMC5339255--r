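#' Synthetic gene-variant map with planted clusters
#'
#' Generates a seeded mock map on the unit square: `n_background` points
#' uniform over the square plus one isotropic Gaussian blob per entry of
#' `blobs`, truncated to the square by resampling (clipping would pile
#' probability on the border). The defaults plant two tight blobs of 15
#' points (sd 0.01) at (0.3, 0.3) and (0.7, 0.7) on 40 background points —
#' a configuration whose blob cells are far denser than the background, so
#' downstream clustering should recover exactly the two blobs.
#'
#' @param n_background Number of uniform background points; default 40.
#' @param blobs List of blob specs, each `list(center = c(x, y), sd, n)`.
#'   Use `list()` for a pure-noise map. Default: the two-blob configuration.
#' @param seed Integer seed; the output is a deterministic function of it.
#' @return A `gene_variant_map` with synthetic genes `G0001`, `G0002`, ...
#'   and an attribute `labels`: integer vector, 0 for background points,
#'   b for points of blob b.
#' @export
make_mock_map <- function(n_background = 40,
                          blobs = list(
                            list(center = c(0.3, 0.3), sd = 0.01, n = 15),
                            list(center = c(0.7, 0.7), sd = 0.01, n = 15)
                          ),
                          seed = 1L) {
  n_total <- n_background + sum(vapply(blobs, function(b) b$n, numeric(1)))
  if (n_total < 4) stop("need at least 4 points in total", call. = FALSE)
  set.seed(seed)

  xs <- stats::runif(n_background)
  ys <- stats::runif(n_background)
  labels <- rep(0L, n_background)
  for (b in seq_along(blobs)) {
    spec <- blobs[[b]]
    if (spec$sd <= 0) stop("blob sd must be positive", call. = FALSE)
    got <- 0L
    bx <- by <- numeric(spec$n)
    while (got < spec$n) {
      px <- stats::rnorm(1, spec$center[1], spec$sd)
      py <- stats::rnorm(1, spec$center[2], spec$sd)
      if (px >= 0 && px <= 1 && py >= 0 && py <= 1) {
        got <- got + 1L
        bx[got] <- px; by[got] <- py
      }
    }
    xs <- c(xs, bx); ys <- c(ys, by)
    labels <- c(labels, rep(b, spec$n))
  }

  pts <- data.frame(
    gene = sprintf("G%04d", seq_along(xs)),
    x = xs, y = ys, stringsAsFactors = FALSE
  )
  map <- structure(
    list(points = pts, score_kind = "one_minus_sift",
         locus_aggregation = "mean", disease_label = "synthetic"),
    class = "gene_variant_map"
  )
  attr(map, "labels") <- labels
  map
}

#' Synthetic gene and variant score tables
#'
#' Emits a small pair of score tables (20 genes, ~60 variants with 1-3
#' alleles each) with the exact input schema of [build_map()], for
#' end-to-end exercises of the score-map stage without any database access.
#' Deterministic for a fixed seed.
#'
#' @param seed Integer seed.
#' @param n_genes,n_variants Table sizes; defaults 20 and 60.
#' @return List with `genes` (data frame `gene`, `z_score`) and `variants`
#'   (data frame `variant_id`, `gene`, `allele_scores` comma-separated,
#'   `disease_associated` 0/1).
#' @export
make_toy_tables <- function(seed = 1L, n_genes = 20L, n_variants = 60L) {
  set.seed(seed)
  genes <- data.frame(
    gene = sprintf("G%02d", seq_len(n_genes)),
    z_score = round(stats::runif(n_genes, 0.2, 5), 3),
    stringsAsFactors = FALSE
  )
  gene_of <- sample(genes$gene, n_variants, replace = TRUE)
  n_alleles <- sample(1:3, n_variants, replace = TRUE)
  allele_scores <- vapply(n_alleles, function(k) {
    paste(sprintf("%.3f", stats::runif(k)), collapse = ",")
  }, character(1))
  variants <- data.frame(
    variant_id = sprintf("rs%06d", sample.int(999999L, n_variants)),
    gene = gene_of,
    allele_scores = allele_scores,
    disease_associated = stats::rbinom(n_variants, 1, 0.5),
    stringsAsFactors = FALSE
  )
  list(genes = genes, variants = variants)
}
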