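#' Aggregate per-allele deleteriousness scores at a variant locus
#'
#' A variant locus may carry several possible variations, each with its own
#' deleteriousness score (1-SIFT or PolyPhen, both in \[0,1\], higher = more
#' damaging). This collapses them to a single per-locus score, either the
#' arithmetic mean or the range (max - min) of the allele scores.
#'
#' @param allele_scores Numeric vector of per-allele scores, each in \[0,1\].
#' @param method `"mean"` (default) or `"range"`.
#' @return A single score in \[0,1\].
#' @examples
#' aggregate_locus_score(c(0.8, 0.2), "mean")   # 0.5
#' aggregate_locus_score(c(0.8, 0.2), "range")  # 0.6
#' @export
aggregate_locus_score <- function(allele_scores, method = c("mean", "range")) {
  method <- match.arg(method)
  if (length(allele_scores) == 0L) {
    stop("allele_scores must be non-empty", call. = FALSE)
  }
  if (anyNA(allele_scores) || !is.numeric(allele_scores)) {
    stop("allele_scores must be numeric without missing values", call. = FALSE)
  }
  if (any(allele_scores < 0 | allele_scores > 1)) {
    stop("allele scores must lie in [0, 1]", call. = FALSE)
  }
  switch(method,
    mean  = mean(allele_scores),
    range = max(allele_scores) - min(allele_scores)
  )
}

#' Normalized variant score for one gene
#'
#' The per-gene variant score S_V is the ratio of the summed per-locus scores
#' of the gene's disease-associated variants to the summed per-locus scores of
#' all its variants. It lies in \[0,1\]: 1 when every scored variant is
#' disease-associated, 0 when none is.
#'
#' @param locus_scores Numeric vector of aggregated per-locus scores for all
#'   variants of one gene (see [aggregate_locus_score()]).
#' @param disease_associated Logical (or 0/1) vector, parallel to
#'   `locus_scores`, flagging variants whose trait terms match the disease.
#' @return S_V in \[0,1\], or `NA_real_` (with a warning) when all locus
#'   scores are zero and the ratio is undefined.
#' @export
normalize_variant_score <- function(locus_scores, disease_associated) {
  if (length(locus_scores) == 0L) {
    stop("locus_scores must be non-empty", call. = FALSE)
  }
  if (length(locus_scores) != length(disease_associated)) {
    stop("locus_scores and disease_associated must have equal length", call. = FALSE)
  }
  disease_associated <- as.logical(disease_associated)
  denom <- sum(locus_scores)
  if (denom <= 0) {
    warning("all locus scores are zero; variant ratio undefined", call. = FALSE)
    return(NA_real_)
  }
  sum(locus_scores[disease_associated]) / denom
}

#' Normalize gene disease-association Z-scores to \[0,1\]
#'
#' Gene scores S_G are the raw Z-scores divided by the maximum Z-score in the
#' table, so the top-ranked gene maps to exactly 1.
#'
#' @param z_scores Numeric vector of Z-scores, optionally named by gene.
#' @return Vector of S_G values, same names and order as the input.
#' @export
normalize_gene_scores <- function(z_scores) {
  if (length(z_scores) == 0L) {
    stop("gene score table is empty", call. = FALSE)
  }
  if (anyNA(z_scores) || any(!is.finite(z_scores))) {
    stop("Z-scores must be finite", call. = FALSE)
  }
  mx <- max(z_scores)
  if (mx <= 0) {
    stop("maximum Z-score must be positive for normalization", call. = FALSE)
  }
  z_scores / mx
}

parse_allele_scores <- function(x) {
  if (is.list(x)) return(lapply(x, as.numeric))
  lapply(strsplit(as.character(x), ",", fixed = TRUE), as.numeric)
}

#' Build a gene-variant map
#'
#' Combines a gene score table and a variant score table into the 2D map on
#' which the Voronoi analysis runs: x = S_G (max-normalized gene Z-score),
#' y = S_V (disease-associated fraction of summed variant deleteriousness).
#'
#' Variants whose gene is absent from the gene table are dropped with a
#' warning, as are genes whose variant-score denominator is zero (0/0 carries
#' no evidence). Genes with no variant record do not appear on the map.
#'
#' @param genes Data frame with columns `gene` and `z_score`.
#' @param variants Data frame with columns `variant_id`, `gene`,
#'   `allele_scores` (numeric list-column or comma-separated character) and
#'   `disease_associated` (logical or 0/1).
#' @param score_kind Which deleteriousness score the allele scores carry:
#'   `"one_minus_sift"` (default) or `"polyphen"`. Metadata only.
#' @param locus_aggregation Per-locus aggregation, `"mean"` (default) or
#'   `"range"`; see [aggregate_locus_score()].
#' @param disease_label Free-text disease name stored on the map.
#' @return An object of class `gene_variant_map`: a list with `points`
#'   (data frame `gene`, `x`, `y`), `score_kind`, `locus_aggregation` and
#'   `disease_label`.
#' @seealso [tessellate()], [read_map()], [write_map()]
#' @export
build_map <- function(genes, variants,
                      score_kind = c("one_minus_sift", "polyphen"),
                      locus_aggregation = c("mean", "range"),
                      disease_label = "") {
  score_kind <- match.arg(score_kind)
  locus_aggregation <- match.arg(locus_aggregation)
  stopifnot(is.data.frame(genes), is.data.frame(variants))
  if (!all(c("gene", "z_score") %in% names(genes))) {
    stop("gene table needs columns `gene` and `z_score`", call. = FALSE)
  }
  need <- c("variant_id", "gene", "allele_scores", "disease_associated")
  if (!all(need %in% names(variants))) {
    stop("variant table needs columns `", paste(need, collapse = "`, `"), "`",
         call. = FALSE)
  }
  if (anyDuplicated(genes$gene)) {
    stop("duplicate gene symbols in gene table", call. = FALSE)
  }
  if (anyDuplicated(variants[c("variant_id", "gene")])) {
    stop("duplicate (variant_id, gene) pairs in variant table", call. = FALSE)
  }

  known <- variants$gene %in% genes$gene
  if (!all(known)) {
    warning(sum(!known), " variant record(s) dropped: gene not in gene table (",
            paste(unique(variants$gene[!known]), collapse = ", "), ")",
            call. = FALSE)
    variants <- variants[known, , drop = FALSE]
  }

  scores <- parse_allele_scores(variants$allele_scores)
  locus <- vapply(scores, aggregate_locus_score, numeric(1),
                  method = locus_aggregation)
  flags <- as.logical(variants$disease_associated)

  sg <- normalize_gene_scores(genes$z_score)
  names(sg) <- genes$gene
  no_var <- setdiff(genes$gene, variants$gene)
  if (length(no_var) > 0L) {
    warning(length(no_var), " gene(s) have no variant records and are not on the map",
            call. = FALSE)
  }

  per_gene <- split(seq_len(nrow(variants)), variants$gene)
  y <- vapply(per_gene, function(idx) {
    suppressWarnings(normalize_variant_score(locus[idx], flags[idx]))
  }, numeric(1))
  undef <- is.na(y)
  if (any(undef)) {
    warning("gene(s) excluded (all variant scores zero): ",
            paste(names(y)[undef], collapse = ", "), call. = FALSE)
    y <- y[!undef]
  }

  pts <- data.frame(
    gene = names(y),
    x = unname(sg[names(y)]),
    y = unname(y),
    stringsAsFactors = FALSE
  )
  pts <- pts[order(pts$gene), , drop = FALSE]
  rownames(pts) <- NULL
  if (nrow(pts) < 3L) {
    warning("fewer than 3 mapped genes; the map cannot be tessellated",
            call. = FALSE)
  }
  structure(
    list(points = pts, score_kind = score_kind,
         locus_aggregation = locus_aggregation, disease_label = disease_label),
    class = "gene_variant_map"
  )
}

#' @export
print.gene_variant_map <- function(x, ...) {
  cat("Gene-variant map", if (nzchar(x$disease_label)) paste0("(", x$disease_label, ")"),
      "\n  genes:", nrow(x$points),
      "\n  score kind:", x$score_kind,
      "| locus aggregation:", x$locus_aggregation, "\n")
  invisible(x)
}

#' @export
as.data.frame.gene_variant_map <- function(x, ...) x$points
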