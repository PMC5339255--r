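#' Disease risk score for a clustered gene
#'
#' The risk score of a gene is the product of its normalized Voronoi cell
#' density and the score of the cluster it belongs to (the sum of member
#' densities). Only clustered genes carry a risk score: a gene outside every
#' cluster has no network support, which is different from a risk of zero.
#'
#' @param gene Gene symbol.
#' @param clusters A `cluster_set` from [detect_clusters()].
#' @param tess The `voronoi_tessellation` the clusters were detected on.
#' @return A `risk_score` object: list with `gene`, `f_norm`,
#'   `cluster_label`, `cluster_score`, `risk`.
#' @export
risk_score <- function(gene, clusters, tess) {
  stopifnot(inherits(clusters, "cluster_set"),
            inherits(tess, "voronoi_tessellation"))
  a <- clusters$assignment
  i <- match(gene, a$gene)
  if (is.na(i)) stop("gene not found on the map: ", gene, call. = FALSE)
  if (a$cluster_label[i] == 0L) {
    stop("no risk defined: gene is not in any cluster (", gene, ")", call. = FALSE)
  }
  out <- list(gene = gene,
              f_norm = a$normalized_density[i],
              cluster_label = a$cluster_label[i],
              cluster_score = a$cluster_score[i],
              risk = a$normalized_density[i] * a$cluster_score[i])
  class(out) <- "risk_score"
  out
}

#' Risk scores for every clustered gene
#'
#' @inheritParams risk_score
#' @return Data frame `gene`, `f_norm`, `cluster_label`, `cluster_score`,
#'   `risk`, one row per clustered gene, sorted by decreasing risk.
#' @export
risk_table <- function(clusters, tess) {
  a <- clusters$assignment
  a <- a[a$cluster_label > 0L, , drop = FALSE]
  out <- data.frame(gene = a$gene, f_norm = a$normalized_density,
                    cluster_label = a$cluster_label,
                    cluster_score = a$cluster_score,
                    risk = a$normalized_density * a$cluster_score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$risk, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

risk_value <- function(r) {
  if (inherits(r, "risk_score")) r$risk else as.numeric(r)
}

#' Relative risk between two gene carriers
#'
#' Ratio of two risk scores (normalized density times cluster score, per
#' gene). Accepts `risk_score` objects or bare numeric risk values. The
#' returned ratio is unrounded; round to two decimals for display.
#'
#' @param r_i,r_j Risk of the numerator and denominator carrier.
#' @return `r_i / r_j` as a single number.
#' @examples
#' relative_risk(112.71, 506.11)  # 0.2227 -> displayed as 0.22
#' @export
relative_risk <- function(r_i, r_j) {
  vi <- risk_value(r_i); vj <- risk_value(r_j)
  if (!is.finite(vi) || !is.finite(vj)) stop("risks must be finite", call. = FALSE)
  if (vj <= 0) stop("denominator risk must be positive", call. = FALSE)
  vi / vj
}

#' Gene/variant association scores for a set of genes
#'
#' Pulls each gene's map coordinates: `s_g` (normalized gene score, map x),
#' `s_v` (normalized variant score, map y) and their product.
#'
#' @param map A `gene_variant_map`.
#' @param genes Character vector of gene symbols (must be on the map).
#' @return Data frame `gene`, `s_g`, `s_v`, `product`.
#' @export
association_scores <- function(map, genes) {
  pts <- if (inherits(map, "gene_variant_map")) map$points else map
  i <- match(genes, pts$gene)
  if (anyNA(i)) {
    stop("gene(s) not on the map: ", paste(genes[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  data.frame(gene = genes, s_g = pts$x[i], s_v = pts$y[i],
             product = pts$x[i] * pts$y[i], stringsAsFactors = FALSE)
}

#' Relative disease association between two gene sets
#'
#' Ratio of the summed S_G x S_V products of set i to those of set j. The
#' exact unrounded ratio is returned in `ratio`; `ratio_as_reported` is the
#' ratio of the two-decimal-rounded summed products, matching the convention
#' of reporting per-set products rounded to two decimals (the two can differ
#' noticeably when products are small).
#'
#' @param set_i,set_j Data frames with columns `s_g` and `s_v` (or a
#'   precomputed `product` column), e.g. from [association_scores()].
#' @return List with `sum_i`, `sum_j`, `ratio`, `ratio_as_reported`.
#' @export
relative_disease_association <- function(set_i, set_j) {
  prod_of <- function(s) {
    if (!is.null(s$product)) return(sum(s$product))
    sum(s$s_g * s$s_v)
  }
  si <- prod_of(set_i); sj <- prod_of(set_j)
  if (sj <= 0) stop("denominator association sum must be positive", call. = FALSE)
  rep_j <- round(sj, 2)
  list(sum_i = si, sum_j = sj, ratio = si / sj,
       ratio_as_reported = if (rep_j > 0) round(si, 2) / rep_j else NA_real_)
}

#' @export
print.risk_score <- function(x, ...) {
  cat(sprintf("%s: risk %.2f (f~ %.3f x cluster %d score %.2f)\n",
              x$gene, x$risk, x$f_norm, x$cluster_label, x$cluster_score))
  invisible(x)
}
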