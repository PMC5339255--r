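#' Detect clusters of high-density Voronoi cells
#'
#' A cluster is a connected component of the graph induced by bounded cells
#' whose normalized density exceeds the threshold (strictly), connected
#' through qualified (Gabriel) neighbor edges. Components smaller than
#' `min_size` are reported as unclustered. Connected components give exactly
#' the partition a flood fill from random seeds would, independent of
#' visiting order. Unbounded cells never join clusters.
#'
#' @param tess A `voronoi_tessellation` with normalized densities and
#'   qualified edges (see [build_tessellation()]).
#' @param threshold Clustering threshold on normalized density, typically
#'   `background_fit(tess)$threshold`.
#' @param min_size Minimum component size to count as a cluster; default 2
#'   (an isolated high-density cell has no network support).
#' @return A `cluster_set`: list with `clusters` (list of integer site-index
#'   vectors), `scores` (per-cluster sum of member normalized densities),
#'   `assignment` (data frame `gene`, `cluster_label` with 0 = unclustered,
#'   `normalized_density`, `cluster_score`), `threshold` and `min_size`.
#'   Cluster labels run 1, 2, ... in decreasing score order (ties broken by
#'   the lexicographically smallest member gene).
#' @export
detect_clusters <- function(tess, threshold, min_size = 2L) {
  stopifnot(inherits(tess, "voronoi_tessellation"))
  if (!is.finite(threshold)) stop("threshold must be finite", call. = FALSE)
  if (min_size < 1L) stop("min_size must be >= 1", call. = FALSE)
  cl <- tess$cells
  if (all(is.na(cl$normalized_density[cl$bounded]))) {
    stop("normalized densities missing; run normalize_densities() first", call. = FALSE)
  }
  if (all(is.na(tess$edges$qualified))) {
    stop("qualified edges missing; run qualified_neighbors() first", call. = FALSE)
  }

  hot <- which(cl$bounded & !is.na(cl$normalized_density) &
                 cl$normalized_density > threshold)
  e <- tess$edges[tess$edges$qualified %in% TRUE, c("site_a", "site_b")]
  e <- e[e$site_a %in% hot & e$site_b %in% hot, , drop = FALSE]

  members <- list()
  if (length(hot) > 0L) {
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = match(e$site_a, hot), to = match(e$site_b, hot)),
      directed = FALSE,
      vertices = data.frame(name = seq_along(hot))
    )
    comp <- igraph::components(g)$membership
    members <- split(hot[as.integer(names(comp))], comp)
    members <- unname(members[lengths(members) >= min_size])
  }

  cs <- structure(
    list(clusters = members, scores = NULL,
         assignment = NULL, threshold = threshold, min_size = as.integer(min_size)),
    class = "cluster_set"
  )
  score_clusters(cs, tess)
}

#' Score clusters and assign canonical labels
#'
#' Each cluster's score is the sum of its members' normalized Voronoi cell
#' densities. Labels are (re)assigned 1, 2, ... by decreasing score, ties
#' broken by the lexicographically smallest member gene symbol.
#'
#' @param cs A `cluster_set` (memberships present).
#' @param tess The `voronoi_tessellation` the clusters were detected on.
#' @return The `cluster_set` with `scores` and `assignment` filled in.
#' @export
score_clusters <- function(cs, tess) {
  stopifnot(inherits(cs, "cluster_set"), inherits(tess, "voronoi_tessellation"))
  cl <- tess$cells
  scores <- vapply(cs$clusters, function(m) sum(cl$normalized_density[m]), numeric(1))
  first_gene <- vapply(cs$clusters, function(m) min(cl$gene[m]), character(1))
  ord <- order(-scores, first_gene)
  cs$clusters <- cs$clusters[ord]
  cs$scores <- scores[ord]

  label <- integer(nrow(cl))
  cscore <- rep(NA_real_, nrow(cl))
  for (k in seq_along(cs$clusters)) {
    label[cs$clusters[[k]]] <- k
    cscore[cs$clusters[[k]]] <- cs$scores[k]
  }
  cs$assignment <- data.frame(
    gene = cl$gene, cluster_label = label,
    normalized_density = cl$normalized_density,
    cluster_score = cscore, stringsAsFactors = FALSE
  )
  cs
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("Voronoi cluster set (threshold ", signif(x$threshold, 4),
      ", min size ", x$min_size, ")\n", sep = "")
  if (length(x$clusters) == 0L) {
    cat("  no clusters detected\n")
  } else {
    for (k in seq_along(x$clusters)) {
      genes <- sort(x$assignment$gene[x$assignment$cluster_label == k])
      cat(sprintf("  cluster %d (score %.2f): %s\n", k, x$scores[k],
                  paste(genes, collapse = ", ")))
    }
  }
  cat("  unclustered sites:", sum(x$assignment$cluster_label == 0L), "\n")
  invisible(x)
}
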