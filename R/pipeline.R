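#' Full Voronoi risk analysis of a gene-variant map
#'
#' Runs the complete pipeline on a map: tessellation with normalized
#' densities and qualified neighbor edges, chi-square background fit and
#' clustering threshold, cluster detection and scoring, and per-gene risk
#' scores.
#'
#' @param map A `gene_variant_map` (from [build_map()], [read_map()] or
#'   [make_mock_map()]).
#' @param fraction Background fraction for the threshold fit; default 0.8.
#' @param significance Significance level for the threshold; default 0.9.
#' @param min_size Minimum cluster size; default 2.
#' @param integer_b Restrict the fitted density exponent to integers.
#' @return A `vorisk_analysis`: list with `map`, `tessellation`, `fit`
#'   (`background_fit`), `clusters` (`cluster_set`) and `risk` (data frame
#'   from [risk_table()]).
#' @examples
#' map <- make_mock_map(seed = 11)
#' res <- voronoi_risk(map)
#' res$fit$threshold
#' length(res$clusters$clusters)
#' @export
voronoi_risk <- function(map, fraction = 0.8, significance = 0.9,
                         min_size = 2L, integer_b = FALSE) {
  tess <- build_tessellation(map)
  fit <- background_fit(tess, fraction = fraction, significance = significance,
                        integer_b = integer_b)
  clusters <- detect_clusters(tess, fit$threshold, min_size = min_size)
  out <- list(map = map, tessellation = tess, fit = fit, clusters = clusters,
              risk = risk_table(clusters, tess))
  class(out) <- "vorisk_analysis"
  out
}

#' @export
print.vorisk_analysis <- function(x, ...) {
  cat("Voronoi risk analysis:", nrow(x$map$points), "genes\n")
  print(x$fit)
  print(x$clusters)
  if (nrow(x$risk) > 0L) {
    cat("Top risk scores:\n")
    print(utils::head(x$risk, 5), row.names = FALSE)
  }
  invisible(x)
}
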