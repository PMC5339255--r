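# In-code fixtures; nothing is read from disk except the golden map TSV.

random_sites <- function(n, seed) {
  set.seed(seed)
  cbind(stats::runif(n), stats::runif(n))
}

sites_map <- function(xy, genes = sprintf("G%04d", seq_len(nrow(xy)))) {
  data.frame(gene = genes, x = xy[, 1], y = xy[, 2], stringsAsFactors = FALSE)
}

# Minimal hand-built tessellation carrying prescribed normalized densities,
# for exercising scoring/risk arithmetic without geometry.
fake_tess <- function(fnorm, genes = sprintf("g%02d", seq_along(fnorm)),
                      edges = data.frame(site_a = integer(0),
                                         site_b = integer(0),
                                         qualified = logical(0))) {
  cells <- data.frame(
    gene = genes, x = seq_along(fnorm), y = 0,
    bounded = !is.na(fnorm), area = 1 / fnorm, density = fnorm,
    normalized_density = fnorm, stringsAsFactors = FALSE
  )
  structure(list(cells = cells, edges = edges,
                 sites = cbind(seq_along(fnorm), 0),
                 n_finite = sum(!is.na(fnorm))),
            class = "voronoi_tessellation")
}

fake_cluster_set <- function(members, tess, min_size = 1L) {
  cs <- structure(list(clusters = members, scores = NULL, assignment = NULL,
                       threshold = 0, min_size = as.integer(min_size)),
                  class = "cluster_set")
  score_clusters(cs, tess)
}
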