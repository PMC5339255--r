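#' Read a gene score table
#'
#' Tab-separated, columns `gene` and `z_score` (case-sensitive); unknown
#' columns are ignored.
#'
#' @param path File path.
#' @return Data frame with columns `gene`, `z_score`.
#' @export
read_gene_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("gene", "z_score") %in% names(d))) {
    stop("gene table must have columns `gene` and `z_score`: ", path, call. = FALSE)
  }
  d[c("gene", "z_score")]
}

#' Read a variant score table
#'
#' Tab-separated, columns `variant_id`, `gene`, `allele_scores`
#' (comma-separated reals) and `disease_associated` (0/1).
#'
#' @param path File path.
#' @return Data frame with the four required columns; `allele_scores` stays a
#'   comma-separated character column (parsed by [build_map()]).
#' @export
read_variant_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("variant_id", "gene", "allele_scores", "disease_associated")
  if (!all(need %in% names(d))) {
    stop("variant table must have columns `", paste(need, collapse = "`, `"),
         "`: ", path, call. = FALSE)
  }
  d$allele_scores <- as.character(d$allele_scores)
  d[need]
}

#' Write a gene-variant map to TSV
#'
#' Columns `gene`, `x`, `y`; coordinates with 6 decimal places.
#'
#' @param map A `gene_variant_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path) {
  pts <- as.data.frame(map)
  out <- data.frame(gene = pts$gene,
                    x = sprintf("%.6f", pts$x),
                    y = sprintf("%.6f", pts$y))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-variant map from TSV
#'
#' @param path File with columns `gene`, `x`, `y`.
#' @param score_kind,locus_aggregation,disease_label Metadata to attach
#'   (TSV maps do not store it).
#' @return A `gene_variant_map`.
#' @export
read_map <- function(path, score_kind = "one_minus_sift",
                     locus_aggregation = "mean", disease_label = "") {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "x", "y") %in% names(d))) {
    stop("map file must have columns `gene`, `x`, `y`: ", path, call. = FALSE)
  }
  pts <- data.frame(gene = as.character(d$gene), x = as.numeric(d$x),
                    y = as.numeric(d$y), stringsAsFactors = FALSE)
  structure(
    list(points = pts, score_kind = score_kind,
         locus_aggregation = locus_aggregation, disease_label = disease_label),
    class = "gene_variant_map"
  )
}

#' Write Voronoi cell and edge tables
#'
#' `write_cells()` writes one row per gene with its coordinates, cell area
#' (empty for unbounded cells), raw density and normalized density.
#' `write_edges()` writes the Delaunay neighbor pairs with their
#' qualified-neighbor (Gabriel) flag.
#'
#' @param tess A `voronoi_tessellation` (densities/qualified flags filled in
#'   so far are written as-is).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cells <- function(tess, path) {
  cl <- tess$cells
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.10g", v))
  out <- data.frame(gene = cl$gene,
                    x = sprintf("%.6f", cl$x), y = sprintf("%.6f", cl$y),
                    area = fmt(cl$area), density = fmt(cl$density),
                    normalized_density = fmt(cl$normalized_density))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cells
#' @export
write_edges <- function(tess, path) {
  e <- tess$edges
  out <- data.frame(gene_a = tess$cells$gene[e$site_a],
                    gene_b = tess$cells$gene[e$site_b],
                    qualified = as.integer(e$qualified))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write cluster assignments to TSV
#'
#' One row per gene: `gene`, `cluster_label` (0 = unclustered),
#' `normalized_density`, `cluster_score` (empty for unclustered genes).
#'
#' @param cs A `cluster_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(cs, path) {
  a <- cs$assignment
  fmt <- function(v) ifelse(is.na(v), "", sprintf("%.10g", v))
  out <- data.frame(gene = a$gene, cluster_label = a$cluster_label,
                    normalized_density = fmt(a$normalized_density),
                    cluster_score = fmt(a$cluster_score))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rebuild pipeline objects from their TSV/table form
#'
#' `tessellation_from_tables()` reconstructs a `voronoi_tessellation` from
#' the cell and edge tables written by [write_cells()] and [write_edges()];
#' `cluster_set_from_table()` reconstructs a `cluster_set` from the table
#' written by [write_clusters()]. These let the pipeline stages be chained
#' through files (as the command-line tool does) without recomputing the
#' geometry.
#'
#' @param cells Data frame with columns `gene`, `x`, `y`, `area`, `density`,
#'   `normalized_density` (blank/NA area marks unbounded cells).
#' @param edges Data frame with columns `gene_a`, `gene_b`, `qualified`.
#' @return A `voronoi_tessellation`.
#' @export
tessellation_from_tables <- function(cells, edges) {
  num <- function(v) suppressWarnings(as.numeric(v))
  cl <- data.frame(
    gene = as.character(cells$gene), x = num(cells$x), y = num(cells$y),
    bounded = !is.na(num(cells$area)), area = num(cells$area),
    density = num(cells$density), normalized_density = num(cells$normalized_density),
    stringsAsFactors = FALSE
  )
  a <- match(edges$gene_a, cl$gene)
  b <- match(edges$gene_b, cl$gene)
  if (anyNA(a) || anyNA(b)) {
    stop("edge table names genes missing from the cell table", call. = FALSE)
  }
  e <- data.frame(site_a = pmin(a, b), site_b = pmax(a, b),
                  qualified = as.logical(as.integer(edges$qualified)))
  e <- e[order(e$site_a, e$site_b), , drop = FALSE]
  rownames(e) <- NULL
  structure(
    list(cells = cl, edges = e, sites = cbind(cl$x, cl$y),
         n_finite = sum(cl$bounded)),
    class = "voronoi_tessellation"
  )
}

#' @rdname tessellation_from_tables
#' @param clusters Data frame with columns `gene`, `cluster_label`,
#'   `normalized_density`, `cluster_score` (0 label = unclustered).
#' @param threshold,min_size Metadata carried on the rebuilt `cluster_set`.
#' @return For `cluster_set_from_table()`, a `cluster_set`.
#' @export
cluster_set_from_table <- function(clusters, threshold = NA_real_, min_size = 2L) {
  lab <- as.integer(clusters$cluster_label)
  members <- lapply(sort(unique(lab[lab > 0L])), function(k) which(lab == k))
  assignment <- data.frame(
    gene = as.character(clusters$gene), cluster_label = lab,
    normalized_density = suppressWarnings(as.numeric(clusters$normalized_density)),
    cluster_score = suppressWarnings(as.numeric(clusters$cluster_score)),
    stringsAsFactors = FALSE
  )
  scores <- vapply(members, function(m) sum(assignment$normalized_density[m]),
                   numeric(1))
  structure(
    list(clusters = members, scores = scores, assignment = assignment,
         threshold = threshold, min_size = as.integer(min_size)),
    class = "cluster_set"
  )
}
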