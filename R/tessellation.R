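#' Voronoi tessellation of a gene-variant map
#'
#' Partitions the plane into Voronoi cells around the map's gene points and
#' extracts the Delaunay neighbor edges. Cells of sites on the convex-hull
#' boundary are unbounded; they carry no area or density and are excluded
#' from density normalization and clustering. Bounded cell areas come from
#' the polygon (shoelace) area of the cell's vertex ring.
#'
#' @param map A `gene_variant_map`, or any data frame with columns
#'   `gene`, `x`, `y`.
#' @param jitter Optional half-width of deterministic uniform jitter added to
#'   every coordinate (opt-in escape hatch for exactly duplicated points;
#'   default 0 = off, duplicates are an error).
#' @param seed Seed for the jitter draw; required when `jitter > 0`.
#' @param bounding_box Optional numeric `c(xmin, xmax, ymin, ymax)`. When
#'   given, cells are clipped to this box and all cells are treated as
#'   bounded — an extension for users who want boundary cells in the
#'   analysis; the default (NULL) mirrors the exclusion of infinite boundary
#'   cells.
#' @return A `voronoi_tessellation`: list with `cells` (data frame `gene`,
#'   `x`, `y`, `bounded`, `area`, `density`, `normalized_density`), `edges`
#'   (data frame `site_a`, `site_b`, `qualified`), `sites` (n x 2 matrix) and
#'   `n_finite` (number of bounded cells). `normalized_density` is filled by
#'   [normalize_densities()], `qualified` by [qualified_neighbors()].
#' @seealso [build_tessellation()] for the one-call pipeline.
#' @export
tessellate <- function(map, jitter = 0, seed = NULL, bounding_box = NULL) {
  pts <- if (inherits(map, "gene_variant_map")) map$points else map
  stopifnot(is.data.frame(pts), all(c("gene", "x", "y") %in% names(pts)))
  n <- nrow(pts)
  if (n < 3L) stop("at least 3 sites are required", call. = FALSE)

  xy <- cbind(pts$x, pts$y)
  if (jitter > 0) {
    if (is.null(seed)) stop("jitter requires a seed for reproducibility", call. = FALSE)
    set.seed(seed)
    xy <- xy + matrix(stats::runif(2L * n, -jitter, jitter), ncol = 2L)
  }

  dup <- duplicated(xy) | duplicated(xy, fromLast = TRUE)
  if (any(dup)) {
    stop("duplicate coordinates for genes: ",
         paste(pts$gene[dup], collapse = ", "),
         " (use jitter= with a seed to separate them)", call. = FALSE)
  }
  sv <- svd(scale(xy, center = TRUE, scale = FALSE))$d
  if (sv[2] <= 1e-12 * max(sv[1], 1)) {
    stop("all sites are collinear; the tessellation is degenerate", call. = FALSE)
  }

  if (is.null(bounding_box)) {
    # window far outside the data: cells clipped by it are exactly the
    # unbounded (convex-hull) cells, and bounded cells keep exact areas
    diam <- max(diff(range(xy[, 1])), diff(range(xy[, 2])))
    pad <- 10 * diam
    rw <- c(range(xy[, 1]) + c(-pad, pad), range(xy[, 2]) + c(-pad, pad))
    clip_all_bounded <- FALSE
  } else {
    stopifnot(length(bounding_box) == 4L)
    rw <- bounding_box
    clip_all_bounded <- TRUE
  }

  dd <- deldir::deldir(xy[, 1], xy[, 2], rw = rw, suppressMsge = TRUE)
  bounded <- if (clip_all_bounded) rep(TRUE, n) else dd$summary$nbpt == 0
  area <- dd$summary$dir.area
  area[!bounded] <- NA_real_

  e <- unique(data.frame(
    site_a = pmin(dd$delsgs$ind1, dd$delsgs$ind2),
    site_b = pmax(dd$delsgs$ind1, dd$delsgs$ind2)
  ))
  e <- e[order(e$site_a, e$site_b), , drop = FALSE]
  rownames(e) <- NULL
  e$qualified <- NA

  cells <- data.frame(
    gene = pts$gene, x = xy[, 1], y = xy[, 2],
    bounded = bounded, area = area,
    density = 1 / area,
    normalized_density = NA_real_,
    stringsAsFactors = FALSE
  )
  structure(
    list(cells = cells, edges = e, sites = xy, n_finite = sum(bounded)),
    class = "voronoi_tessellation"
  )
}

#' Normalize Voronoi cell densities
#'
#' The normalized density of a bounded cell is its raw density (1/area)
#' divided by the inverse mean bounded-cell area — equivalently, the mean
#' bounded area divided by the cell's own area. A value of 1 means locally
#' average point density; large values flag locally crowded regions. The
#' harmonic identity sum(1/f~) = n_finite holds exactly. Unbounded cells are
#' left untouched (no density defined).
#'
#' @param tess A `voronoi_tessellation` from [tessellate()].
#' @return The tessellation with `cells$normalized_density` filled in.
#' @export
normalize_densities <- function(tess) {
  stopifnot(inherits(tess, "voronoi_tessellation"))
  if (tess$n_finite < 1L) {
    stop("no bounded cells: normalization undefined", call. = FALSE)
  }
  b <- tess$cells$bounded
  mean_area <- mean(tess$cells$area[b])
  tess$cells$normalized_density[b] <- mean_area / tess$cells$area[b]
  tess
}

#' Mark qualified (Gabriel) neighbor edges
#'
#' A Delaunay pair qualifies as nearest neighbors when the midpoint of the
#' connecting segment is at least as close to the pair as to every other
#' site, i.e. the open disk with the segment as diameter contains no other
#' site (ties on the circle qualify). Cluster detection walks only these
#' edges.
#'
#' @param tess A `voronoi_tessellation`.
#' @return The tessellation with `edges$qualified` filled in (logical).
#' @export
qualified_neighbors <- function(tess) {
  stopifnot(inherits(tess, "voronoi_tessellation"))
  xy <- tess$sites
  e <- tess$edges
  tol <- 1e-12 * max(1, max(abs(xy)))
  qual <- logical(nrow(e))
  for (k in seq_len(nrow(e))) {
    i <- e$site_a[k]; j <- e$site_b[k]
    m <- (xy[i, ] + xy[j, ]) / 2
    r2 <- sum((xy[i, ] - m)^2)
    d2 <- (xy[, 1] - m[1])^2 + (xy[, 2] - m[2])^2
    d2[c(i, j)] <- Inf
    qual[k] <- min(d2) >= r2 - tol
  }
  tess$edges$qualified <- qual
  tess
}

#' Tessellate, normalize and qualify in one call
#'
#' Convenience wrapper running [tessellate()], [normalize_densities()] and
#' [qualified_neighbors()].
#'
#' @inheritParams tessellate
#' @return A fully populated `voronoi_tessellation`.
#' @export
build_tessellation <- function(map, jitter = 0, seed = NULL, bounding_box = NULL) {
  qualified_neighbors(normalize_densities(
    tessellate(map, jitter = jitter, seed = seed, bounding_box = bounding_box)
  ))
}

#' @export
print.voronoi_tessellation <- function(x, ...) {
  cat("Voronoi tessellation\n",
      " sites:", nrow(x$cells),
      "| bounded cells:", x$n_finite,
      "| Delaunay edges:", nrow(x$edges), "\n")
  if (!all(is.na(x$edges$qualified))) {
    cat("  qualified (Gabriel) edges:", sum(x$edges$qualified), "\n")
  }
  invisible(x)
}
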