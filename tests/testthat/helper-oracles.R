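# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: areas by Monte-Carlo nearest-site sampling, neighbor
# qualification by the all-pairs open-disk test, components by union-find,
# the model CDF by quadrature of the density.

# Monte-Carlo estimate of Voronoi cell areas inside a sampling box.
mc_cell_areas <- function(xy, n_samples = 1e6, box = NULL, seed = 99,
                          chunk = 2e5) {
  set.seed(seed)
  if (is.null(box)) {
    box <- c(range(xy[, 1]), range(xy[, 2]))
  }
  counts <- integer(nrow(xy))
  done <- 0
  while (done < n_samples) {
    m <- min(chunk, n_samples - done)
    px <- stats::runif(m, box[1], box[2])
    py <- stats::runif(m, box[3], box[4])
    d2 <- outer(px, xy[, 1], "-")^2 + outer(py, xy[, 2], "-")^2
    nearest <- max.col(-d2, ties.method = "first")
    counts <- counts + tabulate(nearest, nbins = nrow(xy))
    done <- done + m
  }
  box_area <- (box[2] - box[1]) * (box[4] - box[3])
  counts / n_samples * box_area
}

# All-pairs Gabriel test: (i, j) are qualified neighbors iff no other site
# lies strictly inside the open disk on segment ij as diameter.
brute_gabriel <- function(xy, tol = 1e-12) {
  n <- nrow(xy)
  out <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m <- (xy[i, ] + xy[j, ]) / 2
    r2 <- sum((xy[i, ] - m)^2)
    d2 <- (xy[, 1] - m[1])^2 + (xy[, 2] - m[2])^2
    d2[c(i, j)] <- Inf
    if (min(d2) >= r2 - tol) out <- rbind(out, c(i, j))
  }
  out
}

# Plain union-find over an edge list; returns a component id per node.
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (!is.null(edges) && nrow(edges) > 0) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Randomized flood fill over qualified edges among above-threshold sites;
# mirrors a seed-by-seed cluster growth with random visiting order.
flood_fill_clusters <- function(hot, edges, order_seed = 1) {
  set.seed(order_seed)
  shuffle <- function(v) if (length(v) > 1) sample(v) else v
  adj <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  visited <- logical(max(c(hot, 1)))
  clusters <- list()
  for (p in shuffle(hot)) {
    if (visited[p]) next
    queue <- p; visited[p] <- TRUE; comp <- integer(0)
    while (length(queue) > 0) {
      q <- queue[[1]]; queue <- queue[-1]; comp <- c(comp, q)
      nb <- adj[[as.character(q)]]
      nb <- nb[nb %in% hot & !visited[nb]]
      if (length(nb) > 0) { visited[nb] <- TRUE; queue <- c(queue, shuffle(nb)) }
    }
    clusters[[length(clusters) + 1]] <- sort(comp)
  }
  clusters
}

# Model CDF by quadrature of the transformed chi-square density, and its
# numeric inversion — independent of pchisq-based evaluation in the package.
model_pdf <- function(t, a, b, cc) {
  stats::dchisq(cc * t^b, df = a) * cc * b * t^(b - 1)
}
quad_cdf <- function(t, a, b, cc) {
  stats::integrate(model_pdf, 0, t, a = a, b = b, cc = cc,
                   rel.tol = 1e-10)$value
}
quad_threshold <- function(a, b, cc, significance) {
  hi <- 1
  while (quad_cdf(hi, a, b, cc) < significance) hi <- hi * 2
  stats::uniroot(function(t) quad_cdf(t, a, b, cc) - significance,
                 c(1e-12, hi), tol = 1e-12)$root
}

# Inverse-CDF sampler for the background model: c * X^b ~ chi-square(a).
sample_chisq_model <- function(n, a, b, cc) {
  (stats::qchisq(stats::runif(n), df = a) / cc)^(1 / b)
}

# Best-match F1 of detected clusters against planted blob labels.
planted_f1 <- function(labels, assignment) {
  ks <- setdiff(unique(assignment$cluster_label), 0L)
  blob_ids <- setdiff(unique(labels), 0L)
  if (length(blob_ids) == 0) return(NA_real_)
  f1 <- vapply(blob_ids, function(b) {
    truth <- labels == b
    best <- 0
    for (k in ks) {
      pred <- assignment$cluster_label == k
      tp <- sum(pred & truth)
      if (tp == 0) next
      p <- tp / sum(pred); r <- tp / sum(truth)
      best <- max(best, 2 * p * r / (p + r))
    }
    best
  }, numeric(1))
  mean(f1)
}

# Shoelace area of the convex hull of a point set (sanity bound on the sum
# of bounded cell areas).
hull_area <- function(xy) {
  h <- grDevices::chull(xy)
  hx <- xy[h, 1]; hy <- xy[h, 2]
  abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
}

# Partition of clustered genes as a canonical set-of-sets, for
# order-invariance comparisons.
gene_partition <- function(cs) {
  parts <- lapply(seq_along(cs$clusters), function(k) {
    sort(cs$assignment$gene[cs$assignment$cluster_label == k])
  })
  parts[order(vapply(parts, paste, character(1), collapse = "|"))]
}
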