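# vorisk

Voronoi tessellation network analysis for disease risk assessment from
gene- and variant-level association scores.

## What problem this solves

Gene-level association scores (e.g. Z-scores from text-mining databases) and
variant-level deleteriousness scores (1-SIFT, PolyPhen) each tell half the
story of a complex disease such as an autoimmune disorder. `vorisk` combines
them into a two-dimensional **gene-variant map** — one point per gene, with

- x = S_G: the gene's Z-score normalized by the maximum Z-score in the table,
- y = S_V: Σ(locus scores of disease-associated variants) / Σ(locus scores of
  all variants of the gene),

and then quantifies risk geometrically. The map is tessellated into Voronoi
cells; the normalized cell density

    f~_i = (mean bounded cell area) / A_i

is a local crowding measure (unbounded boundary cells are excluded). A
three-parameter chi-square family F(t) = χ²CDF(c·t^b; a) is fitted by least
squares to the empirical CDF of the lower 80% of densities, and the
clustering threshold t\* solves F(t\*) = 0.9. Clusters are connected
components of cells with f~ > t\* linked by qualified (Gabriel) neighbor
edges — Delaunay pairs whose midpoint is at least as close to the pair as to
any other site. Each cluster is scored by Σ f~ over its members, and a
clustered gene's **risk score** is

    risk(g) = f~(g) × cluster_score(cluster(g)),

with the relative risk between two carriers the ratio of their risk scores
and the relative disease association between gene sets the ratio of their
summed S_G·S_V products.

The package is aimed at statistical geneticists and systems biologists who
have pre-extracted score tables (ClinVar-style variant flags, DISEASES-style
gene scores) and want a reproducible, fully testable implementation of this
density-based clustering and risk pipeline — database parsing is out of
scope by design.

## Worked example

```r
library(vorisk)

map <- make_mock_map(seed = 11)   # 40 uniform background genes + two planted
res <- voronoi_risk(map)          # 15-point blobs at (0.3,0.3) and (0.7,0.7)
print(res)
```

```
Voronoi risk analysis: 70 genes
Chi-square background fit
  a = 13.23, b = 0.2424, c = 10 (objective 0.183)
  background: lower 80% (n = 48, cutoff 278.9)
  clustering threshold at 90% significance: 17.84
Voronoi cluster set (threshold 17.84, min size 2)
  cluster 1 (score 3303.74): G0056, G0057, G0059, G0060, G0061, G0062, G0066, G0067, G0068, G0070
  cluster 2 (score 2581.58): G0041, G0043, G0045, G0046, G0047, G0048, G0049, G0054, G0055
  unclustered sites: 51
Top risk scores:
  gene   f_norm cluster_label cluster_score    risk
 G0060 557.7225             1      3303.737 1842568
 G0067 527.5754             1      3303.737 1742970
 G0043 673.1134             2      2581.583 1737698
 G0056 476.1046             1      3303.737 1572924
 G0057 398.3732             1      3303.737 1316120
```

The two planted blobs come back as the two clusters; every cluster member is
a blob point. Blob cells are hundreds of times denser than average (f~ in the
hundreds vs. ≈1 for background), the 80% background cutoff and the fitted
threshold sit between the two populations, and risk scores rank blob
interiors highest. Carrier comparisons then read:

```r
relative_risk(risk_score("G0043", res$clusters, res$tessellation),
              risk_score("G0060", res$clusters, res$tessellation))
#> [1] 0.9430848
```

A thin command-line front end over the same functions lives at
`inst/cli/vorisk.R` (`build-map`, `tessellate`, `fit-threshold`, `cluster`,
`risk`, `synth-mock-map`, `synth-toy-tables`), chaining the stages through
TSV/JSON files.

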