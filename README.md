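# immunospat

Spatial analysis of the immune microenvironment in whole-slide
multiplexed-imaging cell tables, for computational pathology and tumor
immunology groups working with CyCIF/CODEX-style per-cell data. The package
detects and characterizes immune-cell clusters — candidate tertiary
lymphoid structures (TLS) — in annotated tumor sections, and quantifies
B/T-cell spatial organization from single cells up to whole-slide scale.

## What it computes

**Immune-cluster detection.** B-cell immune clusters (BICs) are found by a
two-stage KNN rule: *nucleation* keeps B cells whose 25 nearest neighbours
are ≥ 50% B cells; nuclei are grouped by connected components of the
symmetric 25-NN graph; each group is *expanded* to a fixpoint with any
immune cell (a 20-marker panel, or by phenotype) having ≥ 20% B cells among
its 100 nearest neighbours and lying within the 100-NN neighbourhood of a
member; clusters under 300 cells are dropped. T-cell clusters (TICs) come
from DBSCAN over T cells with a 50 μm expansion radius and a 100-cell
minimum.

**ICAT.** Cluster organization is scored by the independent-component
dispersion statistic

    ICAT = c · (σ₁ + σ₂) / √n

where σᵢ are the standard deviations of the member coordinates projected on
the two maximally independent directions found by FastICA (orthogonal PCA
axes when the ICA directions are degenerate), and n is the member count.
Dense, symmetric, TLS-like follicles score low; sparse irregular aggregates
score high. Clusters are classed *organized* (< 13.7), *intermediate*, or
*disorganized* (> 32.4) by the reference quartile cutoffs.

**Centered L-functions.** Clustering beyond discrete clusters is measured
with the centered Besag L-function `CLF(r) = √(K̂(r)/π) − r` (zero under
complete spatial randomness) and its multitype analogue (MCLF, zero under
independence of two cell types), estimated per 9 mm² tile with a fourfold
systematic half-tile offset scheme and averaged. Curves are summarized by
the clustering intensity CI (positive integral), the half-mass radius R50,
and the effective clustering radius ECR = 2·R50 (CCI/ECCR for cross-type).

**Geometry and statistics.** Lymphocyte infiltration density over
union-of-20 μm-disk tissue areas, cluster–tumor distances and
intra/extratumoral calls against pathologist GeoJSON annotations, BIC–TIC
association within 500 μm, cell–cell contact at a ≤ 2 μm boundary gap, and
the cohort-level tests used alongside (Jonckheere–Terpstra, Mann–Whitney,
Levene, paired t, two-proportion z, regression F, Jensen–Shannon
divergence).

**Synthetic specimens.** A seeded generator plants organized/disorganized
clusters, Thomas-process T-cell fields and CSR stroma with full ground
truth, and every analysis above is validated against it.

## Worked example

```r
library(immunospat)

sp <- generate_specimen(validation_spec(seed = 11))
sp
#> specimen synthetic - 7760 cells, 1 tumor domain(s), grade group HGG

bics <- score_clusters_icat(detect_bics(sp$cells), sp$cells)
bics <- localize_clusters(bics, sp$domains)
tics <- detect_tics(sp$cells)
for (b in bics) print(b)
#> BIC BIC001: 585 cells, centroid (1199, 1194) um, ICAT 7.73,  extratumoral
#> BIC BIC002: 558 cells, centroid (1304, 4706) um, ICAT 7.92,  extratumoral
#> BIC BIC003: 568 cells, centroid (4605, 1300) um, ICAT 7.86,  extratumoral

infl <- infiltration_density(sp, c("B", "Ki67+ B"))
sprintf("B-cell infiltration: %.1f cells/mm2", infl$specimen)
#> "B-cell infiltration: 49.3 cells/mm2"

curve <- windowed_cohort_curve(sp$cells, c("B", "Ki67+ B"), frame = c(6000, 6000))
summarize_curve(curve)
#> CI = 358022.2 um^2, R50 = 480 um, ECR = 960 um
```

The three planted B-cell clusters are recovered with their ICAT ≈ 7.8
(organized: uniform 150 μm disks of ~560 cells), localized against the
tumor polygon, and the whole-slide CLF summary reflects the planted
clustering scale. `run_pipeline()` executes the same chain end-to-end from
a single YAML/list config and writes a tidy CSV bundle with a manifest;
rerunning with the same config and seed reproduces the CSVs byte for byte.

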