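#' Immune-cluster detection parameters
#'
#' BIC (B-cell immune cluster) detection is a two-stage KNN procedure:
#' nucleation selects B cells whose 25 nearest neighbours are at least 50%
#' B cells; nuclei are grouped by connected components of the symmetric
#' 25-NN graph; each group is then expanded, to a fixpoint, with any
#' immune cell having at least 20% B cells among its 100 nearest
#' neighbours that lies within the (symmetric) 100-NN neighbourhood of a
#' current member; clusters below 300 cells are dropped.
#'
#' A cell counts as "immune" for expansion if its phenotype is in
#' `immune_phenotypes`, or if it carries a positive call for any marker in
#' `immune_markers` (the canonical 20-marker panel: CD11b, CD68, CD163,
#' CD4, CD3d, CD8a, TCF1, FOXP3, PD-1, CD57, CD11c, GZB, CD15, HLA-DR,
#' CD103, CD31, pTBK1, CD24, CD44, CD206).
#'
#' @param k_nucleate,frac_nucleate nucleation neighbourhood size and B
#'   fraction (defaults 25 and 0.50)
#' @param k_expand,frac_expand expansion neighbourhood size and B fraction
#'   (defaults 100 and 0.20)
#' @param min_cells minimum eligible cluster size (default 300)
#' @param b_phenotypes phenotype labels counted as B cells
#' @param immune_phenotypes phenotype labels eligible for expansion
#' @param immune_markers marker names whose positive call makes a cell
#'   eligible for expansion
#' @export
bic_params <- function(k_nucleate = 25, frac_nucleate = 0.50,
                       k_expand = 100, frac_expand = 0.20, min_cells = 300,
                       b_phenotypes = c("B", "Ki67+ B"),
                       immune_phenotypes = c("B", "Ki67+ B", "T", "CD4 T",
                                             "CD8 T", "Treg", "Tex", "Tpex",
                                             "CTL", "macrophage", "DC", "NK",
                                             "myeloid"),
                       immune_markers = c("CD11b", "CD68", "CD163", "CD4",
                                          "CD3d", "CD8a", "TCF1", "FOXP3",
                                          "PD1", "CD57", "CD11c", "GZB",
                                          "CD15", "HLADR", "CD103", "CD31",
                                          "pTBK1", "CD24", "CD44", "CD206")) {
  stopifnot(frac_nucleate > 0, frac_nucleate <= 1,
            frac_expand > 0, frac_expand <= 1,
            k_nucleate >= 1, k_expand >= 1)
  structure(list(k_nucleate = k_nucleate, frac_nucleate = frac_nucleate,
                 k_expand = k_expand, frac_expand = frac_expand,
                 min_cells = min_cells, b_phenotypes = b_phenotypes,
                 immune_phenotypes = immune_phenotypes,
                 immune_markers = immune_markers),
            class = "bic_params")
}

#' @rdname bic_params
#' @param eps DBSCAN expanding neighbourhood radius, micrometres (default 50)
#' @param min_cluster minimum T-cluster size (default 100)
#' @param core_min_samples DBSCAN core-point neighbour count within `eps`
#'   (default 10)
#' @param t_phenotypes phenotype labels counted as T cells (CD3d/CD4/CD8
#'   positive lineages)
#' @export
tic_params <- function(eps = 50, min_cluster = 100, core_min_samples = 10,
                       t_phenotypes = c("T", "CD4 T", "CD8 T", "Treg",
                                        "Tex", "Tpex", "CTL")) {
  stopifnot(eps > 0)
  structure(list(eps = eps, min_cluster = min_cluster,
                 core_min_samples = core_min_samples,
                 t_phenotypes = t_phenotypes),
            class = "tic_params")
}

is_b_cell <- function(table, params) table$phenotype %in% params$b_phenotypes

is_immune_cell <- function(table, params) {
  imm <- table$phenotype %in% params$immune_phenotypes
  for (m in params$immune_markers) {
    cc <- paste0(m, "_call")
    if (cc %in% names(table)) imm <- imm | (table[[cc]] %in% TRUE)
  }
  imm
}

# kNN index matrix (self excluded), deterministic for distinct coordinates.
knn_index <- function(x, y, k) {
  nn <- RANN::nn2(cbind(x, y), k = min(k + 1L, length(x)))
  nn$nn.idx[, -1, drop = FALSE]
}

#' Detect B-cell immune clusters (BICs)
#'
#' @param table a `cell_table` with phenotypes assigned (excluded cells are
#'   ignored)
#' @param params a [bic_params()]
#' @return A list of `immune_cluster` objects (see [cluster_composition()]),
#'   each with member cell ids, centroid and size. Empty when no B cells.
#' @export
detect_bics <- function(table, params = bic_params()) {
  tab <- active_cells(table)
  n <- nrow(tab)
  if (n <= params$k_expand)
    stop("table smaller than the expansion neighbourhood (", params$k_expand, " cells)")
  b <- is_b_cell(tab, params)
  if (!any(b)) return(list())

  nn100 <- knn_index(tab$x_um, tab$y_um, params$k_expand)
  nn25 <- nn100[, seq_len(params$k_nucleate), drop = FALSE]

  # stage 1: nucleation — B cells with >= 50% B among their 25 NN
  frac_b25 <- rowMeans(matrix(b[nn25], nrow = n))
  nuc <- which(b & frac_b25 >= params$frac_nucleate)
  if (length(nuc) == 0) return(list())

  # stage 2: group nuclei by connected components of the symmetric 25-NN graph
  in_nuc <- logical(n); in_nuc[nuc] <- TRUE
  ei <- rep(nuc, each = ncol(nn25))
  ej <- as.vector(t(nn25[nuc, , drop = FALSE]))
  keep <- in_nuc[ej]
  g <- igraph::graph_from_edgelist(cbind(match(ei[keep], nuc),
                                         match(ej[keep], nuc)),
                                   directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(nuc) - igraph::vcount(g)))
  comp_nuc <- igraph::components(g)$membership  # per nucleus

  # stage 3: expansion to fixpoint = connected components over
  # (nuclei + eligible immune cells) under the symmetric 100-NN relation
  frac_b100 <- rowMeans(matrix(b[nn100], nrow = n))
  eligible <- which((is_immune_cell(tab, params) | b) &
                      frac_b100 >= params$frac_expand)
  nodes <- sort(unique(c(nuc, eligible)))
  node_of <- integer(n); node_of[nodes] <- seq_along(nodes)
  ei <- rep(nodes, each = ncol(nn100))
  ej <- as.vector(t(nn100[nodes, , drop = FALSE]))
  keep <- node_of[ej] > 0L
  g2 <- igraph::graph_from_edgelist(cbind(node_of[ei[keep]], node_of[ej[keep]]),
                                    directed = FALSE)
  g2 <- igraph::add_vertices(g2, max(0L, length(nodes) - igraph::vcount(g2)))
  comp2 <- igraph::components(g2)$membership

  # a component is a BIC iff it contains at least one nucleus; nuclei
  # bridged by expansion merge into one cluster
  nuc_comp <- comp2[node_of[nuc]]
  bic_comps <- unique(nuc_comp)
  clusters <- list()
  for (cmp in bic_comps) {
    members <- nodes[comp2 == cmp]
    if (length(members) < params$min_cells) next
    clusters[[length(clusters) + 1L]] <-
      new_immune_cluster(tab, members, kind = "BIC")
  }
  order_clusters(clusters)
}

#' Detect T-cell immune clusters (TICs) by DBSCAN
#'
#' Classic DBSCAN over the T cells with neighbourhood radius `eps` and
#' core threshold `core_min_samples`; border points join the first core
#' point that reaches them (deterministic in cell order); noise points stay
#' unassigned. Clusters below `min_cluster` members are discarded.
#'
#' @param table a `cell_table` with phenotypes assigned
#' @param params a [tic_params()]
#' @export
detect_tics <- function(table, params = tic_params()) {
  tab <- active_cells(table)
  tcells <- tab[tab$phenotype %in% params$t_phenotypes, , drop = FALSE]
  nT <- nrow(tcells)
  if (nT == 0) return(list())
  labels <- dbscan_labels(tcells$x_um, tcells$y_um, eps = params$eps,
                          min_pts = params$core_min_samples)
  clusters <- list()
  for (lab in setdiff(unique(labels), 0L)) {
    members <- which(labels == lab)
    if (length(members) < params$min_cluster) next
    clusters[[length(clusters) + 1L]] <-
      new_immune_cluster(tcells, members, kind = "TIC")
  }
  order_clusters(clusters)
}

# Minimal exact DBSCAN (Euclidean): labels 0 = noise, 1..k = clusters.
dbscan_labels <- function(x, y, eps, min_pts) {
  n <- length(x)
  pts <- cbind(x, y)
  k <- min(n, 64L)
  repeat {  # grow k until no radius query saturates
    nb <- RANN::nn2(pts, k = k, searchtype = "radius", radius = eps)$nn.idx
    if (k >= n || !any(nb[, k] > 0L)) break
    k <- min(n, k * 4L)
  }
  neigh <- lapply(seq_len(n), function(i) {
    v <- nb[i, ]
    v[v > 0L]
  })
  n_neigh <- lengths(neigh)   # includes self
  core <- n_neigh >= min_pts
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- neigh[[i]]
    while (length(frontier) > 0) {
      j <- frontier[[1]]
      frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- c(frontier, neigh[[j]][labels[neigh[[j]]] == 0L])
      }
    }
  }
  labels
}

new_immune_cluster <- function(tab, member_rows, kind) {
  structure(list(
    cluster_id = NA_character_,
    kind = kind,
    member_ids = tab$cell_id[member_rows],
    centroid = c(x = mean(tab$x_um[member_rows]),
                 y = mean(tab$y_um[member_rows])),
    n_cells = length(member_rows),
    icat = NA_real_,
    localization = NA_character_,
    tumor_distance = NA_real_,
    composition = NULL
  ), class = "immune_cluster")
}

# Stable ordering and ids: by centroid (x then y).
order_clusters <- function(clusters) {
  if (length(clusters) == 0) return(clusters)
  cx <- vapply(clusters, function(cl) cl$centroid[["x"]], numeric(1))
  cy <- vapply(clusters, function(cl) cl$centroid[["y"]], numeric(1))
  clusters <- clusters[order(cx, cy)]
  for (i in seq_along(clusters))
    clusters[[i]]$cluster_id <- sprintf("%s%03d", clusters[[i]]$kind, i)
  clusters
}

#' @export
print.immune_cluster <- function(x, ...) {
  cat(sprintf("%s %s: %d cells, centroid (%.0f, %.0f) um", x$kind,
              x$cluster_id %||% "?", x$n_cells, x$centroid[1], x$centroid[2]))
  if (!is.na(x$icat)) cat(sprintf(", ICAT %.2f", x$icat))
  if (!is.na(x$localization)) cat(", ", x$localization)
  cat("\n")
  invisible(x)
}

#' Localize clusters relative to the tumor compartment
#'
#' A cluster is intratumoral iff its centroid lies inside a tumor domain
#' (tumor distance 0); otherwise extratumoral with distance equal to
#' [distance_to_domains()] of the centroid.
#'
#' @param clusters list of immune clusters
#' @param domains nonempty list of [tumor_domain()]s; with no domains the
#'   localization is undefined and an error is raised (tumor-free slides
#'   are excluded from localization analyses)
#' @export
localize_clusters <- function(clusters, domains) {
  if (length(domains) == 0)
    stop("localization undefined: specimen has no tumor domains")
  lapply(clusters, function(cl) {
    d <- distance_to_domains(cl$centroid[["x"]], cl$centroid[["y"]], domains)
    cl$tumor_distance <- d
    cl$localization <- if (d == 0) "intratumoral" else "extratumoral"
    cl
  })
}

#' BIC-TIC spatial association
#'
#' A BIC is TIC-associated when the minimum distance from its centroid to
#' any member cell of any TIC is at most `radius` (default 500 um).
#'
#' @param bics,tics cluster lists from [detect_bics()] / [detect_tics()]
#' @param table the `cell_table` holding the TIC member coordinates
#' @param radius association radius, micrometres
#' @return list with `flags` (per BIC, named by cluster_id) and
#'   `proportion`.
#' @export
bic_tic_association <- function(bics, tics, table, radius = 500) {
  if (length(bics) == 0)
    stop("association proportion undefined: no BICs")
  if (length(tics) == 0) {
    flags <- setNames(rep(FALSE, length(bics)),
                      vapply(bics, `[[`, "", "cluster_id"))
    return(list(flags = flags, proportion = 0))
  }
  tic_ids <- unique(unlist(lapply(tics, `[[`, "member_ids")))
  rows <- match(tic_ids, table$cell_id)
  tp <- cbind(table$x_um[rows], table$y_um[rows])
  flags <- vapply(bics, function(b) {
    nn <- RANN::nn2(tp, matrix(b$centroid, nrow = 1), k = 1)
    nn$nn.dists[1, 1] <= radius
  }, logical(1))
  names(flags) <- vapply(bics, `[[`, "", "cluster_id")
  list(flags = flags, proportion = mean(flags))
}

#' Cluster phenotype composition
#'
#' Counts of the canonical populations among a cluster's members, plus the
#' derived fractions with their conventional denominators: `frac_ki67_b`
#' uses all B cells; `frac_tex`, `frac_tpex`, `frac_ctl` use all T
#' (CD3d-positive lineage) cells in the cluster; `frac_tcf1_t` uses T
#' cells.
#'
#' @param cluster an immune cluster
#' @param table the `cell_table` the cluster was detected on
#' @return The cluster with a `composition` list attached (counts and
#'   fractions).
#' @export
cluster_composition <- function(cluster, table) {
  if (cluster$n_cells == 0) stop("empty cluster has no composition")
  rows <- match(cluster$member_ids, table$cell_id)
  ph <- table$phenotype[rows]
  has_call <- function(m) {
    cc <- paste0(m, "_call")
    if (cc %in% names(table)) table[[cc]][rows] %in% TRUE else rep(FALSE, length(rows))
  }
  t_labels <- c("T", "CD4 T", "CD8 T", "Treg", "Tex", "Tpex", "CTL")
  b_labels <- c("B", "Ki67+ B")
  is_t <- ph %in% t_labels
  is_b <- ph %in% b_labels
  counts <- c(
    n = length(rows),
    B = sum(is_b),
    T = sum(is_t),
    `CD4 T` = sum(ph == "CD4 T"),
    `CD8 T` = sum(ph %in% c("CD8 T", "Tex", "Tpex", "CTL")),
    `Ki67+ B` = sum(ph == "Ki67+ B" | (is_b & has_call("Ki67"))),
    `TCF1+ T` = sum(is_t & (ph == "Tpex" | has_call("TCF1"))),
    Tex = sum(ph == "Tex"),
    Tpex = sum(ph == "Tpex"),
    CTL = sum(ph == "CTL")
  )
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  cluster$composition <- list(
    counts = counts,
    fractions = c(
      frac_b = frac(counts[["B"]], counts[["n"]]),
      frac_t = frac(counts[["T"]], counts[["n"]]),
      frac_ki67_b = frac(counts[["Ki67+ B"]], counts[["B"]]),
      frac_tcf1_t = frac(counts[["TCF1+ T"]], counts[["T"]]),
      frac_tex = frac(counts[["Tex"]], counts[["T"]]),
      frac_tpex = frac(counts[["Tpex"]], counts[["T"]]),
      frac_ctl = frac(counts[["CTL"]], counts[["T"]])
    )
  )
  cluster
}

#' Tabulate clusters
#'
#' Flatten a cluster list to the tidy CSV layout used by the pipeline.
#'
#' @param clusters list of immune clusters
#' @param specimen_id recorded in each row
#' @export
clusters_to_df <- function(clusters, specimen_id = NA_character_) {
  if (length(clusters) == 0) {
    return(data.frame(cluster_id = character(0), kind = character(0),
                      specimen_id = character(0), n_cells = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      icat = numeric(0), localization = character(0),
                      tumor_distance = numeric(0)))
  }
  do.call(rbind, lapply(clusters, function(cl) {
    row <- data.frame(cluster_id = cl$cluster_id, kind = cl$kind,
                      specimen_id = specimen_id, n_cells = cl$n_cells,
                      centroid_x = cl$centroid[["x"]],
                      centroid_y = cl$centroid[["y"]],
                      icat = cl$icat, localization = cl$localization,
                      tumor_distance = cl$tumor_distance,
                      stringsAsFactors = FALSE)
    if (!is.null(cl$composition)) {
      cc <- as.list(cl$composition$counts)
      names(cc) <- paste0("n_", gsub("[ +]", "_", tolower(names(cc))))
      ff <- as.list(cl$composition$fractions)
      row <- cbind(row, as.data.frame(cc, check.names = FALSE),
                   as.data.frame(ff))
    }
    row
  }))
}
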