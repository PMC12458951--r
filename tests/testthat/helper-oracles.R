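# Independent brute-force oracles used to validate the implementations.
# These deliberately avoid the package's own code paths and the libraries
# behind them: plain double loops, ray casting and set logic.

# Ripley K by direct pair enumeration; correction "none" or "translate"
# (translation weights |W| / ((w - |dx|)(h - |dy|)) for a rectangle).
brute_k <- function(x, y, xr, yr, r, correction = "none") {
  n <- length(x)
  W <- diff(xr) * diff(yr)
  sapply(r, function(rr) {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      if (d <= rr) {
        w <- if (correction == "translate") {
          W / ((diff(xr) - abs(x[i] - x[j])) * (diff(yr) - abs(y[i] - y[j])))
        } else 1
        s <- s + w
      }
    }
    W * s / (n * (n - 1))
  })
}

brute_k_cross <- function(xa, ya, xb, yb, xr, yr, r, correction = "none") {
  W <- diff(xr) * diff(yr)
  sapply(r, function(rr) {
    s <- 0
    for (i in seq_along(xa)) for (j in seq_along(xb)) {
      d <- sqrt((xa[i] - xb[j])^2 + (ya[i] - yb[j])^2)
      if (d <= rr) {
        w <- if (correction == "translate") {
          W / ((diff(xr) - abs(xa[i] - xb[j])) * (diff(yr) - abs(ya[i] - yb[j])))
        } else 1
        s <- s + w
      }
    }
    W * s / (length(xa) * length(xb))
  })
}

brute_clf <- function(x, y, xr, yr, r, correction = "none") {
  sqrt(brute_k(x, y, xr, yr, r, correction) / pi) - r
}

# Even-odd ray casting (points assumed off the boundary).
brute_point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  vapply(seq_along(px), function(q) {
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((vy[i] > py[q]) != (vy[j] > py[q])) {
        xint <- vx[i] + (py[q] - vy[i]) / (vy[j] - vy[i]) * (vx[j] - vx[i])
        if (px[q] < xint) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# Textbook DBSCAN with an O(n^2) distance matrix.
brute_dbscan <- function(x, y, eps, min_pts) {
  n <- length(x)
  D <- as.matrix(stats::dist(cbind(x, y)))
  neigh <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- lengths(neigh) >= min_pts
  labels <- integer(n); cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- neigh[[i]]
    while (length(frontier)) {
      j <- frontier[1]; frontier <- frontier[-1]
      if (labels[j] == 0L) {
        labels[j] <- cl
        if (core[j]) frontier <- c(frontier, neigh[[j]][labels[neigh[[j]]] == 0L])
      }
    }
  }
  labels
}

# k nearest neighbour indices by full sort (self excluded).
brute_knn <- function(x, y, k) {
  D <- as.matrix(stats::dist(cbind(x, y)))
  t(vapply(seq_along(x), function(i) order(D[i, ])[2:(k + 1)], integer(k)))
}

# Cluster-level precision/recall of detected vs planted clusters: a match
# requires mutual majority overlap of the member sets.
match_precision_recall <- function(detected, truth, kind_ids) {
  truth_sets <- lapply(kind_ids, function(id)
    truth$cell_id[!is.na(truth$true_cluster_id) & truth$true_cluster_id == id])
  det_sets <- lapply(detected, `[[`, "member_ids")
  is_match <- function(D, T.) {
    ov <- length(intersect(D, T.))
    ov >= 0.5 * length(T.) && ov >= 0.5 * length(D)
  }
  recall <- if (length(truth_sets) == 0) 1 else
    mean(vapply(truth_sets, function(T.)
      any(vapply(det_sets, is_match, logical(1), T. = T.)), logical(1)))
  precision <- if (length(det_sets) == 0) 1 else
    mean(vapply(det_sets, function(D)
      any(vapply(truth_sets, function(T.) is_match(D, T.), logical(1))),
      logical(1)))
  c(precision = precision, recall = recall)
}

# Planted cluster ids of a given lineage (majority phenotype of members).
truth_cluster_ids <- function(spec, lineage) {
  ids <- unique(stats::na.omit(spec$truth$true_cluster_id))
  b_set <- c("B", "Ki67+ B")
  t_set <- c("T", "CD4 T", "CD8 T", "Treg", "Tex", "Tpex", "CTL")
  keep <- vapply(ids, function(id) {
    m <- spec$truth$cell_id[!is.na(spec$truth$true_cluster_id) &
                              spec$truth$true_cluster_id == id]
    ph <- spec$cells$phenotype[match(m, spec$cells$cell_id)]
    if (lineage == "B") mean(ph %in% b_set) > 0.5 else mean(ph %in% t_set) > 0.5
  }, logical(1))
  ids[keep]
}
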