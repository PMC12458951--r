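#' Synthetic specimens with planted ground truth
#'
#' The generator emulates the statistical structure the downstream spatial
#' analyses assume: cells as 2D points in a rectangular micrometre frame,
#' sparse background stroma as independent homogeneous Poisson (CSR)
#' fields per phenotype, immune clusters planted as uniform ellipses
#' ("organized") or anisotropic Gaussian blobs ("disorganized"), clustered
#' T-cell fields as Thomas processes, and tumor domains as smoothed random
#' blobs. Every random draw is governed by a single root seed, split
#' deterministically per component, so adding a cluster never perturbs the
#' background draw.
#'
#' @name synthetic_data
NULL

#' Homogeneous Poisson (CSR) point field
#'
#' @param intensity points per mm^2
#' @param frame c(width, height) in micrometres
#' @param seed integer seed (fixes the draw)
#' @return data.frame with x_um, y_um
#' @export
generate_csr <- function(intensity, frame, seed = NULL) {
  stopifnot(intensity >= 0, length(frame) == 2, all(frame > 0))
  with_seed(seed, {
    area_mm2 <- prod(frame) / 1e6
    n <- stats::rpois(1, intensity * area_mm2)
    data.frame(x_um = stats::runif(n, 0, frame[1]),
               y_um = stats::runif(n, 0, frame[2]))
  })
}

#' Thomas cluster process
#'
#' Poisson parents at `parent_intensity` per mm^2; each parent gets
#' Poisson(`mean_offspring`) children displaced isotropically with
#' Gaussian sd `sigma` micrometres. Children falling outside the frame are
#' truncated (discarded), not reflected; parents are drawn in a
#' `4*sigma`-expanded frame so edge clusters are not under-represented.
#'
#' @param parent_intensity parents per mm^2
#' @param mean_offspring expected children per parent
#' @param sigma offspring displacement sd, micrometres
#' @inheritParams generate_csr
#' @return data.frame with x_um, y_um
#' @export
generate_thomas <- function(parent_intensity, mean_offspring, sigma, frame,
                            seed = NULL) {
  stopifnot(parent_intensity >= 0, mean_offspring >= 0, sigma >= 0)
  with_seed(seed, {
    pad <- 4 * sigma
    ext <- frame + 2 * pad
    n_par <- stats::rpois(1, parent_intensity * prod(ext) / 1e6)
    if (n_par == 0) return(data.frame(x_um = numeric(0), y_um = numeric(0)))
    px <- stats::runif(n_par, -pad, frame[1] + pad)
    py <- stats::runif(n_par, -pad, frame[2] + pad)
    n_off <- stats::rpois(n_par, mean_offspring)
    x <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, sigma)
    y <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, sigma)
    keep <- x >= 0 & x <= frame[1] & y >= 0 & y <= frame[2]
    data.frame(x_um = x[keep], y_um = y[keep])
  })
}

#' Planted-cluster specification
#'
#' `organized_disk`: n cells uniform on an ellipse with semi-axes
#' `radius*sqrt(axis_ratio)` and `radius/sqrt(axis_ratio)` (equal-area
#' family; `axis_ratio = 1` is a disk of the given radius).
#' `disorganized_blob`: anisotropic Gaussian scatter with major/minor sds
#' `sigma` and `sigma/axis_ratio` — a sparser, looser aggregate.
#' `thomas_field`: a local Thomas process centred on `center`.
#' Phenotypes are assigned multinomially by `composition` (fractions
#' summing to at most 1; any remainder becomes `"stroma"`).
#'
#' The defaults of the two presets bracket the organization scale used to
#' classify clusters: the organized preset (1000 cells on a 200 um disk)
#' sits near ICAT 6.3, the disorganized preset (400 cells, 500 um major
#' sd, axis ratio 2) near ICAT 37.5.
#'
#' @param kind one of `"organized_disk"`, `"disorganized_blob"`,
#'   `"thomas_field"`
#' @param center c(x, y) micrometres
#' @param n_cells number of cells (disk/blob)
#' @param radius disk radius, micrometres
#' @param sigma Gaussian sd (blob/thomas), micrometres
#' @param axis_ratio major/minor axis ratio (>= 1)
#' @param composition named phenotype fractions
#' @param rotation orientation of the major axis, radians
#' @param parent_intensity,mean_offspring thomas_field parameters
#' @export
cluster_spec <- function(kind = c("organized_disk", "disorganized_blob", "thomas_field"),
                         center, n_cells = NULL, radius = NULL, sigma = NULL,
                         axis_ratio = 1, composition = c(B = 1),
                         rotation = 0, parent_intensity = NULL,
                         mean_offspring = NULL) {
  kind <- match.arg(kind)
  if (sum(composition) > 1 + 1e-9) stop("composition fractions must sum to <= 1")
  if (axis_ratio < 1) stop("axis_ratio must be >= 1")
  if (kind != "thomas_field" && (is.null(n_cells) || n_cells < 1))
    stop("cluster parameter error: n_cells must be >= 1")
  structure(list(kind = kind, center = center, n_cells = n_cells,
                 radius = radius, sigma = sigma, axis_ratio = axis_ratio,
                 composition = composition, rotation = rotation,
                 parent_intensity = parent_intensity,
                 mean_offspring = mean_offspring),
            class = "cluster_spec")
}

#' @rdname cluster_spec
#' @param center cluster centre, micrometres
#' @param composition phenotype fractions
#' @export
cluster_spec_organized <- function(center, n_cells = 1000, radius = 200,
                                   composition = c(B = 0.80, `CD4 T` = 0.08,
                                                   `CD8 T` = 0.07,
                                                   `Ki67+ B` = 0.03,
                                                   stroma = 0.02)) {
  cluster_spec("organized_disk", center = center, n_cells = n_cells,
               radius = radius, axis_ratio = 1, composition = composition)
}

#' @rdname cluster_spec
#' @export
cluster_spec_disorganized <- function(center, n_cells = 400, sigma = 500,
                                      axis_ratio = 2,
                                      composition = c(B = 0.70, `CD4 T` = 0.10,
                                                      `CD8 T` = 0.10,
                                                      stroma = 0.10)) {
  cluster_spec("disorganized_blob", center = center, n_cells = n_cells,
               sigma = sigma, axis_ratio = axis_ratio,
               composition = composition)
}

#' Sample one planted cluster
#'
#' @param spec a [cluster_spec()]
#' @param seed integer seed
#' @param frame optional frame for truncation (points outside discarded)
#' @return data.frame x_um, y_um, phenotype
#' @export
plant_cluster <- function(spec, seed = NULL, frame = NULL) {
  stopifnot(inherits(spec, "cluster_spec"))
  pts <- with_seed(seed, {
    if (spec$kind == "organized_disk") {
      a <- spec$radius * sqrt(spec$axis_ratio)
      b <- spec$radius / sqrt(spec$axis_ratio)
      th <- stats::runif(spec$n_cells, 0, 2 * pi)
      rr <- sqrt(stats::runif(spec$n_cells))
      u <- a * rr * cos(th); v <- b * rr * sin(th)
      rot_xy(u, v, spec$rotation, spec$center)
    } else if (spec$kind == "disorganized_blob") {
      u <- stats::rnorm(spec$n_cells, 0, spec$sigma)
      v <- stats::rnorm(spec$n_cells, 0, spec$sigma / spec$axis_ratio)
      rot_xy(u, v, spec$rotation, spec$center)
    } else {
      loc <- generate_thomas(spec$parent_intensity, spec$mean_offspring,
                             spec$sigma, frame %||% c(Inf, Inf), seed = NULL)
      data.frame(x_um = loc$x_um, y_um = loc$y_um)
    }
  })
  pts$phenotype <- with_seed(if (is.null(seed)) NULL else split_seed(seed, 999L),
                             draw_phenotypes(nrow(pts), spec$composition))
  if (!is.null(frame)) {
    keep <- pts$x_um >= 0 & pts$x_um <= frame[1] &
            pts$y_um >= 0 & pts$y_um <= frame[2]
    pts <- pts[keep, , drop = FALSE]
  }
  pts
}

rot_xy <- function(u, v, theta, center) {
  data.frame(x_um = center[1] + u * cos(theta) - v * sin(theta),
             y_um = center[2] + u * sin(theta) + v * cos(theta))
}

draw_phenotypes <- function(n, composition) {
  rest <- 1 - sum(composition)
  labs <- names(composition)
  p <- as.numeric(composition)
  if (rest > 1e-9) { labs <- c(labs, "stroma"); p <- c(p, rest) }
  labs[sample.int(length(p), n, replace = TRUE, prob = p)]
}

#' Synthetic specimen specification
#'
#' @param frame c(width, height), micrometres
#' @param background named vector: background CSR intensity per phenotype,
#'   cells/mm^2 (sparse stroma)
#' @param clusters list of [cluster_spec()]s
#' @param tumor_domains list of lists `(center, radius, gleason)` turned
#'   into smoothed random blob polygons, or ready-made [tumor_domain()]s
#' @param seed root integer seed
#' @export
synthetic_spec <- function(frame = c(6000, 6000),
                           background = c(stroma = 150, B = 10, `CD4 T` = 15,
                                          `CD8 T` = 15),
                           clusters = list(), tumor_domains = list(),
                           seed = 1L) {
  stopifnot(all(background >= 0), all(frame > 0))
  structure(list(frame = frame, background = background, clusters = clusters,
                 tumor_domains = tumor_domains, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Fourier-perturbed circle: a smooth random blob polygon.
blob_polygon <- function(center, radius, seed, n_vert = 72, roughness = 0.15,
                         n_harm = 4) {
  with_seed(seed, {
    th <- seq(0, 2 * pi, length.out = n_vert + 1)[-(n_vert + 1)]
    r <- rep(1, n_vert)
    for (h in seq_len(n_harm)) {
      r <- r + roughness / h * (cos(h * th) * stats::rnorm(1) +
                                sin(h * th) * stats::rnorm(1))
    }
    r <- pmax(r, 0.2) * radius
    list(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
  })
}

#' Generate a synthetic specimen
#'
#' Merges background CSR fields, planted clusters and tumor-domain
#' polygons into a [specimen()] whose `truth` table records, per cell, the
#' planted cluster id (`NA` for background) and containing domain.
#' Overlapping planted clusters are allowed; overlap is flagged in the
#' truth table (`overlapped` column).
#'
#' @param spec a [synthetic_spec()]
#' @param specimen_id identifier
#' @return A [specimen()] with ground truth attached.
#' @export
generate_specimen <- function(spec, specimen_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_spec"))
  parts <- list()
  # background fields: child seed per phenotype, stable under cluster edits
  for (i in seq_along(spec$background)) {
    ph <- names(spec$background)[i]
    bg <- generate_csr(spec$background[[i]], spec$frame,
                       seed = split_seed(spec$seed, i))
    if (nrow(bg) > 0) {
      bg$phenotype <- ph
      bg$true_cluster_id <- NA_character_
      parts[[length(parts) + 1L]] <- bg
    }
  }
  # planted clusters: child seeds offset by 1000
  for (j in seq_along(spec$clusters)) {
    cl <- plant_cluster(spec$clusters[[j]], seed = split_seed(spec$seed, 1000L + j),
                        frame = spec$frame)
    if (nrow(cl) > 0) {
      cl$true_cluster_id <- sprintf("C%02d", j)
      parts[[length(parts) + 1L]] <- cl
    }
  }
  all_cells <- if (length(parts) > 0) do.call(rbind, parts)
               else data.frame(x_um = numeric(0), y_um = numeric(0),
                               phenotype = character(0),
                               true_cluster_id = character(0))
  if (nrow(all_cells) > 0)
    all_cells$cell_id <- sprintf("c%06d", seq_len(nrow(all_cells)))
  else all_cells$cell_id <- character(0)

  # tumor domains: prebuilt or blob polygons
  domains <- list()
  for (k in seq_along(spec$tumor_domains)) {
    td <- spec$tumor_domains[[k]]
    if (inherits(td, "tumor_domain")) { domains[[k]] <- td; next }
    pg <- blob_polygon(td$center, td$radius, seed = split_seed(spec$seed, 2000L + k))
    domains[[k]] <- tumor_domain(td$domain_id %||% sprintf("D%02d", k),
                                 pg$x, pg$y, td$gleason %||% 1L)
  }

  tab <- cell_table(all_cells[, c("cell_id", "x_um", "y_um", "phenotype"),
                              drop = FALSE])
  truth <- data.frame(cell_id = all_cells$cell_id,
                      true_cluster_id = all_cells$true_cluster_id,
                      true_domain_id = rep(NA_character_, nrow(all_cells)),
                      stringsAsFactors = FALSE)
  for (d in domains) {
    inside <- points_in_polygon(all_cells$x_um, all_cells$y_um, d$x, d$y)
    truth$true_domain_id[inside] <- d$domain_id
  }
  # flag cluster overlap: planted points of one cluster inside another's hull
  truth$overlapped <- rep(FALSE, nrow(truth))
  if (length(spec$clusters) > 1) {
    ids <- unique(stats::na.omit(truth$true_cluster_id))
    for (id in ids) {
      m <- !is.na(truth$true_cluster_id) & truth$true_cluster_id == id
      if (sum(m) < 3) next
      hx <- all_cells$x_um[m]; hy <- all_cells$y_um[m]
      hull <- grDevices::chull(hx, hy)
      other <- !m & !is.na(truth$true_cluster_id)
      if (any(other)) {
        ins <- points_in_polygon(all_cells$x_um[other], all_cells$y_um[other],
                                 hx[hull], hy[hull])
        truth$overlapped[which(other)[ins]] <- TRUE
      }
    }
  }
  specimen(specimen_id, tab, domains, truth = truth)
}

#' Write a synthetic specimen to disk
#'
#' Emits the cell-table CSV, the domain GeoJSON and the ground-truth CSV
#' in the same dialects the readers consume.
#'
#' @param spec a [specimen()] with truth attached
#' @param dir output directory (created)
#' @export
write_specimen <- function(spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cell_table(spec$cells, file.path(dir, "cells.csv"))
  if (length(spec$domains) > 0)
    write_domains_geojson(spec$domains, file.path(dir, "domains.geojson"))
  if (!is.null(spec$truth))
    utils::write.csv(spec$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

#' Standard validation specimen: well-separated planted BICs and TICs
#'
#' Three organized B-cell clusters (>= 400 B cells each) and three dense
#' T-cell clusters (>= 150 T cells each) on a sparse stromal background,
#' centres at least 1.5 mm apart on a 6 x 6 mm frame, plus one tumor
#' domain. The layout is the package's reference condition for
#' detector-recovery checks.
#'
#' @param seed root seed
#' @param n_b cells per planted B cluster
#' @param n_t cells per planted T cluster
#' @export
validation_spec <- function(seed = 1L, n_b = 560, n_t = 200) {
  centers_b <- list(c(1200, 1200), c(4600, 1300), c(1300, 4700))
  centers_t <- list(c(4700, 4700), c(3000, 3000), c(4600, 3000))
  # keep the planted BICs' T content well below the TIC size cutoff so the
  # ground truth stays unambiguous (exactly 3 B and 3 T clusters)
  cl <- c(
    lapply(centers_b, function(cc)
      cluster_spec_organized(cc, n_cells = n_b, radius = 150,
                             composition = c(B = 0.85, `CD4 T` = 0.05,
                                             `CD8 T` = 0.04, `Ki67+ B` = 0.03,
                                             stroma = 0.03))),
    lapply(centers_t, function(cc)
      cluster_spec("organized_disk", center = cc, n_cells = n_t, radius = 150,
                   composition = c(`CD4 T` = 0.55, `CD8 T` = 0.45)))
  )
  synthetic_spec(frame = c(6000, 6000),
                 background = c(stroma = 120, B = 8, `CD4 T` = 12,
                                `CD8 T` = 10),
                 clusters = cl,
                 tumor_domains = list(list(center = c(3000, 1800),
                                           radius = 900, gleason = "4+4")),
                 seed = seed)
}
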