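#' Run the end-to-end analysis on one specimen
#'
#' Orchestrates the full chain: load (or synthesize) the cell table and
#' tumor domains, exclude QC regions, gate markers, assign phenotypes,
#' classify compartments, quantify infiltration, detect BICs and TICs,
#' score ICAT, localize clusters and test BIC-TIC association, compute
#' windowed CLF/MCLF curves with their summaries, and optionally a
#' contact analysis. All stages communicate through tidy files in
#' `config$out_dir`, so each is independently re-runnable; a manifest
#' (seed, config hash, package version) and a per-stage log are written
#' alongside. Given identical config and seed, the CSV outputs are
#' byte-identical across runs.
#'
#' The configuration is a named list (or YAML file path) with entries:
#' \describe{
#'   \item{input}{list(cells = csv path, domains = geojson path, optional
#'     column_map)}
#'   \item{synthetic}{alternative to `input`: list(kind = "validation",
#'     optional n_b, n_t) or a [synthetic_spec()]}
#'   \item{gating}{named thresholds for [gating_config()] (optional)}
#'   \item{phenotypes}{"default" for [default_phenotype_rules()], or a rule
#'     list; omitted when the table already carries phenotypes}
#'   \item{bic, tic, icat}{parameter overrides for [bic_params()],
#'     [tic_params()], [icat_config()]}
#'   \item{clf}{list(phenotype, cross_phenotype, tile_side, step, rmax,
#'     edge_correction, min_points)}
#'   \item{contact}{list(phenoA, phenoB, gap, cell_radius) (optional)}
#'   \item{infiltration}{phenotype label(s) for the density numerator}
#'   \item{seed}{root seed for every random draw}
#'   \item{out_dir}{output directory}
#' }
#'
#' @param config named list or path to a YAML file
#' @return (invisibly) a list with the specimen, clusters, curves and
#'   output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- config$out_dir %||% stop("config$out_dir is required")
  seed <- as.integer(config$seed %||% 1L)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "log.txt")
  cat(sprintf("[%s] pipeline start, seed %d\n", format(Sys.time()), seed),
      file = logf)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      cat(sprintf("[%s] stage '%s' FAILED: %s\n", format(Sys.time()), name,
                  conditionMessage(e)), file = logf, append = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    cat(sprintf("[%s] stage '%s' done (%.2fs)\n", format(Sys.time()), name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))),
        file = logf, append = TRUE)
    res
  }

  spec <- stage("load", {
    if (!is.null(config$synthetic)) {
      sy <- config$synthetic
      if (inherits(sy, "synthetic_spec")) {
        generate_specimen(sy)
      } else if (identical(sy$kind, "validation")) {
        generate_specimen(validation_spec(seed = seed,
                                          n_b = sy$n_b %||% 560,
                                          n_t = sy$n_t %||% 200))
      } else stop("unknown synthetic kind")
    } else {
      tab <- read_cell_table(config$input$cells,
                             column_map = config$input$column_map)
      doms <- list(); excl <- list()
      if (!is.null(config$input$domains)) {
        gj <- read_domains_geojson(config$input$domains)
        doms <- gj$domains; excl <- gj$exclusions
      }
      if (length(excl) > 0) tab <- exclude_regions(tab, excl)
      specimen(config$specimen_id %||% "specimen", tab, doms)
    }
  })

  if (!is.null(config$gating)) {
    spec$cells <- stage("gate", apply_gates(spec$cells,
                                            gating_config(unlist(config$gating))))
  }
  if (!is.null(config$phenotypes)) {
    rules <- if (identical(config$phenotypes, "default"))
      default_phenotype_rules() else phenotype_rules(config$phenotypes)
    spec$cells <- stage("phenotype", assign_phenotypes(spec$cells, rules))
  }
  if (!"phenotype" %in% names(spec$cells))
    stop("no phenotypes: provide config$phenotypes or a phenotype column")

  has_tumor <- length(spec$domains) > 0
  spec$cells <- stage("compartment", {
    if (has_tumor) classify_compartment(spec$cells, spec$domains)
    else {
      cat(sprintf("[%s] no tumor annotation: compartment stage labels all non_tumor\n",
                  format(Sys.time())), file = logf, append = TRUE)
      tt <- spec$cells
      if (!"compartment" %in% names(tt)) tt$compartment <- "non_tumor"
      tt$compartment[is.na(tt$compartment)] <- "non_tumor"
      tt
    }
  })

  infil <- NULL
  if (has_tumor) {
    infil <- stage("infiltration", {
      ph <- config$infiltration %||% c("B", "Ki67+ B")
      infiltration_density(spec, ph)
    })
    utils::write.csv(cbind(specimen_id = spec$specimen_id,
                           phenotype = paste(config$infiltration %||%
                                               c("B", "Ki67+ B"),
                                             collapse = "|"),
                           infil$per_domain),
                     file.path(out, "infiltration.csv"), row.names = FALSE)
  } else {
    cat(sprintf("[%s] no tumor annotation: infiltration stage skipped\n",
                format(Sys.time())), file = logf, append = TRUE)
  }

  bp <- do.call(bic_params, config$bic %||% list())
  tp <- do.call(tic_params, config$tic %||% list())
  bics <- stage("detect_bics", detect_bics(spec$cells, bp))
  tics <- stage("detect_tics", detect_tics(spec$cells, tp))

  icfg <- do.call(icat_config, config$icat[setdiff(names(config$icat),
                                                   c("q1", "q3"))] %||% list())
  bics <- stage("icat", score_clusters_icat(bics, spec$cells, icfg))
  tics <- score_clusters_icat(tics, spec$cells, icfg)

  if (has_tumor) {
    bics <- stage("localize", localize_clusters(bics, spec$domains))
    tics <- localize_clusters(tics, spec$domains)
  } else {
    cat(sprintf("[%s] no tumor annotation: localization stage skipped\n",
                format(Sys.time())), file = logf, append = TRUE)
  }

  assoc <- NULL
  if (length(bics) > 0 && length(tics) >= 0) {
    assoc <- stage("association",
                   bic_tic_association(bics, tics, spec$cells, radius = 500))
    utils::write.csv(data.frame(specimen_id = spec$specimen_id,
                                cluster_id = names(assoc$flags),
                                tic_within_500um = unname(assoc$flags)),
                     file.path(out, "association.csv"), row.names = FALSE)
  }

  all_cl <- c(lapply(bics, cluster_composition, table = spec$cells),
              lapply(tics, cluster_composition, table = spec$cells))
  cl_df <- clusters_to_df(all_cl, spec$specimen_id)
  if (nrow(cl_df) > 0)
    cl_df$organization <- ifelse(is.na(cl_df$icat), NA_character_,
                                 classify_organization(pmax(cl_df$icat, 0),
                                                       q1 = config$icat$q1 %||% 13.7,
                                                       q3 = config$icat$q3 %||% 32.4))
  utils::write.csv(cl_df, file.path(out, "clusters.csv"), row.names = FALSE)

  clf_cfg <- config$clf %||% list()
  radii <- default_radii(step = clf_cfg$step %||% 30,
                         rmax = clf_cfg$rmax %||% 1500)
  curves <- stage("clf", {
    ph_a <- clf_cfg$phenotype %||% c("B", "Ki67+ B")
    ph_b <- clf_cfg$cross_phenotype %||% c("T", "CD4 T", "CD8 T", "Tex",
                                           "Tpex", "CTL")
    uni <- tryCatch(
      windowed_cohort_curve(spec$cells, ph_a, frame = clf_cfg$frame,
                            tile_side = clf_cfg$tile_side %||% 3000,
                            radii = radii,
                            edge_correction = clf_cfg$edge_correction %||% "isotropic",
                            min_points = clf_cfg$min_points %||% 10),
      error = function(e) NULL)
    crs <- tryCatch(
      windowed_cohort_curve(spec$cells, ph_a, cross_phenotype = ph_b,
                            frame = clf_cfg$frame,
                            tile_side = clf_cfg$tile_side %||% 3000,
                            radii = radii,
                            edge_correction = clf_cfg$edge_correction %||% "isotropic",
                            min_points = clf_cfg$min_points %||% 10),
      error = function(e) NULL)
    list(uni = uni, cross = crs,
         ph_a = paste(ph_a, collapse = "|"), ph_b = paste(ph_b, collapse = "|"))
  })
  cdf <- rbind(
    if (!is.null(curves$uni)) curve_to_df(curves$uni, spec$specimen_id,
                                          curves$ph_a),
    if (!is.null(curves$cross)) curve_to_df(curves$cross, spec$specimen_id,
                                            curves$ph_a, curves$ph_b))
  if (!is.null(cdf))
    utils::write.csv(cdf, file.path(out, "clf_curves.csv"), row.names = FALSE)
  sdf <- do.call(rbind, Filter(Negate(is.null), list(
    if (!is.null(curves$uni)) {
      s <- summarize_curve(curves$uni)
      data.frame(specimen_id = spec$specimen_id, kind = "univariate",
                 ci = s$ci, r50 = s$r50, ecr = s$ecr)
    },
    if (!is.null(curves$cross)) {
      s <- summarize_curve(curves$cross)
      data.frame(specimen_id = spec$specimen_id, kind = "cross",
                 ci = s$ci, r50 = s$r50, ecr = s$ecr)
    })))
  if (!is.null(sdf))
    utils::write.csv(sdf, file.path(out, "clf_summaries.csv"), row.names = FALSE)

  if (!is.null(config$contact)) {
    ct <- stage("contact", {
      contact_fraction(spec$cells, config$contact$phenoA,
                       config$contact$phenoB,
                       gap = config$contact$gap %||% 2,
                       cell_radius = config$contact$cell_radius %||% 5)
    })
    utils::write.csv(data.frame(specimen_id = spec$specimen_id,
                                phenoA = paste(config$contact$phenoA,
                                               collapse = "|"),
                                phenoB = paste(config$contact$phenoB,
                                               collapse = "|"),
                                threshold_um = ct$threshold_um,
                                fraction = ct$fraction),
                     file.path(out, "contact.csv"), row.names = FALSE)
  }

  write_cell_table(spec$cells, file.path(out, "cells.csv"))
  if (!is.null(spec$truth))
    utils::write.csv(spec$truth, file.path(out, "truth.csv"), row.names = FALSE)

  manifest <- list(package = "immunospat",
                   version = as.character(utils::packageVersion("immunospat")),
                   seed = seed,
                   config_hash = config_hash(config),
                   n_cells = nrow(spec$cells),
                   n_bics = length(bics), n_tics = length(tics))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  cat(sprintf("[%s] pipeline done\n", format(Sys.time())), file = logf,
      append = TRUE)
  invisible(list(specimen = spec, bics = bics, tics = tics,
                 association = assoc, infiltration = infil, curves = curves,
                 out_dir = out))
}

# FNV-1a over the canonical YAML serialization of the config.
config_hash <- function(config) {
  config$out_dir <- NULL
  s <- utf8ToInt(yaml::as.yaml(config[order(names(config))]))
  h <- 2166136261
  for (b in s) h <- (bitwXor(as.integer(h %% 2^31), b) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}
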