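# Small deterministic fixtures: planted disks in sparse stroma, built in code.
make_fixture <- function(clusters, seed = 1, frame = c(6000, 6000),
                         background = c(stroma = 60, B = 6, `CD4 T` = 8,
                                        `CD8 T` = 6)) {
  generate_specimen(synthetic_spec(frame = frame, background = background,
                                   clusters = clusters, seed = seed))
}

test_that("BIC detection enforces the 300-cell eligibility cutoff", {
  sp <- make_fixture(list(cluster_spec("organized_disk", c(3000, 3000),
                                       n_cells = 250, radius = 120,
                                       composition = c(B = 1))))
  expect_length(detect_bics(sp$cells), 0)
})

test_that("one mixed B/T disk yields one BIC holding the planted cells", {
  sp <- make_fixture(list(cluster_spec("organized_disk", c(3000, 3000),
                                       n_cells = 560, radius = 150,
                                       composition = c(B = 0.89,
                                                       `CD8 T` = 0.11))))
  bics <- detect_bics(sp$cells)
  expect_length(bics, 1)
  planted <- sp$truth$cell_id[!is.na(sp$truth$true_cluster_id)]
  # all planted B and T members recovered
  expect_true(all(planted %in% bics[[1]]$member_ids))
  # expansion may absorb nearby stragglers (the 100-NN neighbourhood spans
  # ~600 um in sparse stroma) but must not chain to distant cells
  rows <- match(bics[[1]]$member_ids, sp$cells$cell_id)
  d <- sqrt((sp$cells$x_um[rows] - 3000)^2 + (sp$cells$y_um[rows] - 3000)^2)
  expect_lt(max(d), 1200)
  expect_lt(mean(d > 400), 0.1)
})

test_that("well-separated disks give disjoint BICs; nucleation matches brute-force KNN", {
  sp <- make_fixture(list(
    cluster_spec("organized_disk", c(1200, 1200), n_cells = 400, radius = 130,
                 composition = c(B = 1)),
    cluster_spec("organized_disk", c(4800, 4800), n_cells = 400, radius = 130,
                 composition = c(B = 1))))
  bics <- detect_bics(sp$cells)
  expect_length(bics, 2)
  expect_length(intersect(bics[[1]]$member_ids, bics[[2]]$member_ids), 0)

  # brute-force check of the nucleation predicate on a subsample
  params <- bic_params()
  tab <- sp$cells
  idx25 <- brute_knn(tab$x_um, tab$y_um, params$k_nucleate)
  b <- tab$phenotype %in% params$b_phenotypes
  nuc_oracle <- b & rowMeans(matrix(b[idx25], nrow = nrow(tab))) >= 0.5
  members <- unlist(lapply(bics, `[[`, "member_ids"))
  # every oracle nucleation cell ends up in a BIC
  expect_true(all(tab$cell_id[nuc_oracle] %in% members))
})

test_that("BIC membership is restricted to B and immune-eligible cells", {
  sp <- make_fixture(list(cluster_spec("organized_disk", c(3000, 3000),
                                       n_cells = 600, radius = 150,
                                       composition = c(B = 0.7, `CD4 T` = 0.1,
                                                       stroma = 0.2))))
  bics <- detect_bics(sp$cells)
  expect_length(bics, 1)
  ph <- sp$cells$phenotype[match(bics[[1]]$member_ids, sp$cells$cell_id)]
  expect_false(any(ph == "stroma"))
})

test_that("BIC detection is invariant to rigid motion and cell-id relabeling", {
  sp <- make_fixture(list(cluster_spec("organized_disk", c(2000, 2000),
                                       n_cells = 450, radius = 140,
                                       composition = c(B = 1))), seed = 3)
  bics <- detect_bics(sp$cells)
  th <- 0.5
  tab2 <- sp$cells
  tab2$x_um <- 100 + sp$cells$x_um * cos(th) - sp$cells$y_um * sin(th)
  tab2$y_um <- 200 + sp$cells$x_um * sin(th) + sp$cells$y_um * cos(th)
  bics2 <- detect_bics(tab2)
  expect_equal(lapply(bics2, `[[`, "member_ids"),
               lapply(bics, `[[`, "member_ids"))

  tab3 <- sp$cells
  tab3$cell_id <- paste0("z", rev(seq_len(nrow(tab3))))
  bics3 <- detect_bics(tab3)
  expect_equal(sort(match(bics3[[1]]$member_ids, tab3$cell_id)),
               sort(match(bics[[1]]$member_ids, sp$cells$cell_id)))
})

test_that("TIC detection applies the 100-cell cutoff and splits separated groups", {
  # 50 T cells anywhere: no TIC
  sp0 <- make_fixture(list(cluster_spec("organized_disk", c(3000, 3000),
                                        n_cells = 50, radius = 80,
                                        composition = c(`CD8 T` = 1))),
                      background = c(stroma = 30))
  expect_length(detect_tics(sp0$cells), 0)

  # 150 T cells in a 100 um disk: one TIC of >= 150
  sp1 <- make_fixture(list(cluster_spec("organized_disk", c(3000, 3000),
                                        n_cells = 150, radius = 100,
                                        composition = c(`CD8 T` = 1))),
                      background = c(stroma = 30))
  tics1 <- detect_tics(sp1$cells)
  expect_length(tics1, 1)
  expect_gte(tics1[[1]]$n_cells, 150)

  # two groups with a 200 um empty gap (eps = 50): two TICs
  sp2 <- make_fixture(list(
    cluster_spec("organized_disk", c(2800, 3000), n_cells = 150, radius = 80,
                 composition = c(`CD4 T` = 1)),
    cluster_spec("organized_disk", c(3160, 3000), n_cells = 150, radius = 80,
                 composition = c(`CD4 T` = 1))),
    background = c(stroma = 30))
  expect_length(detect_tics(sp2$cells), 2)
})

test_that("the DBSCAN core matches a textbook O(n^2) implementation", {
  set.seed(21)
  x <- c(rnorm(120, 0, 40), rnorm(80, 600, 30), runif(40, -200, 900))
  y <- c(rnorm(120, 0, 40), rnorm(80, 600, 30), runif(40, -200, 900))
  got <- immunospat:::dbscan_labels(x, y, eps = 50, min_pts = 10)
  want <- brute_dbscan(x, y, eps = 50, min_pts = 10)
  # same partition up to label permutation, same noise set
  expect_equal(got == 0, want == 0)
  expect_equal(length(unique(got[got > 0])), length(unique(want[want > 0])))
  for (lab in unique(want[want > 0])) {
    members <- which(want == lab)
    expect_equal(length(unique(got[members])), 1)
  }
})

test_that("cluster localization passes through point-domain geometry", {
  sq <- tumor_domain("D", c(0, 2000, 2000, 0), c(0, 0, 2000, 2000), "4+3")
  mk <- function(cx, cy) structure(list(cluster_id = "x", kind = "BIC",
                                        member_ids = "c", centroid = c(x = cx, y = cy),
                                        n_cells = 1, icat = NA_real_,
                                        localization = NA_character_,
                                        tumor_distance = NA_real_),
                                   class = "immune_cluster")
  loc <- localize_clusters(list(mk(1000, 1000), mk(2799, 1000)), list(sq))
  expect_equal(loc[[1]]$localization, "intratumoral")
  expect_equal(loc[[1]]$tumor_distance, 0)
  expect_equal(loc[[2]]$localization, "extratumoral")
  expect_equal(loc[[2]]$tumor_distance, 799)
  expect_error(localize_clusters(list(mk(0, 0)), list()), "no tumor domains")
})

test_that("BIC-TIC association uses the 500 um centroid-to-member rule", {
  tab <- cell_table(data.frame(cell_id = c("b1", "t1", "t2"),
                               x_um = c(0, 499, 2000), y_um = 0,
                               phenotype = c("B", "CD8 T", "CD8 T")))
  mk <- function(id, kind, ids, cx) structure(
    list(cluster_id = id, kind = kind, member_ids = ids,
         centroid = c(x = cx, y = 0), n_cells = length(ids), icat = NA_real_,
         localization = NA_character_, tumor_distance = NA_real_),
    class = "immune_cluster")
  bic <- mk("BIC001", "BIC", "b1", 0)
  tic_near <- mk("TIC001", "TIC", "t1", 499)
  tic_far <- mk("TIC002", "TIC", "t2", 2000)
  expect_true(bic_tic_association(list(bic), list(tic_near), tab)$flags[[1]])
  expect_false(bic_tic_association(list(bic), list(tic_far), tab)$flags[[1]])
  expect_error(bic_tic_association(list(), list(tic_near), tab), "no BICs")

  # proportion over a 10-BIC fixture matches the hand count
  set.seed(17)
  centers <- seq(0, 9000, by = 1000)
  tics <- list(mk("TIC001", "TIC", "t1", 499))
  bics <- lapply(seq_along(centers), function(i)
    mk(sprintf("BIC%03d", i), "BIC", "b1", centers[i]))
  got <- bic_tic_association(bics, tics, tab)
  want <- abs(centers - 499) <= 500
  expect_equal(unname(got$flags), want)
  expect_equal(got$proportion, mean(want))
})

test_that("cluster composition counts and denominators are as defined", {
  tab <- cell_table(data.frame(
    cell_id = sprintf("c%02d", 1:10),
    x_um = 1:10, y_um = 1:10,
    phenotype = c(rep("B", 4), "Ki67+ B", "CD4 T", "CD8 T", "Tex", "Tpex",
                  "CTL")))
  cl <- structure(list(cluster_id = "BIC001", kind = "BIC",
                       member_ids = tab$cell_id, centroid = c(x = 5, y = 5),
                       n_cells = 10, icat = NA_real_,
                       localization = NA_character_,
                       tumor_distance = NA_real_),
                  class = "immune_cluster")
  comp <- cluster_composition(cl, tab)$composition
  expect_equal(unname(comp$counts[c("B", "T", "Ki67+ B", "Tex", "Tpex",
                                    "CTL")]),
               c(5, 5, 1, 1, 1, 1))
  # Tpex fraction is relative to all T (CD3d+) cells in the cluster
  expect_equal(unname(comp$fractions["frac_tpex"]), 1 / 5)
  expect_equal(unname(comp$fractions["frac_ki67_b"]), 1 / 5)

  # pure-B cluster: Ki67+ B fraction 0
  tabB <- cell_table(data.frame(cell_id = 1:10, x_um = 1:10, y_um = 1:10,
                                phenotype = "B"))
  clB <- cl; clB$member_ids <- as.character(1:10)
  compB <- cluster_composition(clB, tabB)$composition
  expect_equal(unname(compB$counts["B"]), 10)
  expect_equal(unname(compB$fractions["frac_ki67_b"]), 0)

  # planted composition recovered within the binomial interval
  p <- plant_cluster(cluster_spec("organized_disk", c(0, 0), n_cells = 1000,
                                  radius = 200,
                                  composition = c(B = 0.6, `CD4 T` = 0.4)),
                     seed = 2)
  ptab <- cell_table(data.frame(cell_id = seq_len(nrow(p)), x_um = p$x_um,
                                y_um = p$y_um, phenotype = p$phenotype))
  clP <- cl; clP$member_ids <- ptab$cell_id; clP$n_cells <- nrow(ptab)
  fr <- cluster_composition(clP, ptab)$composition$fractions
  expect_lt(abs(fr[["frac_b"]] - 0.6), 1.96 * sqrt(0.6 * 0.4 / 1000) * 1.5)
})
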