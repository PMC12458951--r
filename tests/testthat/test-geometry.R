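test_that("union-of-disks area matches closed forms and its bound", {
  r <- 20
  # single disk
  expect_lt(abs(union_disk_area(0, 0, r) * 1e6 - pi * r^2) / (pi * r^2), 0.005)
  # two disks 20 um apart: 2*pi*r^2 minus the lens
  lens <- 2 * r^2 * acos(10 / r) - 10 * sqrt(4 * r^2 - 400)
  want <- 2 * pi * r^2 - lens
  expect_lt(abs(union_disk_area(c(0, 20), c(0, 0), r) * 1e6 - want) / want,
            0.005)
  # disjoint disks are exactly additive (within polygonal resolution)
  expect_lt(abs(union_disk_area(c(0, 45), c(0, 0), r) * 1e6 - 2 * pi * r^2) /
              (2 * pi * r^2), 0.005)
  expect_equal(union_disk_area(numeric(0), numeric(0), r), 0)

  # n*pi*r^2 upper bound, equality iff all pairwise gaps >= 2r
  set.seed(4)
  x <- runif(30, 0, 300); y <- runif(30, 0, 300)
  a <- union_disk_area(x, y, r) * 1e6
  expect_lte(a, 30 * pi * r^2 * 1.001)
  sep <- min(dist(cbind(x, y))) >= 2 * r
  expect_equal(abs(a - 30 * pi * r^2) / (30 * pi * r^2) < 0.005, sep)
})

test_that("compartment classification agrees with a ray-casting oracle", {
  set.seed(31)
  ring <- local({
    th <- seq(0, 2 * pi, length.out = 13)[-13]
    rr <- 300 * (1 + 0.3 * sin(3 * th))
    list(x = 1000 + rr * cos(th), y = 1000 + rr * sin(th))
  })
  dom <- tumor_domain("D1", ring$x, ring$y, 2)
  tab <- cell_table(data.frame(cell_id = 1:1000,
                               x_um = runif(1000, 0, 2000),
                               y_um = runif(1000, 0, 2000)))
  out <- classify_compartment(tab, list(dom))
  oracle <- brute_point_in_polygon(tab$x_um, tab$y_um, ring$x, ring$y)
  expect_equal(out$compartment == "tumor:D1", oracle)

  # centroid of a square domain is tumor; outside is non_tumor
  sq <- tumor_domain("S", c(0, 100, 100, 0), c(0, 0, 100, 100), 1)
  t2 <- classify_compartment(cell_table(data.frame(cell_id = 1:2,
                                                   x_um = c(50, 500),
                                                   y_um = c(50, 500))),
                             list(sq))
  expect_equal(t2$compartment, c("tumor:S", "non_tumor"))

  # overlapping domains: smallest containing domain wins, with a warning
  big <- tumor_domain("big", c(0, 200, 200, 0), c(0, 0, 200, 200), 1)
  small <- tumor_domain("small", c(40, 60, 60, 40), c(40, 40, 60, 60), 2)
  expect_warning(
    t3 <- classify_compartment(cell_table(data.frame(cell_id = 1,
                                                     x_um = 50, y_um = 50)),
                               list(big, small)),
    "overlap")
  expect_equal(t3$compartment, "tumor:small")
})

test_that("distance to tumor domains is exact on fixtures and 1-Lipschitz", {
  sq <- tumor_domain("S", c(1000, 2000, 2000, 1000), c(0, 0, 1000, 1000), 1)
  expect_equal(distance_to_domains(1500, 500, list(sq)), 0)   # inside
  expect_equal(distance_to_domains(700, 500, list(sq)), 300)  # 300 um out
  # nearer of two domains governs
  sq2 <- tumor_domain("S2", c(0, 100, 100, 0), c(0, 0, 100, 100), 1)
  expect_equal(distance_to_domains(700, 500, list(sq, sq2)), 300)
  expect_error(distance_to_domains(0, 0, list()), "no tumor domains")

  set.seed(5)
  for (i in 1:20) {
    p <- runif(2, -500, 2500)
    q <- p + rnorm(2, 0, 50)
    d1 <- distance_to_domains(p[1], p[2], list(sq))
    d2 <- distance_to_domains(q[1], q[2], list(sq))
    expect_lte(abs(d1 - d2), sqrt(sum((p - q)^2)) + 1e-9)
  }
})

test_that("infiltration density uses the union-disk denominator per domain", {
  dom <- tumor_domain("D", c(0, 1000, 1000, 0), c(0, 0, 1000, 1000), "4+4")
  # a single B cell alone in the domain: 1 / (pi * 0.02^2) = 795.8 /mm^2
  tab1 <- cell_table(data.frame(cell_id = "c", x_um = 500, y_um = 500,
                                phenotype = "B"))
  d1 <- infiltration_density(specimen("s", tab1, list(dom)), "B")
  expect_lt(abs(d1$specimen - 1 / (pi * 0.02^2)) / (1 / (pi * 0.02^2)), 0.005)

  # 100 cells, none B: density 0 (denominator positive)
  set.seed(6)
  tab2 <- cell_table(data.frame(cell_id = 1:100, x_um = runif(100, 0, 1000),
                                y_um = runif(100, 0, 1000),
                                phenotype = "stroma"))
  expect_equal(infiltration_density(specimen("s", tab2, list(dom)),
                                    "B")$specimen, 0)

  # doubling the B count at fixed positions doubles the density
  tab3 <- tab2; tab3$phenotype[1:10] <- "B"
  tab4 <- tab3; tab4$phenotype[11:20] <- "B"
  d3 <- infiltration_density(specimen("s", tab3, list(dom)), "B")$specimen
  d4 <- infiltration_density(specimen("s", tab4, list(dom)), "B")$specimen
  expect_equal(d4, 2 * d3)

  # domain without cells: missing, not zero
  far <- tumor_domain("far", c(5000, 5100, 5100, 5000),
                      c(5000, 5000, 5100, 5100), 1)
  dd <- infiltration_density(specimen("s", tab3, list(dom, far)), "B")
  expect_true(is.na(dd$per_domain$density[dd$per_domain$domain_id == "far"]))

  # rigid motion invariance of the specimen-level density
  th <- 0.7
  tab5 <- tab3
  tab5$x_um <- 300 + tab3$x_um * cos(th) - tab3$y_um * sin(th)
  tab5$y_um <- -100 + tab3$x_um * sin(th) + tab3$y_um * cos(th)
  rot <- function(x, y) list(x = 300 + x * cos(th) - y * sin(th),
                             y = -100 + x * sin(th) + y * cos(th))
  rd <- rot(dom$x, dom$y)
  dom5 <- tumor_domain("D", rd$x, rd$y, "4+4")
  d5 <- infiltration_density(specimen("s", tab5, list(dom5)), "B")$specimen
  expect_lt(abs(d5 - d3) / d3, 1e-3)
})

test_that("contact flags equal the brute-force all-pairs rule", {
  # threshold arithmetic: 2*5 + 2 = 12 um
  tab <- cell_table(data.frame(cell_id = c("a", "b", "c", "d"),
                               x_um = c(0, 10, 100, 120),
                               y_um = c(0, 0, 0, 0),
                               phenotype = c("CTL", "tumor", "CTL", "tumor")))
  ct <- contact_fraction(tab, "CTL", "tumor", gap = 2, cell_radius = 5)
  expect_equal(unname(ct$flags), c(TRUE, FALSE))  # 10 <= 12, 20 > 12
  expect_equal(ct$fraction, 0.5)
  expect_error(contact_fraction(tab, "NK", "tumor"), "no cells")

  set.seed(7)
  n <- 300
  tab2 <- cell_table(data.frame(cell_id = seq_len(n),
                                x_um = runif(n, 0, 500),
                                y_um = runif(n, 0, 500),
                                phenotype = sample(c("CTL", "tumor"), n,
                                                   replace = TRUE)))
  ct2 <- contact_fraction(tab2, "CTL", "tumor")
  A <- tab2[tab2$phenotype == "CTL", ]
  B <- tab2[tab2$phenotype == "tumor", ]
  oracle <- vapply(seq_len(nrow(A)), function(i)
    any(sqrt((B$x_um - A$x_um[i])^2 + (B$y_um - A$y_um[i])^2) <= 12),
    logical(1))
  expect_equal(unname(ct2$flags), oracle)
})

test_that("compartment mean intensity reduces to hand arithmetic", {
  dom <- tumor_domain("D", c(0, 1000, 1000, 0), c(0, 0, 1000, 1000), 1)
  tab <- cell_table(data.frame(cell_id = 1:4,
                               x_um = c(100, 200, 1500, 1600), y_um = 500,
                               HLA = c(2, 4, 1, 3),
                               phenotype = c("tumor", "tumor", "B", "tumor")))
  tab <- classify_compartment(tab, list(dom))
  m <- compartment_mean_intensity(tab, "HLA", normalize = FALSE)
  expect_equal(m$mean[m$compartment == "tumor"], 3)
  expect_equal(m$mean[m$compartment == "non_tumor"], 2)
  # restriction changes the denominator only
  m2 <- compartment_mean_intensity(tab, "HLA", restrict_phenotype = "tumor",
                                   normalize = FALSE)
  expect_equal(m2$mean[m2$compartment == "non_tumor"], 3)
  # constant intensities give both means equal to the constant
  tabc <- tab; tabc$HLA <- 5
  mc <- compartment_mean_intensity(tabc, "HLA", normalize = FALSE)
  expect_true(all(mc$mean == 5))
})
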