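test_that("packing respects the hard core and the sector", {
  g <- tiny_geometry()
  p <- tiny_preset()
  hc <- 0.9 * p$diameter_mean * p$diameter_scale
  for (s in 1:5) {
    set.seed(s)
    cells <- pack_epithelium(g, p)
    # brute-force all-pairs minimum distance
    d <- bf_pairwise_dist(cells$x_um, cells$y_um)
    diag(d) <- Inf
    expect_gte(min(d), hc)
    r <- sqrt(cells$x_um^2 + cells$y_um^2)
    expect_true(all(r <= g$radius))
    expect_true(all(cells$p63), info = "packed cells are p63+")
    expect_false(any(cells$dlc))
  }
})

test_that("zero expected count gives an empty, well-formed table", {
  set.seed(1)
  cells <- pack_epithelium(tiny_geometry(), tiny_preset(n_stem_mean = 0))
  expect_equal(nrow(cells), 0L)
  expect_named(cells, c("embryo_id", "cell_id", "x_um", "y_um",
                        "diameter_um", "p63", "dlc", "brdu", "condition"))
})

test_that("infeasible densities raise packing_infeasible", {
  expect_error(pack_epithelium(tiny_geometry(), tiny_preset(n_stem_mean = 1e5)),
               class = "packing_infeasible")
})

test_that("diameter_scale is recovered from recorded diameters within 1%", {
  g <- tiny_geometry()
  mean_d <- function(scale, seed0) {
    vals <- numeric(20)
    for (i in 1:20) {
      set.seed(seed0 + i)
      vals[i] <- mean(pack_epithelium(g, tiny_preset(diameter_scale = scale))$diameter_um)
    }
    mean(vals)
  }
  ratio <- mean_d(0.921, 300) / mean_d(1.0, 600)
  expect_lt(abs(ratio - 0.921) / 0.921, 0.01)
})

test_that("p_select 0 selects nothing; selection respects the hard core", {
  g <- tiny_geometry()
  p0 <- tiny_preset(p_select = 0)
  set.seed(7)
  cells <- pack_epithelium(g, p0)
  expect_false(any(select_progenitors(cells, p0, g)$dlc))

  # hard-core property at p_cluster = 0, brute-force verified
  p <- tiny_preset()
  excl <- p$inhibition_radius * p$progenitor_diameter_mean * p$diameter_scale
  for (s in 1:8) {
    set.seed(100 + s)
    out <- select_progenitors(pack_epithelium(g, p), p, g)
    dlc <- out[out$dlc, ]
    if (nrow(dlc) >= 2) {
      d <- bf_pairwise_dist(dlc$x_um, dlc$y_um)
      diag(d) <- Inf
      expect_gte(min(d), excl)
    }
  }
})

test_that("chained co-selection produces larger maximum clusters", {
  g <- tiny_geometry(radius = 200)
  max_cl <- function(p_cluster, seed0) {
    vals <- numeric(20)
    p <- tiny_preset(n_stem_mean = 220, p_cluster = p_cluster)
    for (i in 1:20) {
      set.seed(seed0 + i)
      out <- select_progenitors(pack_epithelium(g, p), p, g)
      vals[i] <- decompose_clusters(out)$max_cluster
    }
    vals
  }
  clustered <- max_cl(0.6, 2000)
  unclustered <- max_cl(0.0, 4000)
  expect_gt(mean(clustered), mean(unclustered))
  # with a strict hard core above the contact threshold, p_cluster = 0
  # cannot create any contiguous pair
  expect_true(all(unclustered <= 1))
})

test_that("BrdU labelling matches the configured rates", {
  g <- tiny_geometry()
  p1 <- tiny_preset(brdu_rate_keratinocyte = 1)
  set.seed(11)
  out <- assign_brdu(select_progenitors(pack_epithelium(g, p1), p1, g), p1)
  expect_true(all(out$brdu[out$p63 & !out$dlc]))

  # rate 0.873 over >= 1200 cells: inside the 99% binomial interval
  p2 <- condition_preset("big", n_stem_mean = 1300,
                         brdu_rate_keratinocyte = 0.873)
  set.seed(12)
  out2 <- assign_brdu(pack_epithelium(default_geometry(), p2), p2)
  k <- out2$p63 & !out2$dlc
  phat <- mean(out2$brdu[k])
  half <- qnorm(0.995) * sqrt(0.873 * (1 - 0.873) / sum(k))
  expect_lt(abs(phat - 0.873), half)
})

test_that("dlc+p63- cells arise only through the mislabel channel", {
  g <- tiny_geometry()
  p <- tiny_preset(mislabel_rate = 0)
  set.seed(13)
  out <- assign_brdu(select_progenitors(pack_epithelium(g, p), p, g), p)
  expect_equal(sum(out$dlc & !out$p63), 0L)
  expect_gt(sum(out$dlc), 0L)
})

test_that("cohorts are deterministic and extensible in the seed contract", {
  cfg <- cohort_config(tiny_preset(), n_embryos_per_condition = 3, seed = 9,
                       geometry = tiny_geometry())
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  # byte-identical CSV artifacts
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_cell_table(a$cells, f1)
  write_cell_table(b$cells, f2)
  expect_identical(readLines(f1), readLines(f2))

  # extending the cohort must not perturb earlier embryos
  cfg5 <- cohort_config(tiny_preset(), n_embryos_per_condition = 5, seed = 9,
                        geometry = tiny_geometry())
  big <- generate_cohort(cfg5)
  expect_identical(a$cells,
                   big$cells[big$cells$embryo_id %in% a$cells$embryo_id, ])
})

test_that("empty cohorts come back as empty tables", {
  cfg <- cohort_config(tiny_preset(), n_embryos_per_condition = 0, seed = 1,
                       geometry = tiny_geometry())
  out <- generate_cohort(cfg)
  expect_equal(nrow(out$cells), 0L)
  expect_equal(nrow(out$geometry), 0L)
})

test_that("cohort p63+ counts fluctuate around the preset mean", {
  cfg <- cohort_config(tiny_preset(n_stem_mean = 80),
                       n_embryos_per_condition = 20, seed = 31,
                       geometry = tiny_geometry())
  counts <- table(generate_cohort(cfg)$cells$embryo_id)
  sem <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 80), 3 * sem)
})
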