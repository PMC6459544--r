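test_that("compartment counts partition the marker combinations", {
  cells <- make_cells(x = c(0, 10, 20), y = 0,
                      p63 = c(TRUE, TRUE, FALSE),
                      dlc = c(FALSE, TRUE, TRUE),
                      brdu = c(TRUE, FALSE, TRUE))
  cc <- compartment_counts(cells)
  expect_equal(cc$n_p63, 2L)
  expect_equal(cc$n_kerat, 1L)
  expect_equal(cc$n_brdu_kerat, 1L)
  expect_equal(cc$n_iono, 1L)
  expect_equal(cc$n_brdu_iono, 0L)
  expect_equal(cc$n_mislabel, 1L)
  expect_equal(cc$n_brdu_mislabel, 1L)
  expect_equal(cc$n_p63, cc$n_kerat + cc$n_iono)

  empty <- compartment_counts(make_cells(numeric(0), numeric(0)))
  expect_true(all(unlist(empty) == 0L))
})

test_that("duplicate cell ids are an integrity error", {
  cells <- make_cells(c(0, 5), 0)
  cells$cell_id <- c("c1", "c1")
  expect_error(compartment_counts(cells), class = "integrity_error")
})

test_that("densities divide count by area", {
  expect_equal(cell_density(10, 1e5), 1e-4)
  expect_equal(cell_density(0, 123), 0)
  expect_equal(cell_density(57, 2.7e5), 57 / 2.7e5)
  expect_match(format_density(57 / 2.7e5), "2.11 x 10\\^-4")
  expect_error(cell_density(10, 0), class = "invalid_area")
  expect_error(cell_density(10, -1), class = "invalid_area")
})

test_that("mean diameter estimators behave per contract", {
  cells <- make_cells(c(0, 50, 100), 0, diameter = c(10, 12, 14))
  expect_equal(estimate_mean_diameter(cells), 12)
  expect_error(estimate_mean_diameter(cells[0, ]), class = "estimation_error")
  expect_error(estimate_mean_diameter(cells[1, ], method = "nearest_neighbour"),
               class = "estimation_error")
  # equally spaced collinear cells: every nearest-neighbour distance is d
  expect_equal(estimate_mean_diameter(cells, method = "nearest_neighbour"), 50)
})

test_that("normalized spacing matches hand geometry", {
  g <- make_geometry(100)
  d <- 10
  # two central cells at distance d with mean diameter d
  two <- make_cells(c(0, d), 0, diameter = d)
  sp2 <- normalized_nearest_spacing(two, g)
  expect_false(sp2$undefined)
  expect_equal(sp2$mean_norm_spacing, 1.0)

  # three collinear central cells at 0, 1.3 d, 3 d
  three <- make_cells(c(0, 1.3 * d, 3 * d), 0, diameter = d)
  sp3 <- normalized_nearest_spacing(three, g)
  expect_equal(sort(sp3$values), c(1.3, 1.3, 1.7))
  expect_equal(sp3$mean_norm_spacing, mean(c(1.3, 1.3, 1.7)))
  expect_equal(sp3$n_used, 3L)
})

test_that("spacing focal set is central but neighbours are not restricted", {
  g <- make_geometry(100) # central area: r <= 40
  cells <- make_cells(c(30, 90), 0, diameter = 10)
  sp <- normalized_nearest_spacing(cells, g)
  expect_equal(sp$n_used, 1L) # only the r = 30 cell is focal
  expect_equal(sp$values, 6.0) # its nearest neighbour sits at r = 90
})

test_that("spacing flags degenerate inputs", {
  g <- make_geometry(100)
  one <- make_cells(0, 0)
  expect_true(normalized_nearest_spacing(one, g)$undefined)
  none <- make_cells(c(0, 10), 0, dlc = FALSE)
  expect_true(normalized_nearest_spacing(none, g)$undefined)
  zerod <- make_cells(c(0, 10), 0, diameter = c(0, 0))
  expect_error(normalized_nearest_spacing(zerod, g), class = "invalid_input")
})

test_that("domain angle is the smallest containing arc", {
  g <- make_geometry(100)
  deg <- pi / 180
  at_angles <- function(a_deg) {
    make_cells(50 * cos(a_deg * deg), 50 * sin(a_deg * deg))
  }
  expect_true(is.na(domain_angle(make_cells(0, 0, dlc = FALSE), g)))
  expect_equal(domain_angle(at_angles(45), g), 0)
  expect_equal(domain_angle(at_angles(c(10, 70)), g), 60)
  # wrap-around across the +x axis
  expect_equal(domain_angle(at_angles(c(350, 5, 10)), g), 20)
})

test_that("connected pairs use a strict threshold", {
  d <- 10
  one <- make_cells(0, 0, diameter = d)
  cp1 <- connected_pairs(one)
  expect_equal(cp1$n_connected_pairs, 0L)
  expect_equal(cp1$pct_cells_in_pairs, 0)

  # exactly at 1.25 diameters: NOT connected
  boundary <- make_cells(c(0, 1.25 * d), 0, diameter = d)
  expect_equal(connected_pairs(boundary)$n_connected_pairs, 0L)
  expect_equal(decompose_clusters(boundary)$max_cluster, 1L)

  # collinear at 0, 1.0 d, 2.2 d: pairs 1-2 and 2-3 only
  tri <- make_cells(c(0, 1.0 * d, 2.2 * d), 0, diameter = d)
  cp3 <- connected_pairs(tri)
  expect_equal(cp3$n_connected_pairs, 2L)
  expect_equal(cp3$pct_cells_in_pairs, 100)
})

test_that("cluster decomposition matches hand enumeration", {
  d <- 10
  iso <- decompose_clusters(make_cells(0, 0, diameter = d))
  expect_equal(iso$cluster_sizes, 1L)
  expect_equal(iso$max_cluster, 1L)

  tri <- decompose_clusters(make_cells(c(0, 1.0 * d, 2.2 * d), 0, diameter = d))
  expect_equal(tri$cluster_sizes, 3L)
  expect_equal(tri$max_cluster, 3L)

  two_pairs <- decompose_clusters(
    make_cells(c(0, 1.0 * d, 100, 101 * d / 10), 0, diameter = d))
  expect_equal(two_pairs$cluster_sizes, c(2L, 2L))
  expect_equal(two_pairs$max_cluster, 2L)

  none <- decompose_clusters(make_cells(0, 0, dlc = FALSE))
  expect_equal(none$max_cluster, 0L)
  expect_equal(sum(none$cluster_sizes), 0L)
})

test_that("summarize_embryo aggregates consistently with the single ops", {
  g <- tiny_geometry()
  p <- tiny_preset()
  set.seed(21)
  cells <- generate_cohort(cohort_config(p, 1, 21, g))$cells
  s <- summarize_embryo(cells, g)

  cc <- compartment_counts(cells)
  expect_equal(s$n_p63, cc$n_p63)
  expect_equal(s$n_p63, s$n_kerat + s$n_iono)
  expect_equal(s$density_iono, s$n_iono / g$counting_area)
  expect_equal(s$pct_brdu_kerat, 100 * cc$n_brdu_kerat / cc$n_kerat)
  expect_equal(s$mean_norm_spacing,
               normalized_nearest_spacing(cells, g)$mean_norm_spacing)
  expect_equal(s$domain_angle_deg, domain_angle(cells, g))
  expect_equal(s$max_cluster, decompose_clusters(cells)$max_cluster)

  # empty embryo: zero counts, undefined flags
  s0 <- summarize_embryo(make_cells(numeric(0), numeric(0)), g)
  expect_equal(s0$n_p63, 0L)
  expect_true(is.na(s0$mean_norm_spacing))
  expect_true(is.na(s0$domain_angle_deg))
  expect_true(is.na(s0$pct_brdu_iono))
})

test_that("summarize_embryo refuses mixed embryos", {
  cells <- rbind(make_cells(0, 0, embryo_id = "a"),
                 make_cells(5, 0, embryo_id = "b"))
  expect_error(summarize_embryo(cells, tiny_geometry()),
               class = "integrity_error")
})
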