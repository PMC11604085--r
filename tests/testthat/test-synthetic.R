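test_that("generated case metadata matches the cohort design", {
  md <- generate_case_metadata(4, 5, seed = 1)
  expect_equal(nrow(md), 9)
  expect_equal(sum(md$classification == "growing"), 5)
  st <- md$growth_rate_pct_per_year[md$classification == "static"]
  gr <- md$growth_rate_pct_per_year[md$classification == "growing"]
  expect_true(all(st >= -40 & st <= 16))
  expect_true(all(gr >= 28 & gr <= 267))
  expect_equal(nrow(generate_case_metadata(0, 0)), 0)
  # construction guarantees the rule over many seeds
  for (s in 1:20) {
    m <- generate_case_metadata(3, 3, seed = s)
    expect_identical(m$classification,
                     classify_growth(m$growth_rate_pct_per_year))
  }
})

test_that("simulated ROIs respect windows, non-negativity and determinism", {
  sc <- default_scenario(seed = 5, rois_per_case = 1,
                         roi_width_um = 400, roi_height_um = 300)
  sim1 <- suppressWarnings(simulate_cohort(sc))
  sim2 <- suppressWarnings(simulate_cohort(sc))
  expect_identical(as.data.frame(sim1$cells), as.data.frame(sim2$cells))
  expect_identical(sim1$metadata, sim2$metadata)
  expect_true(all(sim1$cells$x_um >= 0 & sim1$cells$x_um <= 400))
  expect_true(all(sim1$cells$y_um >= 0 & sim1$cells$y_um <= 300))
  mk <- markers(sim1$cells)
  expect_true(all(as.matrix(as.data.frame(sim1$cells)[mk]) >= 0))
  expect_equal(nrow(sim1$truth), nrow(sim1$cells))
})

test_that("poisson populations have calibrated mean and dispersion", {
  pop <- population_spec("P", "other", c(M1 = 1), process = "poisson",
                         intensity_per_mm2 = 100)
  sc <- scenario_config(list(pop), n_static = 1, n_growing = 0,
                        rois_per_case = 1, roi_width_um = 1000,
                        roi_height_um = 1000, seed = 1)
  case <- generate_case_metadata(1, 0, seed = 1)
  counts <- vapply(1:200, function(s)
    nrow(simulate_roi(sc, case[1, ], "r", seed = s)$cells), numeric(1))
  # mean within 3 standard errors of 100 on 1 mm^2
  expect_lt(abs(mean(counts) - 100), 3 * sqrt(100 / 200))
  disp <- var(counts) / mean(counts)
  expect_gt(disp, 0.7)
  expect_lt(disp, 1.3)
})

test_that("linked populations attach to partner points", {
  pops <- list(
    population_spec("A", "other", c(M1 = 1), process = "poisson",
                    intensity_per_mm2 = 50),
    population_spec("B", "other", c(M1 = 1), process = "linked",
                    intensity_per_mm2 = 50, link_partner = "A",
                    link_sigma_um = 0))
  sc <- scenario_config(pops, 1, 0, rois_per_case = 1,
                        roi_width_um = 1000, roi_height_um = 1000, seed = 2)
  case <- generate_case_metadata(1, 0, seed = 2)
  roi <- simulate_roi(sc, case[1, ], "r", seed = 3)
  a <- roi$cells[roi$truth$true_population == "A", c("x_um", "y_um")]
  b <- roi$cells[roi$truth$true_population == "B", c("x_um", "y_um")]
  expect_gt(nrow(b), 0)
  # sigma 0: every linked point coincides with some partner point
  for (i in seq_len(nrow(b))) {
    d <- sqrt((a$x_um - b$x_um[i])^2 + (a$y_um - b$y_um[i])^2)
    expect_lt(min(d), 1e-9)
  }
})

test_that("thomas populations are aggregated at short range", {
  pop <- population_spec("T", "other", c(M1 = 1), process = "thomas",
                         intensity_per_mm2 = 300, thomas_mean_offspring = 10,
                         thomas_sigma_um = 15)
  sc <- scenario_config(list(pop), 1, 0, rois_per_case = 1,
                        roi_width_um = 1000, roi_height_um = 1000, seed = 4)
  case <- generate_case_metadata(1, 0, seed = 4)
  # brute-force within-type pair correlation at r <= 20 um, averaged over seeds
  g20 <- vapply(1:5, function(s) {
    xy <- simulate_roi(sc, case[1, ], "r", seed = s)$cells[, c("x_um", "y_um")]
    n <- nrow(xy)
    d <- as.matrix(dist(xy)); diag(d) <- Inf
    pairs <- sum(d < 20) / 2
    exp_pairs <- n * (n - 1) / 2 * pi * 20^2 / 1e6   # CSR expectation
    pairs / exp_pairs
  }, numeric(1))
  expect_gt(mean(g20), 1.5)
})

test_that("planted growth slopes surface as density-growth correlations", {
  pops <- list(population_spec("A", "other", c(M1 = 1), process = "poisson",
                               intensity_per_mm2 = 200))
  sc0 <- scenario_config(pops, 4, 5, rois_per_case = 2, roi_width_um = 700,
                         roi_height_um = 700,
                         growth_effect = c(A = 0), seed = 1)
  sc1 <- scenario_config(pops, 4, 5, rois_per_case = 2, roi_width_um = 700,
                         roi_height_um = 700,
                         growth_effect = c(A = 0.6), seed = 1)
  rs <- function(sc, seeds) vapply(seeds, function(s) {
    sc$seed <- s
    sim <- simulate_cohort(sc)
    d <- cell_density(sim$cells, sim$geometry, "case")
    cor(d$density_per_mm2,
        sim$metadata$growth_rate_pct_per_year[match(d$case_id,
                                                    sim$metadata$case_id)])
  }, numeric(1))
  r0 <- rs(sc0, 1:10)
  r1 <- rs(sc1, 1:10)
  expect_lt(abs(mean(r0)), 0.25)             # null construction: r near 0
  expect_gt(mean(r1), 0.8)                   # planted slope: strong positive
})

test_that("scenario validation catches inconsistent configurations", {
  pops <- list(population_spec("A", "other", c(M1 = 1),
                               intensity_per_mm2 = 10))
  expect_error(scenario_config(pops, growth_effect = c(A = 1)), "negative intensity")
  expect_error(scenario_config(pops, growth_effect = c(B = 0)), "unknown population")
  expect_error(population_spec("L", "other", c(M1 = 1), process = "linked"),
               "link_partner")
  expect_error(population_spec("T", "other", c(M1 = 1), process = "thomas"),
               "thomas_mean_offspring")
})

test_that("neighbourhood mosaics plant the advertised domain structure", {
  one <- matrix(1, 1, 1, dimnames = list(NULL, "A"))
  mz1 <- plant_neighbourhood_mosaic(1, one, 300, 300, seed = 1)
  expect_true(all(mz1$truth$domain == 1))
  comp <- rbind(c(A = 1, B = 0), c(A = 0, B = 1))
  mz2 <- plant_neighbourhood_mosaic(2, comp, 500, 500, seed = 2)
  expect_true(all(mz2$truth$domain[mz2$cells$population_label == "A"] == 1))
  expect_true(all(mz2$truth$domain[mz2$cells$population_label == "B"] == 2))
  expect_error(plant_neighbourhood_mosaic(2, rbind(c(A = 0, B = 0),
                                                   c(A = 1, B = 0))),
               "positive sum|sum to 1")
  expect_error(plant_neighbourhood_mosaic(2, rbind(c(A = 0.5, B = 0.4),
                                                   c(A = 1, B = 0))),
               "sum to 1")
})

test_that("scenarios round-trip through YAML", {
  sc <- default_scenario(seed = 3, rois_per_case = 2)
  tmp <- tempfile(fileext = ".yaml")
  write_scenario_config(sc, tmp)
  sc2 <- read_scenario_config(tmp)
  expect_equal(names(sc2$populations), names(sc$populations))
  expect_equal(sc2$growth_effect, sc$growth_effect)
  expect_equal(sc2$rois_per_case, 2)
  # identical simulated output from the reread scenario
  s1 <- suppressWarnings(simulate_cohort(sc))
  s2 <- suppressWarnings(simulate_cohort(sc2))
  expect_identical(as.data.frame(s1$cells)[c("cell_id", "x_um", "y_um")],
                   as.data.frame(s2$cells)[c("cell_id", "x_um", "y_um")])
  unlink(tmp)
})
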