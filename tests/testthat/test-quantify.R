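make_table <- function(values, marker = "M1") {
  n <- length(values)
  d <- data.frame(cell_id = paste0("c", seq_len(n)), case_id = "k1",
                  roi_id = "r1", x_um = rep(1, n), y_um = rep(1, n))
  d[[marker]] <- values
  cell_table(d, panel_def(marker), roi_geometry("r1", "k1", 100, 100))
}

test_that("percentile normalisation clips to [0, 1] with an exact percentile", {
  # constant positive marker: percentile equals the constant, all norm = 1
  ct <- normalize_expression(make_table(rep(3, 20)))
  expect_true(all(ct$norm_M1 == 1))
  # all-zero marker: warned, all norm = 0
  expect_warning(ct0 <- normalize_expression(make_table(rep(0, 20))), "zero")
  expect_true(all(ct0$norm_M1 == 0))
  # 10000 values 0..9999 at q = 99.9: oracle by explicit order-statistic
  # interpolation (type-7): h = (n-1) q + 1
  v <- 0:9999
  ct3 <- normalize_expression(make_table(v), q = 99.9)
  h <- (10000 - 1) * 0.999 + 1
  P <- sort(v)[floor(h)] + (h - floor(h)) * (sort(v)[ceiling(h)] - sort(v)[floor(h)])
  expect_equal(attr(ct3, "norm_percentiles")[["M1"]], P)
  expect_equal(max(ct3$norm_M1), 1)
  expect_equal(sum(ct3$norm_M1 == 1), sum(v >= P))
  expect_equal(ct3$norm_M1[v < P], v[v < P] / P)
})

test_that("normalisation is idempotent and scale-equivariant", {
  set.seed(1)
  v <- rlnorm(500)
  ct <- normalize_expression(make_table(v))
  ct_scaled <- normalize_expression(make_table(v * 17))
  expect_equal(ct$norm_M1, ct_scaled$norm_M1, tolerance = 1e-12)
  # idempotence with the same percentile: at q = 100 the percentile of
  # an already-normalised marker is exactly 1, so values stay fixed
  ct100 <- normalize_expression(make_table(v), q = 100)
  ct101 <- normalize_expression(make_table(ct100$norm_M1), q = 100)
  expect_equal(ct101$norm_M1, ct100$norm_M1, tolerance = 1e-12)
})

test_that("case means pool all ROIs of a case", {
  d <- rbind(toy_cells_df(2, roi_id = "r1", case_id = "k1"),
             toy_cells_df(1, roi_id = "r2", case_id = "k2"))
  d$cell_id <- paste0(d$roi_id, d$cell_id)
  geom <- roi_geometry(c("r1", "r2"), c("k1", "k2"), 100, 100)
  ct <- cell_table(d, toy_panel(), geom)
  ct$norm_M1 <- c(0.2, 0.4, 0.9); ct$norm_M2 <- c(0, 0, 0)
  m <- case_mean_expression(ct, "M1")
  expect_equal(unname(m["k1"]), 0.3)
  expect_equal(unname(m["k2"]), 0.9)
  expect_false("k3" %in% names(m))
  expect_error(case_mean_expression(ct, "nope"), "unknown marker")
})

test_that("densities pool ROI areas per case and are additive over labels", {
  d <- toy_cells_df(500, w = 1000, h = 500)      # 0.5 mm^2
  d$cell_id <- paste0("c", 1:500)
  geom <- roi_geometry("r1", "c1", 1000, 500)
  ct <- cell_table(d, toy_panel(), geom)
  dens <- cell_density(ct, geom, "case")
  expect_equal(dens$density_per_mm2, 1000)
  # two-ROI pooling: (300 + 150) cells over (1 + 0.5) mm^2 = 300
  d2 <- rbind(toy_cells_df(300, roi_id = "a", w = 1000, h = 1000),
              toy_cells_df(150, roi_id = "b", w = 1000, h = 500))
  d2$cell_id <- paste0(d2$roi_id, seq_len(450))
  g2 <- roi_geometry(c("a", "b"), "c1", c(1000, 1000), c(1000, 500))
  ct2 <- cell_table(d2, toy_panel(), g2)
  expect_equal(cell_density(ct2, g2, "case")$density_per_mm2, 300)
  # zero-cell case reports 0
  g3 <- roi_geometry(c("a", "b", "c"), c("c1", "c1", "c2"),
                     c(1000, 1000, 500), c(1000, 500, 500))
  expect_equal(cell_density(ct2, g3, "case")$density_per_mm2, c(300, 0))
  # per-population densities sum to the total
  ct2$population_label <- rep(c("X", "Y"), length.out = 450)
  by_pop <- cell_density(ct2, g2, "case_population")
  expect_equal(sum(by_pop$density_per_mm2), 300)
  expect_error(cell_density(ct2, roi_geometry("a", "c1", 1000, 1000), "case"),
               "without geometry")
})

test_that("growth correlations gate Pearson vs Spearman on normality", {
  md <- default_case_metadata()
  x <- md$growth_rate_pct_per_year
  # exact linear relation on raw rates
  v <- setNames(2 * x, md$case_id)
  r <- correlate_with_growth(v, md)
  expect_equal(r$r, 1, tolerance = 1e-12)
  expect_equal(r$slope, 2, tolerance = 1e-12)
  # monotone transform with heavy tails: spearman branch, rho = 1
  v2 <- setNames(exp(x / 25), md$case_id)
  r2 <- correlate_with_growth(v2, md)
  expect_equal(r2$method, "spearman")
  expect_equal(r2$r, 1, tolerance = 1e-12)
  expect_error(correlate_with_growth(v[1:3], md), "at least 4")
  expect_error(correlate_with_growth(setNames(rep(1, 9), md$case_id), md),
               "zero variance")
})

test_that("pearson branch matches the product-moment formula long-hand", {
  md <- case_metadata(paste0("k", 1:5), "F", 30, 1, c(-10, 0, 10, 25, 40))
  y <- c(2.2, 1.9, 3.1, 3.4, 4.4)
  x <- md$growth_rate_pct_per_year
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- correlate_with_growth(setNames(y, md$case_id), md)
  expect_equal(res$method, "pearson")
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  slope_hand <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  expect_equal(res$slope, slope_hand, tolerance = 1e-12)
})

test_that("two-sample comparisons gate on normality and match the U oracle", {
  set.seed(3)
  a <- rnorm(8, 10); b <- rnorm(8, 10)
  same <- compare_groups(c(a, a), rep(c("g1", "g2"), each = 8))
  expect_gt(same$p, 0.9)
  far <- compare_groups(c(1, 2, 3, 4, 101, 102, 103, 104),
                        rep(c("g1", "g2"), each = 4))
  expect_lt(far$p, 0.05)
  # Mann-Whitney U by exhaustive pair counting; a heavy-tailed group
  # fails the normality gate so the nonparametric branch runs
  ga <- c(1, 2, 3, 3.1, 60); gb <- c(70, 80, 90, 100, 110)
  mw <- compare_groups(c(ga, gb), rep(c("g1", "g2"), each = 5))
  expect_equal(mw$test, "mann_whitney")
  expect_equal(unname(mw$statistic), sum(outer(ga, gb, ">")))   # = 0
  # below-3 group: normality untestable, falls back to Mann-Whitney
  expect_warning(mw2 <- compare_groups(c(1, 2, 4, 5, 6),
                                       c("a", "a", "b", "b", "b")), "n < 3")
  expect_equal(mw2$test, "mann_whitney")
  expect_equal(unname(mw2$statistic), 0)
  expect_warning(compare_groups(c(1, 2, 10, 11, 12), c("a", "a", "b", "b", "b")),
                 "n < 3")
})

test_that("two-way ANOVA design detects a planted group effect", {
  set.seed(4)
  d <- expand.grid(case = 1:6, factorB = c("cat1", "cat2"))
  d$factorA <- rep(c("g1", "g2"), length.out = 12)
  d$value <- rnorm(12, sd = 0.1) + ifelse(d$factorA == "g1", 0, 2)
  res <- compare_groups(d[c("value", "factorA", "factorB")], design = "two_way")
  expect_equal(res$test, "anova_2way")
  expect_lt(res$p, 0.01)
})

test_that("pearson and spearman agree in sign on monotone data", {
  md <- default_case_metadata()
  set.seed(5)
  for (i in 1:5) {
    v <- setNames(sort(rlnorm(9, sdlog = 2)), md$case_id[order(md$growth_rate_pct_per_year)])
    res <- correlate_with_growth(v, md)
    x <- md$growth_rate_pct_per_year[match(names(v), md$case_id)]
    expect_gt(res$r * cor(x, as.numeric(v), method = "spearman"), 0)
  }
})
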