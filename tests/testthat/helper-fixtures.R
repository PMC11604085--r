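# Shared fixture builders. Everything is generated in code at test time.

toy_panel <- function(markers = c("M1", "M2")) {
  panel_def(markers)
}

toy_geometry <- function(roi_id = "r1", case_id = "c1", w = 100, h = 100) {
  roi_geometry(roi_id, case_id, w, h)
}

toy_cells_df <- function(n = 3, roi_id = "r1", case_id = "c1",
                         markers = c("M1", "M2"), w = 100, h = 100) {
  set.seed(42)
  d <- data.frame(cell_id = paste0("c", seq_len(n)), case_id = case_id,
                  roi_id = roi_id, x_um = runif(n, 0, w), y_um = runif(n, 0, h),
                  stringsAsFactors = FALSE)
  for (m in markers) d[[m]] <- runif(n, 0, 10)
  d
}

# Small simulated cohort with labels, shared across test files (built once).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- default_scenario(seed = 7, rois_per_case = 2,
                             roi_width_um = 500, roi_height_um = 500)
      sim <- suppressWarnings(simulate_cohort(sc))
      ct <- normalize_expression(sim$cells)
      ct <- suppressWarnings(phenotype_cells(ct, k_neighbours = 10, seed = 3))
      cache <<- list(cells = ct, metadata = sim$metadata,
                     geometry = sim$geometry, truth = sim$truth)
    }
    cache
  }
})

# Dominant-diagonal composition matrix for mosaic experiments.
mosaic_compositions <- function(K, hi = 0.7) {
  m <- matrix((1 - hi) / (K - 1), K, K)
  diag(m) <- hi
  colnames(m) <- LETTERS[seq_len(K)]
  m
}

# Textbook BH step-up oracle, written independently of the package.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) ranked[i] <- min(ranked[i], ranked[i + 1])
  out <- numeric(m)
  out[o] <- pmin(ranked, 1)
  out
}

# Pair-enumeration Fowlkes-Mallows oracle.
fmi_oracle <- function(a, b) {
  n <- length(a)
  tp <- fp <- fn <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) tp <- tp + 1
    else if (sa && !sb) fp <- fp + 1
    else if (!sa && sb) fn <- fn + 1
  }
  if (tp + fp == 0 && tp + fn == 0) return(1)
  if (tp + fp == 0 || tp + fn == 0) return(0)
  tp / sqrt((tp + fp) * (tp + fn))
}

# All permutations of a vector (small n only).
all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}
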