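#' Quadrat counts for one ROI
#'
#' Overlays an axis-aligned grid of square quadrats (side `side_um`,
#' origin at the ROI corner) and counts cells per quadrat and
#' population. Only quadrats fully contained in the ROI are used;
#' cells are assigned by the half-open rule
#' `[x0, x0 + side) x [y0, y0 + side)`, so a cell exactly on an interior
#' boundary belongs to the higher-index quadrat.
#'
#' @param cells data frame with `x_um`, `y_um` and a label column.
#' @param width_um,height_um ROI window.
#' @param side_um quadrat side (default 100 um).
#' @param label_col label column name (default `"population_label"`).
#' @param pop_levels population levels (default: sorted unique labels).
#' @return A `quadrat_counts` list: `counts` (quadrats x populations
#'   matrix), `nx`, `ny`, `side_um`.
#' @export
quadrat_counts <- function(cells, width_um, height_um, side_um = 100,
                           label_col = "population_label",
                           pop_levels = NULL) {
  stopifnot(side_um > 0)
  nx <- floor(width_um / side_um)
  ny <- floor(height_um / side_um)
  pop_levels <- pop_levels %||% sort(unique(cells[[label_col]]))
  if (nx < 1 || ny < 1) {
    warnf("quadrat_counts: ROI smaller than one quadrat")
    return(structure(list(counts = matrix(0, 0, length(pop_levels),
                                          dimnames = list(NULL, pop_levels)),
                          nx = nx, ny = ny, side_um = side_um),
                     class = "quadrat_counts"))
  }
  ix <- floor(cells$x_um / side_um)
  iy <- floor(cells$y_um / side_um)
  keep <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
  q <- iy[keep] * nx + ix[keep] + 1L         # row-major quadrat index
  lab <- factor(cells[[label_col]][keep], levels = pop_levels)
  counts <- matrix(0L, nx * ny, length(pop_levels),
                   dimnames = list(NULL, pop_levels))
  tab <- table(factor(q, levels = seq_len(nx * ny)), lab)
  counts[] <- as.integer(tab)
  structure(list(counts = counts, nx = nx, ny = ny, side_um = side_um),
            class = "quadrat_counts")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (wraps
#' `stats::p.adjust(method = "BH")` after validating the input range).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Quadrat correlation matrix
#'
#' Pairwise Pearson correlation of per-quadrat population counts across
#' the quadrats of one ROI, with two-tailed p-values,
#' Benjamini-Hochberg adjustment over all unordered pairs, and a gated
#' matrix in which non-significant correlations are set to zero.
#'
#' @param counts a [quadrat_counts()] result (>= 10 quadrats).
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @return A `qcm` list: `r`, `p`, `p_adj`, `gated` (all P x P symmetric
#'   matrices), `alpha`, and `notes` for zero-variance populations.
#' @export
quadrat_correlation_matrix <- function(counts, alpha = 0.05) {
  m <- counts$counts
  if (nrow(m) < 10) stopf("need at least 10 quadrats")
  P <- ncol(m)
  pops <- colnames(m)
  rmat <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  pmat <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  diag(rmat) <- 1; diag(pmat) <- 0
  zerovar <- pops[apply(m, 2, stats::sd) == 0]
  notes <- if (length(zerovar))
    sprintf("zero-variance population(s) reported as 0: %s",
            paste(zerovar, collapse = ", ")) else character()
  pairs <- which(upper.tri(rmat), arr.ind = TRUE)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    if (pops[i] %in% zerovar || pops[j] %in% zerovar) {
      rmat[i, j] <- rmat[j, i] <- 0
      pmat[i, j] <- pmat[j, i] <- 1
      next
    }
    ct <- stats::cor.test(m[, i], m[, j], method = "pearson",
                          alternative = "two.sided")
    rmat[i, j] <- rmat[j, i] <- unname(ct$estimate)
    pmat[i, j] <- pmat[j, i] <- ct$p.value
  }
  padj <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  diag(padj) <- 0
  padj_vec <- bh_adjust(pmat[upper.tri(pmat)])
  padj[upper.tri(padj)] <- padj_vec
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  gated <- rmat
  gated[padj >= alpha] <- 0
  structure(list(r = rmat, p = pmat, p_adj = padj, gated = gated,
                 alpha = alpha, notes = notes), class = "qcm")
}

#' @export
print.qcm <- function(x, ...) {
  cat(sprintf("<qcm> %d populations, alpha = %g; significant pairs: %d\n",
              nrow(x$r), x$alpha, sum(x$gated[upper.tri(x$gated)] != 0)))
  if (length(x$notes)) cat(x$notes, "\n")
  invisible(x)
}

#' Topographical correlation map
#'
#' Local association of a sender/receiver population pair across one
#' ROI: on a grid of `scale_um`-sided tiles, the score is the z-value of
#' the observed sender-receiver co-count (`n_sender * n_receiver` in the
#' tile) against its distribution under random permutation of the
#' population labels over all cells of the ROI (seeded), which preserves
#' tile occupancy while randomising which cells carry the pair's labels.
#' Positive scores mark tiles where the pair co-occurs more than chance.
#'
#' @param cells data frame with `x_um`, `y_um` and `label_col`.
#' @param pair character vector of two population names
#'   `c(sender, receiver)`.
#' @param width_um,height_um ROI window.
#' @param scale_um tile side (default 100 um).
#' @param n_perm label permutations (default 500).
#' @param seed integer seed.
#' @param label_col label column (default `"population_label"`).
#' @return A `ny x nx` matrix of signed scores (rows = tile rows).
#' @export
topographical_correlation_map <- function(cells, pair, width_um, height_um,
                                          scale_um = 100, n_perm = 500,
                                          seed = 1L,
                                          label_col = "population_label") {
  stopifnot(length(pair) == 2)
  nx <- floor(width_um / scale_um); ny <- floor(height_um / scale_um)
  score <- matrix(0, ny, nx)
  if (!all(pair %in% cells[[label_col]])) {
    warnf("topographical_correlation_map: population absent; zero map")
    return(score)
  }
  ix <- floor(cells$x_um / scale_um); iy <- floor(cells$y_um / scale_um)
  keep <- ix >= 0 & ix < nx & iy >= 0 & iy < ny
  tile <- iy[keep] * nx + ix[keep] + 1L
  lab <- cells[[label_col]][keep]
  nt <- nx * ny
  cocount <- function(lv) {
    na <- tabulate(tile[lv == pair[1]], nbins = nt)
    nb <- tabulate(tile[lv == pair[2]], nbins = nt)
    na * nb
  }
  obs <- cocount(lab)
  perms <- with_seed(derive_seed(seed, "topo_map"), {
    vapply(seq_len(n_perm), function(i) cocount(sample(lab)), numeric(nt))
  })
  mu <- rowMeans(perms)
  sdv <- apply(perms, 1, stats::sd)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  matrix(z, ny, nx, byrow = TRUE)
}
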