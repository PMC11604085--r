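# Cross-pair correlation functions on rectangular ROI windows.

# Area of the intersection of the quadrant rectangle [0,a] x [0,b] with a
# disc of radius r centred at the origin; a, b vectors >= 0, r scalar.
quadrant_disc_area <- function(a, b, r) {
  if (r <= 0) return(numeric(length(a)))
  Fi <- function(u) 0.5 * (u * sqrt(pmax(r^2 - u^2, 0)) + r^2 * asin(pmin(u / r, 1)))
  ua <- pmin(a, r)
  out <- numeric(length(a))
  big_b <- b >= r
  out[big_b] <- Fi(ua[big_b])
  if (any(!big_b)) {
    bb <- b[!big_b]; aa <- a[!big_b]; uaa <- ua[!big_b]
    ustar <- sqrt(r^2 - bb^2)
    inside <- aa <= ustar
    res <- numeric(length(bb))
    res[inside] <- aa[inside] * bb[inside]
    if (any(!inside))
      res[!inside] <- bb[!inside] * ustar[!inside] +
        Fi(uaa[!inside]) - Fi(ustar[!inside])
    out[!big_b] <- res
  }
  out
}

# Area of disc(center (x,y), radius r) ∩ [0,W] x [0,H]; points inside window.
disc_window_area <- function(x, y, r, W, H) {
  quadrant_disc_area(x, y, r) + quadrant_disc_area(W - x, y, r) +
    quadrant_disc_area(x, H - y, r) + quadrant_disc_area(W - x, H - y, r)
}

# Pairwise distances, optionally toroidal on the window.
pair_dist <- function(A, B, W, H, toroidal = FALSE) {
  dx <- outer(A[, 1], B[, 1], "-")
  dy <- outer(A[, 2], B[, 2], "-")
  if (toroidal) {
    dx <- abs(dx); dx <- pmin(dx, W - dx)
    dy <- abs(dy); dy <- pmin(dy, H - dy)
  }
  sqrt(dx^2 + dy^2)
}

as_xy <- function(p) {
  if (is.data.frame(p)) {
    cols <- if (all(c("x_um", "y_um") %in% names(p))) c("x_um", "y_um") else c("x", "y")
    p <- as.matrix(p[cols])
  }
  p <- as.matrix(p)
  stopifnot(ncol(p) == 2)
  unname(p)
}

#' Cross-pair correlation function
#'
#' Estimates the cross-PCF g(r) between a sender and a receiver point
#' set on a rectangular window: for annuli of width `dr`,
#' \deqn{\hat g(r) = \frac{|W|}{n_A n_B} \sum_{a \in A}
#'   \frac{\#\{b \in B : d(a,b) \in [r, r+dr)\}}{|annulus(a) \cap W|}}
#' with the annulus-window intersection area computed exactly
#' (`correction = "border"`). Under independence g = 1; g > 1 indicates
#' attraction and g < 1 repulsion at that distance. The sender and
#' receiver sets may be the same (auto-PCF); self-pairs are then
#' excluded.
#'
#' @param senders,receivers point coordinates: matrices or data frames
#'   with columns `x_um`, `y_um` (or `x`, `y`), in micrometres.
#' @param window `c(width_um, height_um)` of the ROI.
#' @param r_max maximum distance (default 300 um).
#' @param dr bin width (default 10 um); bins are left-closed
#'   `[r, r + dr)` with left edges 0, dr, 2 dr, ...
#' @param correction `"border"` (exact annulus-window area),
#'   `"toroidal"` (wrap-around distances, full annulus area) or
#'   `"none"` (full annulus area).
#' @return A data frame with columns `r` (bin left edge), `g`.
#' @export
cross_pcf <- function(senders, receivers, window, r_max = 300, dr = 10,
                      correction = c("border", "toroidal", "none")) {
  correction <- match.arg(correction)
  if (dr <= 0) stopf("dr must be positive")
  A <- as_xy(senders); B <- as_xy(receivers)
  if (!nrow(A) || !nrow(B)) stopf("cross_pcf: empty point set")
  W <- window[1]; H <- window[2]
  auto <- nrow(A) == nrow(B) && isTRUE(all.equal(A, B))
  pc <- pcf_precompute(A, B, W, H, r_max, dr, correction, auto)
  g <- pcf_from_weights(pc, rep(1L, nrow(A)), rep(1L, nrow(B)))
  data.frame(r = pc$breaks[-length(pc$breaks)], g = g)
}

# Shared machinery for cross_pcf and bootstrap_pcf: bins pair distances
# once and records, per bin, the (sender, receiver) index pairs and the
# sender's inverse annulus area, so g can be recomputed for arbitrary
# point multiplicities (bootstrap weights) cheaply.
pcf_precompute <- function(A, B, W, H, r_max, dr, correction, auto) {
  nb <- ceiling(r_max / dr)
  breaks <- seq(0, nb * dr, by = dr)
  d <- pair_dist(A, B, W, H, toroidal = correction == "toroidal")
  if (auto) diag(d) <- Inf
  binm <- floor(d / dr) + 1L
  binm[d >= r_max] <- NA_integer_
  nA <- nrow(A)
  area <- matrix(0, nA, nb)
  for (k in seq_len(nb)) {
    if (correction == "border") {
      area[, k] <- disc_window_area(A[, 1], A[, 2], breaks[k + 1], W, H) -
        disc_window_area(A[, 1], A[, 2], breaks[k], W, H)
    } else {
      area[, k] <- pi * (breaks[k + 1]^2 - breaks[k]^2)
    }
  }
  idx <- which(!is.na(binm))
  bins <- binm[idx]
  rows <- (idx - 1L) %% nA + 1L
  cols <- (idx - 1L) %/% nA + 1L
  per_bin <- lapply(seq_len(nb), function(k) {
    sel <- bins == k
    list(rows = rows[sel], cols = cols[sel],
         inv_area = 1 / area[cbind(rows[sel], k)])
  })
  list(per_bin = per_bin, breaks = breaks, nb = nb, area = area,
       W = W, H = H, nA = nA, nB = nrow(B))
}

pcf_from_weights <- function(pc, ka, kb) {
  vol <- pc$W * pc$H
  nA <- sum(ka); nB <- sum(kb)
  vapply(pc$per_bin, function(pb) {
    if (!length(pb$rows)) return(0)
    vol / (nA * nB) * sum(ka[pb$rows] * kb[pb$cols] * pb$inv_area)
  }, numeric(1))
}

#' Bootstrap cross-PCF with confidence intervals
#'
#' Resamples senders and receivers independently with replacement (each
#' at its original size), recomputes g(r), and reports percentile 95%
#' confidence bands. The association call is made at the bin containing
#' r = 20 um: `"positive"` when the lower CI bound exceeds 1,
#' `"negative"` when the upper bound is below 1, `"none"` otherwise.
#'
#' @inheritParams cross_pcf
#' @param n_boot bootstrap replicates (default 200; fewer than 50 warns).
#' @param seed integer seed.
#' @param r_call distance (um) at which the call is made (default 20).
#' @param sender_name,receiver_name optional population names carried on
#'   the result.
#' @return A `crosspcf` object: data frame fields `r`, `g`, `ci_low`,
#'   `ci_high`, plus `gr20`, `call`, `n_boot`.
#' @export
bootstrap_pcf <- function(senders, receivers, window, r_max = 300, dr = 10,
                          n_boot = 200, seed = 1L, r_call = 20,
                          correction = c("border", "toroidal", "none"),
                          sender_name = "sender", receiver_name = "receiver") {
  correction <- match.arg(correction)
  if (n_boot < 50) warnf("bootstrap_pcf: n_boot < 50 gives unstable CIs")
  A <- as_xy(senders); B <- as_xy(receivers)
  if (!nrow(A) || !nrow(B)) stopf("bootstrap_pcf: empty point set")
  W <- window[1]; H <- window[2]
  auto <- nrow(A) == nrow(B) && isTRUE(all.equal(A, B))
  pc <- pcf_precompute(A, B, W, H, r_max, dr, correction, auto)
  g <- pcf_from_weights(pc, rep(1L, nrow(A)), rep(1L, nrow(B)))
  boot <- with_seed(derive_seed(seed, "bootstrap_pcf"), {
    t(vapply(seq_len(n_boot), function(i) {
      ka <- tabulate(sample.int(nrow(A), replace = TRUE), nbins = nrow(A))
      kb <- tabulate(sample.int(nrow(B), replace = TRUE), nbins = nrow(B))
      pcf_from_weights(pc, ka, kb)
    }, numeric(pc$nb)))
  })
  ci_low <- apply(boot, 2, stats::quantile, probs = 0.025, names = FALSE)
  ci_high <- apply(boot, 2, stats::quantile, probs = 0.975, names = FALSE)
  bin20 <- min(pc$nb, floor(r_call / dr) + 1L)
  call <- if (ci_low[bin20] > 1) "positive" else if (ci_high[bin20] < 1)
    "negative" else "none"
  structure(list(sender = sender_name, receiver = receiver_name,
                 r = pc$breaks[-length(pc$breaks)], g = g,
                 ci_low = ci_low, ci_high = ci_high,
                 gr20 = g[bin20], call = call, r_call = r_call,
                 n_boot = n_boot), class = "crosspcf")
}

#' @export
print.crosspcf <- function(x, ...) {
  cat(sprintf("<crosspcf> %s -> %s: g(r=%g) = %.3f [%.3f, %.3f], call = %s\n",
              x$sender, x$receiver, x$r_call, x$gr20,
              x$ci_low[min(length(x$ci_low), floor(x$r_call / diff(x$r[1:2])) + 1)],
              x$ci_high[min(length(x$ci_high), floor(x$r_call / diff(x$r[1:2])) + 1)],
              x$call))
  invisible(x)
}

#' @export
as.data.frame.crosspcf <- function(x, ...) {
  data.frame(sender = x$sender, receiver = x$receiver, r = x$r, g = x$g,
             ci_low = x$ci_low, ci_high = x$ci_high, stringsAsFactors = FALSE)
}

#' @export
plot.crosspcf <- function(x, ...) {
  graphics::plot(x$r, x$g, type = "s", xlab = "r (um)", ylab = "g(r)",
                 main = sprintf("%s -> %s", x$sender, x$receiver), ...)
  graphics::lines(x$r, x$ci_low, lty = 2, type = "s")
  graphics::lines(x$r, x$ci_high, lty = 2, type = "s")
  graphics::abline(h = 1, col = "grey")
  invisible(x)
}
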