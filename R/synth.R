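#' Population specifications for the cohort simulator
#'
#' Describes one simulated cell population: its hierarchy, mean marker
#' expression, multiplicative noise level, and the spatial point process
#' that places its cells.
#'
#' Processes:
#' \describe{
#'   \item{poisson}{homogeneous Poisson (complete spatial randomness) at
#'     the population's intensity.}
#'   \item{thomas}{Neyman-Scott cluster process: Poisson parents, each
#'     with a Poisson(`thomas_mean_offspring`) number of offspring
#'     scattered isotropically with standard deviation `thomas_sigma_um`.
#'     The parent rate is scaled so the expected total intensity equals
#'     the population's intensity; offspring outside the window are
#'     discarded, so realised intensity is slightly below nominal near
#'     edges.}
#'   \item{linked}{each cell is placed at a uniformly chosen cell of
#'     `link_partner` plus an isotropic Gaussian(`link_sigma_um`)
#'     displacement — a direct generator of cross-type attraction.}
#' }
#'
#' @param name population name (unique within a scenario).
#' @param hierarchy one of `"myeloid"`, `"neoplastic"`, `"lymphoid"`,
#'   `"vascular"`, `"proliferative"`, `"other"`.
#' @param mean_expr named non-negative numeric vector of mean raw marker
#'   intensities.
#' @param noise_cv positive coefficient of variation of the lognormal
#'   multiplicative expression noise.
#' @param process `"poisson"`, `"thomas"` or `"linked"`.
#' @param intensity_per_mm2 expected cells per mm^2 at growth rate 0.
#' @param thomas_parent_per_mm2,thomas_mean_offspring,thomas_sigma_um
#'   Thomas process parameters (required when `process == "thomas"`;
#'   `thomas_parent_per_mm2` is retained for reference, the realised
#'   parent rate is `intensity / thomas_mean_offspring`).
#' @param link_partner,link_sigma_um linked-process parameters (required
#'   when `process == "linked"`).
#' @return A `population_spec` list.
#' @export
population_spec <- function(name, hierarchy, mean_expr, noise_cv = 0.5,
                            process = c("poisson", "thomas", "linked"),
                            intensity_per_mm2 = 100,
                            thomas_parent_per_mm2 = NULL,
                            thomas_mean_offspring = NULL,
                            thomas_sigma_um = NULL,
                            link_partner = NULL, link_sigma_um = NULL) {
  process <- match.arg(process)
  stopifnot(is.numeric(mean_expr), all(mean_expr >= 0),
            !is.null(names(mean_expr)))
  if (noise_cv <= 0) stopf("noise_cv must be positive")
  if (intensity_per_mm2 < 0) stopf("intensity_per_mm2 must be non-negative")
  hierarchy <- match.arg(hierarchy, c("myeloid", "neoplastic", "lymphoid",
                                      "vascular", "proliferative", "other"))
  if (process == "thomas" &&
      (is.null(thomas_mean_offspring) || is.null(thomas_sigma_um)))
    stopf("thomas process requires thomas_mean_offspring and thomas_sigma_um")
  if (process == "linked" && (is.null(link_partner) || is.null(link_sigma_um)))
    stopf("linked process requires link_partner and link_sigma_um")
  structure(list(name = name, hierarchy = hierarchy, mean_expr = mean_expr,
                 noise_cv = noise_cv, process = process,
                 intensity_per_mm2 = intensity_per_mm2,
                 thomas_parent_per_mm2 = thomas_parent_per_mm2,
                 thomas_mean_offspring = thomas_mean_offspring,
                 thomas_sigma_um = thomas_sigma_um,
                 link_partner = link_partner, link_sigma_um = link_sigma_um),
            class = "population_spec")
}

#' Scenario configuration for the cohort simulator
#'
#' @param populations list of [population_spec()] objects.
#' @param n_static,n_growing case counts (defaults 4 and 5, the cohort
#'   design emulated throughout the package).
#' @param rois_per_case ROIs imaged per case (default 6).
#' @param roi_width_um,roi_height_um ROI window, default 1000 x 1000 um.
#' @param growth_effect named numeric vector: change in a population's
#'   intensity (cells per mm^2) per unit growth rate (%/yr). Unnamed
#'   populations get slope 0. Slopes must keep intensities non-negative
#'   over the simulated growth-rate range (-40 to 267 %/yr).
#' @param seed integer master seed; all ROI-level seeds derive from it.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(populations, n_static = 4, n_growing = 5,
                            rois_per_case = 6, roi_width_um = 1000,
                            roi_height_um = 1000, growth_effect = NULL,
                            seed = 1L) {
  stopifnot(length(populations) >= 1, n_static >= 0, n_growing >= 0,
            rois_per_case >= 1, roi_width_um > 0, roi_height_um > 0)
  names(populations) <- vapply(populations, `[[`, "", "name")
  if (anyDuplicated(names(populations))) stopf("duplicate population name")
  ge <- setNames(numeric(length(populations)), names(populations))
  if (!is.null(growth_effect)) {
    bad <- setdiff(names(growth_effect), names(populations))
    if (length(bad)) stopf("growth_effect for unknown population(s): %s",
                           paste(bad, collapse = ", "))
    ge[names(growth_effect)] <- growth_effect
  }
  for (p in names(populations)) {
    base <- populations[[p]]$intensity_per_mm2
    if (base + ge[[p]] * -40 < 0 || base + ge[[p]] * 267 < 0)
      stopf("growth_effect slope for '%s' yields negative intensity in range",
            p)
  }
  for (p in populations) {
    if (p$process == "linked" && !p$link_partner %in% names(populations))
      stopf("link_partner '%s' of '%s' is not a scenario population",
            p$link_partner, p$name)
  }
  structure(list(populations = populations, n_static = n_static,
                 n_growing = n_growing, rois_per_case = rois_per_case,
                 roi_width_um = roi_width_um, roi_height_um = roi_height_um,
                 growth_effect = ge, seed = as.integer(seed)),
            class = "scenario_config")
}

#' Generate synthetic case metadata
#'
#' Growth rates are drawn uniformly on the observed ranges of the two
#' classes: static on \[-40, 16\] and growing on \[28, 267\] % volume
#' change per year, so classification by the 20 %/yr rule is consistent
#' by construction.
#'
#' @param n_static,n_growing non-negative case counts.
#' @param seed integer seed.
#' @return A `case_metadata` data frame with `n_static + n_growing` rows.
#' @export
generate_case_metadata <- function(n_static, n_growing, seed = 1L) {
  stopifnot(n_static >= 0, n_growing >= 0)
  n <- n_static + n_growing
  if (n == 0) {
    return(case_metadata(character(), character(), integer(), numeric(),
                         numeric()))
  }
  with_seed(derive_seed(seed, "case_metadata"), {
    rates <- c(stats::runif(n_static, -40, 16), stats::runif(n_growing, 28, 267))
    case_metadata(case_id = sprintf("SIM%02d", seq_len(n)),
                  sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.25, 0.75)),
                  age_years = sample(25:70, n, replace = TRUE),
                  tumour_volume_cm3 = round(stats::rlnorm(n, log(2), 0.9), 2),
                  growth_rate_pct_per_year = round(rates, 2))
  })
}

# Lognormal multiplier with unit mean and coefficient of variation cv.
rlnorm_cv <- function(n, cv) {
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

# Draw marker intensities for n cells of one population.
draw_expression <- function(n, pop, marker_names) {
  out <- matrix(0, nrow = n, ncol = length(marker_names),
                dimnames = list(NULL, marker_names))
  mu <- setNames(numeric(length(marker_names)), marker_names)
  common <- intersect(names(pop$mean_expr), marker_names)
  mu[common] <- pop$mean_expr[common]
  for (m in marker_names) {
    out[, m] <- if (mu[[m]] > 0) mu[[m]] * rlnorm_cv(n, pop$noise_cv) else 0
  }
  out
}

#' Simulate one ROI
#'
#' Places each scenario population by its point process at intensity
#' `base + slope * growth_rate`, draws marker intensities as
#' `mean_expr * LogNormal` noise with the population's CV, and discards
#' out-of-window points.
#'
#' @param scenario a [scenario_config()].
#' @param case one row of a `case_metadata` data frame.
#' @param roi_id identifier for the ROI.
#' @param seed integer seed for this ROI.
#' @return A list with elements `cells` (a `cell_table`), `geometry`
#'   (a one-row `roi_geometry`) and `truth` (data frame of per-cell true
#'   population and hierarchy).
#' @export
simulate_roi <- function(scenario, case, roi_id, seed = 1L) {
  W <- scenario$roi_width_um
  H <- scenario$roi_height_um
  area_mm2 <- W * H / 1e6
  g <- case$growth_rate_pct_per_year
  marker_names <- unique(unlist(lapply(scenario$populations,
                                       function(p) names(p$mean_expr))))
  pts <- with_seed(seed, {
    pts <- list()
    # pass 1: point-placed populations
    for (p in scenario$populations) {
      lambda <- max(0, p$intensity_per_mm2 + scenario$growth_effect[[p$name]] * g)
      if (p$process == "poisson") {
        n <- stats::rpois(1, lambda * area_mm2)
        pts[[p$name]] <- cbind(x = stats::runif(n, 0, W),
                               y = stats::runif(n, 0, H))
      } else if (p$process == "thomas") {
        parent_rate <- lambda / p$thomas_mean_offspring
        n_par <- stats::rpois(1, parent_rate * area_mm2)
        px <- stats::runif(n_par, 0, W)
        py <- stats::runif(n_par, 0, H)
        n_off <- stats::rpois(n_par, p$thomas_mean_offspring)
        x <- rep(px, n_off) + stats::rnorm(sum(n_off), 0, p$thomas_sigma_um)
        y <- rep(py, n_off) + stats::rnorm(sum(n_off), 0, p$thomas_sigma_um)
        keep <- x >= 0 & x <= W & y >= 0 & y <= H
        pts[[p$name]] <- cbind(x = x[keep], y = y[keep])
      }
    }
    # pass 2: linked populations attach to realised partner points
    for (p in scenario$populations) {
      if (p$process != "linked") next
      partner <- pts[[p$link_partner]]
      lambda <- max(0, p$intensity_per_mm2 + scenario$growth_effect[[p$name]] * g)
      if (is.null(partner) || nrow(partner) == 0) {
        warnf("simulate_roi: link partner '%s' empty in %s; '%s' left empty",
              p$link_partner, roi_id, p$name)
        pts[[p$name]] <- cbind(x = numeric(), y = numeric())
        next
      }
      n <- stats::rpois(1, lambda * area_mm2)
      anchor <- partner[sample.int(nrow(partner), n, replace = TRUE), ,
                        drop = FALSE]
      x <- anchor[, "x"] + stats::rnorm(n, 0, p$link_sigma_um)
      y <- anchor[, "y"] + stats::rnorm(n, 0, p$link_sigma_um)
      keep <- x >= 0 & x <= W & y >= 0 & y <= H
      pts[[p$name]] <- cbind(x = x[keep], y = y[keep])
    }
    # order as declared, then draw expression
    pts <- pts[names(scenario$populations)]
    for (nm in names(pts)) {
      n <- nrow(pts[[nm]])
      expr <- draw_expression(n, scenario$populations[[nm]], marker_names)
      pts[[nm]] <- list(xy = pts[[nm]], expr = expr)
    }
    pts
  })
  n_tot <- sum(vapply(pts, function(p) nrow(p$xy), 0L))
  pop_of <- rep(names(pts), vapply(pts, function(p) nrow(p$xy), 0L))
  xy <- do.call(rbind, lapply(pts, `[[`, "xy"))
  expr <- do.call(rbind, lapply(pts, `[[`, "expr"))
  geom <- roi_geometry(roi_id, case$case_id, W, H)
  cells <- data.frame(cell_id = sprintf("%s_c%05d", roi_id, seq_len(n_tot)),
                      case_id = case$case_id, roi_id = roi_id,
                      x_um = if (n_tot) xy[, "x"] else numeric(),
                      y_um = if (n_tot) xy[, "y"] else numeric(),
                      stringsAsFactors = FALSE)
  for (m in marker_names) cells[[m]] <- if (n_tot) expr[, m] else numeric()
  panel <- panel_def(marker_names)
  hier <- vapply(scenario$populations, `[[`, "", "hierarchy")
  truth <- data.frame(roi_id = cells$roi_id, cell_id = cells$cell_id,
                      true_population = pop_of,
                      true_hierarchy = unname(hier[pop_of]),
                      stringsAsFactors = FALSE)
  list(cells = cell_table(cells, panel, geom), geometry = geom, truth = truth)
}

#' Simulate a full cohort
#'
#' Generates case metadata, then simulates `rois_per_case` ROIs per case
#' with per-ROI seeds derived from the scenario seed, so the output is
#' deterministic given the scenario.
#'
#' @param scenario a [scenario_config()].
#' @return A list with `cells` (a pooled `cell_table`), `metadata`
#'   (`case_metadata`), `geometry` (`roi_geometry`) and `truth` (per-cell
#'   ground truth with per-case planted slopes in the
#'   `"growth_effect"` attribute).
#' @export
simulate_cohort <- function(scenario) {
  md <- generate_case_metadata(scenario$n_static, scenario$n_growing,
                               seed = scenario$seed)
  rois <- list()
  for (i in seq_len(nrow(md))) {
    for (r in seq_len(scenario$rois_per_case)) {
      roi_id <- sprintf("%s_roi%d", md$case_id[i], r)
      rois[[roi_id]] <- simulate_roi(scenario, md[i, ], roi_id,
                                     seed = derive_seed(scenario$seed, roi_id))
    }
  }
  geom_df <- do.call(rbind, lapply(rois, function(r) as.data.frame(r$geometry)))
  geometry <- roi_geometry(geom_df$roi_id, geom_df$case_id, geom_df$width_um,
                           geom_df$height_um)
  cells_df <- do.call(rbind, lapply(rois, function(r) as.data.frame(r$cells)))
  rownames(cells_df) <- NULL
  marker_names <- attr(rois[[1]]$cells, "markers")
  cells <- cell_table(cells_df, panel_def(marker_names), geometry)
  truth <- do.call(rbind, lapply(rois, `[[`, "truth"))
  rownames(truth) <- NULL
  attr(truth, "growth_effect") <- scenario$growth_effect
  list(cells = cells, metadata = md, geometry = geometry, truth = truth)
}

#' Plant a mosaic of neighbourhood domains in one ROI
#'
#' Tiles a rectangular ROI into `K` contiguous Voronoi domains (seeded by
#' `K` uniform centres) and fills each domain with cells whose population
#' labels are drawn from that domain's composition vector. Used to test
#' whether neighbourhood clustering recovers spatial domains of known
#' composition.
#'
#' @param K number of domains (>= 1).
#' @param compositions K x P matrix (rows sum to 1, column names are
#'   population names): per-domain population composition.
#' @param width_um,height_um ROI window.
#' @param intensity_per_mm2 total cell intensity (default 2000 cells per
#'   mm^2, a typical segmented-cell density for IMC tissue).
#' @param min_centre_sep_um minimum pairwise separation of the domain
#'   centres (rejection-sampled; default 0 = fully random). Recovery
#'   experiments use a positive separation so every planted domain is
#'   large enough to be identifiable.
#' @param seed integer seed.
#' @return A list with `cells` (data frame: `cell_id`, `x_um`, `y_um`,
#'   `population_label`) and `truth` (data frame with the planted
#'   `domain` per cell and the domain centres as an attribute).
#' @export
plant_neighbourhood_mosaic <- function(K, compositions, width_um = 1000,
                                       height_um = 1000,
                                       intensity_per_mm2 = 2000,
                                       min_centre_sep_um = 0, seed = 1L) {
  stopifnot(K >= 1)
  compositions <- as.matrix(compositions)
  if (nrow(compositions) != K) stopf("compositions must have K rows")
  if (is.null(colnames(compositions))) stopf("compositions needs population column names")
  if (any(compositions < 0) || any(rowSums(compositions) == 0))
    stopf("each domain composition must be non-negative with positive sum")
  if (any(abs(rowSums(compositions) - 1) > 1e-6))
    stopf("each composition row must sum to 1")
  with_seed(seed, {
    cx <- stats::runif(K, 0, width_um)
    cy <- stats::runif(K, 0, height_um)
    if (min_centre_sep_um > 0 && K > 1) {
      for (try in seq_len(500)) {
        if (min(stats::dist(cbind(cx, cy))) >= min_centre_sep_um) break
        cx <- stats::runif(K, 0, width_um)
        cy <- stats::runif(K, 0, height_um)
      }
    }
    n <- stats::rpois(1, intensity_per_mm2 * width_um * height_um / 1e6)
    x <- stats::runif(n, 0, width_um)
    y <- stats::runif(n, 0, height_um)
    d2 <- outer(x, cx, function(a, b) (a - b)^2) +
      outer(y, cy, function(a, b) (a - b)^2)
    domain <- max.col(-d2, ties.method = "first")
    pop <- character(n)
    for (k in seq_len(K)) {
      idx <- which(domain == k)
      pop[idx] <- sample(colnames(compositions), length(idx), replace = TRUE,
                         prob = compositions[k, ])
    }
    cells <- data.frame(cell_id = sprintf("m_c%05d", seq_len(n)),
                        x_um = x, y_um = y, population_label = pop,
                        stringsAsFactors = FALSE)
    truth <- data.frame(cell_id = cells$cell_id, domain = domain,
                        stringsAsFactors = FALSE)
    attr(truth, "centres") <- cbind(x = cx, y = cy)
    list(cells = cells, truth = truth)
  })
}

#' The default simulated tumour micro-environment scenario
#'
#' A nine-case cohort (four static, five growing; six 1 x 1 mm ROIs per
#' case) with populations emulating the cellular landscape the package
#' targets: spatially clustered Schwann (neoplastic) cells, clustered
#' alternatively activated TAMs whose density rises with growth rate,
#' CSR classically activated TAMs, effector-memory T cells linked to
#' alt-act TAMs, clustered vasculature, and a CSR proliferative fraction
#' whose density also rises with growth rate.
#'
#' @param seed integer master seed.
#' @param rois_per_case,roi_width_um,roi_height_um optional overrides of
#'   the cohort geometry (the defaults are the emulated study design;
#'   smaller values are useful for quick examples).
#' @param intensity_scale multiplies every population intensity, for
#'   quick smaller runs (default 1).
#' @return A `scenario_config`.
#' @export
default_scenario <- function(seed = 1L, rois_per_case = 6,
                             roi_width_um = 1000, roi_height_um = 1000,
                             intensity_scale = 1) {
  pm <- default_panel()$marker
  base <- function(...) {
    mu <- setNames(rep(0.2, length(pm)), pm)
    ov <- c(...)
    mu[names(ov)] <- ov
    mu
  }
  pops <- list(
    population_spec("Schwann", "neoplastic",
                    base(S100B = 9, PanCytokeratin = 7, Vimentin = 7, CD56 = 1),
                    process = "thomas", intensity_per_mm2 = 550 * intensity_scale,
                    thomas_mean_offspring = 40, thomas_sigma_um = 60),
    population_spec("AltActTAM", "myeloid",
                    base(CD16 = 8, CX3CR1 = 8, CD163 = 6, CD11b = 6,
                         CD68 = 6, Iba1 = 6, CD14 = 2, CD56 = 0),
                    process = "thomas", intensity_per_mm2 = 120 * intensity_scale,
                    thomas_mean_offspring = 10, thomas_sigma_um = 25),
    population_spec("ClassActTAM", "myeloid",
                    base(CD68 = 7, Iba1 = 7, CD56 = 4, CD14 = 4, `HLA-DR` = 5),
                    process = "poisson", intensity_per_mm2 = 100 * intensity_scale),
    population_spec("TEM", "lymphoid",
                    base(CD3 = 8, CD8a = 8, CD45 = 7, CD45RO = 6),
                    process = "linked", intensity_per_mm2 = 60 * intensity_scale,
                    link_partner = "AltActTAM", link_sigma_um = 10),
    population_spec("Vascular", "vascular",
                    base(SMA = 9, CD31 = 8, vWF = 6),
                    process = "thomas", intensity_per_mm2 = 70 * intensity_scale,
                    thomas_mean_offspring = 15, thomas_sigma_um = 20),
    population_spec("Proliferative", "proliferative",
                    base(`Ki-67` = 8, CD16 = 2, CX3CR1 = 2, CD163 = 1.5,
                         CD11b = 1.5),
                    process = "poisson", intensity_per_mm2 = 40 * intensity_scale)
  )
  scenario_config(pops, n_static = 4, n_growing = 5,
                  rois_per_case = rois_per_case,
                  roi_width_um = roi_width_um, roi_height_um = roi_height_um,
                  growth_effect = c(AltActTAM = 0.5 * intensity_scale,
                                    Proliferative = 0.25 * intensity_scale),
                  seed = seed)
}
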