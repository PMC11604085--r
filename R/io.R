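#' Panel definitions
#'
#' A panel definition describes the antibody panel of an IMC acquisition:
#' one row per marker with its tissue compartment and metal tag. The
#' packaged default panel (see [default_panel()]) is a 35-marker tumour
#' immune panel covering neoplastic, immune, vascular, proliferative and
#' other compartments.
#'
#' @param marker character vector of unique, non-empty marker names.
#' @param compartment compartment per marker; one of `"neoplastic"`,
#'   `"immune"`, `"vascular"`, `"proliferative"`, `"other"`.
#' @param metal_tag metal isotope tag per marker (e.g. `"Sm147"`).
#' @return A `panel_def` data frame with columns `marker`, `compartment`,
#'   `metal_tag`.
#' @export
panel_def <- function(marker, compartment = "other", metal_tag = "") {
  marker <- as.character(marker)
  compartment <- rep_len(as.character(compartment), length(marker))
  metal_tag <- rep_len(as.character(metal_tag), length(marker))
  pd <- data.frame(marker = marker, compartment = compartment,
                   metal_tag = metal_tag, stringsAsFactors = FALSE)
  validate_panel(pd)
}

panel_compartments <- c("neoplastic", "immune", "vascular", "proliferative", "other")

validate_panel <- function(pd) {
  if (nrow(pd) < 1L) stopf("panel must contain at least one marker")
  if (anyNA(pd$marker) || any(!nzchar(pd$marker)))
    stopf("marker names must be non-empty")
  if (anyDuplicated(pd$marker))
    stopf("duplicate marker name in panel: %s",
          paste(unique(pd$marker[duplicated(pd$marker)]), collapse = ", "))
  bad <- setdiff(unique(pd$compartment), panel_compartments)
  if (length(bad))
    stopf("unknown compartment(s): %s", paste(bad, collapse = ", "))
  class(pd) <- c("panel_def", "data.frame")
  pd
}

#' Read or write a panel definition
#'
#' Panels are stored as CSV with columns `marker`, `compartment`,
#' `metal_tag`.
#'
#' @param path file path.
#' @return [read_panel()] returns a `panel_def`; [write_panel()] returns
#'   `path` invisibly.
#' @export
read_panel <- function(path) {
  pd <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  need <- c("marker", "compartment", "metal_tag")
  miss <- setdiff(need, names(pd))
  if (length(miss)) stopf("panel file missing column(s): %s", paste(miss, collapse = ", "))
  validate_panel(pd[need])
}

#' @rdname read_panel
#' @param panel a `panel_def`.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The packaged 35-marker tumour immune panel
#'
#' @return A `panel_def` with 35 markers.
#' @export
default_panel <- function() {
  read_panel(system.file("extdata", "panel.csv", package = "spatialTME",
                         mustWork = TRUE))
}

#' Case metadata and growth classification
#'
#' Case-level clinical metadata for a schwannoma cohort. A tumour is
#' classified `"growing"` when its preoperative volumetric growth rate is
#' at least 20 % per year, and `"static"` (including shrinking tumours)
#' otherwise. [classify_growth()] applies that rule; constructors and
#' readers always recompute the classification from the stored growth
#' rate, so a stale `classification` column can never disagree with the
#' rate (discrepancies are reported).
#'
#' @param case_id unique case identifiers.
#' @param sex `"F"` or `"M"` per case.
#' @param age_years integer ages.
#' @param tumour_volume_cm3 non-negative tumour volumes.
#' @param growth_rate_pct_per_year volumetric growth rate, % per year.
#' @return A `case_metadata` data frame with a recomputed
#'   `classification` column.
#' @export
case_metadata <- function(case_id, sex, age_years, tumour_volume_cm3,
                          growth_rate_pct_per_year) {
  md <- data.frame(case_id = as.character(case_id),
                   sex = as.character(sex),
                   age_years = as.integer(age_years),
                   tumour_volume_cm3 = as.numeric(tumour_volume_cm3),
                   growth_rate_pct_per_year = as.numeric(growth_rate_pct_per_year),
                   stringsAsFactors = FALSE)
  md$classification <- classify_growth(md$growth_rate_pct_per_year)
  validate_case_metadata(md)
}

#' @rdname case_metadata
#' @param rate numeric growth rate(s), % volume change per year.
#' @param threshold classification threshold, default 20 % per year.
#' @export
classify_growth <- function(rate, threshold = 20) {
  ifelse(rate >= threshold, "growing", "static")
}

validate_case_metadata <- function(md) {
  if (anyDuplicated(md$case_id))
    stopf("duplicate case_id: %s",
          paste(unique(md$case_id[duplicated(md$case_id)]), collapse = ", "))
  if (any(!md$sex %in% c("F", "M"))) stopf("sex must be 'F' or 'M'")
  if (any(md$tumour_volume_cm3 < 0)) stopf("tumour_volume_cm3 must be non-negative")
  stopifnot(identical(md$classification,
                      classify_growth(md$growth_rate_pct_per_year)))
  class(md) <- c("case_metadata", "data.frame")
  md
}

#' Read or write case metadata
#'
#' CSV with columns `case_id`, `sex`, `age_years`, `tumour_volume_cm3`,
#' `growth_rate_pct_per_year` and optionally `classification`. Any stored
#' classification is recomputed from the >= 20 %/yr rule; rows whose
#' stored label disagrees are reported with a message.
#'
#' @param path file path.
#' @return [read_case_metadata()] returns a `case_metadata` data frame.
#' @export
read_case_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("case_id", "sex", "age_years", "tumour_volume_cm3",
            "growth_rate_pct_per_year")
  miss <- setdiff(need, names(md))
  if (length(miss)) stopf("case metadata missing column(s): %s",
                          paste(miss, collapse = ", "))
  recomputed <- classify_growth(md$growth_rate_pct_per_year)
  if ("classification" %in% names(md)) {
    bad <- which(md$classification != recomputed)
    if (length(bad))
      message(sprintf("read_case_metadata: reclassified %d case(s) from the stored label: %s",
                      length(bad), paste(md$case_id[bad], collapse = ", ")))
  }
  out <- case_metadata(md$case_id, md$sex, md$age_years, md$tumour_volume_cm3,
                       md$growth_rate_pct_per_year)
  out
}

#' @rdname read_case_metadata
#' @param metadata a `case_metadata` data frame.
#' @export
write_case_metadata <- function(metadata, path) {
  utils::write.csv(as.data.frame(metadata), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The packaged nine-case cohort metadata
#'
#' Clinical metadata of the nine-case schwannoma cohort (four static, five
#' growing by the 20 %/yr rule) used throughout the examples.
#'
#' @return A `case_metadata` data frame with nine rows.
#' @export
default_case_metadata <- function() {
  read_case_metadata(system.file("extdata", "cases.csv", package = "spatialTME",
                                 mustWork = TRUE))
}

#' ROI geometry
#'
#' Regions of interest (ROIs) are rectangular imaging fields. Geometry is
#' supplied explicitly rather than inferred from cell coordinates, so that
#' sparse tissue edges do not bias per-mm^2 densities. Coordinates are
#' continuous micrometres with the origin at the ROI top-left corner and y
#' increasing downward (image convention).
#'
#' @param roi_id unique ROI identifiers.
#' @param case_id parent case per ROI.
#' @param width_um,height_um positive ROI dimensions in micrometres.
#' @return A `roi_geometry` data frame with a derived `area_mm2` column.
#' @export
roi_geometry <- function(roi_id, case_id, width_um, height_um) {
  g <- data.frame(roi_id = as.character(roi_id),
                  case_id = as.character(case_id),
                  width_um = as.numeric(width_um),
                  height_um = as.numeric(height_um),
                  stringsAsFactors = FALSE)
  if (any(g$width_um <= 0) || any(g$height_um <= 0))
    stopf("ROI dimensions must be positive")
  if (anyDuplicated(g$roi_id)) stopf("duplicate roi_id")
  g$area_mm2 <- g$width_um * g$height_um / 1e6
  class(g) <- c("roi_geometry", "data.frame")
  g
}

#' @rdname roi_geometry
#' @param path file path; CSV with columns `roi_id`, `case_id`,
#'   `width_um`, `height_um`.
#' @export
read_roi_geometry <- function(path) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("roi_id", "case_id", "width_um", "height_um")
  miss <- setdiff(need, names(g))
  if (length(miss)) stopf("geometry file missing column(s): %s",
                          paste(miss, collapse = ", "))
  roi_geometry(g$roi_id, g$case_id, g$width_um, g$height_um)
}

#' @rdname roi_geometry
#' @param geometry a `roi_geometry` data frame.
#' @export
write_roi_geometry <- function(geometry, path) {
  utils::write.csv(as.data.frame(geometry)[c("roi_id", "case_id", "width_um",
                                             "height_um")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Cell tables
#'
#' The central data structure: one row per segmented cell with case/ROI
#' identifiers, centroid coordinates in micrometres, raw mean marker
#' intensities (one column per panel marker), optional normalised
#' intensities (`norm_<marker>` columns in [0, 1]) and optional phenotype
#' label columns (`hierarchy_label`, `population_label`,
#' `subpopulation_label`, `nbhd_label`).
#'
#' @param cells a data frame with columns `cell_id`, `case_id`, `roi_id`,
#'   `x_um`, `y_um` and one numeric column per marker in `panel`.
#' @param panel a `panel_def`; every panel marker must have a column.
#' @param geometry a `roi_geometry` covering every `roi_id`; rows whose
#'   coordinates fall outside their ROI window are dropped with a message
#'   and recorded in the `"rejected"` attribute.
#' @return A `cell_table` data frame.
#' @export
cell_table <- function(cells, panel, geometry) {
  need <- c("cell_id", "case_id", "roi_id", "x_um", "y_um")
  miss <- setdiff(need, names(cells))
  if (length(miss)) stopf("cell table missing column(s): %s",
                          paste(miss, collapse = ", "))
  miss_m <- setdiff(panel$marker, names(cells))
  if (length(miss_m)) stopf("cell table missing marker column(s): %s",
                            paste(miss_m, collapse = ", "))
  cells$cell_id <- as.character(cells$cell_id)
  cells$case_id <- as.character(cells$case_id)
  cells$roi_id <- as.character(cells$roi_id)
  unknown_roi <- setdiff(unique(cells$roi_id), geometry$roi_id)
  if (length(unknown_roi)) stopf("roi_id without geometry: %s",
                                 paste(unknown_roi, collapse = ", "))
  for (m in panel$marker) {
    if (!is.numeric(cells[[m]])) stopf("marker column '%s' is not numeric", m)
    if (any(cells[[m]] < 0, na.rm = TRUE)) stopf("negative raw intensity in '%s'", m)
  }
  key <- paste(cells$roi_id, cells$cell_id)
  if (anyDuplicated(key)) stopf("duplicate (roi_id, cell_id) pair")
  gi <- match(cells$roi_id, geometry$roi_id)
  ok <- cells$x_um >= 0 & cells$x_um <= geometry$width_um[gi] &
    cells$y_um >= 0 & cells$y_um <= geometry$height_um[gi]
  rejected <- cells[!ok, , drop = FALSE]
  if (nrow(rejected))
    message(sprintf("cell_table: rejected %d cell(s) with out-of-window coordinates",
                    nrow(rejected)))
  cells <- cells[ok, , drop = FALSE]
  rownames(cells) <- NULL
  norm_cols <- grep("^norm_", names(cells), value = TRUE)
  for (nc in norm_cols) {
    v <- cells[[nc]]
    if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
      stopf("normalised column '%s' outside [0, 1]", nc)
  }
  structure(cells,
            markers = panel$marker,
            rejected = rejected,
            class = c("cell_table", "data.frame"))
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells, %d ROIs, %d cases, %d markers\n",
              nrow(x), length(unique(x$roi_id)), length(unique(x$case_id)),
              length(attr(x, "markers"))))
  labs <- intersect(c("hierarchy_label", "population_label",
                      "subpopulation_label", "nbhd_label"), names(x))
  if (length(labs)) cat("labels:", paste(labs, collapse = ", "), "\n")
  invisible(x)
}

#' Marker names of a cell table
#' @param table a `cell_table`.
#' @export
markers <- function(table) attr(table, "markers")

#' Read or write a cell table
#'
#' Cell tables are stored as UTF-8 CSV with a header row naming the
#' identifier, coordinate and marker columns. Reading validates against
#' the panel and ROI geometry; out-of-window rows are rejected with a
#' report (see [cell_table()]).
#'
#' @param path file path.
#' @param panel a `panel_def`.
#' @param geometry a `roi_geometry`.
#' @return [read_cell_table()] returns a `cell_table`.
#' @export
read_cell_table <- function(path, panel, geometry) {
  cells <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cell_table(cells, panel, geometry)
}

#' @rdname read_cell_table
#' @param table a `cell_table`.
#' @export
write_cell_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Extract a cell table from an image stack and label mask
#'
#' Given a multichannel intensity stack (channels x rows x cols) and an
#' integer label mask from nuclear segmentation (one positive label per
#' cell, 0 = background), computes per-cell mean intensity of every
#' channel under the cell's label and the centroid of the label's pixels.
#' Pixel centres sit at (col - 0.5, row - 0.5) pixels from the image
#' origin, scaled by `pixel_size_um`.
#'
#' @param image_stack numeric array `c(channels, rows, cols)`.
#' @param label_mask integer matrix `rows x cols`.
#' @param panel a `panel_def` with one marker per channel, in channel order.
#' @param pixel_size_um positive pixel edge length in micrometres
#'   (IMC acquisitions are typically 1 um).
#' @param case_id,roi_id identifiers stamped on the extracted cells.
#' @return A `cell_table` with one row per nonzero label.
#' @export
extract_cell_table <- function(image_stack, label_mask, panel,
                               pixel_size_um = 1, case_id = "case1",
                               roi_id = "roi1") {
  d <- dim(image_stack)
  if (length(d) != 3L) stopf("image_stack must be a 3-D array (channels x rows x cols)")
  if (!all(dim(label_mask) == d[2:3]))
    stopf("label_mask dimensions (%s) do not match image spatial dimensions (%s)",
          paste(dim(label_mask), collapse = "x"), paste(d[2:3], collapse = "x"))
  if (d[1] != nrow(panel))
    stopf("channel count (%d) does not equal panel size (%d)", d[1], nrow(panel))
  if (pixel_size_um <= 0) stopf("pixel_size_um must be positive")
  geom <- roi_geometry(roi_id, case_id,
                       width_um = d[3] * pixel_size_um,
                       height_um = d[2] * pixel_size_um)
  labs <- sort(unique(as.vector(label_mask)))
  labs <- labs[labs > 0]
  if (!length(labs)) {
    warnf("extract_cell_table: label mask contains no cells")
    empty <- data.frame(cell_id = character(), case_id = character(),
                        roi_id = character(), x_um = numeric(), y_um = numeric())
    for (m in panel$marker) empty[[m]] <- numeric()
    return(cell_table(empty, panel, geom))
  }
  lab_vec <- as.vector(label_mask)             # column-major over rows x cols
  idx <- which(lab_vec > 0)
  f <- factor(lab_vec[idx], levels = labs)
  rows <- (idx - 1) %% d[2] + 1
  cols <- (idx - 1) %/% d[2] + 1
  x_um <- (tapply(cols, f, mean) - 0.5) * pixel_size_um
  y_um <- (tapply(rows, f, mean) - 0.5) * pixel_size_um
  cells <- data.frame(cell_id = paste0("c", labs), case_id = case_id,
                      roi_id = roi_id, x_um = as.numeric(x_um),
                      y_um = as.numeric(y_um), stringsAsFactors = FALSE)
  for (ch in seq_len(d[1])) {
    chan <- as.vector(image_stack[ch, , ])
    cells[[panel$marker[ch]]] <- as.numeric(tapply(chan[idx], f, mean))
  }
  cell_table(cells, panel, geom)
}

#' Read a multichannel TIFF stack and label mask
#'
#' Thin wrappers over the `tiff` package returning arrays in the layout
#' [extract_cell_table()] expects.
#'
#' @param path TIFF file path.
#' @return `read_image_stack()` returns a channels x rows x cols array;
#'   `read_label_mask()` an integer matrix.
#' @export
read_image_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("the 'tiff' package is required to read TIFF stacks")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
  arr
}

#' @rdname read_image_stack
#' @export
read_label_mask <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stopf("the 'tiff' package is required to read TIFF masks")
  m <- tiff::readTIFF(path, as.is = TRUE)
  storage.mode(m) <- "integer"
  m
}
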