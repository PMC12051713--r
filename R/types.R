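#' Construct a cell table
#'
#' A cell table holds one row per detected nucleus: planar coordinates and
#' the clonal population the cell was classified into. Coordinates are
#' continuous planar positions, in pixels by default; apply a
#' microns-per-pixel factor at read time (see [read_detections()]) to work
#' in physical units.
#'
#' @param x,y Numeric coordinates; must be finite.
#' @param population Character vector of population labels. Canonically the
#'   six barcode classes (`"red"`, `"green"`, `"blue"`, `"orange"`,
#'   `"purple"`, `"cyan"`) but any non-empty strings are accepted.
#' @param cell_id Optional identifiers, unique within the table; generated
#'   (`"cell_00001"`, ...) when omitted. Used as the deterministic
#'   tie-break in the neighbor-order metric.
#' @return A `data.frame` of class `cell_table` with columns `cell_id`,
#'   `x`, `y`, `population`.
#' @examples
#' cell_table(x = c(0, 3), y = c(0, 4), population = c("red", "green"))
#' @export
cell_table <- function(x, y, population, cell_id = NULL) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  population <- as.character(population)
  n <- length(x)
  if (length(y) != n || length(population) != n)
    stop("x, y and population must have equal length", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("coordinates must be finite", call. = FALSE)
  if (any(is.na(population) | !nzchar(population)))
    stop("population labels must be non-empty strings", call. = FALSE)
  if (is.null(cell_id))
    cell_id <- sprintf("cell_%05d", seq_len(n))
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id))
    stop("cell_id values must be unique within a table", call. = FALSE)
  out <- data.frame(cell_id = cell_id, x = x, y = y,
                    population = population, stringsAsFactors = FALSE)
  class(out) <- c("cell_table", "data.frame")
  out
}

#' @export
print.cell_table <- function(x, ...) {
  cat(sprintf("<cell_table> %d cells, %d populations (%s)\n",
              nrow(x), length(unique(x$population)),
              paste(sort(unique(x$population)), collapse = ", ")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' Construct a label image
#'
#' A 2D raster of non-negative integer clonal labels; 0 is reserved for
#' background. Pixels are indexed `[row, column]` and distances are taken
#' between pixel centers.
#'
#' @param pixels Integer matrix of labels, 0 = background.
#' @param label_map Named character vector mapping label integers (names)
#'   to population names (values). Defaults to the identity mapping of the
#'   nonzero labels present.
#' @param pixel_size Optional physical units per pixel; when set, distances
#'   from [pixel_dispersal_score()] are reported in those units.
#' @return A list of class `label_image` with elements `pixels`,
#'   `label_map`, `pixel_size`.
#' @examples
#' label_image(matrix(c(1L, 2L, 2L, 1L), 2, 2))
#' @export
label_image <- function(pixels, label_map = NULL, pixel_size = NULL) {
  if (!is.matrix(pixels))
    stop("pixels must be a 2D matrix", call. = FALSE)
  storage.mode(pixels) <- "integer"
  if (any(is.na(pixels)) || any(pixels < 0L))
    stop("pixel labels must be non-negative integers", call. = FALSE)
  present <- sort(unique(pixels[pixels > 0L]))
  if (is.null(label_map)) {
    label_map <- stats::setNames(as.character(present), as.character(present))
  } else {
    label_map <- stats::setNames(as.character(label_map), names(label_map))
    missing_lab <- setdiff(as.character(present), names(label_map))
    if (length(missing_lab))
      stop("labels present in pixels but absent from label_map: ",
           paste(missing_lab, collapse = ", "), call. = FALSE)
  }
  structure(list(pixels = pixels, label_map = label_map,
                 pixel_size = pixel_size),
            class = "label_image")
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("<label_image> %d x %d pixels, %d populations, %.1f%% background\n",
              nrow(x$pixels), ncol(x$pixels), length(x$label_map),
              100 * mean(x$pixels == 0L)))
  invisible(x)
}

#' Construct a color map configuration
#'
#' Maps population names to 8-bit RGB triplets (for converting color-coded
#' label renders) or to classifier class-name strings. The mapping must be
#' injective: no two populations may share a color or class name.
#'
#' @param map Named list: population name -> length-3 integer RGB vector in
#'   0-255, or a single character class name.
#' @return The validated map, classed `color_map_config`.
#' @examples
#' color_map_config(list(red = c(255, 0, 0), green = c(0, 255, 0)))
#' @export
color_map_config <- function(map) {
  if (!is.list(map) || is.null(names(map)) || any(!nzchar(names(map))))
    stop("map must be a named list keyed by population name", call. = FALSE)
  keys <- vapply(map, function(v) {
    if (is.character(v) && length(v) == 1) return(v)
    if (is.numeric(v) && length(v) == 3 && all(v >= 0 & v <= 255))
      return(paste(as.integer(v), collapse = ","))
    stop("each entry must be an RGB triplet in 0-255 or a class-name string",
         call. = FALSE)
  }, character(1))
  if (anyDuplicated(keys))
    stop("color map must be injective: duplicate color/class assignments",
         call. = FALSE)
  structure(map, class = "color_map_config")
}

# Internal constructor shared by the scoring functions.
new_dispersal_result <- function(metric, per_element_d, per_population_mean,
                                 n_k, D, units, n_zero_excluded = 0L,
                                 id = NA_character_) {
  structure(list(metric = metric, per_element_d = per_element_d,
                 per_population_mean = per_population_mean,
                 N = length(per_population_mean), n_k = n_k, D = D,
                 units = units, n_zero_excluded = n_zero_excluded, id = id),
            class = "dispersal_result")
}

#' @export
print.dispersal_result <- function(x, ...) {
  cat(sprintf("<dispersal_result> metric=%s  D=%.6g  [%s]\n",
              x$metric, x$D, x$units))
  cat(sprintf("  N=%d populations; per-population mean d:\n", x$N))
  print(round(x$per_population_mean, 4))
  if (x$n_zero_excluded > 0)
    cat(sprintf("  (%d zero-distance elements excluded)\n", x$n_zero_excluded))
  invisible(x)
}

#' Construct an expression matrix
#'
#' Genes-by-samples expression values (assumed already normalized /
#' log-scale), optionally paired with a per-sample clonal dispersal score.
#'
#' @param values Numeric matrix, genes as rows and samples as columns; both
#'   dimensions must be named.
#' @param sample_scores Optional numeric vector of dispersal scores, one
#'   per sample (recycled names checked against column names when named).
#' @return A list of class `expression_matrix`.
#' @export
expression_matrix <- function(values, sample_scores = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene (row) and sample (column) names",
         call. = FALSE)
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("gene and sample names must be unique", call. = FALSE)
  if (!is.null(sample_scores)) {
    if (length(sample_scores) != ncol(values))
      stop("sample_scores must have one value per sample", call. = FALSE)
    if (!is.null(names(sample_scores)) &&
        !identical(names(sample_scores), colnames(values)))
      stop("sample_scores names disagree with sample names", call. = FALSE)
    sample_scores <- stats::setNames(as.numeric(sample_scores),
                                     colnames(values))
  }
  structure(list(values = values, sample_scores = sample_scores),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$sample_scores)) "" else " (with dispersal scores)"))
  invisible(x)
}

#' Construct a survival table
#'
#' @param time Positive follow-up times.
#' @param event Event indicator, 1 = event observed, 0 = censored.
#' @param group Group label per subject.
#' @return A `data.frame` of class `survival_table` with columns `time`,
#'   `event`, `group`.
#' @export
survival_table <- function(time, event, group) {
  time <- as.numeric(time)
  event <- as.integer(event)
  group <- as.character(group)
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be positive and finite", call. = FALSE)
  if (any(!event %in% c(0L, 1L)))
    stop("event must be 0 (censored) or 1 (event)", call. = FALSE)
  if (length(event) != length(time) || length(group) != length(time))
    stop("time, event and group must have equal length", call. = FALSE)
  out <- data.frame(time = time, event = event, group = group,
                    stringsAsFactors = FALSE)
  class(out) <- c("survival_table", "data.frame")
  out
}
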