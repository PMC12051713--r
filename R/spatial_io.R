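#' Read a nucleus detection table
#'
#' Parses a delimited detection export (one row per nucleus with centroid
#' coordinates and a classified clonal population) into a [cell_table()].
#' Default column names follow common detection-export conventions
#' (`"Centroid X"`, `"Centroid Y"`, `"Class"`) and are fully overridable.
#' Rows whose class equals `background_class` are dropped; the count of
#' dropped rows is attached as attribute `"n_dropped"` and reported via
#' `message()`.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_spec Named list with entries `x`, `y`, `class` and
#'   optionally `id`, giving the column names to use.
#' @param delimiter Field delimiter; by default inferred from the file
#'   extension (`.csv` = comma, otherwise tab).
#' @param background_class Class value marking non-cell detections to drop
#'   (`NULL` = keep everything).
#' @param scale Multiplier applied to coordinates on load (e.g.
#'   microns-per-pixel to express positions in physical units, making
#'   scores comparable across magnifications).
#' @return A [cell_table()]; attribute `"n_dropped"` holds the number of
#'   background rows removed.
#' @export
read_detections <- function(path,
                            column_spec = list(x = "Centroid X",
                                               y = "Centroid Y",
                                               class = "Class"),
                            delimiter = NULL,
                            background_class = NULL,
                            scale = 1) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.delim(path, sep = delimiter, check.names = FALSE,
                          stringsAsFactors = FALSE)
  for (role in c("x", "y", "class")) {
    cn <- column_spec[[role]]
    if (is.null(cn))
      stop("column_spec is missing the '", role, "' entry", call. = FALSE)
    if (!cn %in% names(df))
      stop("configured ", role, " column '", cn, "' not found in ", path,
           call. = FALSE)
  }
  xs <- suppressWarnings(as.numeric(df[[column_spec$x]]))
  ys <- suppressWarnings(as.numeric(df[[column_spec$y]]))
  bad <- which(is.na(xs) | is.na(ys))
  if (length(bad))
    stop("non-numeric coordinate in row ", bad[1], " of ", path,
         call. = FALSE)
  cls <- as.character(df[[column_spec$class]])
  ids <- if (!is.null(column_spec$id)) as.character(df[[column_spec$id]])
         else sprintf("cell_%05d", seq_along(xs))
  keep <- if (is.null(background_class)) rep(TRUE, length(cls))
          else cls != background_class
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message("read_detections: dropped ", n_dropped, " background row(s)")
  ct <- cell_table(xs[keep] * scale, ys[keep] * scale, cls[keep], ids[keep])
  attr(ct, "n_dropped") <- n_dropped
  ct
}

#' Write a cell table as a detection export
#'
#' Inverse of [read_detections()]: writes `cell_id`, `x`, `y`,
#' `population` columns with full numeric precision, so a write/read
#' round-trip reproduces the table exactly.
#'
#' @param cells A [cell_table()].
#' @param path Output path.
#' @param delimiter Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_detections <- function(cells, path, delimiter = "\t") {
  stopifnot(inherits(cells, "cell_table"))
  df <- as.data.frame(cells)
  df$x <- sprintf("%.17g", df$x)
  df$y <- sprintf("%.17g", df$y)
  utils::write.table(df, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a multi-label section image
#'
#' Reads a TIFF or PNG into a [label_image()]. Single-channel integer
#' images are taken as labels directly (`color_map = "integer"`). RGB
#' images are mapped to labels by exact 8-bit color match against a
#' [color_map_config()]; pixels matching no configured color become
#' background (label 0) with a warning giving the count.
#'
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param color_map `"integer"` or a [color_map_config()] of RGB triplets;
#'   populations are assigned labels 1, 2, ... in the order of the map.
#' @param pixel_size Optional physical units per pixel, stored on the
#'   result.
#' @return A [label_image()].
#' @export
read_label_image <- function(path, color_map = "integer",
                             pixel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  is_png <- grepl("\\.png$", path, ignore.case = TRUE)
  if (is_png) {
    img <- png::readPNG(path, info = TRUE)
    if (is.matrix(img)) {
      depth <- attr(img, "info")$bit.depth
      if (is.null(depth)) depth <- 8L
      img <- round(img * (2^depth - 1))
    }
    attr(img, "info") <- NULL
  } else {
    img <- tiff::readTIFF(path, as.is = TRUE)
    attr(img, "info") <- NULL
  }
  if (length(dim(img)) == 3 && !dim(img)[3] %in% c(3L, 4L))
    stop("unsupported dimensionality: expected 2D labels or RGB, got ",
         paste(dim(img), collapse = "x"), call. = FALSE)
  if (length(dim(img)) > 3)
    stop("unsupported dimensionality: 3D stacks are not supported",
         call. = FALSE)

  if (identical(color_map, "integer")) {
    if (!is.matrix(img))
      stop("color_map = \"integer\" requires a single-channel image",
           call. = FALSE)
    return(label_image(img, pixel_size = pixel_size))
  }
  stopifnot(inherits(color_map, "color_map_config"))
  if (is.matrix(img))
    stop("an RGB color_map was given but the image is single-channel",
         call. = FALSE)
  rgb <- img[, , 1:3, drop = FALSE]
  if (max(rgb) <= 1) rgb <- round(rgb * 255)
  key <- matrix(paste(rgb[, , 1], rgb[, , 2], rgb[, , 3], sep = ","),
                nrow = dim(img)[1])
  pops <- names(color_map)
  wanted <- vapply(color_map, function(v)
    paste(as.integer(v), collapse = ","), character(1))
  px <- matrix(0L, nrow(key), ncol(key))
  for (k in seq_along(pops)) px[key == wanted[k]] <- k
  n_unmapped <- sum(px == 0L & key != "0,0,0")
  if (n_unmapped > 0)
    warning(n_unmapped,
            " pixel(s) matched no configured color; labeled as background",
            call. = FALSE)
  label_image(px, stats::setNames(pops, as.character(seq_along(pops))),
              pixel_size = pixel_size)
}

#' Write a label image
#'
#' Writes the label raster as a 16-bit grayscale TIFF (or PNG), preserving
#' integer labels exactly so that [read_label_image()] round-trips.
#'
#' @param image A [label_image()] with labels below 65536.
#' @param path Output path ending in `.tif`/`.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_label_image <- function(image, path) {
  stopifnot(inherits(image, "label_image"))
  if (max(image$pixels) > 65535L)
    stop("labels exceed 16-bit range", call. = FALSE)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (max(image$pixels) > 255L)
      stop("PNG output supports labels up to 255; use TIFF", call. = FALSE)
    png::writePNG(image$pixels / 255, path)
  } else {
    tiff::writeTIFF(image$pixels / 65535, path, bits.per.sample = 16L,
                    compression = "none")
  }
  invisible(path)
}

#' Write a Dispersal Score report
#'
#' One CSV row per scored image/well: identifier, metric, number of
#' populations, per-population mean distances (packed as
#' `pop=value;pop=value` at full precision) and the score D. Output is
#' bit-stable given identical inputs.
#'
#' @param results A single `dispersal_result` or a list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_score_report()]
#' @export
write_score_report <- function(results, path) {
  if (inherits(results, "dispersal_result")) results <- list(results)
  stopifnot(all(vapply(results, inherits, logical(1), "dispersal_result")))
  rows <- lapply(results, function(r) {
    data.frame(
      id = r$id, metric = r$metric, n_populations = r$N,
      population_means = paste(sprintf("%s=%.17g",
                                       names(r$per_population_mean),
                                       r$per_population_mean),
                               collapse = ";"),
      D = sprintf("%.17g", r$D), units = r$units,
      stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), metric = character(0),
               n_populations = integer(0), population_means = character(0),
               D = character(0), units = character(0))
  ok <- tryCatch({
    utils::write.table(df, path, sep = ",", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write report to ", path, ": ",
                        conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Read back a Dispersal Score report
#'
#' Parses a file written by [write_score_report()] into a data frame with
#' numeric `D` and a list-column `population_means` of named numeric
#' vectors.
#'
#' @param path Report path.
#' @return A `data.frame`.
#' @export
read_score_report <- function(path) {
  df <- utils::read.delim(path, sep = ",", stringsAsFactors = FALSE)
  df$D <- as.numeric(df$D)
  df$population_means <- lapply(df$population_means, function(s) {
    if (is.na(s) || !nzchar(s)) return(stats::setNames(numeric(0), character(0)))
    parts <- strsplit(strsplit(s, ";")[[1]], "=", fixed = TRUE)
    stats::setNames(as.numeric(vapply(parts, `[`, "", 2)),
                    vapply(parts, `[`, "", 1))
  })
  df
}
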