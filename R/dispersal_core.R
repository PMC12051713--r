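#' Minimum cross-population distance per cell
#'
#' For each cell \eqn{i} in population \eqn{P_k}, returns
#' \eqn{d(x_i, P_k) = \min_{l \neq k} d(x_i, x_j)} over all cells \eqn{j}
#' belonging to a population other than \eqn{P_k}: the least Euclidean
#' distance to a neighbor from a different clonal population.
#'
#' Exact duplicates of a cross-population coordinate yield a distance of 0
#' and trigger a warning; [dispersal_score()] excludes such zeros from the
#' means (the score is an inverse, so a zero cannot be absorbed).
#'
#' @param cells A [cell_table()] with at least two populations.
#' @return Numeric vector of distances, named by `cell_id`, aligned with
#'   the rows of `cells`.
#' @examples
#' ct <- cell_table(c(0, 3), c(0, 4), c("A", "B"))
#' cross_population_min_distance(ct)  # 5, 5
#' @export
cross_population_min_distance <- function(cells) {
  check_two_populations(cells)
  pop <- as.integer(factor(cells$population))
  d <- min_cross_dist_cpp(cells$x, cells$y, pop)
  nz <- sum(d == 0)
  if (nz > 0)
    warning(sprintf("%d cell(s) coincide exactly with a cross-population cell (distance 0)",
                    nz), call. = FALSE)
  stats::setNames(d, cells$cell_id)
}

#' Nearest-neighbor order per cell
#'
#' For each cell, all other cells are sorted by ascending Euclidean
#' distance (ties broken by ascending `cell_id`); the returned value is the
#' 1-based position of the first cell whose population differs from the
#' target's. A rank of 1 means the immediate nearest neighbor already
#' belongs to another clonal population.
#'
#' @inheritParams cross_population_min_distance
#' @return Integer vector of ranks, named by `cell_id`.
#' @examples
#' ct <- cell_table(1:4, rep(0, 4), c("A", "B", "A", "B"))
#' neighbor_order_distance(ct)  # all 1
#' @export
neighbor_order_distance <- function(cells) {
  check_two_populations(cells)
  pop <- as.integer(factor(cells$population))
  tiebreak <- rank(cells$cell_id, ties.method = "first")
  r <- neighbor_order_cpp(cells$x, cells$y, pop, as.integer(tiebreak))
  stats::setNames(r, cells$cell_id)
}

check_two_populations <- function(cells) {
  stopifnot(inherits(cells, "cell_table"))
  if (length(unique(cells$population)) < 2)
    stop("dispersal requires at least 2 populations with at least 1 cell each",
         call. = FALSE)
  invisible(cells)
}

#' Aggregate per-element distances into a Dispersal Score
#'
#' Implements
#' \deqn{D = \left(\frac{1}{N} \sum_{k=1}^{N} \frac{1}{n_k}
#'   \sum_{i=1}^{n_k} d(x_i, P_k)\right)^{-1}}
#' where \eqn{N} is the number of populations and \eqn{n_k} the number of
#' scored members of population \eqn{P_k}. The inner mean is taken within
#' each population and the outer mean over populations is unweighted by
#' \eqn{n_k} — so a 1-cell population carries the same weight as a
#' 1000-cell one. A cell-weighted variant (plain mean over all elements)
#' is available via `weighting = "cell"` but is never the default.
#'
#' Zero distances (coincident cross-population points) are excluded from
#' the inner mean with a warning; populations left with no scored member
#' are excluded from \eqn{N} with a warning; if every distance is zero the
#' score is undefined and an error is raised.
#'
#' @param per_element_d Numeric vector of per-cell (or per-pixel) minimum
#'   cross-population distances or neighbor-order ranks; all finite and
#'   non-negative.
#' @param populations Population label per element, aligned with
#'   `per_element_d`.
#' @param metric Metric name recorded in the result, one of
#'   `"euclidean_cell"`, `"neighbor_order_cell"`, `"euclidean_pixel"`.
#' @param weighting `"population"` (the definition above; default) or
#'   `"cell"` (mean over all elements, ignoring population sizes).
#' @param id Optional identifier (image/well name) carried into reports.
#' @return A `dispersal_result`: list with `metric`, `per_element_d`,
#'   `per_population_mean`, `N`, `n_k`, `D`, `units`, `n_zero_excluded`.
#' @examples
#' dispersal_score(c(2, 2, 4, 4), c("A", "A", "B", "B"))$D  # 1/3
#' @export
dispersal_score <- function(per_element_d, populations,
                            metric = "euclidean_cell",
                            weighting = c("population", "cell"),
                            id = NA_character_) {
  weighting <- match.arg(weighting)
  metric <- match.arg(metric,
                      c("euclidean_cell", "neighbor_order_cell",
                        "euclidean_pixel"))
  if (length(per_element_d) != length(populations))
    stop("per_element_d and populations must be aligned", call. = FALSE)
  if (any(!is.finite(per_element_d)) || any(per_element_d < 0))
    stop("distances must be finite and non-negative", call. = FALSE)
  populations <- as.character(populations)

  zero <- per_element_d == 0
  if (all(zero))
    stop("all distances are zero: Dispersal Score undefined", call. = FALSE)
  n_zero <- sum(zero)
  if (n_zero > 0)
    warning(sprintf("excluding %d zero distance(s) from the means", n_zero),
            call. = FALSE)
  d <- per_element_d[!zero]
  p <- populations[!zero]

  dropped <- setdiff(unique(populations), unique(p))
  if (length(dropped))
    warning("population(s) with no scored member excluded from N: ",
            paste(dropped, collapse = ", "), call. = FALSE)

  per_pop <- tapply(d, p, mean)
  per_pop <- per_pop[sort(names(per_pop))]
  n_k <- tapply(d, p, length)[names(per_pop)]
  D <- if (weighting == "population") 1 / mean(per_pop) else 1 / mean(d)
  units <- if (metric == "neighbor_order_cell")
    "dimensionless (1/rank)" else "1/length"
  new_dispersal_result(metric, per_element_d, c(per_pop),
                       stats::setNames(as.integer(n_k), names(n_k)),
                       D, units, as.integer(n_zero), id)
}

#' Score a cell table
#'
#' Dispatch wrapper composing the per-cell distance stage
#' ([cross_population_min_distance()] or [neighbor_order_distance()]) with
#' [dispersal_score()].
#'
#' @inheritParams cross_population_min_distance
#' @param metric `"euclidean_cell"` (least Euclidean distance to a
#'   different population; the in vivo cell-level choice) or
#'   `"neighbor_order_cell"` (rank of the first cross-population neighbor;
#'   the in vitro choice).
#' @inheritParams dispersal_score
#' @return A `dispersal_result` (see [dispersal_score()]).
#' @examples
#' ct <- cell_table(c(0, 10), c(0, 0), c("A", "B"))
#' score_celltable(ct, "euclidean_cell")$D  # 0.1
#' @export
score_celltable <- function(cells, metric = c("euclidean_cell",
                                              "neighbor_order_cell"),
                            weighting = c("population", "cell"),
                            id = NA_character_) {
  if (length(metric) == 1 && !metric %in%
      c("euclidean_cell", "neighbor_order_cell"))
    stop("unknown metric '", metric,
         "': use \"euclidean_cell\" or \"neighbor_order_cell\"",
         call. = FALSE)
  metric <- match.arg(metric)
  d <- if (metric == "euclidean_cell")
    cross_population_min_distance(cells)
  else
    neighbor_order_distance(cells)
  dispersal_score(d, cells$population, metric = metric,
                  weighting = weighting, id = id)
}

#' Pixel-level Dispersal Score
#'
#' Applies the same minimum cross-population distance statistic to every
#' labeled pixel of a section image: for each nonzero pixel, \eqn{d} is the
#' Euclidean distance (between pixel centers, in original-image pixel units
#' or physical units when `pixel_size` is set) to the nearest pixel
#' carrying a different nonzero label. Background (label 0) is ignored both
#' as source and as target. Per-label distances are computed with an exact
#' Euclidean distance transform of the union of all other labels;
#' aggregation follows [dispersal_score()] with populations = labels.
#'
#' @param image A [label_image()] with at least two nonzero labels.
#' @param downsample Positive integer subsampling stride; the image is
#'   subsampled on a regular grid and distances are rescaled to
#'   original-image units. Default 1 (no subsampling); raise it for large
#'   section scans.
#' @inheritParams dispersal_score
#' @return A `dispersal_result` with metric `"euclidean_pixel"`;
#'   `per_element_d` is ordered by label then column-major pixel position.
#' @examples
#' img <- label_image(matrix(c(1L, 2L, 2L, 1L), 2, 2))
#' pixel_dispersal_score(img)$D  # 1
#' @export
pixel_dispersal_score <- function(image, downsample = 1L,
                                  weighting = c("population", "cell"),
                                  id = NA_character_) {
  stopifnot(inherits(image, "label_image"))
  downsample <- as.integer(downsample)
  if (length(downsample) != 1 || is.na(downsample) || downsample < 1)
    stop("downsample must be a positive integer", call. = FALSE)
  px <- image$pixels
  if (downsample > 1)
    px <- px[seq(1, nrow(px), by = downsample),
             seq(1, ncol(px), by = downsample), drop = FALSE]
  labs <- sort(unique(px[px > 0L]))
  if (length(labs) < 2)
    stop("pixel dispersal requires at least 2 nonzero labels after downsampling",
         call. = FALSE)
  scale <- as.numeric(downsample)
  if (!is.null(image$pixel_size)) scale <- scale * image$pixel_size

  d_all <- numeric(0)
  pop_all <- character(0)
  for (lab in labs) {
    # 0 where a *different* nonzero label sits; distmap then gives, for
    # every pixel, the exact Euclidean distance to the nearest such pixel.
    other0 <- matrix(1L, nrow(px), ncol(px))
    other0[px > 0L & px != lab] <- 0L
    dt <- EBImage::distmap(other0, metric = "euclidean")
    dvals <- as.numeric(dt[px == lab]) * scale
    pname <- image$label_map[as.character(lab)]
    if (is.na(pname)) pname <- as.character(lab)
    d_all <- c(d_all, dvals)
    pop_all <- c(pop_all, rep(unname(pname), length(dvals)))
  }
  dispersal_score(d_all, pop_all, metric = "euclidean_pixel",
                  weighting = weighting, id = id)
}
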