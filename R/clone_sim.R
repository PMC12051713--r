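# Canonical barcode class names used when a simulation has <= 6 populations.
BARCODE_CLASSES <- c("red", "green", "blue", "orange", "purple", "cyan")

pop_names <- function(n) {
  if (n <= length(BARCODE_CLASSES)) BARCODE_CLASSES[seq_len(n)]
  else sprintf("pop%02d", seq_len(n))
}

#' Configuration for the clonal growth simulator
#'
#' @param grid_width,grid_height Lattice dimensions in sites.
#' @param n_populations Number of barcoded populations (default 6, the
#'   canonical barcode classes).
#' @param n_initial_clones Number of founder cells, assigned to populations
#'   round-robin so the populations start in equal ratios. Default 30
#'   (five founders per population at the default six populations), enough
#'   for each color to form several colonies.
#' @param mixing_probability Per-division probability `q` that a daughter
#'   occupies a uniformly random empty site anywhere on the lattice
#'   instead of a site adjacent to its parent. `q = 0` gives compact,
#'   demarcated clonal patches; `q = 1` gives fully intermingled growth.
#' @param target_occupancy Fraction of lattice sites occupied when growth
#'   stops; default 0.75, emulating wells imaged at ~75% confluency.
#' @param seed Integer RNG seed; the simulation is a pure function of this
#'   configuration.
#' @return A validated list of class `growth_config`.
#' @export
growth_config <- function(grid_width = 64L, grid_height = 64L,
                          n_populations = 6L, n_initial_clones = 30L,
                          mixing_probability = 0,
                          target_occupancy = 0.75, seed = 1L) {
  cfg <- list(grid_width = as.integer(grid_width),
              grid_height = as.integer(grid_height),
              n_populations = as.integer(n_populations),
              n_initial_clones = as.integer(n_initial_clones),
              mixing_probability = as.numeric(mixing_probability),
              target_occupancy = as.numeric(target_occupancy),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(grid_width > 0, grid_height > 0, n_populations > 0,
              n_initial_clones > 0,
              mixing_probability >= 0, mixing_probability <= 1,
              target_occupancy > 0, target_occupancy <= 1)
    if (n_initial_clones > grid_width * grid_height)
      stop("n_initial_clones exceeds the number of lattice sites",
           call. = FALSE)
  })
  structure(cfg, class = "growth_config")
}

#' Simulate clonal growth on a lattice
#'
#' An Eden-like growth model: founders are seeded at uniformly random
#' distinct sites with populations assigned round-robin; growth then
#' repeatedly picks a random occupied site with at least one empty
#' 4-neighbor and places a same-population daughter in a random empty
#' 4-neighbor. With probability `mixing_probability` a division instead
#' takes any occupied site as parent and places the daughter at a
#' uniformly random empty site anywhere — the single knob that converts
#' demarcated colonies into intermingled growth. Growth stops at
#' `target_occupancy` (or a full grid).
#'
#' @param config A [growth_config()].
#' @return List with elements `cells` (a [cell_table()] of site centers,
#'   `x` = column, `y` = row, in placement order) and `image` (the
#'   corresponding [label_image()]).
#' @examples
#' sim <- simulate_clonal_growth(growth_config(grid_width = 16,
#'   grid_height = 16, n_initial_clones = 4, n_populations = 2, seed = 7))
#' table(sim$cells$population)
#' @export
simulate_clonal_growth <- function(config) {
  stopifnot(inherits(config, "growth_config"))
  W <- config$grid_width; H <- config$grid_height
  n_sites <- W * H
  set.seed(config$seed)
  grid <- integer(n_sites)          # column-major: site = (col-1)*H + row
  target <- max(config$n_initial_clones,
                ceiling(config$target_occupancy * n_sites))
  q <- config$mixing_probability

  seeds <- sample.int(n_sites, config$n_initial_clones)
  grid[seeds] <- rep_len(seq_len(config$n_populations),
                         config$n_initial_clones)
  occupied <- integer(min(target, n_sites))
  occupied[seq_along(seeds)] <- seeds
  n_occ <- length(seeds)
  frontier <- seeds

  empty_nbrs <- function(s) {
    row <- (s - 1L) %% H + 1L
    nb <- c(if (row > 1L) s - 1L, if (row < H) s + 1L,
            if (s > H) s - H, if (s <= n_sites - H) s + H)
    nb[grid[nb] == 0L]
  }

  while (n_occ < target && n_occ < n_sites) {
    if (q > 0 && stats::runif(1) < q) {
      parent <- occupied[sample.int(n_occ, 1L)]
      empties <- which(grid == 0L)
      site <- empties[sample.int(length(empties), 1L)]
    } else {
      site <- NA_integer_
      while (length(frontier)) {
        fi <- sample.int(length(frontier), 1L)
        en <- empty_nbrs(frontier[fi])
        if (length(en)) {
          parent <- frontier[fi]
          site <- en[sample.int(length(en), 1L)]
          break
        }
        # occupancy only increases, so a site that lost its last empty
        # neighbor never regains one: safe to drop permanently
        frontier <- frontier[-fi]
      }
      if (is.na(site)) break  # frontier exhausted <=> grid full
    }
    grid[site] <- grid[parent]
    n_occ <- n_occ + 1L
    occupied[n_occ] <- site
    frontier <- c(frontier, site)
  }

  occ <- occupied[seq_len(n_occ)]
  pops <- pop_names(config$n_populations)
  cells <- cell_table(x = (occ - 1L) %/% H + 1L,
                      y = (occ - 1L) %% H + 1L,
                      population = pops[grid[occ]],
                      cell_id = sprintf("cell_%05d", seq_len(n_occ)))
  img <- label_image(matrix(grid, nrow = H, ncol = W),
                     label_map = stats::setNames(
                       pops, as.character(seq_len(config$n_populations))))
  list(cells = cells, image = img)
}

#' Simulate a Gaussian cluster / uniform mixture point pattern
#'
#' Each population receives a Gaussian cluster center drawn uniformly in
#' the box; each cell is drawn from its population's cluster with
#' probability `1 - mixing` and from a uniform distribution over the box
#' with probability `mixing`. `mixing = 0` gives segregated clusters,
#' `mixing = 1` uniform labeling.
#'
#' @param n_per_population Cells per population.
#' @param n_populations Number of populations.
#' @param cluster_sd Gaussian cluster standard deviation.
#' @param box_size Side length of the square domain.
#' @param mixing Mixture weight in `[0, 1]` toward the uniform component.
#' @param seed Integer RNG seed.
#' @return A [cell_table()].
#' @export
simulate_point_mixture <- function(n_per_population, n_populations = 6L,
                                   cluster_sd = 5, box_size = 100,
                                   mixing = 0, seed = 1L) {
  stopifnot(n_per_population > 0, n_populations > 0, cluster_sd > 0,
            box_size > 0, mixing >= 0, mixing <= 1)
  set.seed(as.integer(seed))
  cx <- runif(n_populations, 0, box_size)
  cy <- runif(n_populations, 0, box_size)
  n <- n_per_population * n_populations
  pop_i <- rep(seq_len(n_populations), each = n_per_population)
  from_unif <- rbinom(n, 1L, mixing) == 1L
  x <- rnorm(n, cx[pop_i], cluster_sd)
  y <- rnorm(n, cy[pop_i], cluster_sd)
  x[from_unif] <- runif(sum(from_unif), 0, box_size)
  y[from_unif] <- runif(sum(from_unif), 0, box_size)
  cell_table(x, y, pop_names(n_populations)[pop_i])
}

#' Render a cell table as a label image
#'
#' Paints a filled disc of the cell's population label at each (rounded)
#' centroid; cells are drawn in ascending `cell_id` order and later discs
#' overwrite earlier ones (no anti-aliasing, so labels stay exact for
#' round-trips). `nucleus_radius = 0` paints exactly one pixel per cell.
#'
#' @param cells A [cell_table()]; coordinates must fall inside the canvas
#'   after rounding.
#' @param nucleus_radius Disc radius in pixels.
#' @param canvas_size `c(width, height)` in pixels (a scalar gives a
#'   square canvas).
#' @return A [label_image()]; populations get labels 1, 2, ... in
#'   lexicographic order.
#' @export
render_label_image <- function(cells, nucleus_radius = 0,
                               canvas_size = c(64L, 64L)) {
  stopifnot(inherits(cells, "cell_table"), nucleus_radius >= 0)
  if (length(canvas_size) == 1) canvas_size <- rep(canvas_size, 2)
  W <- as.integer(canvas_size[1]); H <- as.integer(canvas_size[2])
  col <- as.integer(round(cells$x))
  row <- as.integer(round(cells$y))
  bad <- which(col < 1L | col > W | row < 1L | row > H)
  if (length(bad))
    stop("cells outside the canvas after rounding: ",
         paste(cells$cell_id[bad], collapse = ", "), call. = FALSE)
  pops <- sort(unique(cells$population))
  lab <- match(cells$population, pops)
  r <- nucleus_radius
  off <- expand.grid(dr = -floor(r):floor(r), dc = -floor(r):floor(r))
  off <- off[off$dr^2 + off$dc^2 <= r^2, , drop = FALSE]
  px <- matrix(0L, H, W)
  ord <- order(cells$cell_id)
  for (i in ord) {
    rr <- row[i] + off$dr
    cc <- col[i] + off$dc
    keep <- rr >= 1L & rr <= H & cc >= 1L & cc <= W
    px[cbind(rr[keep], cc[keep])] <- lab[i]
  }
  label_image(px, stats::setNames(pops, as.character(seq_along(pops))))
}

#' Configuration for the expression simulator
#'
#' @param n_samples Number of samples (cell lines / tumors).
#' @param n_genes Total genes in the matrix.
#' @param planted_genes Names of the genes whose expression is constructed
#'   to correlate with the dispersal score.
#' @param effect_r Target Pearson correlation (|r| < 1) between each
#'   planted gene and the dispersal score.
#' @param noise_sd Standard deviation of the Gaussian expression noise.
#' @param background_prefix Name prefix for the non-planted (noise) genes.
#'   Two simulated screening contexts that share only their planted genes
#'   (e.g. separate in vitro and in vivo platforms) are modeled by giving
#'   each context a different prefix.
#' @param seed Integer RNG seed.
#' @return A validated list of class `expression_sim_config`.
#' @export
expression_sim_config <- function(n_samples = 13L, n_genes = 2000L,
                                  planted_genes = sprintf("planted_%02d", 1:5),
                                  effect_r = 0.9, noise_sd = 1,
                                  background_prefix = "gene",
                                  seed = 1L) {
  stopifnot(n_samples >= 3, n_genes >= length(planted_genes),
            abs(effect_r) < 1, noise_sd > 0)
  planted_genes <- as.character(planted_genes)
  if (anyDuplicated(planted_genes))
    stop("planted gene names must be unique", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_genes = as.integer(n_genes),
                 planted_genes = planted_genes,
                 effect_r = as.numeric(effect_r),
                 noise_sd = as.numeric(noise_sd),
                 background_prefix = as.character(background_prefix),
                 seed = as.integer(seed)),
            class = "expression_sim_config")
}

#' Simulate an expression matrix with planted dispersal-correlated genes
#'
#' Planted genes are built as `effect_r` times the standardized dispersal
#' score plus `sqrt(1 - effect_r^2)` times independent Gaussian noise
#' (then scaled by `noise_sd`), so their expected Pearson correlation with
#' the score is `effect_r`. All other genes are pure Gaussian noise.
#'
#' @param config An [expression_sim_config()].
#' @param dispersal_scores Numeric per-sample dispersal scores, length
#'   `config$n_samples`; must not be constant.
#' @return An [expression_matrix()] carrying `dispersal_scores` as its
#'   `sample_scores`.
#' @export
simulate_expression <- function(config, dispersal_scores) {
  stopifnot(inherits(config, "expression_sim_config"))
  if (length(dispersal_scores) != config$n_samples)
    stop("dispersal_scores must have length n_samples", call. = FALSE)
  if (sd(dispersal_scores) == 0)
    stop("dispersal_scores must not be constant", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_samples
  g <- config$n_genes
  k <- length(config$planted_genes)
  genes <- c(config$planted_genes,
             sprintf("%s_%05d", config$background_prefix, seq_len(g - k)))
  samples <- if (!is.null(names(dispersal_scores)))
    names(dispersal_scores) else sprintf("sample_%02d", seq_len(n))
  vals <- matrix(rnorm(g * n, 0, config$noise_sd), g, n,
                 dimnames = list(genes, samples))
  z <- as.numeric(scale(dispersal_scores))
  r <- config$effect_r
  for (i in seq_len(k)) {
    vals[i, ] <- config$noise_sd *
      (r * z + sqrt(1 - r^2) * rnorm(n))
  }
  expression_matrix(vals, stats::setNames(as.numeric(dispersal_scores),
                                          samples))
}

#' Simulate two-group survival data
#'
#' Event times are exponential with the `"high"` group's hazard equal to
#' `hazard_ratio` times the `"low"` group's baseline hazard; censoring
#' times are independent exponentials with rate `censoring_rate`
#' (`0` = no censoring, all events observed).
#'
#' @param n_per_group Subjects per group.
#' @param hazard_ratio Hazard ratio of group `"high"` versus `"low"`.
#' @param censoring_rate Rate of the independent exponential censoring
#'   distribution.
#' @param baseline_hazard Event rate in the `"low"` group (default 0.1
#'   per time unit).
#' @param seed Integer RNG seed.
#' @return A [survival_table()] with groups `"low"` and `"high"`.
#' @export
simulate_survival <- function(n_per_group, hazard_ratio = 1,
                              censoring_rate = 0, baseline_hazard = 0.1,
                              seed = 1L) {
  stopifnot(n_per_group > 0, hazard_ratio > 0, censoring_rate >= 0,
            baseline_hazard > 0)
  set.seed(as.integer(seed))
  n <- as.integer(n_per_group)
  ev <- c(rexp(n, baseline_hazard),
          rexp(n, baseline_hazard * hazard_ratio))
  cens <- if (censoring_rate > 0) rexp(2 * n, censoring_rate)
          else rep(Inf, 2 * n)
  survival_table(time = pmin(ev, cens),
                 event = as.integer(ev <= cens),
                 group = rep(c("low", "high"), each = n))
}
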