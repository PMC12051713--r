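# Exhaustive O(n^2) / O(p^2) reference implementations, independent of the
# package's accelerated paths: full distance matrices via stats::dist and
# explicit sorted neighbor lists.

oracle_min_cross <- function(cells) {
  dm <- as.matrix(dist(cbind(cells$x, cells$y)))
  n <- nrow(cells)
  vapply(seq_len(n), function(i) {
    other <- cells$population != cells$population[i]
    min(dm[i, other])
  }, numeric(1))
}

oracle_neighbor_order <- function(cells) {
  dm <- as.matrix(dist(cbind(cells$x, cells$y)))
  n <- nrow(cells)
  vapply(seq_len(n), function(i) {
    j <- setdiff(seq_len(n), i)
    ord <- j[order(dm[i, j], cells$cell_id[j])]
    which(cells$population[ord] != cells$population[i])[1]
  }, integer(1))
}

# population-level aggregation done independently of dispersal_score()
oracle_D <- function(d, pop) 1 / mean(tapply(d, pop, mean))

# pixel image -> point cloud of nonzero pixel centers
pixels_to_cells <- function(img) {
  idx <- which(img$pixels > 0L, arr.ind = TRUE)
  lab <- img$pixels[idx]
  pname <- img$label_map[as.character(lab)]
  pname[is.na(pname)] <- as.character(lab[is.na(pname)])
  cell_table(x = idx[, "col"], y = idx[, "row"], population = unname(pname))
}

# fixture generators
random_cells <- function(n, n_pop, seed, box = 100) {
  set.seed(seed)
  stopifnot(n >= n_pop)
  pop <- c(letters[seq_len(n_pop)],  # every population represented
           sample(letters[seq_len(n_pop)], n - n_pop, replace = TRUE,
                  prob = runif(n_pop, 0.5, 1.5)))
  cell_table(runif(n, 0, box), runif(n, 0, box), population = pop)
}

random_label_image <- function(nr, nc, n_lab, seed, p_bg = 0.3) {
  set.seed(seed)
  m <- matrix(sample(0:n_lab, nr * nc, replace = TRUE,
                     prob = c(p_bg, rep((1 - p_bg) / n_lab, n_lab))),
              nr, nc)
  m[1, 1] <- 1L; m[1, 2] <- 2L  # guarantee >= 2 labels present
  label_image(m)
}

alternating_lattice <- function(n = 8) {
  cell_table(seq_len(n), rep(0, n), rep(c("A", "B"), length.out = n))
}
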