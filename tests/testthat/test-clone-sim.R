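test_that("growth at q = 0 produces contiguous single-population patches", {
  sim <- simulate_clonal_growth(growth_config(grid_width = 32,
    grid_height = 32, n_populations = 2, n_initial_clones = 2,
    mixing_probability = 0, target_occupancy = 0.9, seed = 21))
  px <- sim$image$pixels
  for (lab in sort(unique(px[px > 0]))) {
    # flood fill from one member site must reach the whole population
    mask <- px == lab
    comp <- matrix(FALSE, nrow(px), ncol(px))
    start <- which(mask, arr.ind = TRUE)[1, ]
    comp[start[1], start[2]] <- TRUE
    queue <- list(start)
    while (length(queue)) {
      s <- queue[[1]]; queue <- queue[-1]
      for (dd in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r <- s[1] + dd[1]; c <- s[2] + dd[2]
        if (r >= 1 && r <= nrow(px) && c >= 1 && c <= ncol(px) &&
            mask[r, c] && !comp[r, c]) {
          comp[r, c] <- TRUE
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
    expect_true(all(comp[mask]))
  }
})

test_that("growth respects occupancy, round-robin seeding and determinism", {
  cfg <- growth_config(grid_width = 32, grid_height = 32,
                       n_initial_clones = 12, target_occupancy = 0.5,
                       seed = 8)
  sim <- simulate_clonal_growth(cfg)
  expect_equal(nrow(sim$cells), ceiling(0.5 * 32 * 32))
  expect_equal(sum(sim$image$pixels > 0), nrow(sim$cells))
  # 12 founders round-robin over 6 populations: every population seeded twice
  first12 <- sim$cells$population[1:12]
  expect_equal(unname(table(first12)), rep(2L, 6), ignore_attr = TRUE)
  sim2 <- simulate_clonal_growth(cfg)
  expect_identical(sim$cells, sim2$cells)
  expect_identical(sim$image$pixels, sim2$image$pixels)
  # cells and raster agree
  expect_equal(sim$image$pixels[cbind(sim$cells$y, sim$cells$x)],
               match(sim$cells$population,
                     c("red", "green", "blue", "orange", "purple", "cyan")))
})

test_that("full mixing scores higher than compact growth on the same seed", {
  base <- list(grid_width = 40, grid_height = 40, n_initial_clones = 12,
               target_occupancy = 0.75, seed = 14)
  d0 <- score_celltable(simulate_clonal_growth(
    do.call(growth_config, c(base, mixing_probability = 0)))$cells,
    "neighbor_order_cell")$D
  d1 <- score_celltable(simulate_clonal_growth(
    do.call(growth_config, c(base, mixing_probability = 1)))$cells,
    "neighbor_order_cell")$D
  expect_gt(d1, d0)
})

test_that("growth terminates at a full grid without error", {
  sim <- simulate_clonal_growth(growth_config(grid_width = 8,
    grid_height = 8, n_initial_clones = 4, n_populations = 2,
    target_occupancy = 1, seed = 2))
  expect_equal(nrow(sim$cells), 64)
})

test_that("point mixtures separate clusters at mixing 0 and mix at 1", {
  seg <- simulate_point_mixture(50, 3, cluster_sd = 2, box_size = 200,
                                mixing = 0, seed = 4)
  mix <- simulate_point_mixture(50, 3, cluster_sd = 2, box_size = 200,
                                mixing = 1, seed = 4)
  expect_equal(nrow(seg), 150)
  expect_gt(score_celltable(mix, "euclidean_cell")$D,
            score_celltable(seg, "euclidean_cell")$D)
  one <- simulate_point_mixture(1, 4, seed = 6)
  expect_equal(nrow(one), 4)
  expect_identical(simulate_point_mixture(10, 2, seed = 9),
                   simulate_point_mixture(10, 2, seed = 9))
})

test_that("fully mixed labeling is exchangeable across quadrants", {
  # at mixing = 1 every cell's position is uniform regardless of label:
  # chi-square of population x quadrant counts should not reject
  pvals <- vapply(1:20, function(s) {
    ct <- simulate_point_mixture(60, 2, cluster_sd = 1, box_size = 100,
                                 mixing = 1, seed = 500 + s)
    quad <- paste(ct$x > 50, ct$y > 50)
    suppressWarnings(chisq.test(table(ct$population, quad))$p.value)
  }, numeric(1))
  expect_gt(min(p.adjust(pvals, "bonferroni")), 0.01)
})

test_that("rendering paints exact discs with deterministic overwrites", {
  ct <- cell_table(c(5, 20), c(5, 20), c("A", "B"))
  r0 <- render_label_image(ct, nucleus_radius = 0, canvas_size = 30)
  expect_equal(sum(r0$pixels > 0), 2)
  expect_equal(r0$pixels[5, 5], 1L)
  expect_equal(r0$pixels[20, 20], 2L)

  r3 <- render_label_image(ct, nucleus_radius = 3, canvas_size = 30)
  disc_area <- sum(outer((-3):3, (-3):3,
                         function(a, b) a^2 + b^2 <= 9))
  expect_equal(unname(table(r3$pixels[r3$pixels > 0])),
               rep(disc_area, 2), ignore_attr = TRUE)

  # later cell_id overwrites earlier on overlap
  ov <- cell_table(c(10, 11), c(10, 10), c("A", "B"))
  rov <- render_label_image(ov, nucleus_radius = 2, canvas_size = 20)
  expect_equal(rov$pixels[10, 11], 2L)

  expect_error(render_label_image(ct, canvas_size = 10), "outside the canvas")
})

test_that("radius-0 renders reproduce the cell-level Euclidean score", {
  sim <- simulate_clonal_growth(growth_config(grid_width = 28,
    grid_height = 28, n_initial_clones = 9, target_occupancy = 0.5,
    seed = 17))
  d_cell <- score_celltable(sim$cells, "euclidean_cell")$D
  img <- render_label_image(sim$cells, nucleus_radius = 0,
                            canvas_size = 28)
  expect_equal(pixel_dispersal_score(img)$D, d_cell, tolerance = 1e-12)
})

test_that("expression simulator plants correlated genes and is seeded", {
  scores <- c(1.2, 0.3, 2.5, 0.8, 1.9, 0.1, 1.4, 2.2, 0.6, 1.1, 1.7,
              0.4, 2.0)
  cfg <- expression_sim_config(n_samples = 13, n_genes = 500,
                               effect_r = 0.95, seed = 33)
  ex <- simulate_expression(cfg, scores)
  expect_equal(dim(ex$values), c(500L, 13L))
  rs <- apply(ex$values[cfg$planted_genes, ], 1, cor, y = scores)
  expect_true(all(rs > 0.6))
  expect_identical(ex$values, simulate_expression(cfg, scores)$values)
  # null genes are noise
  rs_null <- apply(ex$values[400:500, ], 1, cor, y = scores)
  expect_lt(max(abs(rs_null)), 0.95)
})

test_that("planted-gene correlations exceed 0.6 in nearly all seeds", {
  scores <- qnorm((1:13) / 14)
  ok <- vapply(1:100, function(s) {
    ex <- simulate_expression(
      expression_sim_config(n_samples = 13, n_genes = 6, effect_r = 0.95,
                            planted_genes = c("g1", "g2", "g3", "g4", "g5"),
                            seed = 900 + s), scores)
    all(apply(ex$values[1:5, ], 1, cor, y = scores) > 0.6)
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("survival simulator honors censoring and hazard ratio", {
  st <- simulate_survival(50, hazard_ratio = 1, censoring_rate = 0,
                          seed = 10)
  expect_true(all(st$event == 1))
  expect_equal(unname(table(st$group)), c(50L, 50L), ignore_attr = TRUE)
  st2 <- simulate_survival(200, hazard_ratio = 4, censoring_rate = 0,
                           seed = 10)
  expect_lt(median(st2$time[st2$group == "high"]),
            median(st2$time[st2$group == "low"]))
  expect_identical(simulate_survival(20, 2, 0.05, seed = 3),
                   simulate_survival(20, 2, 0.05, seed = 3))
})

test_that("log-rank power is high at hazard ratio 3 with 100 per arm", {
  rejected <- vapply(1:200, function(s) {
    st <- simulate_survival(100, hazard_ratio = 3, censoring_rate = 0.02,
                            seed = 2000 + s)
    km_logrank(st)$p < 0.05
  }, logical(1))
  expect_gt(mean(rejected), 0.9)
})

test_that("mean D of both metrics increases with the mixing probability", {
  qs <- c(0, 0.5, 1)
  means <- sapply(qs, function(q) {
    ds <- sapply(1:3, function(s) {
      sim <- simulate_clonal_growth(growth_config(grid_width = 40,
        grid_height = 40, mixing_probability = q, seed = 300 + s))
      c(score_celltable(sim$cells, "euclidean_cell")$D,
        score_celltable(sim$cells, "neighbor_order_cell")$D)
    })
    rowMeans(ds)
  })
  expect_true(all(diff(means[1, ]) > 0))
  expect_true(all(diff(means[2, ]) > 0))
})
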