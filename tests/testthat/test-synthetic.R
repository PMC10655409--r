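test_that("density extremes and validation behave", {
  expect_true(all(gen_density_matrix(5, 7, 0, seed = 1) == 0L))
  expect_true(all(gen_density_matrix(5, 7, 1, seed = 1) == 1L))
  expect_error(gen_density_matrix(5, 5, 1.2), "density")
  expect_error(gen_density_matrix(5, 5, -0.1), "density")
})

test_that("empirical density sits inside the binomial envelope", {
  # pooled over replicates: 3-sigma band around p
  p <- 0.3
  reps <- 50
  n_cells <- 100 * 100
  means <- vapply(seq_len(reps), function(r) {
    mean(gen_density_matrix(100, 100, p, seed = 1000 + r))
  }, numeric(1))
  se <- sqrt(p * (1 - p) / (n_cells * reps))
  expect_lt(abs(mean(means) - p), 3 * se)
})

test_that("generation is reproducible and seed-sensitive", {
  a <- gen_density_matrix(30, 30, 0.4, seed = 5)
  b <- gen_density_matrix(30, 30, 0.4, seed = 5)
  c <- gen_density_matrix(30, 30, 0.4, seed = 6)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("scaling suite enumerates the full size-by-density grid", {
  suite <- gen_scaling_suite(sizes = c(50L, 100L), seed = 3)
  expect_length(suite, 2L)
  expect_identical(vapply(suite, `[[`, integer(1), "size"), c(50L, 100L))
  for (g in suite) {
    expect_length(g$matrices, 10L)
    expect_identical(vapply(g$matrices, attr, numeric(1), "density"),
                     seq(0.1, 1, by = 0.1))
    for (m in g$matrices) expect_identical(dim(m), c(g$size, g$size))
  }
  # element-wise reproducibility
  suite2 <- gen_scaling_suite(sizes = c(50L, 100L), seed = 3)
  expect_identical(suite, suite2)
})

test_that("implanted regions are all-ones and recorded exactly", {
  g <- gen_implanted(size = 40, n_implants = 3, implant_rows = c(10, 12, 8),
                     implant_cols = c(9, 10, 11), overlap_degree = 0,
                     background_density = 0.1, seed = 9)
  expect_length(g$truth$biclusters, 3L)
  for (b in g$truth$biclusters) {
    expect_true(all(g$matrix[b$rows, b$cols] == 1L))
  }
  # background density within binomial tolerance
  implant_cells <- matrix(FALSE, 40, 40)
  for (b in g$truth$biclusters) implant_cells[b$rows, b$cols] <- TRUE
  bg <- g$matrix[!implant_cells]
  expect_lt(abs(mean(bg) - 0.1), 3 * sqrt(0.1 * 0.9 / length(bg)))
  # regeneration is bit-identical
  expect_identical(g, gen_implanted(size = 40, n_implants = 3,
                                    implant_rows = c(10, 12, 8),
                                    implant_cols = c(9, 10, 11),
                                    overlap_degree = 0,
                                    background_density = 0.1, seed = 9))
})

test_that("overlap geometry shares the requested rows and columns", {
  g <- gen_implanted(size = 28, n_implants = 3, implant_rows = 10,
                     implant_cols = 10, shared = 1, seed = 2)
  tb <- g$truth$biclusters
  expect_identical(length(intersect(tb[[1]]$rows, tb[[2]]$rows)), 1L)
  expect_identical(length(intersect(tb[[2]]$cols, tb[[3]]$cols)), 1L)
  expect_false(g$truth$degenerate_nesting)

  # 100% overlap: consecutive implants coincide; degenerate nesting flagged
  g100 <- gen_implanted(size = 10, n_implants = 2, implant_rows = 10,
                        implant_cols = 10, overlap_degree = 100, seed = 2)
  expect_true(g100$truth$degenerate_nesting)
  expect_identical(g100$truth$biclusters[[1]], g100$truth$biclusters[[2]])

  expect_error(gen_implanted(size = 15, n_implants = 3, implant_rows = 10,
                             implant_cols = 10, overlap_degree = 0),
               "exceed")
})

test_that("implant suite reproduces the benchmark matrix dimensions", {
  suite <- gen_implant_suite(c(0L, 50L, 100L), seed = 1)
  expect_identical(vapply(suite, function(s) nrow(s$matrix), integer(1)),
                   c(100L, 105L, 110L))
  expect_identical(vapply(suite, function(s) length(s$truth$biclusters), integer(1)),
                   rep(10L, 3))
  # implant side grows with overlap: 10, 15, 20
  expect_identical(vapply(suite, function(s) length(s$truth$biclusters[[1]]$rows),
                          integer(1)), c(10L, 15L, 20L))
})
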