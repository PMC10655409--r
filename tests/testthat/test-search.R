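test_that("templates are the nibble-wise AND of their seed rows", {
  # rows 0101 1100 and 0111 1000 -> nibbles (5,12) & (7,8) -> (5,8), width 3
  x <- rbind(c(0, 1, 0, 1, 1, 1, 0, 0),
             c(0, 1, 1, 1, 1, 0, 0, 0))
  enc <- encode_matrix(x)
  t12 <- make_template(enc, 1, 2)
  expect_identical(t12$nibbles, c(5L, 8L))
  expect_identical(t12$width, 3L)
  expect_identical(t12$columns, c(2L, 4L, 5L))
  expect_identical(t12$seed_pair, c(1, 2))

  # zero row is absorbing
  enc0 <- encode_matrix(rbind(c(1, 1, 1, 1), c(0, 0, 0, 0)))
  expect_identical(make_template(enc0, 1, 2)$width, 0L)

  expect_error(make_template(enc, 2, 2), "distinct")
  expect_error(make_template(enc, 2, 1), "i < j")
  expect_error(make_template(enc, 1, 9), "distinct|valid")
})

test_that("templates agree with the bit-level oracle on random rows", {
  set.seed(21)
  for (rep in 1:25) {
    m <- sample(3:20, 1)
    x <- as_binary_matrix(matrix(rbinom(2 * m, 1, 0.5), 2, m))
    tm <- make_template(encode_matrix(x), 1, 2)
    expect_identical(tm$columns, which(bit_template(x, 1, 2) == 1L))
    expect_identical(tm$width, sum(bit_template(x, 1, 2)))
  }
})

test_that("row inclusion tests use the submask table with early exit", {
  v <- submask_table()
  tmpl <- structure(list(nibbles = c(5L, 8L), width = 3L,
                         columns = c(2L, 4L, 5L), seed_pair = c(1, 2)),
                    class = "bic_template")
  r1 <- row_matches_template(c(7L, 12L), tmpl, v)
  expect_true(r1$match)
  expect_identical(r1$checks_used, 2L)
  r2 <- row_matches_template(c(3L, 15L), tmpl, v)
  expect_false(r2$match)
  expect_identical(r2$checks_used, 1L)
  expect_error(row_matches_template(c(3L, 15L, 0L), tmpl, v), "length")
})

test_that("row inclusion agrees with the whole-row bitwise predicate", {
  set.seed(22)
  v <- submask_table()
  for (rep in 1:50) {
    bits <- matrix(rbinom(16, 1, 0.5), 2, 8)
    x <- as_binary_matrix(rbind(bits[1, ] & bits[2, ], bits[1, ], bits[2, ]))
    enc <- encode_matrix(x)
    tmpl <- make_template(enc, 2, 3)
    probe <- as_binary_matrix(matrix(rbinom(8, 1, 0.5), 1, 8))
    got <- row_matches_template(encode_matrix(probe)$nibbles[1, ], tmpl, v)
    expected <- all(bitwAnd(probe[1, ], x[1, ]) == x[1, ])  # template AND row == template
    expect_identical(got$match, expected)
  }
})

test_that("degenerate inputs give empty results, not errors", {
  expect_identical(bitclust(diag(1L, 4))$n, 0L)           # pairwise ANDs all zero
  expect_identical(bitclust(matrix(0L, 3, 3))$n, 0L)
  expect_identical(bitclust(matrix(1L, 1, 5))$n, 0L)      # single row: no seed pair
  expect_identical(bitclust(matrix(1L, 5, 5), r_min = 9L, c_min = 2L,
                            mode = "flex")$n, 0L)
  expect_identical(bitclust(matrix(1L, 5, 5), r_min = 2L, c_min = 9L,
                            mode = "flex")$n, 0L)
})

test_that("an all-ones matrix yields the single full bicluster", {
  fit <- bitclust(matrix(1L, 4, 4))
  expect_identical(fit$n, 1L)
  expect_identical(fit$biclusters[[1]]$rows, 1:4)
  expect_identical(fit$biclusters[[1]]$cols, 1:4)
})

test_that("emitted biclusters are sound, unique, and deterministic", {
  set.seed(31)
  for (rep in 1:10) {
    x <- gen_density_matrix(25, 25, 0.3, seed = 100 + rep)
    fit <- bitclust(x)
    # soundness: every cell of every bicluster is 1
    for (b in fit$biclusters) {
      expect_true(all(x[b$rows, b$cols] == 1L))
      expect_gte(length(b$rows), 2L)
      expect_gte(length(b$cols), 2L)
    }
    # uniqueness of (rows, cols)
    keys <- bicluster_keys(fit)
    expect_identical(anyDuplicated(keys), 0L)
    # determinism including ordering
    fit2 <- bitclust(x)
    expect_identical(fit$biclusters, fit2$biclusters)
  }
})

test_that("duplicate rows are retained as distinct members", {
  x <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0), c = c(1, 1, 1, 1))
  fit <- bitclust(x)
  expect_identical(fit$n, 1L)
  expect_identical(fit$biclusters[[1]]$rows, 1:3)
  expect_identical(fit$biclusters[[1]]$cols, 1:2)
})

test_that("base mode coerces user minimums back to 2 with a warning", {
  x <- block_diag_matrix(c(3, 3))
  expect_warning(fit <- bitclust(x, r_min = 5L), "base mode")
  expect_identical(fit$params$r_min, 2L)
  expect_identical(fit$n, 2L)
  expect_error(bitclust(x, r_min = 1L, mode = "flex"), "r_min")
})

test_that("sparse-seed pre-skip is output-equivalent", {
  set.seed(33)
  for (rep in 1:5) {
    x <- gen_density_matrix(20, 17, 0.2, seed = 200 + rep)
    a <- bitclust(x, skip_sparse_seeds = TRUE)
    b <- bitclust(x, skip_sparse_seeds = FALSE)
    expect_identical(a$biclusters, b$biclusters)
  }
})

test_that("flex mode supports stricter minimums and top-k truncation", {
  x <- block_diag_matrix(c(5, 3, 2))
  base <- bitclust(x)
  expect_identical(base$n, 3L)
  strict <- bitclust(x, r_min = 4L, c_min = 4L, mode = "flex")
  expect_identical(strict$n, 1L)
  expect_identical(length(strict$biclusters[[1]]$rows), 5L)
  topped <- bitclust(x, mode = "flex", top_k = 2L)
  expect_identical(topped$n, 2L)
  areas <- vapply(topped$biclusters, function(b) length(b$rows) * length(b$cols), numeric(1))
  expect_identical(sort(areas, decreasing = TRUE), c(25, 9))
})

test_that("symmetric removal keeps one member per transpose pair", {
  # bipartite clique {a,b} x {c,d} as a symmetric adjacency
  adj <- edges_to_adjacency(data.frame(from = c("a", "a", "b", "b"),
                                       to = c("c", "d", "c", "d")))
  fit <- bitclust(adj, mode = "flex", remove_symmetric = TRUE)
  expect_identical(fit$n, 1L)
  plain <- bitclust(adj)
  expect_identical(plain$n, 2L)

  # self-symmetric clusters only: nothing removed
  x <- block_diag_matrix(c(3, 2))
  dimnames(x) <- list(paste0("n", 1:5), paste0("n", 1:5))
  fit2 <- bitclust(x, mode = "flex", remove_symmetric = TRUE)
  expect_identical(bicluster_keys(fit2), bicluster_keys(bitclust(x)))

  # non-square input: warning + unchanged
  y <- bitclust(matrix(1L, 3, 5))
  expect_warning(out <- remove_symmetric(y), "square")
  expect_identical(out$biclusters, y$biclusters)
})

test_that("symmetric removal agrees with brute-force transpose matching", {
  set.seed(44)
  for (rep in 1:10) {
    n <- 10L
    up <- matrix(rbinom(n * n, 1, 0.35), n, n)
    adj <- (up | t(up)) + 0L
    diag(adj) <- 0L
    dimnames(adj) <- list(paste0("p", 1:n), paste0("p", 1:n))
    fit <- bitclust(as_binary_matrix(adj))
    filtered <- remove_symmetric(fit)
    keys <- vapply(fit$biclusters, function(b)
      paste(paste(b$rows, collapse = ","), paste(b$cols, collapse = ","), sep = "|"),
      character(1))
    tkeys <- vapply(fit$biclusters, function(b)
      paste(paste(b$cols, collapse = ","), paste(b$rows, collapse = ","), sep = "|"),
      character(1))
    has_mirror <- tkeys %in% keys
    self_sym <- keys == tkeys
    # expected survivors: all unpaired + self-symmetric + half of mirrored pairs
    n_expected <- sum(!has_mirror) + sum(self_sym) + (sum(has_mirror & !self_sym)) / 2
    expect_identical(filtered$n, as.integer(n_expected))
  }
})

test_that("comparison counts hit the exact worst case on all-ones input", {
  n <- 9L
  fit <- bitclust(matrix(1L, n, 8), collect_stats = TRUE)
  st <- comparison_stats(fit)
  p <- st$n_nibbles
  expect_identical(st$n_templates_scanned, 1)     # single unique template
  expect_equal(st$per_template_checks, (n - 2) * p)
  expect_identical(as.vector(st$k_sequences[[1]]), c(0L, 0L))  # nothing excluded
})

test_that("a crafted first-column rejector realizes the best case", {
  n <- 12L
  x <- best_case_matrix(n)
  fit <- bitclust(x, collect_stats = TRUE)
  st <- comparison_stats(fit)
  # first scanned template comes from seed pair (1,2): all non-seed rows are
  # checked at position 1, all but row 3 fail there
  expect_identical(st$template_seeds[1, ], c(1L, 2L))
  k1 <- st$k_sequences[[1]]
  expect_identical(k1[1], n - 3L)            # rows excluded at the first nibble
  expect_equal(st$per_template_checks[1], (n - 2) + 1)  # N-2 first checks + 1 later
})

test_that("instrumented checks respect their analytic bounds", {
  set.seed(55)
  x <- gen_density_matrix(20, 20, 0.4, seed = 77)
  st <- comparison_stats(bitclust(x, collect_stats = TRUE))
  p <- st$n_nibbles
  n <- st$n_rows
  expect_true(all(st$per_template_checks <= (n - 2) * p))
  expect_true(all(st$per_template_checks >= n - 2))  # every row examined at least once
  for (k in st$k_sequences) {
    expect_true(all(k >= 0L))
    expect_lte(sum(k), n - 2L)
  }
  expect_equal(sum(st$per_template_checks), st$total_checks)
})

test_that("survivor ratios follow the geometric-decay prediction", {
  x <- gen_density_matrix(80, 60, 0.25, seed = 7)
  rp <- retention_profile(x, max_templates = 2000, positions = 3)
  expect_true(all(abs(rp$ratios - 0.25) < 0.05))
  expect_lt(abs(rp$overall - 0.25), 0.03)
})
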