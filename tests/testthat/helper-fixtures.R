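# Shared fixture builders. All fixtures are generated in code; no data files.

# block-diagonal all-ones matrix
block_diag_matrix <- function(block_sizes) {
  n <- sum(block_sizes)
  m <- matrix(0L, n, n)
  at <- 1L
  for (s in block_sizes) {
    m[at:(at + s - 1L), at:(at + s - 1L)] <- 1L
    at <- at + s
  }
  m
}

# matrix engineered so the seed pair (1, 2) produces an all-ones template that
# rejects every other row except row 3 at the first nibble position
best_case_matrix <- function(n, m = 8L) {
  stopifnot(m %% 4L == 0L, n >= 4L)
  x <- matrix(0L, n, m)
  x[1:3, ] <- 1L
  x[4:n, (m - 3L):m] <- 1L  # first nibble 0 -> fails template nibble 15
  x
}

# bit-level template oracle: positionwise AND of two decoded rows
bit_template <- function(x, i, j) {
  as.integer(x[i, ] & x[j, ])
}

expect_set_equal_biclusters <- function(a, b) {
  expect_identical(bicluster_keys(a), bicluster_keys(b))
}
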