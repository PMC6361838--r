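test_that("the ISFC cross-product matches the per-element loop oracle", {
  set.seed(21)
  for (case in 1:10) {
    P <- sample(3:6, 1); N <- sample(10:30, 1)
    target <- normalize_rows(random_run(P = P, N = N))
    reference <- matrix(rnorm(P * N), P, N)
    raw <- isfc_matrix(target, reference, apply_fisher = FALSE,
                       symmetrize = FALSE)$values
    oracle <- matrix(0, P, P)
    for (i in seq_len(P)) for (j in seq_len(P)) {
      oracle[i, j] <- sum(target$data[i, ] * reference[j, ]) / N
    }
    expect_lt(max(abs(raw - oracle)), 1e-12)
  }
})

test_that("ISFC against itself reproduces the within-matrix correlations", {
  target <- normalize_rows(random_run(P = 5, N = 40, seed = 3))
  raw <- isfc_matrix(target, target, apply_fisher = FALSE,
                     symmetrize = FALSE)$values
  expect_equal(diag(raw), rep(1, 5), tolerance = 1e-12)
  expect_equal(raw, cor(t(target$data)), tolerance = 1e-12)
  # full pipeline: diagonal Fisher value is the clipped atanh of 1
  z <- isfc_matrix(target, target)
  expect_equal(diag(z$values), rep(atanh(1 - 1e-6), 5), tolerance = 1e-9)
  expect_lt(max(abs(z$values - t(z$values))), 1e-14)
})

test_that("orthogonal target and reference give a zero ISFC matrix", {
  N <- 8
  t1 <- rep(c(1, -1), N / 2)
  t2 <- rep(c(1, 1, -1, -1), N / 4)
  target <- normalize_rows(run_ts(rbind(t1, t2), TR = 1))
  reference <- rbind(rep(c(1, -1, -1, 1), N / 4), rep(c(1, 1, 1, 1, -1, -1, -1, -1), N / 8))
  expect_true(all(abs(tcrossprod(target$data, reference)) < 1e-12))
  out <- isfc_matrix(target, reference)
  expect_equal(out$values, matrix(0, 2, 2))
})

test_that("a known two-node swap has unit cross-correlation before symmetrisation", {
  X <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  target <- normalize_rows(run_ts(X, TR = 1))
  reference <- target$data[c(2, 1), ]
  raw <- isfc_matrix(target, reference, apply_fisher = FALSE,
                     symmetrize = FALSE)$values
  expect_equal(raw[1, 2], 1)   # node 1 vs swapped row = itself
  expect_equal(raw[2, 1], 1)
  expect_equal(raw[1, 1], 0)   # the two rows are orthogonal
  expect_equal(raw[2, 2], 0)
})

test_that("ISFC validates its inputs", {
  run <- random_run(P = 3, N = 10, seed = 1)
  expect_error(isfc_matrix(run, run$data), "must be normalized")
  norm <- normalize_rows(run)
  expect_error(isfc_matrix(norm, matrix(0, 4, 10)), "reference is")
})

test_that("group averaging is the element-wise mean", {
  set.seed(9)
  mats <- lapply(1:5, function(i) {
    M <- matrix(rnorm(16), 4, 4); M <- (M + t(M)) / 2
    isfcdecode:::new_conn_matrix(M, "isfc", TRUE, TRUE)
  })
  avg <- group_isfc(mats)
  oracle <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    oracle[i, j] <- mean(sapply(mats, function(m) m$values[i, j]))
  }
  expect_equal(avg$values, oracle, tolerance = 1e-14)
  expect_equal(group_isfc(mats[c(1, 1)])$values, mats[[1]]$values)
  neg <- mats[[1]]; neg$values <- -neg$values
  expect_equal(group_isfc(list(mats[[1]], neg))$values, matrix(0, 4, 4))
  expect_error(group_isfc(list()), "empty")
})

test_that("FC matrices are Pearson correlations with unit diagonal", {
  run <- random_run(P = 4, N = 50, seed = 6)
  run$data[2, ] <- -run$data[1, ]
  C <- fc_matrix(run)
  expect_equal(diag(C$values), rep(1, 4))
  expect_equal(C$values[1, 2], -1)
  expect_true(C$symmetric)
  # independent rows: off-diagonal correlations bounded by sampling noise
  big <- random_run(P = 5, N = 10000, seed = 8)
  Cb <- fc_matrix(big)$values
  expect_lt(max(abs(Cb[upper.tri(Cb)])), 0.05)
  crun <- run_ts(rbind(rep(1, 10), rnorm(10)), TR = 1)
  expect_error(fc_matrix(crun), "constant")
})

test_that("Fisher transform matches atanh with clipping and is odd", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306, tolerance = 1e-6)
  expect_equal(fisher_z(1.0), atanh(1 - 1e-6))
  expect_equal(fisher_z(-1.0), -atanh(1 - 1e-6))
  r <- seq(-0.9, 0.9, by = 0.1)
  expect_equal(fisher_z(-r), -fisher_z(r), tolerance = 1e-14)
  expect_error(fisher_z(NaN), "finite")
})

test_that("edge vectorisation is ordered, invertible and validated", {
  C <- matrix(c(1, 2, 2, 3), 2, 2)
  idx2 <- edge_index(2, TRUE)
  expect_equal(vectorize_edges(C, idx2), c(1, 2, 3))
  set.seed(4)
  M <- matrix(rnorm(36), 6, 6); M <- (M + t(M)) / 2
  idx <- edge_index(6, TRUE)
  expect_equal(devectorize_edges(vectorize_edges(M, idx), idx), M)
  idx_nd <- edge_index(6, FALSE)
  v <- vectorize_edges(M, idx_nd)
  back <- devectorize_edges(v, idx_nd)
  expect_equal(back[upper.tri(back)], M[upper.tri(M)])
  A <- M; A[1, 2] <- A[1, 2] + 1
  expect_error(vectorize_edges(A, idx), "not symmetric")
})

test_that("matrix similarity is an affine-invariant edge correlation", {
  set.seed(10)
  M <- matrix(rnorm(25), 5, 5); M <- (M + t(M)) / 2
  expect_equal(matrix_similarity(M, M), 1.0)
  expect_equal(matrix_similarity(M, 2 * M + 0.3), 1.0)
  C1 <- matrix(c(1, 2, 2, 3), 2, 2)
  C2 <- matrix(c(3, 2, 2, 1), 2, 2)
  expect_equal(matrix_similarity(C1, C2), -1.0)
  expect_error(matrix_similarity(M, matrix(1, 5, 5)), "constant")
  expect_error(matrix_similarity(M, M, subset = 1:2), "at least 3")
})

test_that("the literal cross-product is the renormalised ISFC damped by reference spread", {
  target <- normalize_rows(random_run(P = 4, N = 60, seed = 13))
  set.seed(14)
  reference <- matrix(rnorm(4 * 60, sd = 0.5), 4, 60)
  lit <- isfc_matrix(target, reference, apply_fisher = FALSE,
                     symmetrize = FALSE)$values
  ren <- isfc_matrix(target, reference, renormalize_reference = TRUE,
                     apply_fisher = FALSE, symmetrize = FALSE)$values
  mu <- rowMeans(reference)
  sd_pop <- sqrt(rowSums((reference - mu)^2) / 60)
  # column j of the literal matrix is shrunk by the sd of reference row j
  # (plus the mean offset, which the normalised target annihilates)
  expect_equal(lit, sweep(ren, 2, sd_pop, `*`), tolerance = 1e-12)
})
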