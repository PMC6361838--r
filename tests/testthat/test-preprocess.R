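test_that("node extraction averages voxels in atlas order", {
  atl <- atlas(tiny_atlas_table(P = 2, labels = c("A", "B")))
  vox <- rbind(c(1, 2, 3), c(3, 4, 5), c(10, 10, 10), c(0, 0, 0))
  labels <- c(1, 1, 2, 2)
  out <- extract_node_series(vox, labels, atl, TR = 2)
  expect_equal(out$data[1, ], c(2, 3, 4))
  expect_equal(out$data[2, ], c(5, 5, 5))
  expect_error(extract_node_series(vox, c(1, 1, 1, 1), atl, TR = 2),
               "no voxels for atlas node\\(s\\): 2")
})

test_that("linear detrending matches the normal-equation oracle", {
  N <- 48; TR <- 2
  t_idx <- seq_len(N)
  row1 <- 2 + 0.5 * t_idx
  row2 <- sin(2 * pi * 0.1 * t_idx * TR) + 3 * t_idx
  run <- run_ts(rbind(row1, row2), TR = TR)
  out <- detrend_linear(run)
  expect_lt(max(abs(out$data[1, ])), 1e-10)
  # independent oracle: solve the normal equations explicitly
  X <- cbind(1, t_idx)
  beta <- solve(t(X) %*% X, t(X) %*% row2)
  expect_lt(max(abs(out$data[2, ] - (row2 - X %*% beta))), 1e-10)
  expect_lt(abs(mean(out$data[2, ])), 1e-10)
  expect_lt(abs(coef(lm(out$data[2, ] ~ t_idx))[2]), 1e-10)
  expect_error(detrend_linear(run_ts(matrix(1:4, 2, 2), TR = 1)), "3 time points")
})

test_that("confound regression leaves residuals orthogonal to the design", {
  set.seed(31)
  N <- 60
  conf <- matrix(rnorm(N * 3), N, 3)
  run <- run_ts(rbind(conf[, 2], rnorm(N)), TR = 2)
  out <- regress_confounds(run, conf, add_derivatives = TRUE)
  expect_lt(max(abs(out$data[1, ])), 1e-10)   # row equal to a confound -> 0
  D <- rbind(0, diff(conf))
  design <- cbind(1, conf, D)
  expect_lt(max(abs(out$data %*% design)), 1e-8)
  # duplicated column triggers the rank-deficiency warning, result unchanged
  expect_warning(out2 <- regress_confounds(run, cbind(conf, conf[, 1]),
                                           add_derivatives = FALSE),
                 "rank deficient")
  out_ref <- regress_confounds(run, conf, add_derivatives = FALSE)
  expect_equal(out2$data, out_ref$data, tolerance = 1e-10)
})

test_that("orthogonal zero-mean signals survive confound regression", {
  N <- 40
  conf <- matrix(rep(c(-1, 1), N / 2), N, 1)
  x <- rep(c(1, 1, -1, -1), N / 4)      # zero mean, orthogonal to conf
  expect_equal(sum(x * conf), 0)
  out <- regress_confounds(run_ts(rbind(x), TR = 2), conf,
                           add_derivatives = FALSE)
  expect_lt(max(abs(out$data[1, ] - x)), 1e-10)
})

test_that("the DCT high-pass removes slow and keeps fast oscillations", {
  N <- 196; TR <- 2
  t_s <- (seq_len(N) - 1) * TR
  slow <- sin(2 * pi * 0.02 * t_s)
  fast <- sin(2 * pi * 0.15 * t_s)
  run <- run_ts(rbind(slow, fast, rep(5, N)), TR = TR)
  out <- highpass_filter(run, cutoff_hz = 0.08)
  expect_lt(sum(out$data[1, ]^2), 0.01 * sum(slow^2))
  expect_gt(sum(out$data[2, ]^2), 0.95 * sum(fast^2))
  expect_lt(max(abs(out$data[3, ])), 1e-10)   # constant row -> zeros
  expect_error(highpass_filter(run, cutoff_hz = 0.3), "Nyquist")
})

test_that("task-evoked removal regresses out HRF-convolved events", {
  N <- 98; TR <- 2
  events <- data.frame(onset = c(10, 50, 110), duration = 2, condition = "clip")
  # oracle regressor: boxcar convolved with the canonical HRF, as the model
  # defines it
  grid <- (seq_len(N) - 1) * TR
  box <- as.numeric(rowSums(sapply(events$onset, function(on)
    grid >= on & grid < on + 2)) > 0)
  kern <- canonical_hrf(seq(0, 32, by = TR))
  reg <- stats::convolve(box, rev(kern), type = "open")[seq_len(N)]
  run <- run_ts(rbind(3 * reg + 1, rnorm(N)), TR = TR)
  out <- remove_task_evoked(run, events)
  expect_lt(max(abs(out$data[1, ])), 1e-8)
  expect_lt(max(abs(out$data %*% cbind(1, reg))), 1e-8)
  expect_message(out2 <- remove_task_evoked(run, events[0, ]), "intercept only")
  expect_equal(out2$data, run$data - rowMeans(run$data), tolerance = 1e-12)
  bad <- data.frame(onset = 500, duration = 2, condition = "clip")
  expect_error(remove_task_evoked(run, bad), "within the run")
})

test_that("row normalisation uses the population variance convention", {
  run <- run_ts(rbind(c(1, 2, 3), c(4, 0, 2)), TR = 1)
  out <- normalize_rows(run)
  expect_equal(out$data[1, ], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  expect_true(out$normalized)
  expect_equal(rowMeans(out$data), c(0, 0))
  expect_equal(rowSums(out$data^2) / 3, c(1, 1))
  again <- normalize_rows(out)
  expect_equal(again$data, out$data, tolerance = 1e-12)
  expect_error(normalize_rows(run_ts(rbind(c(1, 1, 1)), TR = 1)),
               "constant time series at node\\(s\\): 1")
})

test_that("framewise displacement follows the translation + arc-length rule", {
  N <- 20
  m <- matrix(0, N, 6)
  expect_equal(mean_framewise_displacement(m), 0)
  m[10:N, 1] <- 1          # single 1 mm x-translation step
  expect_equal(mean_framewise_displacement(m), 1 / (N - 1))
  m2 <- matrix(0, N, 6)
  m2[5:N, 4] <- 0.01       # single 0.01 rad pitch step -> 0.5 mm that frame
  fd <- abs(diff(m2[, 4])) * 50
  expect_equal(fd[4], 0.5)
  expect_equal(mean_framewise_displacement(m2), 0.5 / (N - 1))
  expect_error(mean_framewise_displacement(m[, 1:5]), "6 columns")
})

test_that("task-run averaging equals the per-element oracle", {
  runs <- lapply(1:3, function(i)
    random_run(P = 4, N = 10, seed = i, subject_id = "s1", task = "beh"))
  avg <- average_task_runs(runs, task = "beh")
  oracle <- matrix(0, 4, 10)
  for (i in 1:4) for (j in 1:10) {
    oracle[i, j] <- mean(sapply(runs, function(r) r$data[i, j]))
  }
  expect_equal(avg$data, oracle, tolerance = 1e-14)
  expect_equal(average_task_runs(rep(runs[1], 5))$data, runs[[1]]$data)
  # runs x and -x average to zero; normalisation then fails loudly
  neg <- runs[[1]]; neg$data <- -neg$data
  zero_avg <- average_task_runs(list(runs[[1]], neg))
  expect_error(normalize_rows(zero_avg), "constant")
  other <- runs[[2]]; other$subject_id <- "s2"
  expect_error(average_task_runs(list(runs[[1]], other)), "different subjects")
})

test_that("cleaning steps are linear projections", {
  set.seed(77)
  N <- 60
  conf <- matrix(rnorm(N * 2), N, 2)
  events <- data.frame(onset = c(8, 40), duration = 2, condition = "clip")
  x <- run_ts(matrix(rnorm(2 * N), 2, N), TR = 2)
  y <- run_ts(matrix(rnorm(2 * N), 2, N), TR = 2)
  comb <- run_ts(2 * x$data - 0.5 * y$data, TR = 2)
  steps <- list(
    detrend_linear,
    function(r) regress_confounds(r, conf),
    function(r) highpass_filter(r, 0.08),
    function(r) remove_task_evoked(r, events))
  for (step in steps) {
    lhs <- step(comb)$data
    rhs <- 2 * step(x)$data - 0.5 * step(y)$data
    expect_lt(max(abs(lhs - rhs)), 1e-9)
  }
})

test_that("the full cleaning chain ends normalised and idempotent there", {
  set.seed(5)
  N <- 80
  run <- random_run(P = 4, N = N, TR = 2)
  conf <- matrix(rnorm(N * 2), N, 2)
  events <- data.frame(onset = c(10, 60), duration = 2, condition = "clip")
  out <- clean_run(run, confounds = conf, events = events)
  expect_true(out$normalized)
  expect_lt(max(abs(rowMeans(out$data))), 1e-10)
  expect_equal(unname(rowSums(out$data^2) / N), rep(1, 4), tolerance = 1e-10)
  expect_equal(normalize_rows(out)$data, out$data, tolerance = 1e-12)
})
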