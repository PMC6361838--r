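#' A single run of node time series
#'
#' The basic data unit: a P x N matrix of node time series (rows = nodes,
#' columns = time points) for one run of one subject, with its repetition
#' time, identifiers and task label.
#'
#' @param data numeric P x N matrix, no missing values, N >= 2.
#' @param TR repetition time in seconds.
#' @param subject_id,run_id identifiers.
#' @param task task label, conventionally one of `"beh"`, `"tax"`.
#' @param normalized logical; `TRUE` only if every row has zero mean and unit
#'   population variance (the `1/N` convention).
#' @return Object of class `run_ts`.
#' @export
run_ts <- function(data, TR, subject_id = NA, run_id = NA, task = NA,
                   normalized = FALSE) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data)) stop("run data must be numeric with no missing values")
  if (ncol(data) < 2L) stop("a run needs at least 2 time points")
  if (!is.numeric(TR) || length(TR) != 1L || TR <= 0) stop("TR must be a positive scalar")
  structure(list(data = unname(data), TR = TR,
                 subject_id = subject_id, run_id = run_id,
                 task = if (is.na(task)) NA_character_ else as.character(task),
                 normalized = isTRUE(normalized)),
            class = "run_ts")
}

#' @export
print.run_ts <- function(x, ...) {
  cat(sprintf("Run time series: %d nodes x %d time points (TR = %gs)\n",
              nrow(x$data), ncol(x$data), x$TR))
  cat(sprintf("  subject %s, run %s, task %s, normalized: %s\n",
              x$subject_id, x$run_id, x$task, x$normalized))
  invisible(x)
}

#' @export
dim.run_ts <- function(x) dim(x$data)

## replace the data matrix, dropping the normalized flag unless stated
update_run <- function(run, data, normalized = FALSE) {
  run$data <- data
  run$normalized <- normalized
  run
}

#' Average voxel time series into node time series
#'
#' Row p of the result is the mean over all voxels carrying node label p,
#' with nodes in atlas order.
#'
#' @param voxel_series numeric V x N matrix of voxel time series.
#' @param labels length-V vector of node ids mapping voxels to atlas nodes.
#' @param atlas an [atlas()] object; every node must have at least one voxel.
#' @param TR repetition time in seconds.
#' @param ... passed to [run_ts()] (identifiers, task).
#' @return A `run_ts` with P = number of atlas nodes.
#' @export
extract_node_series <- function(voxel_series, labels, atlas, TR, ...) {
  voxel_series <- as.matrix(voxel_series)
  if (length(labels) != nrow(voxel_series)) {
    stop("labels length (", length(labels), ") must match voxel count (",
         nrow(voxel_series), ")")
  }
  ids <- atlas$node_id
  missing_nodes <- ids[!ids %in% labels]
  if (length(missing_nodes) > 0L) {
    stop("no voxels for atlas node(s): ", paste(missing_nodes, collapse = ", "))
  }
  out <- matrix(0, nrow = length(ids), ncol = ncol(voxel_series))
  for (p in seq_along(ids)) {
    rows <- which(labels == ids[p])
    out[p, ] <- if (length(rows) == 1L) voxel_series[rows, ] else colMeans(voxel_series[rows, , drop = FALSE])
  }
  run_ts(out, TR = TR, ...)
}

## residual of each row of Y (P x N) against design X (N x q), closed-form OLS
project_out <- function(Y, X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    warning("design is rank deficient; dropping ", ncol(X) - qr_x$rank,
            " dependent column(s)")
    X <- X[, keep, drop = FALSE]
    qr_x <- qr(X)
  }
  t(qr.resid(qr_x, t(Y)))
}

#' Remove linear trends
#'
#' Removes, per node, the ordinary least-squares fit of an intercept plus
#' linear term in the time index; output rows have zero mean and zero slope.
#'
#' @param series a `run_ts` with at least 3 time points.
#' @return The detrended `run_ts`.
#' @export
detrend_linear <- function(series) {
  stopifnot(inherits(series, "run_ts"))
  N <- ncol(series$data)
  if (N < 3L) stop("detrending needs at least 3 time points")
  X <- cbind(1, seq_len(N))
  update_run(series, project_out(series$data, X))
}

#' Regress out nuisance signals
#'
#' Removes, per node, the least-squares projection onto an intercept, the
#' given confound columns and (optionally) their temporal derivatives. The
#' derivative is the backward difference with a leading zero. Linearly
#' dependent design columns are dropped with a warning.
#'
#' @param series a `run_ts`.
#' @param confounds numeric N x Q matrix or data frame of nuisance regressors
#'   (e.g. motion parameters, white-matter and CSF means).
#' @param add_derivatives also regress out backward differences? Default
#'   `TRUE`.
#' @return The cleaned `run_ts`.
#' @export
regress_confounds <- function(series, confounds, add_derivatives = TRUE) {
  stopifnot(inherits(series, "run_ts"))
  C <- as.matrix(confounds)
  N <- ncol(series$data)
  if (nrow(C) != N) stop("confounds have ", nrow(C), " rows but the run has ", N,
                         " time points")
  if (add_derivatives) {
    D <- rbind(0, diff(C))
    C <- cbind(C, D)
  }
  X <- cbind(1, C)
  update_run(series, project_out(series$data, X))
}

## discrete cosine basis (DCT-II shape) over N samples; column k has
## frequency k / (2 N TR) Hz
dct_basis <- function(N, K) {
  t_idx <- seq_len(N) - 0.5
  sapply(seq_len(K), function(k) cos(pi * k * t_idx / N))
}

#' High-pass filter via discrete-cosine regression
#'
#' Removes the mean plus every discrete cosine component with frequency below
#' `cutoff_hz`. Realising the filter as a regression keeps it an exact linear
#' projection that composes cleanly with the other cleaning steps and has
#' exact spectral nulls at the removed frequencies.
#'
#' @param series a `run_ts`.
#' @param cutoff_hz cutoff frequency in Hz; components strictly below it are
#'   removed. Default 0.08 Hz. Must be below the Nyquist frequency
#'   `1/(2 TR)`.
#' @return The filtered `run_ts`.
#' @export
highpass_filter <- function(series, cutoff_hz = 0.08) {
  stopifnot(inherits(series, "run_ts"))
  N <- ncol(series$data)
  nyquist <- 1 / (2 * series$TR)
  if (cutoff_hz >= nyquist) {
    stop("cutoff (", cutoff_hz, " Hz) must be below Nyquist (", nyquist, " Hz)")
  }
  ## component k spans frequency k / (2 N TR); drop all below the cutoff
  K <- floor(2 * N * series$TR * cutoff_hz)
  K <- min(K, N - 1L)
  X <- if (K >= 1L) cbind(1, dct_basis(N, K)) else matrix(1, N, 1)
  update_run(series, project_out(series$data, X))
}

#' Canonical double-gamma haemodynamic response function
#'
#' The standard BOLD impulse response: a gamma-density response peaking at
#' 6 s minus a 1/6-scaled undershoot peaking at 16 s, evaluated over a 32 s
#' kernel.
#'
#' @param t time in seconds (vector).
#' @param peak1,peak2 response and undershoot peak times (s).
#' @param ratio response/undershoot amplitude ratio.
#' @return HRF values at `t` (arbitrary units, peak normalised to 1).
#' @export
canonical_hrf <- function(t, peak1 = 6, peak2 = 16, ratio = 6) {
  ## gamma densities with scale 1: shape = peak + 1 so mode = peak
  shape_of <- function(tt) stats::dgamma(tt, shape = peak1 + 1, rate = 1) -
    stats::dgamma(tt, shape = peak2 + 1, rate = 1) / ratio
  shape_of(t) / shape_of(peak1)
}

## one boxcar-convolved HRF regressor per condition, sampled at TR
task_regressors <- function(events, N, TR, kernel_s = 32) {
  conds <- unique(as.character(events$condition))
  grid <- (seq_len(N) - 1) * TR
  kern_t <- seq(0, kernel_s, by = TR)
  kern <- canonical_hrf(kern_t)
  sapply(conds, function(cn) {
    ev <- events[events$condition == cn, , drop = FALSE]
    box <- numeric(N)
    for (r in seq_len(nrow(ev))) {
      on <- ev$onset[r]
      box <- box + as.numeric(grid >= on & grid < on + ev$duration[r])
    }
    conv <- stats::convolve(box, rev(kern), type = "open")[seq_len(N)]
    conv
  })
}

#' Remove task-evoked responses
#'
#' Builds one regressor per condition by convolving the stimulus boxcar
#' (onset, duration) with the canonical double-gamma HRF sampled at TR, and
#' removes the least-squares projection onto an intercept plus these
#' regressors. With an empty event table only the intercept (row mean) is
#' removed, with a message.
#'
#' @param series a `run_ts`.
#' @param events data frame with columns `onset` (s), `duration` (s),
#'   `condition`; onsets must lie within the run.
#' @return The cleaned `run_ts`.
#' @export
remove_task_evoked <- function(series, events) {
  stopifnot(inherits(series, "run_ts"))
  N <- ncol(series$data)
  if (is.null(events) || nrow(events) == 0L) {
    message("empty event table: removing intercept only")
    X <- matrix(1, N, 1)
  } else {
    if (any(events$onset < 0) || any(events$onset >= N * series$TR)) {
      stop("event onsets must lie within the run duration")
    }
    X <- cbind(1, task_regressors(events, N, series$TR))
  }
  update_run(series, project_out(series$data, X))
}

#' Normalise node time series to zero mean and unit variance
#'
#' Each row is centred and scaled by its population standard deviation
#' (the `1/N` convention), so that `(1/N) * sum(x^2) = 1`. Under this
#' convention the cross-product form of the ISFC estimator is an exact
#' Pearson correlation when target and reference coincide.
#'
#' @param series a `run_ts` with no constant row.
#' @return The normalised `run_ts` (`normalized = TRUE`).
#' @export
normalize_rows <- function(series) {
  stopifnot(inherits(series, "run_ts"))
  X <- series$data
  N <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  sd_pop <- sqrt(rowSums(Xc^2) / N)
  bad <- which(sd_pop == 0)
  if (length(bad) > 0L) {
    stop("constant time series at node(s): ", paste(bad, collapse = ", "))
  }
  update_run(series, Xc / sd_pop, normalized = TRUE)
}

#' Full signal-level cleaning chain
#'
#' Applies, in order: linear detrending, nuisance regression (with
#' derivatives), discrete-cosine high-pass filtering, removal of task-evoked
#' responses, and row normalisation. Steps with `NULL` inputs are skipped.
#'
#' @param series a `run_ts`.
#' @param confounds optional N x Q nuisance table.
#' @param events optional event table.
#' @param cutoff_hz high-pass cutoff in Hz; `NULL` skips filtering.
#' @param add_derivatives passed to [regress_confounds()].
#' @return The cleaned, normalised `run_ts`.
#' @export
clean_run <- function(series, confounds = NULL, events = NULL,
                      cutoff_hz = 0.08, add_derivatives = TRUE) {
  out <- detrend_linear(series)
  if (!is.null(confounds)) out <- regress_confounds(out, confounds, add_derivatives)
  if (!is.null(cutoff_hz)) out <- highpass_filter(out, cutoff_hz)
  if (!is.null(events)) out <- remove_task_evoked(out, events)
  normalize_rows(out)
}

#' Mean framewise displacement
#'
#' Summarises a 6-parameter rigid-body motion trace as the mean over frames
#' of the framewise displacement: the sum of absolute frame-to-frame
#' differences of the three translations (mm) plus the three rotations
#' (radians) converted to arc length on a sphere of radius `radius_mm`.
#'
#' @param motion N x 6 matrix: translations x, y, z in mm then rotations
#'   pitch, roll, yaw in radians; N >= 2.
#' @param radius_mm head radius for the rotation arc length; default 50 mm.
#' @return Mean framewise displacement in mm (scalar).
#' @export
mean_framewise_displacement <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop("motion table must have 6 columns, got ", ncol(motion))
  if (nrow(motion) < 2L) stop("motion table needs at least 2 frames")
  d <- abs(diff(motion))
  fd <- rowSums(d[, 1:3, drop = FALSE]) + rowSums(d[, 4:6, drop = FALSE]) * radius_mm
  mean(fd)
}

#' Average a subject's runs of one task
#'
#' Time-point-wise mean of several runs from the same subject and task;
#' the result is typically re-normalised with [normalize_rows()] before ISFC
#' estimation.
#'
#' @param runs list of `run_ts` from one subject, all with the same P and N.
#' @param task optional label; if given, all runs must carry it.
#' @return A `run_ts` holding the element-wise mean.
#' @export
average_task_runs <- function(runs, task = NULL) {
  if (length(runs) == 0L) stop("no runs to average")
  stopifnot(all(vapply(runs, inherits, logical(1), "run_ts")))
  dims <- vapply(runs, function(r) dim(r$data), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("runs differ in dimensions")
  }
  subs <- vapply(runs, function(r) as.character(r$subject_id), character(1))
  if (length(unique(subs)) > 1L) stop("runs come from different subjects")
  tasks <- vapply(runs, function(r) as.character(r$task), character(1))
  if (length(unique(tasks)) > 1L) stop("runs carry mixed task labels")
  if (!is.null(task) && !all(tasks == task)) stop("runs do not carry task '", task, "'")
  acc <- Reduce(`+`, lapply(runs, `[[`, "data")) / length(runs)
  run_ts(acc, TR = runs[[1]]$TR, subject_id = runs[[1]]$subject_id,
         run_id = "task-average", task = tasks[1])
}
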