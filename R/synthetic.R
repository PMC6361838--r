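## run code with a temporarily seeded RNG, restoring the caller's stream
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  force(code)
}

#' Configuration of the synthetic multi-subject generator
#'
#' Defines the study design emulated by [generate_dataset()]: K subjects each
#' completing `runs_per_task` runs of each of two attention tasks ("beh",
#' "tax"), with P atlas nodes observed over N time points at repetition time
#' TR. Signals decompose into a task-specific stimulus-locked component
#' shared across subjects, a subject-specific intrinsic component with
#' task-independent covariance, and unstructured noise.
#'
#' The defaults mirror a 12-subject, 5-runs-per-task design with 196 time
#' points at TR = 2 s (392 s runs), scaled to 60 nodes in 6 subnetworks, with
#' intrinsic fluctuations dominating the shared stimulus-locked signal
#' (`sigma_intrinsic > sigma_shared`) — the regime in which inter-subject
#' correlation methods outperform within-subject connectivity.
#'
#' @param K subjects (>= 1).
#' @param runs_per_task runs per task per subject.
#' @param P nodes.
#' @param N time points per run; defaults to `duration_s / TR`.
#' @param TR repetition time (s).
#' @param duration_s run length (s); used only to derive the default N.
#' @param L latent shared components per task.
#' @param L_int latent intrinsic components.
#' @param sigma_shared,sigma_intrinsic,sigma_noise standard deviations of the
#'   three signal components (arbitrary units).
#' @param n_networks subnetworks in the fixture atlas (contiguous node
#'   blocks).
#' @param intrinsic_idiosyncrasy weight w in [0, 1] of the subject-specific
#'   part of the intrinsic loading matrix: subject k uses
#'   `B_k = sqrt(1 - w^2) B + w E_k` with a common B and independent per-
#'   subject `E_k`, both task-independent. At w = 0 every subject shares one
#'   intrinsic covariance; at the default 0.8 intrinsic connectivity is
#'   mostly subject-idiosyncratic, the regime in which within-subject FC
#'   patterns transfer poorly across subjects while ISFC is unaffected.
#' @param ar lag-1 autocorrelation of the latent trajectories; 0 (default)
#'   gives white latents, for which the analytic covariance is exact.
#' @param seed RNG seed for [generate_dataset()].
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(K = 12, runs_per_task = 5, P = 60, N = NULL,
                             TR = 2, duration_s = 392, L = 5, L_int = 5,
                             sigma_shared = 0.25, sigma_intrinsic = 1.5,
                             sigma_noise = 1.0, n_networks = 6,
                             intrinsic_idiosyncrasy = 0.8, ar = 0,
                             seed = 1) {
  if (is.null(N)) N <- duration_s / TR
  counts <- c(K = K, runs_per_task = runs_per_task, P = P, N = N, L = L,
              L_int = L_int, n_networks = n_networks)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("K, runs_per_task, P, N, L, L_int and n_networks must be positive integers")
  }
  if (N <= L) stop("N must exceed L")
  if (P < n_networks) stop("P must be at least n_networks")
  sig <- c(sigma_shared, sigma_intrinsic, sigma_noise)
  if (any(!is.finite(sig)) || any(sig < 0)) stop("sigmas must be >= 0")
  if (abs(ar) >= 1) stop("ar must be in (-1, 1)")
  if (intrinsic_idiosyncrasy < 0 || intrinsic_idiosyncrasy > 1) {
    stop("intrinsic_idiosyncrasy must be in [0, 1]")
  }
  structure(list(K = as.integer(K), runs_per_task = as.integer(runs_per_task),
                 P = as.integer(P), N = as.integer(N), TR = TR, L = as.integer(L),
                 L_int = as.integer(L_int), sigma_shared = sigma_shared,
                 sigma_intrinsic = sigma_intrinsic, sigma_noise = sigma_noise,
                 n_networks = as.integer(n_networks),
                 intrinsic_idiosyncrasy = intrinsic_idiosyncrasy, ar = ar,
                 seed = as.integer(seed)),
            class = "generator_config")
}

## L x N latent trajectories, white or AR(1) with unit marginal variance
latent_traj <- function(L, N, ar) {
  E <- matrix(stats::rnorm(L * N), L, N)
  if (ar == 0) return(E)
  out <- E
  out[, 1] <- E[, 1]
  sc <- sqrt(1 - ar^2)
  for (t in 2:N) out[, t] <- ar * out[, t - 1] + sc * E[, t]
  out
}

## atlas fixture: P nodes in n_networks contiguous blocks
fixture_atlas <- function(P, n_networks) {
  sizes <- diff(round(seq(0, P, length.out = n_networks + 1)))
  labels <- rep(paste0("Net", seq_len(n_networks)), times = sizes)
  atlas(data.frame(node_id = seq_len(P),
                   x = round(stats::runif(P, -70, 70), 1),
                   y = round(stats::runif(P, -100, 70), 1),
                   z = round(stats::runif(P, -45, 75), 1),
                   network_label = labels),
        name = sprintf("synthetic-%dnode", P))
}

## block-structured loading matrix: component l loads only on nodes of
## network block ((l - 1 + shift) %% n_networks) + 1
block_loadings <- function(P, L, labels, n_networks, shift) {
  A <- matrix(0, P, L)
  nets <- paste0("Net", seq_len(n_networks))
  for (l in seq_len(L)) {
    b <- ((l - 1 + shift) %% n_networks) + 1
    rows <- which(labels == nets[b])
    A[rows, l] <- stats::rnorm(length(rows))
  }
  A
}

#' Generate a synthetic multi-subject, two-task dataset
#'
#' Node series for subject k, run r of task m are
#' `x(t) = sigma_shared * A_m s_mr(t) + sigma_intrinsic * B g_kr(t) +
#' sigma_noise * eps(t)`, where the stimulus-locked latent trajectories
#' `s_mr` are bit-identical across subjects for a given (task, run index) —
#' the alignment inter-subject correlation requires — the intrinsic latents
#' `g_kr` are independent across subjects with a task-independent loading
#' matrix `B_k` mixing a common and a subject-idiosyncratic part (see
#' `intrinsic_idiosyncrasy`), and `eps` is i.i.d. noise. The task loading matrices
#' `A_beh` and `A_tax` load on different subnetwork blocks of the fixture
#' atlas, so the edges that genuinely differ between tasks are known. B is
#' scaled so a node's expected intrinsic variance is `sigma_intrinsic^2`.
#' Rows are returned un-normalised.
#'
#' @param config a [generator_config()].
#' @return A `study_dataset` whose `ground_truth` field carries the loading
#'   matrices, the per-(task, run) latent trajectories, and the edge
#'   positions (diagonal-inclusive convention) where the task covariance
#'   structure differs.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  cfg <- config
  with_seed(cfg$seed, {
    atl <- fixture_atlas(cfg$P, cfg$n_networks)
    labels <- atl$network_label
    A_beh <- block_loadings(cfg$P, cfg$L, labels, cfg$n_networks, shift = 0)
    A_tax <- block_loadings(cfg$P, cfg$L, labels, cfg$n_networks, shift = 1)
    B <- matrix(stats::rnorm(cfg$P * cfg$L_int, sd = 1 / sqrt(cfg$L_int)),
                cfg$P, cfg$L_int)
    ## per-subject intrinsic loadings, identical across that subject's tasks
    ## and runs; at w = 0 all subjects share B
    w <- cfg$intrinsic_idiosyncrasy
    B_subj <- lapply(seq_len(cfg$K), function(k) {
      if (w == 0) return(B)
      Ek <- matrix(stats::rnorm(cfg$P * cfg$L_int, sd = 1 / sqrt(cfg$L_int)),
                   cfg$P, cfg$L_int)
      sqrt(1 - w^2) * B + w * Ek
    })
    tasks <- c("beh", "tax")
    ## shared latents: one trajectory per (task, run index), reused verbatim
    ## for every subject
    shared <- lapply(tasks, function(m)
      lapply(seq_len(cfg$runs_per_task), function(r)
        latent_traj(cfg$L, cfg$N, cfg$ar)))
    names(shared) <- tasks
    events <- data.frame(
      onset = seq(4, cfg$N * cfg$TR - 12, by = 8),
      duration = 2,
      condition = "clip")
    runs <- list()
    motion <- list()
    for (k in seq_len(cfg$K)) {
      for (m in tasks) {
        A_m <- if (m == "beh") A_beh else A_tax
        for (r in seq_len(cfg$runs_per_task)) {
          g <- latent_traj(cfg$L_int, cfg$N, cfg$ar)
          eps <- matrix(stats::rnorm(cfg$P * cfg$N), cfg$P, cfg$N)
          X <- cfg$sigma_shared * A_m %*% shared[[m]][[r]] +
            cfg$sigma_intrinsic * B_subj[[k]] %*% g +
            cfg$sigma_noise * eps
          id <- sprintf("sub%02d_%s%d", k, m, r)
          runs[[id]] <- run_ts(X, TR = cfg$TR, subject_id = sprintf("sub%02d", k),
                               run_id = sprintf("%s%d", m, r), task = m)
          motion[[id]] <- generate_motion(cfg$N, amplitude = 0.02)
        }
      }
    }
    D <- A_beh %*% t(A_beh) - A_tax %*% t(A_tax)
    idx <- edge_index(cfg$P, include_diagonal = TRUE)
    diff_edges <- which(abs(D[idx$lin]) > 1e-12)
    gt <- list(A_beh = A_beh, A_tax = A_tax, B = B, B_subject = B_subj,
               shared_latents = shared,
               diff_edges = diff_edges, edge_index = idx)
    study_dataset(runs, atlas = atl, events = events, motion = motion,
                  ground_truth = gt, config = cfg)
  })
}

#' Generate a synthetic 6-parameter motion trace
#'
#' A random walk in all six rigid-body parameters (translations in mm,
#' rotations in rad), starting at zero, with i.i.d. Gaussian steps of
#' standard deviation `amplitude`.
#'
#' @param N frames (>= 2).
#' @param amplitude step standard deviation; 0 gives an all-zero trace.
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return N x 6 matrix with columns `trans_x, trans_y, trans_z, rot_pitch,
#'   rot_roll, rot_yaw`.
#' @export
generate_motion <- function(N, amplitude = 0.05, seed = NULL) {
  if (N < 2) stop("motion trace needs N >= 2")
  gen <- function() {
    steps <- matrix(stats::rnorm(6 * (N - 1), sd = amplitude), N - 1, 6)
    out <- rbind(0, apply(steps, 2, cumsum))
    colnames(out) <- c("trans_x", "trans_y", "trans_z",
                       "rot_pitch", "rot_roll", "rot_yaw")
    out
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Expand node series to synthetic voxel series
#'
#' Copies each node's time series to `voxels_per_node` voxels with added
#' i.i.d. Gaussian noise, returning the voxel matrix and the voxel-to-node
#' label vector. [extract_node_series()] inverts the expansion exactly when
#' `sigma_voxel = 0`, and with noise the recovery error shrinks as
#' `1/sqrt(voxels_per_node)`.
#'
#' @param series a `run_ts`.
#' @param voxels_per_node voxels per node (>= 1).
#' @param sigma_voxel voxel noise standard deviation.
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return List with `voxels` ((P*voxels_per_node) x N matrix) and `labels`
#'   (node id per voxel row).
#' @export
expand_to_voxels <- function(series, voxels_per_node, sigma_voxel = 0,
                             seed = NULL) {
  stopifnot(inherits(series, "run_ts"))
  if (voxels_per_node < 1 || voxels_per_node != round(voxels_per_node)) {
    stop("voxels_per_node must be a positive integer")
  }
  gen <- function() {
    P <- nrow(series$data); N <- ncol(series$data)
    V <- P * voxels_per_node
    vox <- series$data[rep(seq_len(P), each = voxels_per_node), , drop = FALSE]
    if (sigma_voxel > 0) {
      vox <- vox + matrix(stats::rnorm(V * N, sd = sigma_voxel), V, N)
    }
    list(voxels = vox, labels = rep(seq_len(P), each = voxels_per_node))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}
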