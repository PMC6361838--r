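#' A labelled multi-subject study dataset
#'
#' The collection of all subjects' runs, each a [run_ts()] with subject, run
#' and task identifiers, plus optional atlas, event table, motion traces and
#' (for synthetic data) ground truth.
#'
#' @param runs named list of `run_ts`; every subject must have at least one
#'   run per task, and all runs must share P, N and TR.
#' @param atlas optional [atlas()].
#' @param events optional event table (onset, duration, condition) shared by
#'   all runs, or a per-run list.
#' @param motion optional per-run list of N x 6 motion matrices.
#' @param ground_truth optional generator ground truth.
#' @param config optional [generator_config()].
#' @param tasks ordered task labels; the first is the tie-break winner.
#' @return Object of class `study_dataset`.
#' @export
study_dataset <- function(runs, atlas = NULL, events = NULL, motion = NULL,
                          ground_truth = NULL, config = NULL,
                          tasks = c("beh", "tax")) {
  if (length(runs) == 0L) stop("dataset needs at least one run")
  stopifnot(all(vapply(runs, inherits, logical(1), "run_ts")))
  dims <- vapply(runs, function(r) dim(r$data), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all runs must share P and N")
  }
  subs <- vapply(runs, function(r) as.character(r$subject_id), character(1))
  labs <- vapply(runs, function(r) as.character(r$task), character(1))
  if (!all(labs %in% tasks)) {
    stop("run task labels outside ", paste(tasks, collapse = "/"))
  }
  for (s in unique(subs)) {
    have <- unique(labs[subs == s])
    if (!all(tasks %in% have)) {
      stop("subject ", s, " lacks runs for task(s): ",
           paste(setdiff(tasks, have), collapse = ", "))
    }
  }
  structure(list(runs = runs, atlas = atlas, events = events, motion = motion,
                 ground_truth = ground_truth, config = config, tasks = tasks,
                 subjects = unique(subs), K = length(unique(subs))),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  P <- nrow(x$runs[[1]]$data); N <- ncol(x$runs[[1]]$data)
  cat(sprintf("Study dataset: %d subjects, %d runs (%s), %d nodes x %d time points\n",
              x$K, length(x$runs),
              paste(sprintf("%s: %d", x$tasks,
                            vapply(x$tasks, function(m)
                              sum(task_labels(x) == m), integer(1))),
                    collapse = ", "),
              P, N))
  invisible(x)
}

#' Task labels of all runs, in dataset order
#'
#' @param dataset a `study_dataset`.
#' @return Character vector, one label per run.
#' @export
task_labels <- function(dataset) {
  vapply(dataset$runs, function(r) as.character(r$task), character(1))
}

run_subjects <- function(dataset) {
  vapply(dataset$runs, function(r) as.character(r$subject_id), character(1))
}

## restrict every run to columns start..start+n-1
crop_dataset <- function(dataset, start, n) {
  N <- ncol(dataset$runs[[1]]$data)
  if (start < 1 || start + n - 1 > N) stop("window outside the run")
  dataset$runs <- lapply(dataset$runs, function(r) {
    r$data <- r$data[, start:(start + n - 1), drop = FALSE]
    r$normalized <- FALSE
    r
  })
  dataset
}

## per-subject, per-task normalised task-average series under the given
## labels: out[[subject]][[task]] is a P x N matrix
task_average_series <- function(dataset, subjects, labels) {
  subs <- run_subjects(dataset)
  out <- list()
  for (s in subjects) {
    out[[s]] <- list()
    for (m in dataset$tasks) {
      sel <- which(subs == s & labels == m)
      if (length(sel) == 0L) stop("subject ", s, " has no '", m, "' runs under these labels")
      acc <- Reduce(`+`, lapply(dataset$runs[sel], `[[`, "data")) / length(sel)
      out[[s]][[m]] <- normalize_matrix(acc)
    }
  }
  out
}

## row-normalise a plain matrix (population sd), erroring on constant rows
normalize_matrix <- function(X) {
  N <- ncol(X)
  Xc <- X - rowMeans(X)
  sd_pop <- sqrt(rowSums(Xc^2) / N)
  if (any(sd_pop == 0)) {
    stop("constant time series at node(s): ", paste(which(sd_pop == 0), collapse = ", "))
  }
  Xc / sd_pop
}

## group ISFC from a list of normalised P x N matrices: each subject's raw
## cross-product against the leave-one-out mean, Fisher z, symmetrise, average
group_isfc_series <- function(series_list, clip = 1 - 1e-6) {
  Kg <- length(series_list)
  if (Kg < 2L) stop("group ISFC needs at least 2 subjects")
  N <- ncol(series_list[[1]])
  total <- Reduce(`+`, series_list)
  acc <- 0
  for (X in series_list) {
    ref <- (total - X) / (Kg - 1)
    C <- fisher_z(tcrossprod(X, ref) / N, clip = clip)
    acc <- acc + (C + t(C)) / 2
  }
  acc / Kg
}

#' Build per-task classification templates from a training set
#'
#' For ISFC templates, each training subject's runs are averaged per task and
#' row-normalised, each subject's ISFC is computed against the leave-one-out
#' mean of the other training subjects' series, Fisher z-transformed and
#' symmetrised, and the per-subject matrices are averaged into the group
#' template. The across-training-subject mean normalised series per task is
#' stored as the reference against which test runs are correlated. For FC
#' templates, per-run correlation matrices are averaged within subject per
#' task and then across subjects (raw r).
#'
#' @param training a `study_dataset` containing only training subjects (the
#'   held-out subject's data must not appear).
#' @param mode `"isfc"` or `"fc"`.
#' @param labels optional task-label override (one per run), used by
#'   permutation tests.
#' @return Object of class `template_set` with fields `templates` (per-task
#'   `conn_matrix`), `references` (per-task mean normalised series, ISFC
#'   only) and `training_subjects`.
#' @export
build_templates <- function(training, mode = c("isfc", "fc"), labels = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(training, "study_dataset"))
  if (is.null(labels)) labels <- task_labels(training)
  subs <- training$subjects
  if (mode == "isfc" && length(subs) < 2L) {
    stop("ISFC templates need at least 2 training subjects")
  }
  templates <- list(); references <- list()
  if (mode == "isfc") {
    avg <- task_average_series(training, subs, labels)
    for (m in training$tasks) {
      series <- lapply(avg, `[[`, m)
      templates[[m]] <- new_conn_matrix(group_isfc_series(series),
                                        kind = "isfc", fisher_z = TRUE,
                                        symmetric = TRUE,
                                        provenance = list(task = m, template = TRUE))
      references[[m]] <- Reduce(`+`, series) / length(series)
    }
  } else {
    rsubs <- run_subjects(training)
    for (m in training$tasks) {
      per_subject <- lapply(subs, function(s) {
        sel <- which(rsubs == s & labels == m)
        if (length(sel) == 0L) stop("subject ", s, " has no '", m, "' runs under these labels")
        mats <- lapply(training$runs[sel], function(r) fc_matrix(r)$values)
        Reduce(`+`, mats) / length(mats)
      })
      templates[[m]] <- new_conn_matrix(Reduce(`+`, per_subject) / length(per_subject),
                                        kind = "fc", fisher_z = FALSE,
                                        symmetric = TRUE,
                                        provenance = list(task = m, template = TRUE))
      references[[m]] <- NULL
    }
  }
  structure(list(templates = templates, references = references,
                 training_subjects = subs, mode = mode,
                 tasks = training$tasks),
            class = "template_set")
}

#' @export
print.template_set <- function(x, ...) {
  cat(sprintf("Template set (%s): tasks %s, %d training subjects\n", x$mode,
              paste(x$tasks, collapse = "/"), length(x$training_subjects)))
  invisible(x)
}

## argmax over task scores with deterministic tie-break to the first task
pick_task <- function(scores, tasks, warn = TRUE) {
  best <- which(scores == max(scores))
  if (length(best) > 1L) {
    if (warn) warning("tied template scores; choosing '", tasks[1], "'")
    best <- best[1]
  }
  tasks[best]
}

#' Classify a single run by template matching
#'
#' In ISFC mode the run is row-normalised, its ISFC matrix against each
#' task's training reference series is computed (Fisher z, symmetrised), and
#' the run is assigned the task whose template correlates most strongly with
#' that matrix. In FC mode the run's within-subject correlation matrix is
#' compared with the FC templates. Exactly tied scores go to the first task
#' in canonical order, with a warning.
#'
#' @param run a `run_ts` from a subject not in the training set.
#' @param templates a [build_templates()] result.
#' @param subset optional edge positions restricting the comparison; at least
#'   3 edges.
#' @param index optional [edge_index()]; defaults to all edges with diagonal.
#' @return Predicted task label (character scalar) with attribute `scores`.
#' @export
classify_run <- function(run, templates, subset = NULL, index = NULL) {
  stopifnot(inherits(run, "run_ts"), inherits(templates, "template_set"))
  if (as.character(run$subject_id) %in% templates$training_subjects) {
    stop("run's subject is in the training set; leave-one-subject-out violated")
  }
  if (!is.null(subset) && length(subset) < 3L) {
    stop("edge subset must contain at least 3 edges")
  }
  tasks <- templates$tasks
  scores <- numeric(length(tasks)); names(scores) <- tasks
  if (templates$mode == "isfc") {
    Xn <- run_ts(normalize_matrix(run$data), TR = run$TR,
                 subject_id = run$subject_id, run_id = run$run_id,
                 task = run$task, normalized = TRUE)
    for (m in tasks) {
      Cm <- isfc_matrix(Xn, templates$references[[m]])
      scores[m] <- matrix_similarity(Cm, templates$templates[[m]],
                                     subset = subset, index = index)
    }
  } else {
    Cr <- fc_matrix(run)
    for (m in tasks) {
      scores[m] <- matrix_similarity(Cr, templates$templates[[m]],
                                     subset = subset, index = index)
    }
  }
  structure(pick_task(scores, tasks), scores = scores)
}

## Precompute, per LOSOCV fold, the vectorised templates and per-test-run
## candidate matrices so that accuracies over many edge subsets (subnetwork
## cells, discriminative maps) reuse one pass of matrix algebra.
losocv_artifacts <- function(dataset, mode = c("isfc", "fc"), labels = NULL,
                             index = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(dataset, "study_dataset"))
  if (dataset$K < 3L) stop("LOSOCV needs at least 3 subjects")
  if (is.null(labels)) labels <- task_labels(dataset)
  P <- nrow(dataset$runs[[1]]$data)
  if (is.null(index)) index <- edge_index(P, include_diagonal = TRUE)
  subs <- run_subjects(dataset)
  tasks <- dataset$tasks
  folds <- vector("list", dataset$K)
  names(folds) <- dataset$subjects
  for (s in dataset$subjects) {
    train_sel <- which(subs != s)
    training <- dataset
    training$runs <- dataset$runs[train_sel]
    training$subjects <- setdiff(dataset$subjects, s)
    training$K <- length(training$subjects)
    tset <- build_templates(training, mode = mode, labels = labels[train_sel])
    tmpl_vecs <- sapply(tasks, function(m)
      tset$templates[[m]]$values[index$lin])
    test_sel <- which(subs == s)
    test_runs <- lapply(test_sel, function(ri) {
      r <- dataset$runs[[ri]]
      if (mode == "isfc") {
        Xn <- normalize_matrix(r$data)
        vecs <- sapply(tasks, function(m) {
          C <- fisher_z(tcrossprod(Xn, tset$references[[m]]) / ncol(Xn))
          C <- (C + t(C)) / 2
          C[index$lin]
        })
      } else {
        C <- fc_matrix(r)$values
        vecs <- matrix(C[index$lin], ncol = 1)
      }
      list(run_id = r$run_id, true = labels[ri], vecs = vecs)
    })
    folds[[s]] <- list(subject = s, templates = tmpl_vecs, test = test_runs)
  }
  list(folds = folds, index = index, mode = mode, tasks = tasks)
}

## predictions for one edge subset from precomputed artifacts
predict_from_artifacts <- function(art, subset = NULL, warn_ties = FALSE) {
  tasks <- art$tasks
  rows <- list()
  for (f in art$folds) {
    tmpl <- if (is.null(subset)) f$templates else f$templates[subset, , drop = FALSE]
    for (tr in f$test) {
      vecs <- if (is.null(subset)) tr$vecs else tr$vecs[subset, , drop = FALSE]
      scores <- vapply(seq_along(tasks), function(mi) {
        v <- vecs[, min(mi, ncol(vecs))]
        stats::cor(v, tmpl[, mi])
      }, numeric(1))
      names(scores) <- tasks
      rows[[length(rows) + 1L]] <- data.frame(
        subject = f$subject, run_id = tr$run_id, true = tr$true,
        predicted = pick_task(scores, tasks, warn = warn_ties),
        score_beh = scores[1], score_tax = scores[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## population z-score of an edge vector
zscore_edges <- function(v) {
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2))
  if (s == 0) stop("constant edge vector cannot be z-normalized")
  (v - mu) / s
}

## per-edge discriminative binaries aggregated over all (run, fold) instances
phi_from_artifacts <- function(art, subset = NULL) {
  tasks <- art$tasks
  E <- if (is.null(subset)) art$index$n_edges else length(subset)
  acc <- numeric(E); count <- 0L
  for (f in art$folds) {
    tmpl <- if (is.null(subset)) f$templates else f$templates[subset, , drop = FALSE]
    tz <- apply(tmpl, 2, zscore_edges)
    for (tr in f$test) {
      vecs <- if (is.null(subset)) tr$vecs else tr$vecs[subset, , drop = FALSE]
      mi <- match(tr$true, tasks)
      v <- zscore_edges(vecs[, min(mi, ncol(vecs))])
      ui <- if (mi == 1L) 2L else 1L
      acc <- acc + as.numeric(tz[, mi] * v > tz[, ui] * v)
      count <- count + 1L
    }
  }
  new_discriminative_map(acc / count, counts = count, index = art$index,
                         subset = subset)
}

#' Leave-one-subject-out template-matching classification
#'
#' The central decoding procedure: for each fold, one subject's runs are held
#' out, per-task templates are built from the remaining subjects
#' ([build_templates()]), and every held-out run is assigned the task whose
#' template its connectivity pattern matches best. Accuracy is the fraction
#' of runs assigned their correct task over all folds.
#'
#' @param dataset a `study_dataset` with at least 3 subjects.
#' @param mode `"isfc"` (inter-subject correlation patterns) or `"fc"`
#'   (within-subject correlation patterns).
#' @param subset optional edge positions restricting the template comparison.
#' @param index optional [edge_index()]; defaults to all edges with diagonal.
#' @param discriminative also aggregate the per-edge discriminative map
#'   (fraction of (run, fold) instances in which the edge's product with the
#'   correct-task template exceeds its product with the other template)?
#' @param labels optional task-label override (one per run, dataset order);
#'   used by permutation tests.
#' @return Object of class `isfc_losocv`: predictions data frame, overall
#'   `accuracy`, `per_subject` accuracies, and optionally `phi` (a
#'   `discriminative_map`).
#' @export
losocv <- function(dataset, mode = c("isfc", "fc"), subset = NULL,
                   index = NULL, discriminative = FALSE, labels = NULL) {
  mode <- match.arg(mode)
  if (!is.null(subset) && length(subset) < 3L) {
    stop("edge subset must contain at least 3 edges")
  }
  art <- losocv_artifacts(dataset, mode = mode, labels = labels, index = index)
  preds <- predict_from_artifacts(art, subset = subset, warn_ties = TRUE)
  per_subject <- tapply(preds$predicted == preds$true, preds$subject, mean)
  out <- structure(list(predictions = preds,
                        accuracy = mean(preds$predicted == preds$true),
                        per_subject = per_subject[dataset$subjects],
                        mode = mode, K = dataset$K,
                        n_edges_used = if (is.null(subset)) art$index$n_edges else length(subset),
                        phi = NULL),
                   class = "isfc_losocv")
  if (discriminative) out$phi <- phi_from_artifacts(art, subset = subset)
  out
}

#' @export
print.isfc_losocv <- function(x, ...) {
  cat(sprintf("LOSOCV template matching (%s): accuracy %.2f%% over %d runs (%d folds)\n",
              x$mode, 100 * x$accuracy, nrow(x$predictions), x$K))
  invisible(x)
}

#' @export
summary.isfc_losocv <- function(object, ...) {
  cat(sprintf("Leave-one-subject-out template matching, mode = %s\n", object$mode))
  cat(sprintf("  runs: %d   folds: %d   edges used: %d\n",
              nrow(object$predictions), object$K, object$n_edges_used))
  cat(sprintf("  overall accuracy: %.2f%%\n", 100 * object$accuracy))
  cat("  per-subject accuracy:\n")
  print(round(object$per_subject, 3))
  tab <- table(true = object$predictions$true,
               predicted = object$predictions$predicted)
  cat("  confusion:\n")
  print(tab)
  invisible(object)
}

#' Group-split similarity analysis
#'
#' Splits the subjects into all unordered pairs of complementary half-groups,
#' computes each half's group ISFC per task from the subjects' normalised
#' task-averaged series, and records for every split the mean within-task
#' similarity (group 1 vs group 2, same task) and mean between-task
#' similarity (crossed tasks). If task context modulates connectivity,
#' within-task similarity exceeds between-task similarity.
#'
#' @param dataset a `study_dataset` with an even number of subjects (>= 4).
#' @param index optional [edge_index()].
#' @return Object of class `similarity_table`: data frame with one row per
#'   split (`within`, `between`), with mean values as attributes. For K
#'   subjects there are `choose(K, K/2)/2` rows (462 for K = 12).
#' @export
similarity_analysis <- function(dataset, index = NULL) {
  stopifnot(inherits(dataset, "study_dataset"))
  K <- dataset$K
  if (K %% 2L != 0L) stop("similarity analysis needs an even subject count")
  if (K < 4L) stop("similarity analysis needs at least 4 subjects")
  P <- nrow(dataset$runs[[1]]$data)
  if (is.null(index)) index <- edge_index(P, include_diagonal = TRUE)
  labels <- task_labels(dataset)
  avg <- task_average_series(dataset, dataset$subjects, labels)
  tasks <- dataset$tasks
  half <- K %/% 2L
  ## fixing subject 1 in group 1 enumerates each unordered complementary
  ## split exactly once: choose(K-1, half-1) splits
  others <- dataset$subjects[-1]
  combos <- utils::combn(others, half - 1L)
  n_split <- ncol(combos)
  within <- numeric(n_split); between <- numeric(n_split)
  for (sp in seq_len(n_split)) {
    g1 <- c(dataset$subjects[1], combos[, sp])
    g2 <- setdiff(dataset$subjects, g1)
    gvec <- list()
    for (g_id in 1:2) {
      g <- if (g_id == 1) g1 else g2
      for (m in tasks) {
        G <- group_isfc_series(lapply(avg[g], `[[`, m))
        gvec[[paste(g_id, m)]] <- G[index$lin]
      }
    }
    within[sp] <- mean(c(stats::cor(gvec[["1 beh"]], gvec[["2 beh"]]),
                         stats::cor(gvec[["1 tax"]], gvec[["2 tax"]])))
    between[sp] <- mean(c(stats::cor(gvec[["1 beh"]], gvec[["2 tax"]]),
                          stats::cor(gvec[["1 tax"]], gvec[["2 beh"]])))
  }
  out <- data.frame(split = seq_len(n_split), within = within, between = between)
  structure(out, mean_within = mean(within), mean_between = mean(between),
            class = c("similarity_table", "data.frame"))
}

#' @export
print.similarity_table <- function(x, ...) {
  cat(sprintf("Similarity analysis: %d group splits\n", nrow(x)))
  cat(sprintf("  mean within-task:  %.4f\n", attr(x, "mean_within")))
  cat(sprintf("  mean between-task: %.4f\n", attr(x, "mean_between")))
  invisible(x)
}

#' Subnetwork-restricted classification
#'
#' Repeats the LOSOCV template matching using only the edges within one
#' subnetwork (diagonal cells) or between one pair of subnetworks
#' (off-diagonal cells), yielding a symmetric accuracy matrix over
#' subnetworks, plus each network's mean accuracy over its across-network
#' cells. Cells whose edge subset has fewer than 3 edges are `NA`.
#'
#' @param dataset a `study_dataset`.
#' @param atlas an [atlas()]; defaults to the dataset's own.
#' @param mode `"isfc"` or `"fc"`.
#' @param labels optional task-label override (permutation tests).
#' @return Object of class `subnet_accuracy`: `accuracy` (networks x
#'   networks matrix), `across_mean` (per network, off-diagonal cells only)
#'   and `networks`.
#' @export
subnetwork_classification <- function(dataset, atlas = NULL,
                                      mode = c("isfc", "fc"), labels = NULL) {
  mode <- match.arg(mode)
  if (is.null(atlas)) atlas <- dataset$atlas
  if (is.null(atlas)) stop("no atlas supplied and the dataset carries none")
  P <- nrow(dataset$runs[[1]]$data)
  if (nrow(atlas) != P) stop("atlas node count does not match the data")
  index <- edge_index(P, include_diagonal = TRUE)
  art <- losocv_artifacts(dataset, mode = mode, labels = labels, index = index)
  nets <- networks(atlas)
  n <- length(nets)
  accm <- matrix(NA_real_, n, n, dimnames = list(nets, nets))
  for (a in seq_len(n)) {
    for (b in a:n) {
      sub <- edge_subset(atlas, index,
                         nets[a], if (b == a) NULL else nets[b])
      if (length(sub) < 3L) next
      preds <- predict_from_artifacts(art, subset = sub)
      accm[a, b] <- accm[b, a] <- mean(preds$predicted == preds$true)
    }
  }
  across <- vapply(seq_len(n), function(a)
    mean(accm[a, -a], na.rm = TRUE), numeric(1))
  names(across) <- nets
  structure(list(accuracy = accm, across_mean = across, networks = nets,
                 mode = mode),
            class = "subnet_accuracy")
}

#' @export
print.subnet_accuracy <- function(x, ...) {
  cat(sprintf("Subnetwork classification accuracy (%s):\n", x$mode))
  print(round(x$accuracy, 3))
  cat("mean across-network accuracy per network:\n")
  print(round(x$across_mean, 3))
  invisible(x)
}

#' Effect of scan length on classification accuracy
#'
#' For each window length n, a random start point is drawn per repetition and
#' the same n-point window is applied to every run of every subject — the
#' shared window preserves the inter-subject temporal alignment that ISFC
#' requires — before re-running the full LOSOCV. Reported accuracy per
#' length is the mean over repetitions.
#'
#' @param dataset a `study_dataset`.
#' @param lengths window lengths in time points; all must be at most N.
#' @param reps repetitions (random window draws) per length.
#' @param seed optional seed for the window draws.
#' @param mode `"isfc"` (default) or `"fc"`.
#' @return Object of class `scanlength_result`: `accuracy` (reps x lengths
#'   matrix), `mean_accuracy` per length, `lengths`, `starts`.
#' @export
scanlength_analysis <- function(dataset, lengths = seq(20, 180, by = 10),
                                reps = 10, seed = NULL,
                                mode = c("isfc", "fc")) {
  mode <- match.arg(mode)
  N <- ncol(dataset$runs[[1]]$data)
  if (max(lengths) > N) {
    stop("window length ", max(lengths), " exceeds the run length ", N)
  }
  run_all <- function() {
    accs <- matrix(NA_real_, reps, length(lengths),
                   dimnames = list(NULL, lengths))
    starts <- matrix(NA_integer_, reps, length(lengths),
                     dimnames = list(NULL, lengths))
    for (li in seq_along(lengths)) {
      n <- lengths[li]
      for (rep_i in seq_len(reps)) {
        s <- sample.int(N - n + 1L, 1L)
        starts[rep_i, li] <- s
        cropped <- crop_dataset(dataset, s, n)
        accs[rep_i, li] <- losocv(cropped, mode = mode)$accuracy
      }
    }
    list(accs = accs, starts = starts)
  }
  res <- if (is.null(seed)) run_all() else with_seed(seed, run_all())
  structure(list(accuracy = res$accs,
                 mean_accuracy = colMeans(res$accs),
                 lengths = lengths, starts = res$starts, mode = mode),
            class = "scanlength_result")
}

#' @export
print.scanlength_result <- function(x, ...) {
  cat(sprintf("Scan-length analysis (%s), %d repetitions:\n", x$mode,
              nrow(x$accuracy)))
  print(round(x$mean_accuracy, 3))
  invisible(x)
}

#' @export
plot.scanlength_result <- function(x, ...) {
  graphics::plot(x$lengths, x$mean_accuracy, type = "b", pch = 16,
                 xlab = "time points used", ylab = "mean accuracy",
                 ylim = c(0.4, 1), ...)
  graphics::abline(h = 0.5, lty = 2)
  invisible(x)
}
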