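new_discriminative_map <- function(phi, counts, index, subset = NULL) {
  structure(list(phi = phi, counts = counts, index = index, subset = subset),
            class = "discriminative_map")
}

#' @export
print.discriminative_map <- function(x, ...) {
  cat(sprintf("Discriminative map: %d edges, %d (run, fold) instances, phi in [%.3f, %.3f]\n",
              length(x$phi), x$counts, min(x$phi), max(x$phi)))
  invisible(x)
}

#' Per-edge discriminative comparison for one classified run
#'
#' The correlation between two z-normalised edge vectors is the mean of their
#' element-wise products, so each edge's product measures its contribution to
#' the template match. An edge is scored 1 for this (run, fold) instance if
#' its product with the correct-task template strictly exceeds its product
#' with the other task's template, and 0 otherwise (ties score 0).
#'
#' @param test_vec edge vector of the run's connectivity matrix for its true
#'   task, z-normalised across edges (mean 0, unit variance).
#' @param template_vecs named list (or 2-column matrix) of the per-task
#'   template edge vectors, each z-normalised across edges.
#' @param true_task the run's task label; must name one template.
#' @param tol tolerance for the normalisation check.
#' @return Binary vector over edges.
#' @export
run_discriminative <- function(test_vec, template_vecs, true_task,
                               tol = 1e-6) {
  if (is.matrix(template_vecs)) {
    template_vecs <- lapply(seq_len(ncol(template_vecs)),
                            function(i) template_vecs[, i]) |>
      stats::setNames(colnames(template_vecs))
  }
  if (!true_task %in% names(template_vecs)) {
    stop("true_task '", true_task, "' does not name a template")
  }
  check_norm <- function(v, what) {
    if (abs(mean(v)) > tol || abs(mean(v^2) - 1) > tol) {
      stop(what, " is not z-normalized (zero mean, unit variance)")
    }
  }
  check_norm(test_vec, "test_vec")
  for (nm in names(template_vecs)) check_norm(template_vecs[[nm]], paste("template", nm))
  other <- setdiff(names(template_vecs), true_task)
  if (length(other) != 1L) stop("exactly two templates are required")
  within <- template_vecs[[true_task]] * test_vec
  between <- template_vecs[[other]] * test_vec
  as.numeric(within > between)
}

#' Aggregate discriminative binaries into a map
#'
#' Element-wise mean of the per-(run, fold) binary vectors; the resulting
#' phi(e) in [0, 1] is the fraction of classification instances in which edge
#' e favoured the correct task.
#'
#' @param binaries non-empty list of equal-length binary vectors.
#' @param index optional [edge_index()] recorded on the map.
#' @return A `discriminative_map`.
#' @export
aggregate_phi <- function(binaries, index = NULL) {
  if (length(binaries) == 0L) stop("no binary vectors to aggregate")
  lens <- lengths(binaries)
  if (any(lens != lens[1])) stop("binary vectors differ in length")
  phi <- Reduce(`+`, binaries) / length(binaries)
  new_discriminative_map(phi, counts = length(binaries), index = index)
}

#' Discriminative map of a dataset
#'
#' Convenience wrapper: runs the full LOSOCV with discriminative aggregation
#' and returns the per-edge map.
#'
#' @param dataset a `study_dataset`.
#' @param mode `"isfc"` or `"fc"`.
#' @param labels optional label override (permutations).
#' @return A `discriminative_map`.
#' @export
discriminative_map <- function(dataset, mode = "isfc", labels = NULL) {
  losocv(dataset, mode = mode, discriminative = TRUE, labels = labels)$phi
}

## nearest-rank empirical quantile: the ceil(q * n)-th order statistic
nearest_rank_quantile <- function(x, q) {
  sort(x)[max(1L, ceiling(q * length(x)))]
}

#' Select discriminative edges against a max-statistic null
#'
#' An edge is selected when its observed phi strictly exceeds the
#' `(1 - alpha)` empirical quantile (nearest-rank rule) of the null
#' distribution of the maximum phi over all edges, giving family-wise error
#' control at level alpha.
#'
#' @param map a `discriminative_map`.
#' @param null_maxima numeric vector of per-permutation maxima (see
#'   [label_permutation_test()] with `max_statistic = TRUE`), or a
#'   `null_distribution`.
#' @param alpha significance level in (0, 1); default 0.05.
#' @return Integer vector of selected edge positions, with the threshold as
#'   attribute `threshold`.
#' @export
select_edges <- function(map, null_maxima, alpha = 0.05) {
  stopifnot(inherits(map, "discriminative_map"))
  if (inherits(null_maxima, "null_distribution")) null_maxima <- null_maxima$samples
  if (length(null_maxima) == 0L) stop("empty null distribution")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  thr <- nearest_rank_quantile(null_maxima, 1 - alpha)
  structure(which(map$phi > thr), threshold = thr)
}
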