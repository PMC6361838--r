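#' Container for a permutation null distribution
#'
#' @param samples numeric vector of the statistic under permutation.
#' @param statistic_name short description of the statistic.
#' @param scheme description of the permutation scheme.
#' @param seed seed used to generate the samples, if any.
#' @return Object of class `null_distribution`.
#' @export
null_distribution <- function(samples, statistic_name = "statistic",
                              scheme = "permutation", seed = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L || any(!is.finite(samples))) {
    stop("null samples must be a non-empty finite vector")
  }
  structure(list(samples = samples, n_perm = length(samples),
                 statistic_name = statistic_name, scheme = scheme,
                 seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("Null distribution of %s: %d permutations (%s)\n",
              x$statistic_name, x$n_perm, x$scheme))
  cat(sprintf("  range [%.4f, %.4f], mean %.4f\n",
              min(x$samples), max(x$samples), mean(x$samples)))
  invisible(x)
}

#' One-sided permutation p-value
#'
#' The fraction of null samples greater than or equal to the observed
#' statistic, floored at `1/n_perm` so the smallest reportable p-value with
#' 1000 permutations is 0.001.
#'
#' @param observed observed statistic (scalar).
#' @param null a `null_distribution` or numeric vector of null samples.
#' @return p-value in `[1/n_perm, 1]`.
#' @export
pvalue_from_null <- function(observed, null) {
  if (inherits(null, "null_distribution")) null <- null$samples
  if (length(null) == 0L) stop("empty null distribution")
  max(sum(null >= observed), 1L) / length(null)
}

#' Permutation test of the within- vs between-task similarity difference
#'
#' Pools the within-task and between-task similarity values, repeatedly
#' splits the pool at random into two equal halves, and takes the difference
#' of the half-means as the null statistic. The observed statistic is
#' `mean(within) - mean(between)`.
#'
#' @param within,between equal-length numeric vectors (one value per group
#'   split, see [similarity_analysis()]).
#' @param n_perm permutations; default 1000.
#' @param seed optional seed.
#' @return Object of class `permutation_result`: `observed`, `null`
#'   (a `null_distribution`) and `p_value`.
#' @export
similarity_permutation_test <- function(within, between, n_perm = 1000,
                                        seed = NULL) {
  if (length(within) != length(between)) {
    stop("within and between must have equal length")
  }
  if (n_perm < 1) stop("n_perm must be at least 1")
  observed <- mean(within) - mean(between)
  pool <- c(within, between)
  n <- length(within)
  draw <- function() {
    vapply(seq_len(n_perm), function(i) {
      pick <- sample.int(2L * n, n)
      mean(pool[pick]) - mean(pool[-pick])
    }, numeric(1))
  }
  samples <- if (is.null(seed)) draw() else with_seed(seed, draw())
  null <- null_distribution(samples, "mean(within) - mean(between)",
                            scheme = "pooled equal resplit", seed = seed)
  structure(list(observed = observed, null = null,
                 p_value = pvalue_from_null(observed, null)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Permutation test of %s\n", x$null$statistic_name))
  cat(sprintf("  observed %.4f, p = %.4g (%d permutations)\n",
              x$observed, x$p_value, x$null$n_perm))
  invisible(x)
}

#' Label-permutation test of a classification analysis
#'
#' Shuffles the task labels of all runs (globally by default, or within
#' subject), re-runs the supplied analysis on the permuted labels, and builds
#' the null distribution of the resulting statistic. When the analysis
#' yields a vector of statistics (one per subnetwork cell, scan length or
#' edge) and `max_statistic = TRUE`, the per-permutation maximum forms a
#' single shared null, giving family-wise error control: each observed
#' statistic is compared against the null of the maximum.
#'
#' @param dataset a `study_dataset`.
#' @param analysis function `(dataset, labels) -> statistic` (scalar or
#'   vector); must be deterministic given data and labels. Called once with
#'   the true labels to obtain the observed statistic(s).
#' @param n_perm permutations; default 1000.
#' @param seed optional seed.
#' @param max_statistic collapse vector-valued statistics to their maximum
#'   per permutation?
#' @param scheme `"global"` shuffles all run labels jointly; `"within_subject"`
#'   shuffles each subject's labels separately (keeps per-subject balance).
#' @return For scalar statistics, a `permutation_result`. For vector
#'   statistics with `max_statistic = TRUE`, a `permutation_result` whose
#'   `observed` is the vector and whose `p_value` is a vector of per-element
#'   p-values against the shared max-null.
#' @export
label_permutation_test <- function(dataset, analysis, n_perm = 1000,
                                   seed = NULL, max_statistic = FALSE,
                                   scheme = c("global", "within_subject")) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be at least 1")
  labels <- task_labels(dataset)
  subs <- run_subjects(dataset)
  observed <- analysis(dataset, labels)
  tasks <- unique(labels)
  valid <- function(lab) {
    for (s in unique(subs)) {
      if (!all(tasks %in% lab[subs == s])) return(FALSE)
    }
    TRUE
  }
  shuffle <- function() {
    if (scheme == "global") {
      ## a global shuffle can strand a subject without any run of one task,
      ## leaving its template undefined; redraw until every subject keeps at
      ## least one run per task
      for (try in seq_len(1000L)) {
        lab <- sample(labels)
        if (valid(lab)) return(lab)
      }
      stop("could not draw a valid global label permutation")
    } else {
      out <- labels
      for (s in unique(subs)) {
        sel <- which(subs == s)
        out[sel] <- sample(labels[sel])
      }
      out
    }
  }
  run_perms <- function() {
    vapply(seq_len(n_perm), function(i) {
      stat <- analysis(dataset, shuffle())
      if (max_statistic) max(stat) else {
        if (length(stat) != 1L) {
          stop("analysis returned a vector; set max_statistic = TRUE")
        }
        stat
      }
    }, numeric(1))
  }
  samples <- if (is.null(seed)) run_perms() else with_seed(seed, run_perms())
  null <- null_distribution(
    samples,
    statistic_name = if (max_statistic) "max statistic" else "statistic",
    scheme = paste0(scheme, " label permutation"), seed = seed)
  p <- vapply(observed, pvalue_from_null, numeric(1), null = null)
  structure(list(observed = observed, null = null, p_value = p),
            class = "permutation_result")
}
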