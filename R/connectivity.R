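#' Fisher r-to-z transformation
#'
#' `atanh` of the correlation, with the argument clamped to `[-clip, clip]`
#' so that values at exactly +/-1 (e.g. the self-correlation diagonal when
#' target and reference coincide) stay finite.
#'
#' @param r correlation value(s); must be finite.
#' @param clip clamp magnitude, default `1 - 1e-6`.
#' @return z value(s), `atanh(pmin(pmax(r, -clip), clip))`.
#' @export
fisher_z <- function(r, clip = 1 - 1e-6) {
  if (any(!is.finite(r))) stop("fisher_z needs finite input")
  atanh(pmin(pmax(r, -clip), clip))
}

new_conn_matrix <- function(values, kind, fisher_z, symmetric, provenance = NULL) {
  structure(list(values = unname(values), kind = kind, fisher_z = fisher_z,
                 symmetric = symmetric, provenance = provenance),
            class = "conn_matrix")
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("%s matrix: %d x %d, %s, %s\n", toupper(x$kind),
              nrow(x$values), ncol(x$values),
              if (x$fisher_z) "Fisher z" else "raw r",
              if (x$symmetric) "symmetric" else "asymmetric"))
  invisible(x)
}

#' @export
dim.conn_matrix <- function(x) dim(x$values)

#' @export
as.matrix.conn_matrix <- function(x, ...) x$values

conn_values <- function(x) {
  if (inherits(x, "conn_matrix")) x$values else as.matrix(x)
}

#' Inter-subject functional correlation matrix
#'
#' The ISFC of a subject against a reference is the cross-correlation matrix
#' between the subject's normalised node time series and the average series
#' of the other subjects: element (i, j) of the raw matrix is
#' `(1/N) * sum_t x_i(t) * xbar_j(t)`, i.e. the correlation between node i of
#' the target and node j of the reference. Because the reference is itself an
#' average, its rows do not have unit variance, so the literal cross-product
#' is a damped correlation; `renormalize_reference = TRUE` rescales the
#' reference rows first, yielding exact Pearson correlations. The raw matrix
#' is Fisher z-transformed element-wise and then symmetrised as
#' `(C + t(C))/2`.
#'
#' @param target a normalised `run_ts` ([normalize_rows()]).
#' @param reference a `run_ts` (or P x N matrix) with the same dimensions,
#'   typically the mean of the other subjects' normalised series.
#' @param renormalize_reference rescale reference rows to unit variance
#'   before the product? Default `FALSE` (the literal cross-product form).
#' @param apply_fisher,symmetrize stages of the standard pipeline; both
#'   default `TRUE`.
#' @param clip Fisher clamp, see [fisher_z()].
#' @return A `conn_matrix` of kind `"isfc"`.
#' @export
isfc_matrix <- function(target, reference, renormalize_reference = FALSE,
                        apply_fisher = TRUE, symmetrize = TRUE,
                        clip = 1 - 1e-6) {
  stopifnot(inherits(target, "run_ts"))
  if (!isTRUE(target$normalized)) {
    stop("target must be normalized (see normalize_rows())")
  }
  X <- target$data
  R <- if (inherits(reference, "run_ts")) reference$data else as.matrix(reference)
  if (!all(dim(X) == dim(R))) {
    stop("target is ", paste(dim(X), collapse = "x"), " but reference is ",
         paste(dim(R), collapse = "x"))
  }
  N <- ncol(X)
  if (renormalize_reference) {
    mu <- rowMeans(R)
    Rc <- R - mu
    sd_pop <- sqrt(rowSums(Rc^2) / N)
    if (any(sd_pop == 0)) stop("constant reference row; cannot renormalize")
    R <- Rc / sd_pop
  }
  C <- tcrossprod(X, R) / N
  if (apply_fisher) C <- fisher_z(C, clip = clip)
  if (symmetrize) C <- (C + t(C)) / 2
  new_conn_matrix(C, kind = "isfc", fisher_z = apply_fisher,
                  symmetric = symmetrize,
                  provenance = list(subject = target$subject_id,
                                    run = target$run_id, task = target$task))
}

#' Group-average connectivity matrix
#'
#' Element-wise mean of per-subject matrices (all symmetric, same P); for
#' ISFC this is the group matrix obtained by averaging the subjects'
#' symmetrised z-matrices.
#'
#' @param mats non-empty list of `conn_matrix` objects of equal dimension.
#' @return A `conn_matrix` holding the mean.
#' @export
group_isfc <- function(mats) {
  if (length(mats) == 0L) stop("empty list of matrices")
  stopifnot(all(vapply(mats, inherits, logical(1), "conn_matrix")))
  Ps <- vapply(mats, function(m) nrow(m$values), integer(1))
  if (any(Ps != Ps[1])) stop("matrices differ in dimension")
  avg <- Reduce(`+`, lapply(mats, `[[`, "values")) / length(mats)
  new_conn_matrix(avg, kind = mats[[1]]$kind, fisher_z = mats[[1]]$fisher_z,
                  symmetric = all(vapply(mats, `[[`, logical(1), "symmetric")),
                  provenance = list(group_of = length(mats)))
}

#' Within-subject functional connectivity matrix
#'
#' The ordinary Pearson correlation matrix between every pair of node time
#' series of one run. The diagonal is exactly 1 when no Fisher transform is
#' applied.
#'
#' @param series a `run_ts` with no constant row.
#' @param apply_fisher apply [fisher_z()] element-wise? Default `FALSE`.
#' @return A `conn_matrix` of kind `"fc"`.
#' @export
fc_matrix <- function(series, apply_fisher = FALSE) {
  stopifnot(inherits(series, "run_ts"))
  X <- series$data
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant time series at node(s): ", paste(which(sds == 0), collapse = ", "))
  }
  C <- stats::cor(t(X))
  diag(C) <- 1
  if (apply_fisher) C <- fisher_z(C)
  new_conn_matrix(C, kind = "fc", fisher_z = apply_fisher, symmetric = TRUE,
                  provenance = list(subject = series$subject_id,
                                    run = series$run_id, task = series$task))
}

#' Vectorise a symmetric connectivity matrix
#'
#' Extracts the unique elements of a symmetric matrix in the canonical
#' [edge_index()] order; `devectorize_edges()` is the inverse for symmetric
#' matrices.
#'
#' @param C a symmetric `conn_matrix` (or plain symmetric matrix).
#' @param index an [edge_index()] with matching P.
#' @return Numeric vector of length `index$n_edges`.
#' @export
vectorize_edges <- function(C, index) {
  stopifnot(inherits(index, "edge_index"))
  V <- conn_values(C)
  if (nrow(V) != index$P) stop("matrix P = ", nrow(V), " but index P = ", index$P)
  if (max(abs(V - t(V))) > 1e-8) stop("matrix is not symmetric")
  V[index$lin]
}

#' @rdname vectorize_edges
#' @param values edge-vector of length `index$n_edges`.
#' @return `devectorize_edges()`: the symmetric P x P matrix.
#' @export
devectorize_edges <- function(values, index) {
  stopifnot(inherits(index, "edge_index"))
  if (length(values) != index$n_edges) {
    stop("edge vector length ", length(values), " but index expects ", index$n_edges)
  }
  M <- matrix(0, index$P, index$P)
  M[cbind(index$i, index$j)] <- values
  M[cbind(index$j, index$i)] <- values
  M
}

#' Spatial similarity between two connectivity matrices
#'
#' Pearson correlation between the edge vectors of two symmetric matrices,
#' optionally restricted to a subset of edge positions (e.g. the edges of one
#' subnetwork pair). The diagonal is included by default through the edge
#' index convention.
#'
#' @param C1,C2 symmetric `conn_matrix` objects (or matrices) with equal P.
#' @param subset integer vector of edge positions (see [edge_subset()]), or
#'   `NULL` for all edges; at least 3 positions.
#' @param index an [edge_index()]; defaults to all edges including the
#'   diagonal.
#' @return Pearson correlation (scalar).
#' @export
matrix_similarity <- function(C1, C2, subset = NULL, index = NULL) {
  V1 <- conn_values(C1); V2 <- conn_values(C2)
  if (!all(dim(V1) == dim(V2))) stop("matrices differ in dimension")
  if (is.null(index)) index <- edge_index(nrow(V1), include_diagonal = TRUE)
  v1 <- vectorize_edges(V1, index)
  v2 <- vectorize_edges(V2, index)
  if (!is.null(subset)) {
    v1 <- v1[subset]; v2 <- v2[subset]
  }
  if (length(v1) < 3L) stop("similarity needs at least 3 edges")
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("constant edge vector; similarity undefined")
  }
  stats::cor(v1, v2)
}
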