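#' Write a run matrix with a JSON sidecar
#'
#' Two on-disk forms are supported. `"tsv"` writes the P x N matrix as
#' tab-separated text (round trip exact to printed precision, 17 significant
#' digits so doubles survive); `"bin"` writes raw little-endian doubles
#' (bit-exact round trip). Either way a `<path>.json` sidecar records the
#' dimensions, TR, identifiers, task and format.
#'
#' @param series a `run_ts`.
#' @param path output path for the matrix file.
#' @param format `"tsv"` (default) or `"bin"`.
#' @return `path`, invisibly.
#' @export
write_run_matrix <- function(series, path, format = c("tsv", "bin")) {
  format <- match.arg(format)
  stopifnot(inherits(series, "run_ts"))
  X <- series$data
  if (format == "tsv") {
    utils::write.table(format(X, digits = 17, scientific = TRUE, trim = TRUE),
                       path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.vector(t(X)), con, size = 8, endian = "little")
  }
  meta <- list(P = nrow(X), N = ncol(X), TR = series$TR,
               subject_id = as.character(series$subject_id),
               run_id = as.character(series$run_id),
               task = as.character(series$task),
               normalized = series$normalized, format = format)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_run_matrix
#' @return `read_run_matrix()`: the reconstructed `run_ts`.
#' @export
read_run_matrix <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("run matrix file not found: ", path)
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (identical(meta$format, "bin")) {
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, "double", n = meta$P * meta$N, size = 8, endian = "little")
    X <- matrix(v, nrow = meta$P, byrow = TRUE)
  } else {
    lines <- readLines(path)
    if (length(lines) != meta$P) {
      stop("format error in ", path, ": expected ", meta$P, " rows, found ",
           length(lines))
    }
    cells <- strsplit(lines, "\t", fixed = TRUE)
    X <- matrix(NA_real_, meta$P, meta$N)
    for (r in seq_along(cells)) {
      if (length(cells[[r]]) != meta$N) {
        stop("format error in ", path, " row ", r, ": expected ", meta$N,
             " columns, found ", length(cells[[r]]))
      }
      vals <- suppressWarnings(as.numeric(cells[[r]]))
      if (anyNA(vals)) {
        bad <- which(is.na(vals))[1]
        stop("format error in ", path, " row ", r, " column ", bad,
             ": non-numeric cell '", cells[[r]][bad], "'")
      }
      X[r, ] <- vals
    }
  }
  run_ts(X, TR = meta$TR, subject_id = meta$subject_id, run_id = meta$run_id,
         task = meta$task, normalized = isTRUE(meta$normalized))
}

#' Write a study dataset as per-run files plus a JSON manifest
#'
#' Each run goes to its own matrix file (see [write_run_matrix()]); the
#' manifest lists subject, run, task, TR and relative path per run, and the
#' atlas (if any) is written alongside.
#'
#' @param dataset a `study_dataset`.
#' @param dir output directory (created if needed).
#' @param format run-matrix format, see [write_run_matrix()].
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, format = c("tsv", "bin")) {
  format <- match.arg(format)
  stopifnot(inherits(dataset, "study_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  for (nm in names(dataset$runs)) {
    r <- dataset$runs[[nm]]
    fname <- paste0(nm, ".", if (format == "tsv") "tsv" else "bin")
    write_run_matrix(r, file.path(dir, fname), format = format)
    entries[[length(entries) + 1L]] <- list(
      subject_id = as.character(r$subject_id), run_id = as.character(r$run_id),
      task = as.character(r$task), TR = r$TR, path = fname)
  }
  atlas_file <- NULL
  if (!is.null(dataset$atlas)) {
    atlas_file <- "atlas.tsv"
    write_atlas(dataset$atlas, file.path(dir, atlas_file))
  }
  manifest <- list(runs = entries, atlas = atlas_file,
                   tasks = dataset$tasks, format = format)
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' @rdname write_dataset
#' @param manifest_path path to a `manifest.json` written by
#'   [write_dataset()]. All referenced files are checked for existence
#'   before any matrix is read.
#' @return `read_dataset()`: the reconstructed `study_dataset`.
#' @export
read_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  dir <- dirname(manifest_path)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = FALSE)
  paths <- vapply(manifest$runs, function(e) file.path(dir, e$path), character(1))
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L) {
    stop("manifest references missing file(s): ", paste(missing, collapse = ", "))
  }
  runs <- lapply(paths, read_run_matrix)
  names(runs) <- vapply(manifest$runs, function(e)
    paste0(e$subject_id, "_", e$run_id), character(1))
  atl <- if (!is.null(manifest$atlas)) read_atlas(file.path(dir, manifest$atlas))
  study_dataset(runs, atlas = atl,
                tasks = unlist(manifest$tasks))
}

#' Export selected edges for BrainNet-style surface rendering
#'
#' Writes the two plain-text files the BrainNet viewer consumes: a `.node`
#' file (`x y z color size label`, one row per node touched by the
#' selection) and a `.edge` file (space-delimited P x P symmetric matrix
#' holding phi at selected positions and 0 elsewhere).
#'
#' @param selection integer edge positions (see [select_edges()]).
#' @param atlas the [atlas()] the edge index refers to.
#' @param map the `discriminative_map` supplying phi values and the edge
#'   index.
#' @param out_prefix output path prefix; `<prefix>.node` and `<prefix>.edge`
#'   are written.
#' @return Named character vector of the two paths, invisibly.
#' @export
export_brainnet <- function(selection, atlas, map, out_prefix) {
  stopifnot(inherits(atlas, "isfc_atlas"), inherits(map, "discriminative_map"))
  index <- map$index
  if (is.null(index)) stop("map carries no edge index")
  if (nrow(atlas) != index$P) stop("atlas does not match the map's edge index")
  if (length(selection) > 0L &&
      (min(selection) < 1L || max(selection) > index$n_edges)) {
    stop("selection contains invalid edge positions")
  }
  if (length(selection) == 0L) warning("empty selection: writing empty files")
  M <- matrix(0, index$P, index$P)
  ii <- index$i[selection]; jj <- index$j[selection]
  M[cbind(ii, jj)] <- map$phi[selection]
  M[cbind(jj, ii)] <- map$phi[selection]
  touched <- sort(unique(c(ii, jj)))
  nets <- networks(atlas)
  node_tab <- data.frame(
    x = atlas$x[touched], y = atlas$y[touched], z = atlas$z[touched],
    color = match(atlas$network_label[touched], nets),
    size = rep(1, length(touched)),
    label = gsub("[ \t]", "_", atlas$network_label[touched]))
  node_path <- paste0(out_prefix, ".node")
  edge_path <- paste0(out_prefix, ".edge")
  utils::write.table(node_tab, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(M, edge_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(node = node_path, edge = edge_path))
}

#' Validated analysis configuration
#'
#' Collects the tunable parameters of the pipeline in one validated list;
#' unknown keys are rejected so that typos fail loudly rather than silently
#' falling back to defaults.
#'
#' @param ... named overrides of the defaults: `cutoff_hz`, `add_derivatives`,
#'   `renormalize_reference`, `include_diagonal`, `fisher_clip`, `mode`,
#'   `scan_lengths`, `scan_reps`, `n_perm`, `alpha`, `seed`.
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(cutoff_hz = 0.08, add_derivatives = TRUE,
                   renormalize_reference = FALSE, include_diagonal = TRUE,
                   fisher_clip = 1 - 1e-6, mode = "isfc",
                   scan_lengths = seq(20, 180, by = 10), scan_reps = 10,
                   n_perm = 1000, alpha = 0.05, seed = 1)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  defaults[names(override)] <- override
  if (!defaults$mode %in% c("isfc", "fc")) stop("mode must be 'isfc' or 'fc'")
  if (defaults$alpha <= 0 || defaults$alpha >= 1) stop("alpha must be in (0, 1)")
  structure(defaults, class = "pipeline_config")
}
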