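#' Construct a parcellation atlas
#'
#' An atlas is an ordered table of nodes (brain parcels), each with an integer
#' id, MNI coordinates in millimetres, and a subnetwork label. Node order is
#' fixed and defines the row/column order of every connectivity matrix built
#' downstream.
#'
#' @param nodes data frame with columns `node_id`, `x`, `y`, `z`,
#'   `network_label`.
#' @param name atlas name (informational).
#' @return An object of class `isfc_atlas`: the node table plus a `name`
#'   attribute.
#' @export
atlas <- function(nodes, name = "atlas") {
  required <- c("node_id", "x", "y", "z", "network_label")
  missing_cols <- setdiff(required, names(nodes))
  if (length(missing_cols) > 0L) {
    stop("atlas table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[required]
  if (nrow(nodes) < 2L) {
    stop("an atlas needs at least 2 nodes, got ", nrow(nodes))
  }
  if (anyDuplicated(nodes$node_id)) {
    dup <- unique(nodes$node_id[duplicated(nodes$node_id)])
    stop("duplicate node_id in atlas: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(as.character(nodes$network_label))) || anyNA(nodes$network_label)) {
    stop("every node needs a non-empty network_label")
  }
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$network_label <- as.character(nodes$network_label)
  rownames(nodes) <- NULL
  structure(nodes, name = name, class = c("isfc_atlas", "data.frame"))
}

#' Read an atlas from a tab-separated node table
#'
#' The expected format is tab-separated text with a header line
#' `node_id x y z network_label`; rows are nodes in matrix order.
#'
#' @param path path to the file.
#' @param name atlas name; defaults to the file name.
#' @return An [atlas()] object.
#' @export
read_atlas <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("atlas file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) stop("atlas table is empty: ", path)
  atlas(tab, name = name)
}

#' Write an atlas node table
#'
#' @param x an [atlas()] object.
#' @param path output path; tab-separated with header.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(x, path) {
  stopifnot(inherits(x, "isfc_atlas"))
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.isfc_atlas <- function(x, ...) {
  cat(sprintf("Atlas '%s': %d nodes, %d subnetworks\n",
              attr(x, "name"), nrow(x), length(unique(x$network_label))))
  tab <- table(x$network_label)
  cat(paste(sprintf("  %s (%d)", names(tab), as.integer(tab)), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Subnetwork labels of an atlas
#'
#' @param x an [atlas()] object.
#' @return Character vector of unique labels, in order of first appearance.
#' @export
networks <- function(x) {
  stopifnot(inherits(x, "isfc_atlas"))
  unique(x$network_label)
}

#' Merge subnetworks into coarser groups
#'
#' Relabels nodes according to `merge_map` without touching node order or
#' coordinates. Used, e.g., to fold the cerebellar, memory-retrieval and
#' uncertain groups of a 14-network parcellation into a single "Others"
#' network, giving the 11-network partition used for subnetwork analyses.
#'
#' @param x an [atlas()] object.
#' @param merge_map named character vector, `old label -> new label`. An empty
#'   map returns the atlas unchanged.
#' @return The relabelled atlas.
#' @export
collapse_networks <- function(x, merge_map) {
  stopifnot(inherits(x, "isfc_atlas"))
  if (length(merge_map) == 0L) return(x)
  if (is.null(names(merge_map)) || any(!nzchar(names(merge_map)))) {
    stop("merge_map must be a named vector (old label -> new label)")
  }
  unknown <- setdiff(names(merge_map), x$network_label)
  if (length(unknown) > 0L) {
    stop("merge_map refers to label(s) not in the atlas: ",
         paste(unknown, collapse = ", "))
  }
  hit <- x$network_label %in% names(merge_map)
  x$network_label[hit] <- unname(merge_map[x$network_label[hit]])
  x
}

#' Default 14-to-11 subnetwork merge
#'
#' The standard coarsening of the 264-node parcellation's 14 subnetworks:
#' the cerebellar, memory-retrieval and uncertain groups are folded into a
#' single "Others" network, leaving 11.
#'
#' @return Named character vector suitable for [collapse_networks()].
#' @export
default_merge_map <- function() {
  c("Cerebellar" = "Others",
    "Memory retrieval" = "Others",
    "Uncertain" = "Others")
}

#' Canonical edge ordering for symmetric connectivity matrices
#'
#' Enumerates the unique elements of a symmetric P x P matrix in row-major
#' upper-triangle order: (1,1), (1,2), ..., (1,P), (2,2), ..., (P,P) when the
#' diagonal is included. The diagonal is included by default, matching the
#' convention in which a 264-node matrix has 264*265/2 = 34980 connections
#' (the diagonal of an ISFC matrix is the inter-subject correlation of a node
#' with itself and is a real connection in this sense).
#'
#' @param P node count, at least 2.
#' @param include_diagonal include (i,i) elements? Default `TRUE`.
#' @return An object of class `edge_index` with fields `P`,
#'   `include_diagonal`, `i`, `j` (1-based node indices, `i <= j`) and
#'   `n_edges`.
#' @export
edge_index <- function(P, include_diagonal = TRUE) {
  if (!is.numeric(P) || length(P) != 1L || P < 2 || P != as.integer(P)) {
    stop("P must be a single integer >= 2")
  }
  P <- as.integer(P)
  if (include_diagonal) {
    i <- rep.int(seq_len(P), times = P:1L)
    j <- unlist(lapply(seq_len(P), function(a) a:P), use.names = FALSE)
  } else {
    i <- rep.int(seq_len(P - 1L), times = (P - 1L):1L)
    j <- unlist(lapply(seq_len(P - 1L), function(a) (a + 1L):P), use.names = FALSE)
  }
  structure(list(P = P, include_diagonal = include_diagonal,
                 i = i, j = j, n_edges = length(i),
                 lin = (j - 1L) * P + i),
            class = "edge_index")
}

#' @export
print.edge_index <- function(x, ...) {
  cat(sprintf("Edge index: P = %d, %s diagonal, %d edges\n", x$P,
              if (x$include_diagonal) "with" else "without", x$n_edges))
  invisible(x)
}

#' Edge positions within or between subnetworks
#'
#' Returns the positions (into the edge ordering of `index`) of the edges
#' restricted to one subnetwork (within-network; both endpoints in
#' `network_a`) or to a pair of distinct subnetworks (across-network; one
#' endpoint in each).
#'
#' @param x an [atlas()] object whose node order matches `index`.
#' @param index an [edge_index()] with `P` equal to the atlas node count.
#' @param network_a subnetwork label.
#' @param network_b second label for an across-network subset, or `NULL`
#'   (default) for within-network.
#' @return Integer vector of edge positions.
#' @export
edge_subset <- function(x, index, network_a, network_b = NULL) {
  stopifnot(inherits(x, "isfc_atlas"), inherits(index, "edge_index"))
  if (nrow(x) != index$P) stop("atlas has ", nrow(x), " nodes but index P = ", index$P)
  labs <- x$network_label
  check_label <- function(l) {
    if (!l %in% labs) stop("unknown subnetwork label: ", l)
  }
  check_label(network_a)
  in_a <- labs[index$i] == network_a
  jn_a <- labs[index$j] == network_a
  if (is.null(network_b) || identical(network_b, network_a)) {
    which(in_a & jn_a)
  } else {
    check_label(network_b)
    in_b <- labs[index$i] == network_b
    jn_b <- labs[index$j] == network_b
    which((in_a & jn_b) | (in_b & jn_a))
  }
}
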