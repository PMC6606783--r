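# Hierarchical clustering of strain production profiles: Euclidean
# distances between strain columns, complete linkage, leaf-ordered matrix
# and Newick export -- the settings used for published producer-profile
# heat maps.

#' Euclidean distances between strain columns
#'
#' @param m Numeric matrix, compounds in rows, strains in columns
#'   (at least two).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
column_distance <- function(m) {
  m <- as.matrix(m)
  if (!is.numeric(m)) stop("profile matrix must be numeric", call. = FALSE)
  if (ncol(m) < 2L) stop("need at least two strain columns", call. = FALSE)
  as.matrix(stats::dist(t(m), method = "euclidean"))
}

#' Complete-linkage clustering of strains
#'
#' Agglomerative clustering in which the distance between clusters is the
#' maximum pairwise member distance, applied to the strain columns of a
#' production matrix.  Columns are sorted by name before clustering so the
#' result is invariant to the input column order; merge heights of complete
#' linkage are non-decreasing by construction and this is asserted on every
#' run.
#'
#' @param m Numeric profile matrix (compounds x strains), or a symmetric
#'   distance matrix via `dist_matrix`.
#' @param dist_matrix Optional precomputed distance matrix (overrides `m`).
#' @param scale_rows Optional unit-variance scaling of compound rows before
#'   distance computation (off by default: raw semi-quantitative levels are
#'   clustered).
#' @return An object of class `hclust`.
#' @export
cluster_strains <- function(m = NULL, dist_matrix = NULL,
                            scale_rows = FALSE) {
  if (is.null(dist_matrix)) {
    stopifnot(!is.null(m))
    m <- as.matrix(m)
    if (is.null(colnames(m))) colnames(m) <- paste0("strain_", seq_len(ncol(m)))
    m <- m[, order(colnames(m)), drop = FALSE]
    if (scale_rows) {
      sds <- apply(m, 1L, stats::sd)
      m <- m / ifelse(sds > 0, sds, 1)
    }
    dist_matrix <- column_distance(m)
  } else {
    dist_matrix <- as.matrix(dist_matrix)
    o <- order(colnames(dist_matrix))
    dist_matrix <- dist_matrix[o, o, drop = FALSE]
  }
  if (ncol(dist_matrix) < 2L) stop("need at least two items", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(dist_matrix), method = "complete")
  if (is.unsorted(hc$height)) {
    stop("internal error: complete-linkage heights are not monotone",
         call. = FALSE)
  }
  hc
}

#' Top split of a strain dendrogram
#'
#' @param hc An `hclust` tree.
#' @return Named integer vector assigning each strain to one of the two
#'   root children.
#' @export
top_split <- function(hc) {
  stats::cutree(hc, k = 2)
}

#' Export a clustered heat-map bundle
#'
#' Permutes the matrix columns to dendrogram leaf order and serialises the
#' tree as Newick with branch heights.  Rendering the heat-map image is out
#' of scope; the ordering and serialisation are the reproducible artefacts.
#'
#' @param m Profile matrix whose columns are the tree leaves.
#' @param hc `hclust` tree from [cluster_strains()].
#' @param matrix_path,tree_path Optional output files (TSV / Newick).
#' @return A list with `ordered` (the column-permuted matrix) and `newick`
#'   (character scalar).
#' @export
export_heatmap <- function(m, hc, matrix_path = NULL, tree_path = NULL) {
  m <- as.matrix(m)
  leaves <- hc$labels[hc$order]
  if (!setequal(leaves, colnames(m))) {
    stop("tree leaves do not match matrix columns", call. = FALSE)
  }
  ordered <- m[, leaves, drop = FALSE]
  phy <- ape::as.phylo(hc)
  newick <- ape::write.tree(phy)
  if (!is.null(matrix_path)) {
    utils::write.table(data.frame(compound = rownames(ordered), ordered,
                                  check.names = FALSE),
                       matrix_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(tree_path)) writeLines(newick, tree_path)
  list(ordered = ordered, newick = newick)
}

#' Read and write profile matrices
#'
#' TSV layout: first column `compound`, remaining columns one per strain.
#'
#' @param path File path.
#' @return `read_profile_matrix`: numeric matrix with compound rownames.
#' @export
read_profile_matrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(m) <- tab[[1L]]
  storage.mode(m) <- "double"
  if (anyNA(m)) stop("profile matrix contains non-numeric values",
                     call. = FALSE)
  if (anyDuplicated(colnames(m))) stop("strain names must be unique",
                                       call. = FALSE)
  m
}

#' @rdname read_profile_matrix
#' @param m Matrix to write.
#' @export
write_profile_matrix <- function(m, path) {
  utils::write.table(data.frame(compound = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
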