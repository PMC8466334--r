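#' UPGMA hierarchical clustering
#'
#' Unweighted pair group method with arithmetic mean (average linkage on the
#' raw distances), producing an ultrametric tree with non-decreasing merge
#' heights. Rows/columns are sorted lexicographically by label before
#' agglomeration so that ties are broken deterministically.
#'
#' @param distance_matrix Symmetric non-negative matrix with zero diagonal
#'   and labels as dimnames.
#' @return A list of class `upgma_clust`: `hclust` (the [stats::hclust()]
#'   object), `leaf_order` (labels in display order), `merge_heights`.
#' @export
upgma_cluster <- function(distance_matrix) {
  d <- as.matrix(distance_matrix)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-10)))
    stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(abs(diag(d)) > 1e-12)) stop("diagonal must be zero")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- seq_len(nrow(d))
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  structure(list(hclust = hc,
                 leaf_order = hc$labels[hc$order],
                 merge_heights = hc$height),
            class = "upgma_clust")
}

#' @export
print.upgma_clust <- function(x, ...) {
  cat("UPGMA clustering of", length(x$leaf_order), "items;",
      "merge heights", sprintf("%.3g", min(x$merge_heights)), "..",
      sprintf("%.3g", max(x$merge_heights)), "\n")
  invisible(x)
}

#' Sort a dendrogram smallest-first
#'
#' Reorders the children of every internal node so that the subtree with the
#' smaller minimum merge height comes first (single leaves count as height
#' 0); ties are broken by the lexicographically smallest leaf label. Only the
#' leaf order changes; topology and merge heights are untouched. This is the
#' tightest-cluster-first convention used to make heatmap dendrograms
#' reproducible.
#'
#' @param cluster An `upgma_clust` (or any `hclust`-backed result).
#' @return The cluster with updated `leaf_order` and `hclust$order`.
#' @export
sort_dendrogram <- function(cluster) {
  stopifnot(inherits(cluster, "upgma_clust"))
  hc <- cluster$hclust
  merge <- hc$merge
  height <- hc$height
  n <- length(hc$labels)

  # per node: ordered leaves, min merge height within the subtree (a bare
  # leaf counts as 0 when compared, but does not lower its parent's minimum),
  # and the smallest leaf label for tie-breaking
  info <- function(node) {
    if (node < 0) {
      return(list(leaves = -node, minh = NA_real_, minlab = hc$labels[-node]))
    }
    a <- info(merge[node, 1])
    b <- info(merge[node, 2])
    va <- if (is.na(a$minh)) 0 else a$minh
    vb <- if (is.na(b$minh)) 0 else b$minh
    first_a <- va < vb || (va == vb && a$minlab <= b$minlab)
    ordered <- if (first_a) c(a$leaves, b$leaves) else c(b$leaves, a$leaves)
    list(leaves = ordered,
         minh = min(c(height[node], a$minh, b$minh), na.rm = TRUE),
         minlab = min(a$minlab, b$minlab))
  }
  root <- info(nrow(merge))
  hc$order <- root$leaves
  cluster$hclust <- hc
  cluster$leaf_order <- hc$labels[hc$order]
  cluster
}

#' Count nests whose two tags cluster adjacently
#'
#' For a marks-only clustering, counts how many nests have their (two or
#' more) mark sleeves occupying consecutive positions in the dendrogram leaf
#' order, the "clasped column captions" statistic.
#'
#' @param cluster An `upgma_clust` over mark samples.
#' @param meta Sample metadata (`sample_id`, `nest_id`).
#' @return Integer count of nests with all tags adjacent.
#' @export
tag_adjacency <- function(cluster, meta) {
  stopifnot(inherits(cluster, "upgma_clust"))
  pos <- stats::setNames(seq_along(cluster$leaf_order), cluster$leaf_order)
  nests <- unique(meta$nest_id[meta$sample_id %in% cluster$leaf_order])
  count <- 0L
  for (b in nests) {
    ids <- meta$sample_id[meta$nest_id == b &
                            meta$sample_id %in% cluster$leaf_order]
    if (length(ids) < 1) next
    p <- sort(pos[ids])
    if (length(p) == 1 || all(diff(p) == 1)) count <- count + 1L
  }
  count
}

#' Render a clustered heatmap
#'
#' Draws a compounds x samples heatmap with the supplied UPGMA row and
#' column clusterings (typically after [sort_dendrogram()]), color-coded by
#' compound class and sample origin, and writes the row/column leaf orders
#' to a TSV next to the image so that figure content is testable.
#'
#' @param matrix Numeric matrix (e.g. compounds in rows, samples in columns
#'   of normalized clr values).
#' @param row_cluster,col_cluster `upgma_clust` objects over the rows and
#'   columns of `matrix`.
#' @param path Output image path (`.png`).
#' @param annotation_row,annotation_col Optional single-column data frames
#'   (rownames = labels) used for color coding, e.g. compound class and
#'   sample origin.
#' @return Invisibly, a list with `image` and `leaf_orders` paths.
#' @export
render_heatmap <- function(matrix, row_cluster, col_cluster, path,
                           annotation_row = NULL, annotation_col = NULL) {
  stopifnot(inherits(row_cluster, "upgma_clust"),
            inherits(col_cluster, "upgma_clust"))
  if (!dir.exists(dirname(path)))
    stop("unwritable path: directory does not exist: ", dirname(path))
  if (!setequal(rownames(matrix), row_cluster$leaf_order) ||
      !setequal(colnames(matrix), col_cluster$leaf_order))
    stop("cluster leaf labels do not match matrix dimnames")
  ph <- pheatmap::pheatmap(
    matrix,
    cluster_rows = row_cluster$hclust,
    cluster_cols = col_cluster$hclust,
    annotation_row = annotation_row,
    annotation_col = annotation_col,
    fontsize_row = 5, fontsize_col = 5,
    filename = path, silent = TRUE
  )
  lo_path <- paste0(sub("\\.[A-Za-z]+$", "", path), "_leaforder.tsv")
  n <- max(length(row_cluster$leaf_order), length(col_cluster$leaf_order))
  pad <- function(v) c(v, rep("", n - length(v)))
  utils::write.table(
    data.frame(row = pad(row_cluster$leaf_order),
               column = pad(col_cluster$leaf_order),
               stringsAsFactors = FALSE),
    lo_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(image = path, leaf_orders = lo_path, pheatmap = ph))
}
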