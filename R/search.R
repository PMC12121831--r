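# Distance metrics, k-nearest-neighbour semantic search, Neighbor-Joining
# dendrograms and Newick serialization. Euclidean distance is the default
# retrieval metric and the metric for expression trees; the fractional
# Lk-norm (k = 0.3) is used for the per-word trees of the HTML reports.
# For k < 1 the Lk-norm violates the triangle inequality and is used
# purely as a dissimilarity.

#' Distance metric configuration
#'
#' @param name `"euclidean"` or `"lk_norm"`.
#' @param k Exponent of the Lk-norm (default 0.3). `lk_norm` with `k = 2`
#'   is the Euclidean distance.
#' @return Object of class `metric_config`.
#' @export
metric_config <- function(name = c("euclidean", "lk_norm"), k = 0.3) {
  name <- match.arg(name)
  if (k <= 0) stop("Lk exponent must be positive")
  structure(list(name = name, k = if (name == "euclidean") 2 else k),
            class = "metric_config")
}

.as_metric <- function(metric) {
  if (inherits(metric, "metric_config")) metric else metric_config(metric)
}

#' Distance between two vectors
#'
#' Euclidean: `sqrt(sum((x-y)^2))`; Lk-norm: `sum(|x-y|^k)^(1/k)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param metric A [metric_config] (or its name).
#' @return Nonnegative scalar.
#' @export
pairwise_distance <- function(x, y, metric = metric_config("euclidean")) {
  metric <- .as_metric(metric)
  if (length(x) != length(y)) {
    stop("length mismatch: ", length(x), " vs ", length(y))
  }
  d <- abs(x - y)
  if (metric$name == "euclidean") sqrt(sum(d^2)) else sum(d^metric$k)^(1 / metric$k)
}

#' All pairwise distances of an embedding space
#'
#' @param m Numeric matrix with rownames (rows = items).
#' @param metric A [metric_config] (or its name).
#' @return A symmetric `matrix` with zero diagonal and the row labels.
#' @export
distance_matrix <- function(m, metric = metric_config("euclidean")) {
  metric <- .as_metric(metric)
  d <- if (metric$name == "euclidean") {
    stats::dist(unclass(m))
  } else {
    stats::dist(unclass(m), method = "minkowski", p = metric$k)
  }
  out <- as.matrix(d)
  dimnames(out) <- list(rownames(m), rownames(m))
  out
}

#' k-nearest neighbours of a query vector
#'
#' Returns the `k` rows of the space with the smallest distance to the
#' query, ascending; ties are broken by lexicographic label order. If the
#' space has fewer than `k` rows, all rows are returned.
#'
#' @param query Numeric vector of the space's dimensionality.
#' @param space An [embedding_matrix] (or labelled matrix).
#' @param k Number of neighbours (default 30).
#' @param metric A [metric_config] (or its name).
#' @param exclude Labels to drop before ranking (e.g. the query itself).
#' @return Data frame with columns `label`, `distance`.
#' @export
knn_search <- function(query, space, k = 30, metric = metric_config("euclidean"),
                       exclude = NULL) {
  metric <- .as_metric(metric)
  if (nrow(space) == 0L) stop("empty embedding space")
  if (length(query) != ncol(space)) {
    stop("query length ", length(query), " does not match space dimension ", ncol(space))
  }
  m <- unclass(space)
  if (!is.null(exclude)) m <- m[setdiff(rownames(m), exclude), , drop = FALSE]
  d <- abs(sweep(m, 2, query))
  dist <- if (metric$name == "euclidean") {
    sqrt(rowSums(d^2))
  } else {
    rowSums(d^metric$k)^(1 / metric$k)
  }
  ord <- order(dist, rownames(m))
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(label = rownames(m)[ord], distance = unname(dist[ord]),
             stringsAsFactors = FALSE)
}

# -- trees -------------------------------------------------------------------

.validate_dist <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- paste0("L", seq_len(nrow(d)))
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal is not zero")
  d
}

#' Neighbor-Joining dendrogram
#'
#' Standard Saitou-Nei agglomeration over a validated symmetric distance
#' matrix; negative branch lengths are clamped to zero. On additive
#' matrices NJ reconstructs the generating tree exactly.
#'
#' @param d Symmetric distance matrix (labelled) or `dist` object, at
#'   least 2 labels.
#' @return An [ape::ape-package] `phylo` tree (unrooted for >= 3 leaves).
#' @export
neighbor_joining <- function(d) {
  d <- .validate_dist(d)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 labels")
  if (n == 2) {
    # single edge of total length d, represented with a degree-2 root
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
               edge.length = rep(d[1, 2] / 2, 2),
               tip.label = rownames(d), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Root a tree at a designated leaf
#'
#' Used to anchor expression/word dendrograms at a reference term; the
#' unrooted topology is preserved.
#'
#' @param tree A `phylo` tree.
#' @param leaf Tip label to root at.
#' @return A rooted `phylo` tree.
#' @export
root_at_leaf <- function(tree, leaf) {
  if (!leaf %in% tree$tip.label) stop("leaf not in tree: ", leaf)
  ape::root(tree, outgroup = leaf, resolve.root = TRUE)
}

#' Tree over the rows of an embedding space
#'
#' Convenience wrapper: pairwise distances of the rows, then
#' Neighbor-Joining, optionally rooted at one label.
#'
#' @param space An [embedding_matrix].
#' @param metric A [metric_config] (or its name).
#' @param root Optional label to root at.
#' @return A `phylo` tree.
#' @export
embedding_tree <- function(space, metric = metric_config("euclidean"), root = NULL) {
  tr <- neighbor_joining(distance_matrix(space, metric))
  if (!is.null(root)) tr <- root_at_leaf(tr, root)
  tr
}

# -- Newick ------------------------------------------------------------------

.nwk_quote <- function(lab) {
  needs <- grepl("[](){},;:'\"|&~_ \\[]", lab)
  lab[needs] <- paste0("'", gsub("'", "''", lab[needs], fixed = TRUE), "'")
  lab
}

#' Serialize a tree as Newick
#'
#' Labels containing Newick metacharacters (expression strings contain
#' `|`, `&`, braces, spaces) are single-quoted so they survive a
#' parse-write roundtrip.
#'
#' @param tree A `phylo` tree.
#' @param path Optional file to write to.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when writing to a file.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  labs <- .nwk_quote(tree$tip.label)
  fmt <- function(x) format(x, digits = digits, scientific = FALSE, trim = TRUE)
  rec <- function(node, elen) {
    s <- if (node <= ntip) {
      labs[node]
    } else {
      rows <- kids[[as.character(node)]]
      paste0("(", paste(vapply(rows, function(r) {
        rec(tree$edge[r, 2], tree$edge.length[r])
      }, ""), collapse = ","), ")")
    }
    if (!is.na(elen)) paste0(s, ":", fmt(elen)) else s
  }
  root <- ntip + 1L
  out <- paste0(rec(root, NA_real_), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Parse a Newick file or string
#'
#' Wraps `ape::read.tree` and strips the single-quoting applied by
#' [write_newick()] from labels.
#'
#' @param path Newick file, or `text =` a Newick string.
#' @param text Newick string (alternative to `path`).
#' @return A `phylo` tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  unquote <- function(lab) {
    q <- grepl("^'.*'$", lab)
    lab[q] <- gsub("''", "'", sub("^'(.*)'$", "\\1", lab[q]), fixed = TRUE)
    lab
  }
  tr$tip.label <- unquote(tr$tip.label)
  if (!is.null(tr$node.label)) tr$node.label <- unquote(tr$node.label)
  tr
}
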