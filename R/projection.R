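#' One-mode projection of a bipartite network
#'
#' Projects the bipartite gene-disease network onto one side: two nodes are
#' connected iff they share at least one neighbor on the opposite side, and
#' `shared_count` records how many neighbors they share. Projecting the
#' disease side of a lncRNA-disease network gives the lncRNA-implicated
#' disease network (lncDN); projecting the gene side gives the
#' disease-associated lncRNA network (DlncN).
#'
#' @param net a [bdnet].
#' @param side `"gene"` or `"disease"`: the side kept as projection nodes.
#' @return An object of class `one_mode_projection`: list with `side`,
#'   `nodes` (all ids from that side, including isolated ones) and `edges`
#'   (data.frame `from`, `to`, `shared_count`, with `from < to`).
#' @export
one_mode_projection <- function(net, side = c("gene", "disease")) {
  side <- match.arg(side)
  stopifnot(inherits(net, "bdnet"))
  if (nrow(net$edges) == 0 && nrow(net$genes) + nrow(net$diseases) == 0)
    stop("empty network", call. = FALSE)
  A <- adjacency_matrix(net)
  if (side == "disease") A <- Matrix::t(A)
  S <- Matrix::tcrossprod(A)            # shared-neighbor counts
  S <- methods::as(Matrix::triu(S, k = 1), "TsparseMatrix")
  keep <- S@x > 0
  ids <- rownames(A)
  edges <- data.frame(from = ids[S@i[keep] + 1L],
                      to = ids[S@j[keep] + 1L],
                      shared_count = as.integer(S@x[keep]),
                      stringsAsFactors = FALSE)
  swap <- edges$from > edges$to
  tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]; edges$to[swap] <- tmp
  edges <- edges[order(edges$from, edges$to, method = "radix"), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(side = side, nodes = ids, edges = edges),
            class = "one_mode_projection")
}

#' @export
print.one_mode_projection <- function(x, ...) {
  cat(sprintf("One-mode projection (%s side): %d nodes, %d edges\n",
              x$side, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

# projection as an undirected simple igraph, isolated nodes included
projection_igraph <- function(proj) {
  stopifnot(inherits(proj, "one_mode_projection"))
  igraph::graph_from_data_frame(proj$edges, directed = FALSE,
                                vertices = data.frame(name = proj$nodes))
}

#' Resource-allocation weights of the gene projection
#'
#' Implements the two-step resource-allocation weighting of the gene
#' projection: each gene first splits its resource equally among its
#' diseases, each disease then splits what it received equally among its
#' genes. The resulting matrix W has entries
#' \deqn{w_{ij} = \frac{1}{k(x_j)} \sum_l \frac{a_{il} a_{jl}}{k(y_l)}}
#' the fraction of gene j's resource that ends up on gene i, where
#' \eqn{a_{il}} is the bipartite adjacency and \eqn{k(\cdot)} the degree.
#' Columns of connected genes sum to exactly 1; a gene with no disease gets
#' an all-zero row and column, which keeps gene indexing stable when edges
#' are held out upstream.
#'
#' @param net a [bdnet].
#' @param zero_diagonal set the self-return weights \eqn{w_{jj}} to zero
#'   (for sensitivity analysis; the weighting itself produces a positive
#'   diagonal for every connected gene and propagation keeps it by default).
#' @return A square weight matrix with dimnames = gene ids, column j =
#'   source gene j. Dense (`matrix`) below 2000 genes, sparse
#'   (`Matrix::dgCMatrix`) above; the contract is identical either way.
#' @seealso [two_step_spread()] for the explicit two-step process that this
#'   matrix reproduces as `W %*% f`.
#' @export
resource_allocation_weights <- function(net, zero_diagonal = FALSE) {
  stopifnot(inherits(net, "bdnet"))
  A <- adjacency_matrix(net)
  kx <- Matrix::rowSums(A)
  ky <- Matrix::colSums(A)
  inv_ky <- ifelse(ky > 0, 1 / ky, 0)
  inv_kx <- ifelse(kx > 0, 1 / kx, 0)
  W <- A %*% Matrix::Diagonal(x = inv_ky) %*% Matrix::t(A) %*%
    Matrix::Diagonal(x = inv_kx)
  dimnames(W) <- list(net$genes$id, net$genes$id)
  if (zero_diagonal) Matrix::diag(W) <- 0
  if (nrow(W) < 2000) as.matrix(W) else methods::as(W, "CsparseMatrix")
}

#' Two-step resource spreading across the bipartite network
#'
#' The explicit resource-allocation process: step 1 divides each gene's
#' resource equally among its diseases; step 2 divides each disease's
#' received resource equally among its genes. Serves as the executable
#' definition that [resource_allocation_weights()] compresses into a single
#' matrix: the result equals `W %*% f` entrywise.
#'
#' @param net a [bdnet].
#' @param f numeric resource vector, one entry per gene, in the order of
#'   `net$genes$id` (or named by gene id).
#' @return Numeric vector of final per-gene resources, named by gene id.
#' @export
two_step_spread <- function(net, f) {
  stopifnot(inherits(net, "bdnet"))
  ids <- net$genes$id
  if (!is.null(names(f))) f <- f[ids]
  if (length(f) != length(ids))
    stop("`f` must have one entry per gene", call. = FALSE)
  A <- adjacency_matrix(net)
  kx <- Matrix::rowSums(A)
  ky <- Matrix::colSums(A)
  # step 1: gene -> disease, equal split over the gene's diseases
  g_out <- ifelse(kx > 0, f / kx, 0)
  on_disease <- as.numeric(Matrix::crossprod(A, g_out))
  # step 2: disease -> gene, equal split over the disease's genes
  d_out <- ifelse(ky > 0, on_disease / ky, 0)
  res <- as.numeric(A %*% d_out)
  stats::setNames(res, ids)
}
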