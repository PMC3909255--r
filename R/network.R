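#' Bipartite gene-disease association networks
#'
#' A `bdnet` object holds a simple bipartite graph between genes (long
#' non-coding RNAs and protein-coding genes) and diseases. Edges record
#' curated association links; everything downstream (projection weighting,
#' propagation scoring, cross-validation, randomization) consumes this
#' container.
#'
#' @param genes data.frame with columns `id` and `gene_type` (one of
#'   `"lncRNA"`, `"coding"`) and optionally `label`.
#' @param diseases data.frame with column `id` and optionally `name`,
#'   `mim`, `disease_class`.
#' @param edges data.frame with columns `gene_id`, `disease_id`.
#' @return An object of class `bdnet`: a list with components `genes`,
#'   `diseases` and `edges` (deduplicated, all character columns).
#' @examples
#' net <- bdnet(
#'   genes = data.frame(id = c("g1", "g2"), gene_type = c("lncRNA", "coding")),
#'   diseases = data.frame(id = c("d1", "d2")),
#'   edges = data.frame(gene_id = c("g1", "g2", "g1"),
#'                      disease_id = c("d1", "d1", "d2"))
#' )
#' net
#' @export
bdnet <- function(genes, diseases, edges) {
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  diseases <- as.data.frame(diseases, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("id", "gene_type") %in% names(genes)))
    stop("`genes` needs columns `id` and `gene_type`", call. = FALSE)
  if (!"id" %in% names(diseases))
    stop("`diseases` needs a column `id`", call. = FALSE)
  if (!all(c("gene_id", "disease_id") %in% names(edges)))
    stop("`edges` needs columns `gene_id` and `disease_id`", call. = FALSE)
  genes$id <- as.character(genes$id)
  genes$gene_type <- as.character(genes$gene_type)
  diseases$id <- as.character(diseases$id)
  edges$gene_id <- as.character(edges$gene_id)
  edges$disease_id <- as.character(edges$disease_id)
  if (!"disease_class" %in% names(diseases)) diseases$disease_class <- NA_character_

  if (anyDuplicated(genes$id))
    stop("duplicate gene ids: ",
         paste(unique(genes$id[duplicated(genes$id)]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(diseases$id))
    stop("duplicate disease ids: ",
         paste(unique(diseases$id[duplicated(diseases$id)]), collapse = ", "),
         call. = FALSE)
  bad_type <- !genes$gene_type %in% c("lncRNA", "coding")
  if (any(bad_type))
    stop("gene_type must be 'lncRNA' or 'coding'; offending ids: ",
         paste(genes$id[bad_type], collapse = ", "), call. = FALSE)
  shared <- intersect(genes$id, diseases$id)
  if (length(shared))
    stop("ids used on both the gene and the disease side: ",
         paste(shared, collapse = ", "), call. = FALSE)
  if (!all(edges$gene_id %in% genes$id))
    stop("edge references unregistered gene id: ",
         paste(unique(setdiff(edges$gene_id, genes$id)), collapse = ", "),
         call. = FALSE)
  if (!all(edges$disease_id %in% diseases$id))
    stop("edge references unregistered disease id: ",
         paste(unique(setdiff(edges$disease_id, diseases$id)), collapse = ", "),
         call. = FALSE)
  edges <- unique(edges[c("gene_id", "disease_id")])
  rownames(edges) <- NULL
  structure(list(genes = genes, diseases = diseases, edges = edges),
            class = "bdnet")
}

#' @export
print.bdnet <- function(x, ...) {
  n_lnc <- sum(x$genes$gene_type == "lncRNA")
  cat("Bipartite gene-disease association network\n")
  cat(sprintf("  genes:    %d (%d lncRNA, %d coding)\n",
              nrow(x$genes), n_lnc, nrow(x$genes) - n_lnc))
  cat(sprintf("  diseases: %d\n", nrow(x$diseases)))
  cat(sprintf("  edges:    %d\n", nrow(x$edges)))
  invisible(x)
}

#' @export
summary.bdnet <- function(object, ...) {
  kg <- gene_degrees(object)
  kd <- disease_degrees(object)
  out <- list(
    n_genes = nrow(object$genes),
    n_lncrna = sum(object$genes$gene_type == "lncRNA"),
    n_diseases = nrow(object$diseases),
    n_edges = nrow(object$edges),
    gene_degree = summary(kg),
    disease_degree = summary(kd),
    n_classes = length(unique(stats::na.omit(object$diseases$disease_class)))
  )
  class(out) <- "summary.bdnet"
  out
}

#' @export
print.summary.bdnet <- function(x, ...) {
  cat(sprintf("bdnet: %d genes (%d lncRNA), %d diseases, %d edges, %d disease classes\n",
              x$n_genes, x$n_lncrna, x$n_diseases, x$n_edges, x$n_classes))
  cat("gene degree:\n"); print(x$gene_degree)
  cat("disease degree:\n"); print(x$disease_degree)
  invisible(x)
}

#' Node degrees in the bipartite network
#'
#' @param net a [bdnet].
#' @return Named integer vector of edge-incidence counts, covering every
#'   registered node (zero for isolated nodes).
#' @export
gene_degrees <- function(net) {
  tab <- table(factor(net$edges$gene_id, levels = net$genes$id))
  stats::setNames(as.integer(tab), names(tab))
}

#' @rdname gene_degrees
#' @export
disease_degrees <- function(net) {
  tab <- table(factor(net$edges$disease_id, levels = net$diseases$id))
  stats::setNames(as.integer(tab), names(tab))
}

# genes x diseases sparse 0/1 adjacency with dimnames
adjacency_matrix <- function(net) {
  i <- match(net$edges$gene_id, net$genes$id)
  j <- match(net$edges$disease_id, net$diseases$id)
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(nrow(net$genes), nrow(net$diseases)),
                       dimnames = list(net$genes$id, net$diseases$id))
}

#' Read a gene-disease association table
#'
#' Parses a tab-separated association table with a header row naming at
#' least `gene_id`, `gene_type` and `disease_id`; optional columns
#' `disease_class` and `source` are carried along. Lines starting with `#`
#' are ignored. Duplicate association rows collapse to one edge.
#'
#' @param path path to a TSV file.
#' @return A [bdnet]; `attr(, "parse_report")` records rows read and
#'   duplicates dropped.
#' @export
read_associations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, colClasses = "character",
                           quote = "")
  required <- c("gene_id", "gene_type", "disease_id")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("association table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- which(!tab$gene_type %in% c("lncRNA", "coding"))
  if (length(bad))
    stop(sprintf("invalid gene_type '%s' in data row %d of %s",
                 tab$gene_type[bad[1]], bad[1], path), call. = FALSE)
  conflict <- tapply(tab$gene_type, tab$gene_id,
                     function(v) length(unique(v)) > 1)
  if (any(conflict))
    stop("gene id(s) with conflicting gene_type: ",
         paste(names(conflict)[conflict], collapse = ", "), call. = FALSE)

  genes <- unique(tab[c("gene_id", "gene_type")])
  names(genes) <- c("id", "gene_type")
  if ("disease_class" %in% names(tab)) {
    dis <- unique(tab[c("disease_id", "disease_class")])
    names(dis) <- c("id", "disease_class")
    dis$disease_class[!nzchar(dis$disease_class)] <- NA_character_
    dis <- dis[order(is.na(dis$disease_class)), , drop = FALSE]
    dis <- dis[!duplicated(dis$id), , drop = FALSE]
  } else {
    dis <- data.frame(id = unique(tab$disease_id), stringsAsFactors = FALSE)
  }
  n_dup <- nrow(tab) - nrow(unique(tab[c("gene_id", "disease_id")]))
  net <- bdnet(genes, dis, tab[c("gene_id", "disease_id")])
  attr(net, "parse_report") <- list(rows_read = nrow(tab),
                                    duplicates_dropped = n_dup)
  net
}

#' Merge two association networks
#'
#' Node and edge sets are unioned; an association present in both inputs is
#' counted once. Typical use: integrating a lncRNA-disease network with a
#' protein-coding gene-disease network over a shared disease vocabulary.
#'
#' @param a,b [bdnet] objects.
#' @return The union [bdnet].
#' @export
merge_networks <- function(a, b) {
  stopifnot(inherits(a, "bdnet"), inherits(b, "bdnet"))
  both <- intersect(a$genes$id, b$genes$id)
  ta <- a$genes$gene_type[match(both, a$genes$id)]
  tb <- b$genes$gene_type[match(both, b$genes$id)]
  if (any(ta != tb))
    stop("conflicting gene_type on merge for: ",
         paste(both[ta != tb], collapse = ", "), call. = FALSE)
  genes <- rbind(a$genes[c("id", "gene_type")], b$genes[c("id", "gene_type")])
  genes <- genes[!duplicated(genes$id), , drop = FALSE]
  dis <- rbind(a$diseases[c("id", "disease_class")],
               b$diseases[c("id", "disease_class")])
  # keep the first non-missing class label per disease
  dis <- dis[order(is.na(dis$disease_class)), , drop = FALSE]
  dis <- dis[!duplicated(dis$id), , drop = FALSE]
  bdnet(genes, dis, rbind(a$edges, b$edges))
}

#' Drop low-degree nodes from a bipartite network
#'
#' Keeps exactly the edges whose two endpoints both have degree at least
#' `min_degree` in the *input* network (a single pass over the original
#' degrees); isolated nodes are dropped. With `iterate = TRUE` the pass is
#' repeated until no further endpoint falls below the threshold.
#'
#' @param net a [bdnet].
#' @param min_degree minimum degree (>= 1) an endpoint must have.
#' @param iterate repeat pruning to a fixpoint instead of a single pass.
#' @return The filtered [bdnet] (possibly empty).
#' @export
filter_min_degree <- function(net, min_degree, iterate = FALSE) {
  stopifnot(inherits(net, "bdnet"), min_degree >= 1)
  repeat {
    kg <- gene_degrees(net)
    kd <- disease_degrees(net)
    keep <- kg[net$edges$gene_id] >= min_degree &
      kd[net$edges$disease_id] >= min_degree
    edges <- net$edges[keep, , drop = FALSE]
    genes <- net$genes[net$genes$id %in% edges$gene_id, , drop = FALSE]
    dis <- net$diseases[net$diseases$id %in% edges$disease_id, , drop = FALSE]
    out <- bdnet(genes, dis, edges)
    if (!iterate || nrow(out$edges) == nrow(net$edges)) return(out)
    net <- out
  }
}

#' Export / import a bipartite network
#'
#' `write_network()` serializes a [bdnet] either as an association TSV
#' (`format = "edgelist"`: columns `gene_id`, `gene_type`, `disease_id`,
#' `disease_class`) or as GraphML with node attributes `side`, `gene_type`
#' and `disease_class`. `read_network()` reverses either format; for both,
#' export followed by import reproduces the node ids, gene types and edge
#' set exactly.
#'
#' @param net a [bdnet].
#' @param path output (input) file path.
#' @param format `"edgelist"` or `"graphml"`.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a [bdnet].
#' @export
write_network <- function(net, path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  stopifnot(inherits(net, "bdnet"))
  if (format == "edgelist") {
    tab <- data.frame(
      gene_id = net$edges$gene_id,
      gene_type = net$genes$gene_type[match(net$edges$gene_id, net$genes$id)],
      disease_id = net$edges$disease_id,
      disease_class = net$diseases$disease_class[
        match(net$edges$disease_id, net$diseases$id)],
      stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("edgelist", "graphml")) {
  format <- match.arg(format)
  if (format == "edgelist") return(read_associations(path))
  g <- igraph::read_graph(path, format = "graphml")
  v <- igraph::as_data_frame(g, what = "vertices")
  e <- igraph::as_data_frame(g, what = "edges")
  is_gene <- v$side == "gene"
  genes <- data.frame(id = v$name[is_gene],
                      gene_type = v$gene_type[is_gene],
                      stringsAsFactors = FALSE)
  dis <- data.frame(id = v$name[!is_gene],
                    disease_class = if ("disease_class" %in% names(v))
                      v$disease_class[!is_gene] else NA_character_,
                    stringsAsFactors = FALSE)
  dis$disease_class[!nzchar(dis$disease_class) | is.na(dis$disease_class)] <- NA_character_
  gene_first <- e$from %in% genes$id
  edges <- data.frame(gene_id = ifelse(gene_first, e$from, e$to),
                      disease_id = ifelse(gene_first, e$to, e$from),
                      stringsAsFactors = FALSE)
  bdnet(genes, dis, edges)
}

#' Convert a bipartite network to an igraph object
#'
#' @param net a [bdnet].
#' @return An undirected bipartite [igraph::graph] with vertex attributes
#'   `type` (TRUE for diseases), `side`, `gene_type`, `disease_class`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "bdnet"))
  verts <- data.frame(
    name = c(net$genes$id, net$diseases$id),
    type = c(rep(FALSE, nrow(net$genes)), rep(TRUE, nrow(net$diseases))),
    side = c(rep("gene", nrow(net$genes)), rep("disease", nrow(net$diseases))),
    gene_type = c(net$genes$gene_type, rep("", nrow(net$diseases))),
    disease_class = c(rep("", nrow(net$genes)),
                      ifelse(is.na(net$diseases$disease_class), "",
                             net$diseases$disease_class)),
    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE, vertices = verts)
}
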