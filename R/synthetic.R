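# Synthetic bipartite gene-disease networks with planted class structure.
#
# The generator emulates the statistical features the propagation method
# relies on: heavy-tailed degree sequences on both sides (preferential
# attachment) and within-class co-association (diseases grouped into
# phenotype classes, each gene biased towards the diseases of one home
# class). Class co-membership is exactly the structure that makes hidden
# associations recoverable, so fixtures carry a planted, testable signal
# without copying any curated data.

#' Configuration for the synthetic network generator
#'
#' Two presets bracket the scales of interest: `"small"` (60 diseases, 70
#' lncRNAs + 180 coding genes, 500 edges) keeps full-pipeline runs fast;
#' `"paper_scale"` (214 diseases, 295 lncRNAs + 801 coding genes, 1558
#' edges) matches the size of a curated coding-non-coding gene-disease
#' network. Any field can be overridden.
#'
#' @param preset `"small"` or `"paper_scale"`.
#' @param ... overrides for `n_diseases`, `n_lncrna`, `n_coding`,
#'   `n_edges`, `n_classes`, `within_class_bias`, `degree_exponent`,
#'   `n_hidden`.
#' @return A list of generator parameters.
#' @export
synthetic_config <- function(preset = c("small", "paper_scale"), ...) {
  preset <- match.arg(preset)
  cfg <- switch(preset,
    small = list(n_diseases = 60L, n_lncrna = 70L, n_coding = 180L,
                 n_edges = 500L, n_classes = 20L, within_class_bias = 100,
                 degree_exponent = 2, n_hidden = 25L),
    paper_scale = list(n_diseases = 214L, n_lncrna = 295L, n_coding = 801L,
                       n_edges = 1558L, n_classes = 20L,
                       within_class_bias = 100, degree_exponent = 2,
                       n_hidden = 50L))
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  cfg
}

#' Generate a synthetic bipartite gene-disease network
#'
#' Diseases are partitioned into classes; each gene is assigned a home
#' class. Edges are placed one at a time by preference-weighted sampling:
#' the gene is drawn with weight `(degree + 1)^p` and its disease with
#' weight `(degree + 1)^p * within_class_bias^[disease in home class]`,
#' where `p = 1 / (degree_exponent - 1)` shapes the degree tail. Each
#' disease is seeded with one edge first so every disease is reachable.
#' Duplicate edges are rejected. `n_hidden` additional pairs drawn by the
#' same biased rule — but never emitted as edges — form the planted truth
#' used in recovery tests.
#'
#' @param config list from [synthetic_config()].
#' @param seed integer seed; the generator is deterministic given
#'   (config, seed).
#' @return List with `network` (a [bdnet], disease classes attached) and
#'   `truth` (list: `gene_class` and `disease_class` named vectors, and
#'   `hidden` data.frame of held-out true associations).
#' @export
generate_network <- function(config = synthetic_config(), seed = 1) {
  set.seed(seed)
  nd <- config$n_diseases
  ng <- config$n_lncrna + config$n_coding
  if (config$n_edges > ng * nd)
    stop("n_edges exceeds the number of possible gene-disease pairs",
         call. = FALSE)
  if (config$n_edges < nd)
    stop("need at least one edge per disease (n_edges >= n_diseases)",
         call. = FALSE)
  if (config$within_class_bias < 1)
    stop("within_class_bias must be >= 1", call. = FALSE)
  if (config$degree_exponent <= 1)
    stop("degree_exponent must be > 1", call. = FALSE)
  p <- 1 / (config$degree_exponent - 1)

  gene_ids <- c(sprintf("L%03d", seq_len(config$n_lncrna)),
                sprintf("C%03d", seq_len(config$n_coding)))
  gene_type <- rep(c("lncRNA", "coding"),
                   c(config$n_lncrna, config$n_coding))
  disease_ids <- sprintf("D%03d", seq_len(nd))
  class_labels <- sprintf("class%02d", seq_len(config$n_classes))
  disease_class <- sample(rep_len(class_labels, nd))
  gene_class <- sample(class_labels, ng, replace = TRUE)
  names(disease_class) <- disease_ids
  names(gene_class) <- gene_ids

  deg_g <- integer(ng)
  deg_d <- integer(nd)
  # class match matrix: genes x diseases bias factor
  bias <- matrix(1, ng, nd)
  bias[outer(gene_class, disease_class, "==")] <- config$within_class_bias
  has_edge <- matrix(FALSE, ng, nd)
  eg <- integer(config$n_edges)
  ed <- integer(config$n_edges)
  n_placed <- 0L

  place <- function(i, l) {
    n_placed <<- n_placed + 1L
    eg[n_placed] <<- i; ed[n_placed] <<- l
    has_edge[i, l] <<- TRUE
    deg_g[i] <<- deg_g[i] + 1L
    deg_d[l] <<- deg_d[l] + 1L
  }

  # seed every disease with one edge
  for (l in sample.int(nd)) {
    w <- (deg_g + 1)^p * bias[, l]
    place(sample.int(ng, 1, prob = w), l)
  }
  # remaining edges by biased preferential attachment
  while (n_placed < config$n_edges) {
    i <- sample.int(ng, 1, prob = (deg_g + 1)^p)
    w <- (deg_d + 1)^p * bias[i, ]
    w[has_edge[i, ]] <- 0
    if (all(w == 0)) next
    place(i, sample.int(nd, 1, prob = w))
  }

  # hidden true associations: same rule, never emitted
  hidden_g <- integer(config$n_hidden)
  hidden_d <- integer(config$n_hidden)
  taken <- has_edge
  h <- 0L
  while (h < config$n_hidden) {
    i <- sample.int(ng, 1, prob = (deg_g + 1)^p)
    w <- (deg_d + 1)^p * bias[i, ]
    w[taken[i, ]] <- 0
    if (all(w == 0)) next
    l <- sample.int(nd, 1, prob = w)
    h <- h + 1L
    hidden_g[h] <- i; hidden_d[h] <- l
    taken[i, l] <- TRUE
  }

  net <- bdnet(
    genes = data.frame(id = gene_ids, gene_type = gene_type,
                       stringsAsFactors = FALSE),
    diseases = data.frame(id = disease_ids,
                          disease_class = unname(disease_class),
                          stringsAsFactors = FALSE),
    edges = data.frame(gene_id = gene_ids[eg], disease_id = disease_ids[ed],
                       stringsAsFactors = FALSE))
  truth <- list(gene_class = gene_class, disease_class = disease_class,
                hidden = data.frame(gene_id = gene_ids[hidden_g],
                                    disease_id = disease_ids[hidden_d],
                                    stringsAsFactors = FALSE))
  list(network = net, truth = truth)
}

#' Paired lncRNA-only / integrated fixtures
#'
#' Generates one integrated coding-non-coding network and returns it
#' together with its restriction to lncRNA genes: the integrated network
#' is exactly the lncRNA-only network plus the coding-gene edges, sharing
#' one class structure. Used to test that integrating coding-gene
#' associations improves cross-validated recovery.
#'
#' @inheritParams generate_network
#' @return List with `lnc_only`, `integrated` (both [bdnet]) and `truth`.
#' @export
make_paired_fixture <- function(config = synthetic_config(), seed = 1) {
  out <- generate_network(config, seed)
  net <- out$network
  lnc_genes <- net$genes[net$genes$gene_type == "lncRNA", , drop = FALSE]
  lnc_edges <- net$edges[net$edges$gene_id %in% lnc_genes$id, , drop = FALSE]
  lnc_only <- bdnet(lnc_genes, net$diseases, lnc_edges)
  list(lnc_only = lnc_only, integrated = net, truth = out$truth)
}

#' Write a generated fixture to disk
#'
#' Emits the association TSV plus a `truth.tsv` of hidden associations and
#' a `classes.tsv` mapping nodes to classes.
#'
#' @param generated output of [generate_network()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(generated$network, file.path(dir, "associations.tsv"),
                format = "edgelist")
  utils::write.table(generated$truth$hidden, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  classes <- rbind(
    data.frame(id = names(generated$truth$gene_class),
               class = unname(generated$truth$gene_class)),
    data.frame(id = names(generated$truth$disease_class),
               class = unname(generated$truth$disease_class)))
  utils::write.table(classes, file.path(dir, "classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
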