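# Shared fixtures: tiny hand-built networks, a uniform random bipartite
# generator, and brute-force oracles kept independent of the package's
# own matrix implementations.

toy_net <- function() {
  bdnet(
    genes = data.frame(id = c("g1", "g2"), gene_type = c("lncRNA", "coding")),
    diseases = data.frame(id = c("d1", "d2")),
    edges = data.frame(gene_id = c("g1", "g2", "g1"),
                       disease_id = c("d1", "d1", "d2")))
}

# uniform random simple bipartite network; all genes/diseases registered,
# some may stay isolated
rand_bdnet <- function(n_genes, n_diseases, n_edges, seed) {
  set.seed(seed)
  gids <- sprintf("g%02d", seq_len(n_genes))
  dids <- sprintf("d%02d", seq_len(n_diseases))
  pairs <- expand.grid(gene_id = gids, disease_id = dids,
                       stringsAsFactors = FALSE)
  pick <- sample(nrow(pairs), min(n_edges, nrow(pairs)))
  bdnet(genes = data.frame(id = gids,
                           gene_type = rep_len(c("lncRNA", "coding"), n_genes)),
        diseases = data.frame(id = dids),
        edges = pairs[pick, , drop = FALSE])
}

# two disjoint complete blocks: n_genes_block genes all linked to
# n_dis_block diseases, twice over
block_net <- function(n_genes_block = 5, n_dis_block = 3) {
  mk <- function(tag) {
    g <- sprintf("%sg%d", tag, seq_len(n_genes_block))
    d <- sprintf("%sd%d", tag, seq_len(n_dis_block))
    expand.grid(gene_id = g, disease_id = d, stringsAsFactors = FALSE)
  }
  edges <- rbind(mk("a"), mk("b"))
  genes <- data.frame(id = unique(edges$gene_id), gene_type = "coding")
  bdnet(genes, data.frame(id = unique(edges$disease_id)), edges)
}

# brute-force Eq-definition of the resource-allocation weights:
# w_ij = (1/k(x_j)) * sum_l a_il a_jl / k(y_l), element by element
brute_weights <- function(net) {
  ids <- net$genes$id
  dids <- net$diseases$id
  a <- matrix(0, length(ids), length(dids), dimnames = list(ids, dids))
  for (r in seq_len(nrow(net$edges)))
    a[net$edges$gene_id[r], net$edges$disease_id[r]] <- 1
  kx <- rowSums(a)
  ky <- colSums(a)
  W <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (kx[j] == 0) next
    s <- 0
    for (l in seq_along(dids))
      if (ky[l] > 0) s <- s + a[i, l] * a[j, l] / ky[l]
    W[i, j] <- s / kx[j]
  }
  W
}

# O(n^3) local clustering by explicit triple enumeration
brute_clustering <- function(proj, include_low_degree = TRUE) {
  n <- length(proj$nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(proj$nodes, proj$nodes))
  for (r in seq_len(nrow(proj$edges))) {
    adj[proj$edges$from[r], proj$edges$to[r]] <- TRUE
    adj[proj$edges$to[r], proj$edges$from[r]] <- TRUE
  }
  local <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ])
    k <- length(nb)
    if (k < 2) { local[v] <- 0; next }
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (adj[nb[a], nb[b]]) tri <- tri + 1
    local[v] <- tri / (k * (k - 1) / 2)
  }
  names(local) <- proj$nodes
  deg <- rowSums(adj)
  avg <- if (include_low_degree) mean(local)
         else mean(local[deg >= 2])
  list(local = local, average = avg)
}

# random unipartite projection-shaped graph on <= n nodes
rand_projection <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(ids, 2))
  keep <- which(runif(nrow(pairs)) < p_edge)
  structure(list(side = "disease", nodes = ids,
                 edges = data.frame(from = pairs[keep, 1],
                                    to = pairs[keep, 2],
                                    shared_count = rep(1L, length(keep)),
                                    stringsAsFactors = FALSE)),
            class = "one_mode_projection")
}

write_assoc_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(c("gene_id\tgene_type\tdisease_id", lines), path)
  path
}
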