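# Degree-preserving randomization and robustness resampling.

#' Degree-preserving shuffle of a bipartite network
#'
#' Randomizes the edge set by repeated double-edge swaps — pick two edges
#' (g1,d1), (g2,d2) and rewire to (g1,d2), (g2,d1) — rejecting any swap
#' that would duplicate an existing edge. Every gene degree and every
#' disease degree is preserved exactly, as is bipartiteness and
#' simplicity; this is the null model used throughout.
#'
#' @param net a [bdnet].
#' @param n_swaps number of attempted swaps; default `10 * |edges|`, a
#'   standard mixing heuristic.
#' @param seed optional integer seed (sets the RNG via [set.seed()]).
#' @return A shuffled [bdnet] with identical node sets and degree
#'   sequences. Networks admitting no legal swap come back unchanged.
#' @export
shuffle_bipartite <- function(net, n_swaps = NULL, seed = NULL) {
  stopifnot(inherits(net, "bdnet"))
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(net$edges)
  if (is.null(n_swaps)) n_swaps <- 10L * m
  if (n_swaps < 0) stop("n_swaps must be >= 0", call. = FALSE)
  if (m < 2 || n_swaps == 0) return(net)
  g <- net$edges$gene_id
  d <- net$edges$disease_id
  key <- function(gg, dd) paste0(gg, "\r", dd)
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (k in key(g, d)) assign(k, TRUE, envir = present)
  picks <- matrix(sample.int(m, 2L * n_swaps, replace = TRUE), ncol = 2L)
  for (s in seq_len(n_swaps)) {
    e1 <- picks[s, 1L]; e2 <- picks[s, 2L]
    if (e1 == e2) next
    g1 <- g[e1]; d1 <- d[e1]; g2 <- g[e2]; d2 <- d[e2]
    if (d1 == d2 || g1 == g2) next
    k1 <- key(g1, d2); k2 <- key(g2, d1)
    if (exists(k1, envir = present, inherits = FALSE) ||
        exists(k2, envir = present, inherits = FALSE)) next
    rm(list = c(key(g1, d1), key(g2, d2)), envir = present)
    assign(k1, TRUE, envir = present)
    assign(k2, TRUE, envir = present)
    d[e1] <- d2; d[e2] <- d1
  }
  bdnet(net$genes, net$diseases,
        data.frame(gene_id = g, disease_id = d, stringsAsFactors = FALSE))
}

#' Robustness of predictions under edge resampling (MSS-style)
#'
#' Fixes the prediction set from the full network (every gene in the top
#' fraction of its disease's candidate ranking), then repeatedly removes a
#' fraction of edges uniformly at random, re-runs the prediction on the
#' remaining network, and counts for each fixed prediction how often it is
#' re-predicted (recurrence count R). The same count under
#' degree-preserving shuffles of the full network gives the random
#' baseline R_r; a z-statistic compares mean recurrence against the random
#' ensemble.
#'
#' "Re-predicted" means the pair lands in the resampled network's own top
#' fraction for its disease, with the threshold recomputed on the reduced
#' candidate pool.
#'
#' @param net a [bdnet].
#' @inheritParams lncprop
#' @param n_resample number of resampling (and random) experiments.
#' @param drop_frac fraction of edges removed per resample, in (0,1).
#' @param fraction top fraction defining a prediction (default 0.01).
#' @param seed optional integer seed.
#' @return An object of class `robustness_result`: list with `predictions`
#'   (data.frame `gene_id`, `disease_id`, `R`, `R_random`), `n_resample`,
#'   `z` (the [ensemble_ztest()] of mean R against the per-replicate mean
#'   R_r distribution).
#' @export
mss_robustness <- function(net, alpha = 0.618, tol = 1e-5, max_iter = 1000,
                           n_resample = 1000, drop_frac = 0.10,
                           fraction = 0.01, seed = NULL) {
  stopifnot(inherits(net, "bdnet"))
  if (!(drop_frac > 0 && drop_frac < 1))
    stop("drop_frac must be in (0,1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  predict_pairs <- function(network) {
    A <- adjacency_matrix(network)
    W <- .ra_weights_from_A(A)
    ids <- rownames(A)
    res <- vector("list", ncol(A))
    for (j in seq_len(ncol(A))) {
      y <- as.numeric(A[, j] > 0)
      if (sum(y) == 0) next
      scores <- .propagate_fast(W, y, alpha, tol, max_iter)
      cand <- which(A[, j] == 0)
      if (!length(cand)) next
      ord <- order(-scores[cand], ids[cand], method = "radix")
      n_keep <- max(1L, ceiling(fraction * length(cand)))
      res[[j]] <- paste0(ids[cand][ord[seq_len(n_keep)]], "\r",
                         colnames(A)[j])
    }
    unlist(res)
  }

  base_pairs <- predict_pairs(net)
  m <- nrow(net$edges)
  n_drop <- floor(drop_frac * m)
  R <- stats::setNames(integer(length(base_pairs)), base_pairs)
  R_r <- stats::setNames(integer(length(base_pairs)), base_pairs)
  mean_rr <- numeric(n_resample)
  for (b in seq_len(n_resample)) {
    keep <- sort(sample.int(m, m - n_drop))
    sub <- bdnet(net$genes, net$diseases, net$edges[keep, , drop = FALSE])
    hit <- base_pairs %in% predict_pairs(sub)
    R[hit] <- R[hit] + 1L
    rnd <- shuffle_bipartite(net)
    hit_r <- base_pairs %in% predict_pairs(rnd)
    R_r[hit_r] <- R_r[hit_r] + 1L
    mean_rr[b] <- mean(hit_r)
  }
  parts <- do.call(rbind, strsplit(base_pairs, "\r", fixed = TRUE))
  z <- if (n_resample >= 2 && stats::sd(mean_rr) > 0)
    ensemble_ztest(mean(R) / n_resample, mean_rr) else NULL
  structure(list(predictions = data.frame(gene_id = parts[, 1],
                                          disease_id = parts[, 2],
                                          R = as.integer(R),
                                          R_random = as.integer(R_r),
                                          stringsAsFactors = FALSE),
                 n_resample = n_resample, drop_frac = drop_frac,
                 fraction = fraction, z = z),
            class = "robustness_result")
}

#' @export
print.robustness_result <- function(x, ...) {
  cat(sprintf("MSS robustness: %d predictions, %d resamples (drop %.0f%%)\n",
              nrow(x$predictions), x$n_resample, 100 * x$drop_frac))
  cat(sprintf("  median R = %d, median R_random = %d\n",
              stats::median(x$predictions$R),
              stats::median(x$predictions$R_random)))
  if (!is.null(x$z)) cat(sprintf("  z (R vs random ensemble) = %.2f\n", x$z$z))
  invisible(x)
}

#' z-test of an observed statistic against a null ensemble
#'
#' @param observed observed value of the statistic.
#' @param null_samples values of the same statistic on the null ensemble
#'   (at least two, with nonzero variance).
#' @return List with `observed`, `null_mean`, `null_sd` (sample, n-1
#'   denominator) and `z = (observed - null_mean) / null_sd`.
#' @export
ensemble_ztest <- function(observed, null_samples) {
  if (length(null_samples) < 2)
    stop("need at least two null samples", call. = FALSE)
  s <- stats::sd(null_samples)
  if (s == 0) stop("null ensemble has zero variance", call. = FALSE)
  m <- mean(null_samples)
  list(observed = observed, null_mean = m, null_sd = s,
       z = (observed - m) / s)
}

#' Count projection links between same-class diseases
#'
#' Counts the edges of a one-mode projection whose two endpoints carry the
#' same class label. Nodes without a class label are excluded (with a
#' warning). Comparing the count against a degree-preserving shuffled
#' ensemble quantifies within-class clustering of disease associations.
#'
#' @param proj a `one_mode_projection`.
#' @param classes named character vector mapping node id to class label.
#' @return Integer count of same-class edges.
#' @export
same_class_link_count <- function(proj, classes) {
  stopifnot(inherits(proj, "one_mode_projection"))
  cf <- classes[proj$edges$from]
  ct <- classes[proj$edges$to]
  unlabeled <- is.na(cf) | is.na(ct)
  if (any(unlabeled))
    warning(sum(unlabeled), " projection edge(s) with unlabeled endpoint excluded")
  sum(cf == ct, na.rm = TRUE)
}
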