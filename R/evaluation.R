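# Leave-one-out cross-validation and rank-threshold ROC/AUC.
#
# LOOCV hides one association at a time, rebuilds the resource-allocation
# weights on the reduced network (removal changes both endpoint degrees, so
# the held-out edge must not leak through W), propagates for the disease,
# and records the held-out gene's rank among that disease's candidates.

# fast internal propagation + ranking on a sparse adjacency; x-index based
.ra_weights_from_A <- function(A) {
  kx <- Matrix::rowSums(A)
  ky <- Matrix::colSums(A)
  A %*% Matrix::Diagonal(x = ifelse(ky > 0, 1 / ky, 0)) %*% Matrix::t(A) %*%
    Matrix::Diagonal(x = ifelse(kx > 0, 1 / kx, 0))
}

.propagate_fast <- function(W, y, alpha, tol, max_iter, stat = "mad") {
  f <- y
  base <- (1 - alpha) * y
  it <- 0L
  repeat {
    it <- it + 1L
    f_new <- alpha * as.numeric(W %*% f) + base
    d <- f_new - f
    dev <- if (stat == "msd") mean(d * d) else mean(abs(d))
    f <- f_new
    if (dev <= tol || it >= max_iter) break
  }
  f
}

# dense rank of gene index `target` among candidate indices `cand`
# (descending score, ties by ascending gene id)
.rank_of <- function(scores, cand, ids, target) {
  s_t <- scores[target]
  id_t <- ids[target]
  s_c <- scores[cand]
  1L + sum(s_c > s_t) + sum(s_c == s_t & ids[cand] < id_t)
}

#' Leave-one-out cross-validation of the propagation predictor
#'
#' Each retained association (g, d) is removed in turn; the
#' resource-allocation weight matrix is rebuilt on the reduced network, the
#' propagation is run for d, and the rank of g among the genes not
#' associated with d (in the reduced network) is recorded as a positive.
#' Negative ranks — the ranks of all unassociated gene-disease pairs — are
#' computed once from the full (filtered) network by default, or per fold
#' with `per_fold_negatives = TRUE`.
#'
#' Nodes of degree one are removed first (single pass, via
#' [filter_min_degree()]): a held-out edge at a degree-one endpoint would
#' isolate the node, which can then receive no information.
#'
#' @param net a [bdnet].
#' @inheritParams lncprop
#' @param prefilter drop degree-one nodes before validation (default TRUE).
#' @param per_fold_negatives recompute negative ranks on every reduced
#'   network instead of once on the full network.
#' @param progress print a dot every 50 folds.
#' @return An object of class `loocv_result`: list with `folds`
#'   (data.frame `gene_id`, `disease_id`, `rank`, `n_candidates`),
#'   `negatives` (data.frame `gene_id`, `disease_id`, `rank`),
#'   `n_skipped`, and the configuration used.
#' @export
loocv <- function(net, alpha = 0.618, tol = 1e-5, max_iter = 1000,
                  stat = c("mad", "msd"), prefilter = TRUE,
                  per_fold_negatives = FALSE, progress = FALSE) {
  stopifnot(inherits(net, "bdnet"))
  stat <- match.arg(stat)
  if (prefilter) net <- filter_min_degree(net, 2)
  if (nrow(net$edges) == 0)
    stop("network is empty after degree filtering", call. = FALSE)
  A <- adjacency_matrix(net)
  ids <- rownames(A)
  ei <- match(net$edges$gene_id, ids)
  ej <- match(net$edges$disease_id, colnames(A))

  score_disease <- function(Am, W, j) {
    y <- as.numeric(Am[, j] > 0)
    .propagate_fast(W, y, alpha, tol, max_iter, stat)
  }

  ranks <- integer(length(ei))
  ncand <- integer(length(ei))
  for (f in seq_along(ei)) {
    i <- ei[f]; j <- ej[f]
    A2 <- A
    A2[i, j] <- 0
    W2 <- .ra_weights_from_A(A2)
    scores <- score_disease(A2, W2, j)
    cand <- which(A2[, j] == 0)
    ranks[f] <- .rank_of(scores, cand, ids, i)
    ncand[f] <- length(cand)
    if (progress && f %% 50 == 0) cat(".")
  }
  if (progress) cat("\n")
  folds <- data.frame(gene_id = net$edges$gene_id,
                      disease_id = net$edges$disease_id,
                      rank = ranks, n_candidates = ncand,
                      stringsAsFactors = FALSE)

  negatives <- if (per_fold_negatives) {
    neg <- vector("list", length(ei))
    for (f in seq_along(ei)) {
      i <- ei[f]; j <- ej[f]
      A2 <- A
      A2[i, j] <- 0
      W2 <- .ra_weights_from_A(A2)
      scores <- score_disease(A2, W2, j)
      cand <- setdiff(which(A2[, j] == 0), i)
      ord <- order(-scores[cand], ids[cand], method = "radix")
      neg[[f]] <- data.frame(gene_id = ids[cand][ord],
                             disease_id = colnames(A)[j],
                             rank = seq_along(ord),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, neg)
  } else {
    W <- .ra_weights_from_A(A)
    neg <- vector("list", ncol(A))
    for (j in seq_len(ncol(A))) {
      scores <- score_disease(A, W, j)
      cand <- which(A[, j] == 0)
      if (!length(cand)) next
      ord <- order(-scores[cand], ids[cand], method = "radix")
      neg[[j]] <- data.frame(gene_id = ids[cand][ord],
                             disease_id = colnames(A)[j],
                             rank = seq_along(cand),
                             stringsAsFactors = FALSE)
    }
    do.call(rbind, neg)
  }
  rownames(negatives) <- NULL
  structure(list(folds = folds, negatives = negatives, n_skipped = 0L,
                 config = list(alpha = alpha, tol = tol, max_iter = max_iter,
                               stat = stat, prefilter = prefilter,
                               per_fold_negatives = per_fold_negatives)),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV: %d folds, %d negative pairs (alpha = %g)\n",
              nrow(x$folds), nrow(x$negatives), x$config$alpha))
  cat(sprintf("  median positive rank: %g\n", stats::median(x$folds$rank)))
  invisible(x)
}

#' Rank-threshold ROC curve and AUC from LOOCV ranks
#'
#' For each rank threshold delta = 1..`delta_max`, TPR(delta) is the
#' fraction of held-out associations recovered within the top delta ranks
#' and FPR(delta) the fraction of unassociated pairs ranked within the top
#' delta. The AUC is the trapezoidal area over the (FPR, TPR) sweep with
#' endpoints (0,0) and (1,1) appended (the sweep need not reach FPR = 1).
#'
#' @param result a `loocv_result` from [loocv()].
#' @param delta_max largest rank threshold (default 100).
#' @return An object of class `roc_curve`: list with `curve` (data.frame
#'   `delta`, `tpr`, `fpr`), `auc`, `n_folds`, `n_negatives`.
#' @export
roc_from_ranks <- function(result, delta_max = 100) {
  stopifnot(inherits(result, "loocv_result"))
  pos <- result$folds$rank
  neg <- result$negatives$rank
  if (!length(pos)) stop("no LOOCV folds to evaluate", call. = FALSE)
  if (!length(neg)) stop("no negative pairs to evaluate", call. = FALSE)
  delta <- seq_len(delta_max)
  tpr <- vapply(delta, function(d) mean(pos <= d), 0)
  fpr <- vapply(delta, function(d) mean(neg <= d), 0)
  fx <- c(0, fpr, 1)
  fy <- c(0, tpr, 1)
  auc <- sum(diff(fx) * (utils::head(fy, -1) + utils::tail(fy, -1)) / 2)
  structure(list(curve = data.frame(delta = delta, tpr = tpr, fpr = fpr),
                 auc = auc, n_folds = length(pos), n_negatives = length(neg)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Rank-threshold ROC (delta = 1..%d): AUC = %.4f (%d folds, %d negatives)\n",
              max(x$curve$delta), x$auc, x$n_folds, x$n_negatives))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(c(0, x$curve$fpr, 1), c(0, x$curve$tpr, 1), type = "l",
       xlab = "FPR", ylab = "TPR", xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Compare LOOCV performance of two networks
#'
#' Runs [loocv()] and [roc_from_ranks()] on both networks (typically the
#' lncRNA-only association network versus the integrated coding-non-coding
#' network) and reports both AUCs and their difference.
#'
#' @param lnc_only,integrated [bdnet] objects.
#' @inheritParams loocv
#' @param delta_max largest rank threshold for the ROC sweep.
#' @return List with `auc_lnc_only`, `auc_integrated`, `difference`
#'   (integrated minus lnc-only) and the two `roc_curve` objects.
#' @export
compare_networks <- function(lnc_only, integrated, alpha = 0.618,
                             tol = 1e-5, max_iter = 1000, delta_max = 100) {
  roc_a <- roc_from_ranks(loocv(lnc_only, alpha, tol, max_iter), delta_max)
  roc_b <- roc_from_ranks(loocv(integrated, alpha, tol, max_iter), delta_max)
  list(auc_lnc_only = roc_a$auc, auc_integrated = roc_b$auc,
       difference = roc_b$auc - roc_a$auc,
       roc_lnc_only = roc_a, roc_integrated = roc_b)
}
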