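#' Fit a propagation model on a gene-disease bipartite network
#'
#' `lncprop()` is the central model constructor: it takes a bipartite
#' gene-disease association network, builds the resource-allocation
#' weighted gene projection W, and stores the propagation configuration.
#' Scores for any query disease are then obtained with
#' [predict.lncprop()], which iterates
#' \deqn{F_t = \alpha W F_{t-1} + (1-\alpha) Y, \qquad F_0 = Y,}
#' where Y is the 0/1 initial-information vector of the disease (1 for
#' genes already associated with it). The iteration stops when the mean
#' score deviation between consecutive score vectors drops to `tol`.
#'
#' @param net a [bdnet].
#' @param alpha relative weight of propagated versus initial information,
#'   in (0,1); default 0.618.
#' @param tol stopping threshold on the mean score deviation between
#'   consecutive iterations; default 1e-5.
#' @param max_iter iteration safeguard; default 1000.
#' @param stat deviation statistic: `"mad"` (mean absolute per-gene
#'   deviation, default) or `"msd"` (mean of squared deviations). The
#'   absolute form is the default because at `tol` it leaves the iterate
#'   within a small multiple of `tol` of the closed-form limit, while the
#'   squared form stops already at deviations around `sqrt(tol)`.
#' @param zero_diagonal drop the self-return weights from W (sensitivity
#'   analysis; default keeps them, as the weighting produces them).
#' @return An object of class `lncprop` with components `net`, `W`,
#'   `alpha`, `tol`, `max_iter`, `stat`.
#' @examples
#' net <- bdnet(
#'   genes = data.frame(id = c("g1", "g2", "g3"),
#'                      gene_type = c("lncRNA", "coding", "lncRNA")),
#'   diseases = data.frame(id = c("d1", "d2")),
#'   edges = data.frame(gene_id = c("g1", "g2", "g3"),
#'                      disease_id = c("d1", "d1", "d2"))
#' )
#' fit <- lncprop(net)
#' predict(fit, diseases = "d1")
#' @export
lncprop <- function(net, alpha = 0.618, tol = 1e-5, max_iter = 1000,
                    stat = c("mad", "msd"), zero_diagonal = FALSE) {
  stopifnot(inherits(net, "bdnet"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  stat <- match.arg(stat)
  W <- resource_allocation_weights(net, zero_diagonal = zero_diagonal)
  structure(list(net = net, W = W, alpha = alpha, tol = tol,
                 max_iter = max_iter, stat = stat),
            class = "lncprop")
}

#' @export
print.lncprop <- function(x, ...) {
  cat("Propagation model on a gene-disease bipartite network\n")
  cat(sprintf("  genes: %d, diseases: %d, edges: %d\n",
              nrow(x$net$genes), nrow(x$net$diseases), nrow(x$net$edges)))
  cat(sprintf("  alpha = %g, tol = %g (%s), max_iter = %d\n",
              x$alpha, x$tol, x$stat, x$max_iter))
  invisible(x)
}

#' @export
summary.lncprop <- function(object, ...) {
  print(object)
  cat("weight matrix W:\n")
  cs <- colSums(as.matrix(object$W))
  cat(sprintf("  %d x %d, %d connected gene columns summing to 1\n",
              nrow(object$W), ncol(object$W), sum(abs(cs - 1) < 1e-9)))
  invisible(object)
}

#' @export
coef.lncprop <- function(object, ...) object$W

#' Initial-information vector for a query disease
#'
#' @param net a [bdnet].
#' @param disease a disease id present in `net`.
#' @return Named 0/1 numeric vector over genes: 1 iff the gene is
#'   associated with `disease`. A zero-degree disease yields all zeros with
#'   a warning (propagation then returns all-zero scores).
#' @export
initial_information <- function(net, disease) {
  stopifnot(inherits(net, "bdnet"))
  if (!disease %in% net$diseases$id)
    stop("unknown disease id: ", disease, call. = FALSE)
  y <- as.numeric(net$genes$id %in%
                    net$edges$gene_id[net$edges$disease_id == disease])
  if (sum(y) == 0)
    warning("disease '", disease, "' has no associated genes; Y is all zero")
  stats::setNames(y, net$genes$id)
}

#' Iterative propagation of initial information over the weighted projection
#'
#' Runs \eqn{F_t = \alpha W F_{t-1} + (1-\alpha) Y} from \eqn{F_0 = Y}
#' until the mean (squared) deviation between consecutive score vectors is
#' at most `tol`, or `max_iter` is hit.
#'
#' @param W weight matrix from [resource_allocation_weights()].
#' @param Y numeric initial-information vector in W's gene order.
#' @inheritParams lncprop
#' @return List with `scores` (named like `Y` if `Y` is named),
#'   `iterations_used`, `converged`, `deviation` (the last deviation).
#' @export
propagate <- function(W, Y, alpha = 0.618, tol = 1e-5, max_iter = 1000,
                      stat = c("mad", "msd")) {
  stat <- match.arg(stat)
  if (!(alpha >= 0 && alpha < 1)) stop("alpha must be in [0,1)", call. = FALSE)
  if (any(!is.finite(Y)) || any(!is.finite(W@x %||% as.numeric(W))))
    stop("non-finite values in W or Y", call. = FALSE)
  f <- as.numeric(Y)
  base <- (1 - alpha) * f
  dev <- Inf
  devs <- numeric(0)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    f_new <- alpha * as.numeric(W %*% f) + base
    d <- f_new - f
    dev <- if (stat == "msd") mean(d * d) else mean(abs(d))
    devs[it] <- dev
    f <- f_new
    if (dev <= tol) break
  }
  list(scores = stats::setNames(f, names(Y)), iterations_used = it,
       converged = dev <= tol, deviation = dev, deviations = devs)
}

`%||%` <- function(a, b) tryCatch(a, error = function(e) b)

#' Closed-form limit of the propagation iteration
#'
#' Solves \eqn{(I - \alpha W) F = (1-\alpha) Y} directly. The spectral
#' radius of \eqn{\alpha W} is below 1 for \eqn{\alpha < 1} because W's
#' columns sum to at most 1, so the linear system is non-singular and the
#' solution is the limit of [propagate()]. Used as the independent oracle
#' for the iterative path.
#'
#' @inheritParams propagate
#' @return Named numeric score vector.
#' @export
propagate_closed_form <- function(W, Y, alpha = 0.618) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  n <- nrow(W)
  M <- diag(n) - alpha * as.matrix(W)
  stats::setNames(as.numeric(solve(M, (1 - alpha) * as.numeric(Y))), names(Y))
}

#' Rank candidate genes for a disease
#'
#' Ranks the genes *not* associated with the query disease by descending
#' propagation score. Ties are broken by ascending gene id (radix order,
#' locale-independent), so ranks are 1-based, dense and deterministic.
#'
#' @param scores named numeric score vector over all genes (e.g.
#'   `propagate(...)$scores`).
#' @param net a [bdnet].
#' @param disease the query disease id.
#' @return data.frame `gene_id`, `score`, `rank`, ordered by rank.
#' @export
rank_candidates <- function(scores, net, disease) {
  stopifnot(inherits(net, "bdnet"))
  assoc <- net$edges$gene_id[net$edges$disease_id == disease]
  cand <- setdiff(net$genes$id, assoc)
  s <- scores[cand]
  ord <- order(-s, cand, method = "radix")
  data.frame(gene_id = cand[ord], score = as.numeric(s[ord]),
             rank = seq_along(ord), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Prediction sets from a ranked candidate list
#'
#' `predict_top_fraction()` keeps the top `ceiling(fraction * n)` ranked
#' candidates (at least one when any candidate exists), the "top 1%" rule;
#' `predict_top_k()` keeps the first `min(k, n)`.
#'
#' @param ranked data.frame from [rank_candidates()].
#' @param fraction fraction of candidates to keep, in (0, 1].
#' @param k number of candidates to keep, >= 0.
#' @return The head of `ranked`.
#' @export
predict_top_fraction <- function(ranked, fraction = 0.01) {
  if (!(fraction > 0 && fraction <= 1))
    stop("fraction must be in (0,1]", call. = FALSE)
  n <- nrow(ranked)
  if (n == 0) return(ranked)
  utils::head(ranked, max(1L, ceiling(fraction * n)))
}

#' @rdname predict_top_fraction
#' @export
predict_top_k <- function(ranked, k = 10) {
  if (k < 0) stop("k must be non-negative", call. = FALSE)
  utils::head(ranked, min(k, nrow(ranked)))
}

#' Score and rank candidate genes for diseases
#'
#' Runs the propagation for each requested disease on the fitted model and
#' returns the ranked candidate genes, optionally truncated by the top-1%
#' rule or a top-k cut.
#'
#' @param object an [lncprop] model.
#' @param diseases disease ids to score; default all diseases in the
#'   network.
#' @param threshold `"none"` (all candidates), `"fraction"` (top
#'   `fraction` by the ceiling rule) or `"k"` (top `k`).
#' @param fraction,k thresholds for the respective rules.
#' @param ... unused.
#' @return data.frame `disease_id`, `gene_id`, `gene_type`, `score`,
#'   `rank`, one block per disease.
#' @export
predict.lncprop <- function(object, diseases = NULL,
                            threshold = c("none", "fraction", "k"),
                            fraction = 0.01, k = 10, ...) {
  threshold <- match.arg(threshold)
  net <- object$net
  if (is.null(diseases)) diseases <- net$diseases$id
  unknown <- setdiff(diseases, net$diseases$id)
  if (length(unknown))
    stop("unknown disease id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- lapply(diseases, function(d) {
    Y <- initial_information(net, d)
    pr <- propagate(object$W, Y, object$alpha, object$tol,
                    object$max_iter, object$stat)
    ranked <- rank_candidates(pr$scores, net, d)
    ranked <- switch(threshold,
                     none = ranked,
                     fraction = predict_top_fraction(ranked, fraction),
                     k = predict_top_k(ranked, k))
    if (nrow(ranked) == 0) return(NULL)
    cbind(data.frame(disease_id = d, stringsAsFactors = FALSE), ranked)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(disease_id = character(), gene_id = character(),
                      score = numeric(), rank = integer())
  out$gene_type <- net$genes$gene_type[match(out$gene_id, net$genes$id)]
  rownames(out) <- NULL
  out[c("disease_id", "gene_id", "gene_type", "score", "rank")]
}
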