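# Descriptive topology: degree distributions, clustering, components.

#' Degree distribution with a descriptive log-log slope
#'
#' Tabulates the degree histogram of a one-mode projection or of one side
#' of the bipartite network, and fits (least squares) the slope of
#' log P(k) versus log k over degrees k >= 1. Heavy-tailed, power-law-like
#' distributions show a clearly negative slope; the fit is descriptive
#' only, not a maximum-likelihood exponent estimate.
#'
#' @param x a `one_mode_projection` or a [bdnet].
#' @param side for a [bdnet], which side's degrees to tabulate.
#' @return List with `histogram` (data.frame `degree`, `count`,
#'   `fraction`, including degree 0) and `loglog_slope` (NA when fewer
#'   than two positive degrees occur).
#' @export
degree_distribution <- function(x, side = c("gene", "disease")) {
  if (inherits(x, "bdnet")) {
    side <- match.arg(side)
    deg <- if (side == "gene") gene_degrees(x) else disease_degrees(x)
  } else if (inherits(x, "one_mode_projection")) {
    deg <- projection_degrees(x)
  } else stop("unsupported input", call. = FALSE)
  if (!length(deg)) stop("empty graph", call. = FALSE)
  tab <- table(deg)
  hist <- data.frame(degree = as.integer(names(tab)),
                     count = as.integer(tab),
                     fraction = as.integer(tab) / length(deg))
  pos <- hist[hist$degree >= 1, , drop = FALSE]
  slope <- if (nrow(pos) >= 2)
    unname(stats::coef(stats::lm(log(fraction) ~ log(degree), data = pos))[2])
  else NA_real_
  list(histogram = hist, loglog_slope = slope)
}

#' Degrees of projection nodes
#'
#' @param proj a `one_mode_projection`.
#' @return Named integer vector over all projection nodes (0 for isolated
#'   nodes).
#' @export
projection_degrees <- function(proj) {
  stopifnot(inherits(proj, "one_mode_projection"))
  tab <- table(factor(c(proj$edges$from, proj$edges$to), levels = proj$nodes))
  stats::setNames(as.integer(tab), names(tab))
}

#' Local clustering coefficients and their average
#'
#' Watts-Strogatz local clustering: for each node, the number of edges
#' among its neighbors divided by the number of neighbor pairs. Nodes of
#' degree below two have no closed triple and contribute 0 by default; set
#' `include_low_degree = FALSE` to average over degree >= 2 nodes only.
#'
#' @param proj a `one_mode_projection` (simple undirected graph).
#' @param include_low_degree count degree-<2 nodes as 0 in the average
#'   (default) or exclude them.
#' @return List with `local` (named vector) and `average`.
#' @export
clustering_coefficient <- function(proj, include_low_degree = TRUE) {
  g <- projection_igraph(proj)
  local <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(local) <- igraph::V(g)$name
  if (include_low_degree) {
    avg <- if (length(local)) mean(local) else NaN
  } else {
    deg <- igraph::degree(g)
    avg <- if (any(deg >= 2)) mean(local[deg >= 2]) else NaN
  }
  list(local = local, average = avg)
}

#' Size of the giant connected component
#'
#' @param proj a `one_mode_projection`.
#' @return Size (node count) of the largest connected component; 0 for an
#'   empty graph.
#' @export
giant_component_size <- function(proj) {
  if (!length(proj$nodes)) return(0L)
  g <- projection_igraph(proj)
  max(igraph::components(g)$csize)
}

#' Compare a projection statistic against a degree-sequence-preserving
#' random ensemble
#'
#' Builds `n_random` randomized versions of the projection by double-edge
#' swaps that preserve every node's degree (and keep the graph simple),
#' evaluates the chosen statistic on each, and z-tests the observed value
#' against the ensemble via [ensemble_ztest()].
#'
#' @param proj a `one_mode_projection`.
#' @param statistic `"avg_clustering"` or `"giant_component"`.
#' @param n_random ensemble size (>= 2).
#' @param n_swaps swap attempts per draw; default `10 * |edges|`.
#' @param include_low_degree passed to [clustering_coefficient()].
#' @param seed optional integer seed.
#' @return The [ensemble_ztest()] list, plus `null_samples`.
#' @export
topology_vs_random <- function(proj,
                               statistic = c("avg_clustering", "giant_component"),
                               n_random = 100, n_swaps = NULL,
                               include_low_degree = TRUE, seed = NULL) {
  statistic <- match.arg(statistic)
  if (n_random < 2) stop("n_random must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_swaps)) n_swaps <- 10L * nrow(proj$edges)
  stat_fun <- function(p) {
    if (statistic == "avg_clustering")
      clustering_coefficient(p, include_low_degree)$average
    else as.numeric(giant_component_size(p))
  }
  obs <- stat_fun(proj)
  g <- projection_igraph(proj)
  null_samples <- vapply(seq_len(n_random), function(b) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                   niter = n_swaps))
    e <- igraph::as_data_frame(gr, what = "edges")
    p <- structure(list(side = proj$side, nodes = proj$nodes,
                        edges = data.frame(from = e$from, to = e$to,
                                           shared_count = NA_integer_,
                                           stringsAsFactors = FALSE)),
                   class = "one_mode_projection")
    stat_fun(p)
  }, 0)
  out <- ensemble_ztest(obs, null_samples)
  out$null_samples <- null_samples
  out$statistic <- statistic
  out
}
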