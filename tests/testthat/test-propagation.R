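test_that("worked 2-gene example reproduces the hand-solved scores", {
  # (I - aW) F = (1-a) Y with W = [[.5,.5],[.5,.5]], Y = (1,0), a = .618
  # has the closed-form solution F = (0.691, 0.309)
  W <- matrix(0.5, 2, 2)
  Y <- c(1, 0)
  expect_equal(propagate_closed_form(W, Y, 0.618), c(0.691, 0.309),
               tolerance = 5e-4)
  it <- propagate(W, Y, alpha = 0.618, tol = 1e-12)
  expect_true(it$converged)
  expect_equal(unname(it$scores), c(0.691, 0.309), tolerance = 5e-4)
})

test_that("propagation degenerate cases behave as the update rule implies", {
  W <- matrix(c(0.6, 0.4, 0.4, 0.6), 2)
  # alpha = 0 returns Y after one iteration
  r0 <- propagate(W, c(1, 0), alpha = 0)
  expect_equal(unname(r0$scores), c(1, 0))
  expect_equal(r0$iterations_used, 1L)
  # Y = 0 is a fixed point
  expect_equal(unname(propagate(W, c(0, 0), alpha = 0.618)$scores), c(0, 0))
  # W = I leaves Y unchanged in the closed form
  expect_equal(propagate_closed_form(diag(3), c(0.2, 1, 0), 0.5),
               c(0.2, 1, 0))
  expect_error(propagate(matrix(c(1, NA, 0, 1), 2), c(1, 0)), "non-finite")
})

test_that("iterative and closed-form propagation agree on random instances", {
  tol <- 1e-5
  worst <- 0
  for (s in 1:100) {
    set.seed(s)
    net <- rand_bdnet(sample(4:15, 1), sample(3:10, 1), sample(6:30, 1),
                      seed = s + 1000)
    W <- resource_allocation_weights(net)
    Y <- as.numeric(stats::runif(nrow(W)) < 0.3)
    alpha <- stats::runif(1, 0.1, 0.9)
    fi <- propagate(W, Y, alpha, tol = tol)$scores
    fc <- propagate_closed_form(W, Y, alpha)
    worst <- max(worst, max(abs(fi - fc)))
  }
  expect_lte(worst, 10 * tol)
})

test_that("propagation scores are bounded, scale-equivariant, and the
           deviation sequence decreases", {
  for (s in 1:25) {
    net <- rand_bdnet(sample(4:12, 1), sample(3:8, 1), sample(6:25, 1),
                      seed = s + 2000)
    W <- resource_allocation_weights(net)
    set.seed(s)
    Y <- as.numeric(stats::runif(nrow(W)) < 0.4)
    r <- propagate(W, Y, alpha = 0.618, tol = 1e-9)
    # scores are non-negative and propagation conserves total information
    # mass when no gene is isolated (columns of W sum to one), so no score
    # can exceed the number of seed genes
    expect_true(all(r$scores >= 0))
    if (all(gene_degrees(net) > 0)) {
      expect_equal(sum(r$scores), sum(Y), tolerance = 1e-6)
      expect_lte(max(r$scores), sum(Y) + 1e-9)
    }
    # scale equivariance: exact in the limit, approximate for the stopped
    # iteration (the deviation threshold is not scale-free)
    expect_equal(propagate_closed_form(W, 3 * Y, 0.618),
                 3 * propagate_closed_form(W, Y, 0.618), tolerance = 1e-12)
    r3 <- propagate(W, 3 * Y, alpha = 0.618, tol = 1e-9)
    expect_equal(unname(r3$scores), unname(3 * r$scores), tolerance = 1e-3)
    # mean-square deviation non-increasing after the second iteration
    if (length(r$deviations) > 2)
      expect_true(all(diff(r$deviations[-1]) <= 1e-15))
  }
})

test_that("initial information marks exactly the associated genes", {
  net <- toy_net()
  expect_equal(initial_information(net, "d2"), c(g1 = 1, g2 = 0))
  expect_equal(initial_information(net, "d1"), c(g1 = 1, g2 = 1))
  expect_error(initial_information(net, "dX"), "unknown disease")
  iso <- bdnet(net$genes, data.frame(id = c("d1", "d2", "d3")), net$edges)
  expect_warning(y <- initial_information(iso, "d3"), "no associated genes")
  expect_equal(unname(y), c(0, 0))
})

test_that("candidate ranking excludes known genes and breaks ties by id", {
  net <- bdnet(data.frame(id = c("g1", "g2", "g3"), gene_type = "coding"),
               data.frame(id = "d1"),
               data.frame(gene_id = "g1", disease_id = "d1"))
  ranked <- rank_candidates(c(g1 = 9, g2 = 0.2, g3 = 0.4), net, "d1")
  expect_equal(ranked$gene_id, c("g3", "g2"))
  expect_equal(ranked$rank, 1:2)
  # tie -> lexicographically smaller id first
  tied <- rank_candidates(c(g1 = 9, g3 = 0.4, g2 = 0.4), net, "d1")
  expect_equal(tied$gene_id, c("g2", "g3"))
  # every gene associated -> empty list
  all_net <- bdnet(net$genes, net$diseases,
                   data.frame(gene_id = c("g1", "g2", "g3"),
                              disease_id = "d1"))
  expect_equal(nrow(rank_candidates(c(g1 = 1, g2 = 1, g3 = 1),
                                    all_net, "d1")), 0)
})

test_that("top-fraction and top-k cuts follow the ceiling and min rules", {
  ranked <- data.frame(gene_id = sprintf("g%03d", 1:200),
                       score = seq(1, 0.005, length.out = 200),
                       rank = 1:200)
  expect_equal(nrow(predict_top_fraction(ranked, 0.01)), 2)
  expect_equal(nrow(predict_top_fraction(ranked[1:50, ], 0.01)), 1)
  expect_equal(nrow(predict_top_fraction(ranked[0, ], 0.01)), 0)
  expect_error(predict_top_fraction(ranked, 0), "fraction")
  expect_equal(nrow(predict_top_k(ranked[1:15, ], 10)), 10)
  expect_equal(nrow(predict_top_k(ranked[1:4, ], 10)), 4)
  expect_equal(nrow(predict_top_k(ranked, 0)), 0)
  expect_error(predict_top_k(ranked, -1), "non-negative")
})

test_that("the fitted model predicts ranked candidates per disease", {
  gen <- generate_network(synthetic_config("small", n_diseases = 15L,
                                           n_lncrna = 10L, n_coding = 30L,
                                           n_edges = 60L, n_hidden = 5L),
                          seed = 5)
  fit <- lncprop(gen$network)
  expect_s3_class(fit, "lncprop")
  pred <- predict(fit, threshold = "k", k = 10)
  expect_true(all(pred$rank <= 10))
  expect_setequal(unique(pred$disease_id), gen$network$diseases$id)
  # predicted pairs are never known associations
  known <- paste(gen$network$edges$gene_id, gen$network$edges$disease_id)
  expect_false(any(paste(pred$gene_id, pred$disease_id) %in% known))
  expect_error(lncprop(gen$network, alpha = 1.2), "alpha")
  expect_error(predict(fit, diseases = "nope"), "unknown disease")
})
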