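test_that("association tables parse, deduplicate and validate", {
  path <- write_assoc_tsv(c("g1\tlncRNA\td1", "g2\tcoding\td1",
                            "g1\tlncRNA\td2"))
  net <- read_associations(path)
  expect_equal(nrow(net$genes), 2)
  expect_equal(nrow(net$diseases), 2)
  expect_equal(nrow(net$edges), 3)

  dup <- write_assoc_tsv(c("g1\tlncRNA\td1", "g1\tlncRNA\td1"))
  net2 <- read_associations(dup)
  expect_equal(nrow(net2$edges), 1)
  expect_equal(attr(net2, "parse_report")$duplicates_dropped, 1)

  bad <- write_assoc_tsv(c("g1\tlncRNA\td1", "g2\tmRNA\td1"))
  expect_error(read_associations(bad), "mRNA.*row 2")

  nohdr <- tempfile()
  writeLines(c("gene_id\tdisease_id", "g1\td1"), nohdr)
  expect_error(read_associations(nohdr), "required column")
})

test_that("degree sums equal the edge count on loaded and merged networks", {
  for (s in 1:20) {
    net <- rand_bdnet(8, 6, sample(5:30, 1), seed = s)
    expect_identical(sum(gene_degrees(net)), nrow(net$edges))
    expect_identical(sum(disease_degrees(net)), nrow(net$edges))
  }
})

test_that("merging unions nodes and edges, shared edges counted once", {
  a <- bdnet(data.frame(id = c("g1", "g2"), gene_type = "lncRNA"),
             data.frame(id = "d1"),
             data.frame(gene_id = c("g1", "g2"), disease_id = "d1"))
  b <- bdnet(data.frame(id = "g3", gene_type = "coding"),
             data.frame(id = "d2"),
             data.frame(gene_id = "g3", disease_id = "d2"))
  m <- merge_networks(a, b)
  expect_equal(nrow(m$genes), 3)
  expect_equal(nrow(m$diseases), 2)
  expect_equal(nrow(m$edges), 3)

  b2 <- bdnet(data.frame(id = "g1", gene_type = "lncRNA"),
              data.frame(id = "d1"),
              data.frame(gene_id = "g1", disease_id = "d1"))
  m2 <- merge_networks(a, b2)
  expect_equal(nrow(m2$edges), 2)

  conflict <- bdnet(data.frame(id = "g1", gene_type = "coding"),
                    data.frame(id = "d1"),
                    data.frame(gene_id = "g1", disease_id = "d1"))
  expect_error(merge_networks(a, conflict), "conflicting gene_type")
})

test_that("merging paper-scale lncRNA and coding fixtures reproduces the integrated scale", {
  cfg <- synthetic_config("paper_scale")
  pf <- make_paired_fixture(cfg, seed = 3)
  coding_genes <- pf$integrated$genes[pf$integrated$genes$gene_type == "coding", ]
  coding_edges <- pf$integrated$edges[
    pf$integrated$edges$gene_id %in% coding_genes$id, ]
  coding_net <- bdnet(coding_genes, pf$integrated$diseases, coding_edges)
  merged <- merge_networks(pf$lnc_only, coding_net)
  expect_equal(nrow(merged$edges), 1558)
  expect_equal(nrow(merged$genes), 1096)
  expect_equal(nrow(merged$diseases), 214)
})

test_that("degree filtering is single-pass on input degrees", {
  net <- bdnet(data.frame(id = c("g1", "g2"), gene_type = "lncRNA"),
               data.frame(id = c("d1", "d2")),
               data.frame(gene_id = c("g1", "g1", "g2"),
                          disease_id = c("d1", "d2", "d1")))
  f <- filter_min_degree(net, 2)
  # g2 and d2 have degree 1 in the input, so only g1-d1 survives even
  # though g1 and d1 then drop to degree 1 themselves
  expect_equal(f$edges,
               data.frame(gene_id = "g1", disease_id = "d1"))
  # iterating to fixpoint empties it
  expect_equal(nrow(filter_min_degree(net, 2, iterate = TRUE)$edges), 0)

  # complete 2x2 is untouched
  full <- bdnet(data.frame(id = c("g1", "g2"), gene_type = "coding"),
                data.frame(id = c("d1", "d2")),
                expand.grid(gene_id = c("g1", "g2"),
                            disease_id = c("d1", "d2"),
                            stringsAsFactors = FALSE))
  expect_equal(nrow(filter_min_degree(full, 2)$edges), 4)

  single <- bdnet(data.frame(id = "g1", gene_type = "coding"),
                  data.frame(id = "d1"),
                  data.frame(gene_id = "g1", disease_id = "d1"))
  expect_equal(nrow(filter_min_degree(single, 2)$edges), 0)
})

test_that("export then import round-trips both formats", {
  for (s in 1:5) {
    net <- rand_bdnet(7, 5, 12, seed = s)
    for (fmt in c("edgelist", "graphml")) {
      path <- tempfile()
      write_network(net, path, fmt)
      back <- read_network(path, fmt)
      expect_setequal(back$genes$id, net$genes$id)
      expect_equal(back$genes$gene_type[order(back$genes$id)],
                   net$genes$gene_type[order(net$genes$id)])
      expect_setequal(paste(back$edges$gene_id, back$edges$disease_id),
                      paste(net$edges$gene_id, net$edges$disease_id))
    }
  }
  # empty network exports a valid zero-edge file
  empty <- bdnet(data.frame(id = "g1", gene_type = "coding"),
                 data.frame(id = "d1"),
                 data.frame(gene_id = character(), disease_id = character()))
  path <- tempfile()
  write_network(empty, path, "graphml")
  expect_equal(nrow(read_network(path, "graphml")$edges), 0)
})

test_that("constructor rejects malformed networks", {
  expect_error(bdnet(data.frame(id = "x", gene_type = "lncRNA"),
                     data.frame(id = "x"),
                     data.frame(gene_id = "x", disease_id = "x")),
               "both the gene and the disease side")
  expect_error(bdnet(data.frame(id = "g1", gene_type = "lncRNA"),
                     data.frame(id = "d1"),
                     data.frame(gene_id = "g1", disease_id = "d9")),
               "unregistered disease")
})
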