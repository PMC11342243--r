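# Thresholded interaction graph and topology metrics.

test_that("graph construction thresholds strictly and collapses duplicates", {
  edges <- data.frame(
    protein_a = c("a", "b", "a", "b", "c", "d"),
    protein_b = c("b", "a", "c", "c", "d", "d"),
    combined_score = c(950, 920, 900, 980, 999, 995))
  g <- build_graph(edges, threshold = 900)
  # (a,c) at exactly 900 dropped; (a,b)+(b,a) collapse keeping max;
  # self-loop (d,d) dropped
  expect_equal(igraph::ecount(g), 3)
  ab <- igraph::E(g)[igraph::V(g)["a"] %--% igraph::V(g)["b"]]
  expect_equal(ab$combined_score, 950)
  # all scores <= threshold: empty graph
  g0 <- build_graph(data.frame(protein_a = "a", protein_b = "b",
                               combined_score = 900), 900)
  expect_equal(igraph::ecount(g0), 0)
  # 3 of 5 rows above threshold
  e5 <- data.frame(protein_a = letters[1:5], protein_b = letters[c(2:5, 1)],
                   combined_score = c(901, 950, 999, 880, 700))
  expect_equal(igraph::ecount(build_graph(e5, 900)), 3)
  expect_error(build_graph(data.frame(protein_a = "a", protein_b = "b",
                                      combined_score = 1200)),
               "malformed edge row")
})

test_that("topology metrics match hand-derived small-graph values", {
  path3 <- build_graph(data.frame(protein_a = c("a", "b"),
                                  protein_b = c("b", "c"),
                                  combined_score = 950), 900)
  tp <- compute_topology(path3)
  expect_equal(tp$betweenness[tp$gene_id == "b"], 1)
  expect_equal(tp$betweenness[tp$gene_id == "a"], 0)
  tri <- build_graph(data.frame(protein_a = c("a", "b", "c"),
                                protein_b = c("b", "c", "a"),
                                combined_score = 950), 900)
  tt <- compute_topology(tri)
  expect_equal(tt$clustering, rep(1, 3))
  expect_equal(tt$betweenness, rep(0, 3))
  star <- build_graph(data.frame(protein_a = rep("hub", 4),
                                 protein_b = paste0("leaf", 1:4),
                                 combined_score = 950), 900)
  st <- compute_topology(star)
  expect_equal(st$betweenness[st$gene_id == "hub"], choose(4, 2))
  expect_equal(st$clustering[st$gene_id == "hub"], 0)
  expect_equal(st$degree[st$gene_id == "hub"], 4)
  expect_true(all(st$degree[st$gene_id != "hub"] == 1))
})

test_that("metrics agree with exhaustive brute force on random graphs", {
  withr::with_seed(17, {
    for (i in 1:30) {
      n <- sample(3:8, 1)
      fx <- random_graph_fixture(n, p_edge = runif(1, 0.25, 0.7))
      if (is.null(fx$edges)) next
      g <- build_graph(fx$edges, 900)
      tp <- compute_topology(g)
      oracle <- brute_topology(fx$adj)
      idx <- match(tp$gene_id, fx$ids)
      expect_equal(tp$degree, unname(oracle$degree[idx]))
      expect_equal(tp$betweenness, oracle$betweenness[idx],
                   tolerance = 1e-10)
      expect_equal(tp$clustering, oracle$clustering[idx],
                   tolerance = 1e-10)
      # handshake lemma
      expect_equal(sum(tp$degree), 2 * igraph::ecount(g))
    }
  })
})

test_that("class comparisons behave under identity and label swap", {
  withr::with_seed(23, {
    records <- data.frame(gene_id = sprintf("g%02d", 1:30),
                          degree = rpois(30, 5),
                          betweenness = runif(30, 0, 20),
                          clustering = runif(30))
    cls <- data.frame(gene_id = records$gene_id,
                      class = rep(c("Class1", "Class2", "control"), each = 10))
    res <- compare_topology(records, cls)
    expect_identical(nrow(res), 9L)
    # swapping the two class labels negates t
    cls2 <- cls
    cls2$class[cls$class == "Class1"] <- "Class2"
    cls2$class[cls$class == "Class2"] <- "Class1"
    res2 <- compare_topology(records, cls2)
    r12 <- res$t[res$comparison == "Class1_vs_Class2"]
    s12 <- res2$t[res2$comparison == "Class1_vs_Class2"]
    expect_equal(r12, -s12)
    # identical groups: p = 1
    cls3 <- cls
    cls3$class <- rep(c("Class1", "Class2", "control"), 10)  # interleave
    rec3 <- records
    rec3$degree <- rep(c(1, 2, 3), each = 10)[order(rep(1:10, 3))]
    same <- data.frame(gene_id = c(sprintf("a%d", 1:4), sprintf("b%d", 1:4)),
                       degree = rep(c(2, 5, 2, 5), 2),
                       betweenness = rep(c(1, 3, 1, 3), 2),
                       clustering = rep(c(0.1, 0.9, 0.1, 0.9), 2))
    cls4 <- data.frame(gene_id = same$gene_id,
                       class = rep(c("Class1", "Class2"), each = 4))
    cls4 <- rbind(cls4, data.frame(gene_id = c("c1", "c2"),
                                   class = "control"))
    same <- rbind(same, data.frame(gene_id = c("c1", "c2"), degree = c(2, 5),
                                   betweenness = c(1, 3),
                                   clustering = c(0.1, 0.9)))
    res4 <- compare_topology(same, cls4)
    expect_true(all(res4$t[res4$comparison == "Class1_vs_Class2"] == 0))
    expect_true(all(res4$p[res4$comparison == "Class1_vs_Class2"] == 1))
    # absent group errors
    expect_error(compare_topology(records[1:10, ], cls), "fewer than 2")
  })
})

test_that("missing genes are excluded unless zero-filling is requested", {
  records <- data.frame(gene_id = sprintf("g%02d", 1:20),
                        degree = rep(4, 20), betweenness = rep(2, 20),
                        clustering = rep(0.5, 20))
  cls <- data.frame(gene_id = sprintf("g%02d", 1:30),
                    class = rep(c("Class1", "Class2", "control"), 10))
  res <- compare_topology(records, cls)
  expect_true(all(res$n_a <= 10))
  resz <- compare_topology(records, cls, include_missing_as_zero = TRUE)
  expect_true(all(resz$n_a == 10))
})
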