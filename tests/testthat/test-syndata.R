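# Synthetic-data generators: determinism, input contracts, and planted
# statistical structure.

test_that("identical seeds and parameters yield bit-identical outputs", {
  cfg <- small_cfg()
  a <- simulate_study(cfg, seed = 11L)
  b <- simulate_study(cfg, seed = 11L)
  expect_identical(a$expr, b$expr)
  expect_identical(a$imaging, b$imaging)
  expect_identical(a$dev$expr, b$dev$expr)
  expect_identical(a$edges, b$edges)
  expect_identical(a$refs, b$refs)
  c <- simulate_study(cfg, seed = 12L)
  expect_false(identical(a$expr, c$expr))
})

test_that("generator preconditions are enforced", {
  zero_maps <- lapply(mdd_indices(), function(i) rep(0, 10))
  names(zero_maps) <- mdd_indices()
  expect_error(gen_imaging_cohort(10, 5, zero_maps, noise_sd = 0),
               "noise_sd")
  expect_error(gen_imaging_cohort(10, 5, zero_maps[1:3]), "indices")
  tr <- default_truth(small_cfg())
  em <- gen_effect_maps(60, seed = 1)
  expect_error(gen_expression_matrix(tr, em$sites[1:2], em$maps), "3 sites")
  expect_error(gen_expression_matrix(tr, em$sites, em$maps,
                                     corr_strength = 1), "between 0 and 1")
  expect_error(gen_dev_expression(tr, periods = c("a", "b")), "8 period")
  expect_error(gen_dev_expression(tr, regions = letters[1:5]), "16 region")
  expect_error(gen_interaction_network(tr, n_nodes = 1), "2 nodes")
  expect_error(gen_interaction_network(tr, hub_fraction = 1.2),
               "hub_fraction")
  expect_error(gen_reference_lists(tr, c(class1 = 1.5, class2 = 0,
                                         control = 0)), "rates")
})

test_that("null effect maps give nominal false-positive rates downstream", {
  zero_maps <- lapply(mdd_indices(), function(i) rep(0, 200))
  names(zero_maps) <- mdd_indices()
  cohort <- gen_imaging_cohort(200, 50, zero_maps, noise_sd = 1, seed = 5)
  p <- unlist(lapply(cohort, function(ds) group_difference_map(ds)$p))
  frac <- mean(p < 0.05)
  se <- sqrt(0.05 * 0.95 / length(p))
  expect_lt(abs(frac - 0.05), 4 * se)
})

test_that("a planted site effect yields the closed-form t noncentrality", {
  # effect 2.0 at site 1, noise 1, n = 100/group: E[t] ~ 2 * sqrt(100/2)
  maps <- lapply(mdd_indices(), function(i) c(2, rep(0, 9)))
  names(maps) <- mdd_indices()
  t1 <- vapply(1:15, function(s) {
    co <- gen_imaging_cohort(10, 100, maps, noise_sd = 1, seed = s)
    group_difference_map(co$ALFF)$t[1]
  }, numeric(1))
  expect_lt(abs(mean(t1) - 2 * sqrt(100 / 2)), 1.5)
})

test_that("planted class genes track the effect maps with the planted signs", {
  em <- gen_effect_maps(200, seed = 3)
  genes <- sprintf("G%04d", 1:50)
  tr <- ground_truth(genes, class1_genes = genes[1:10],
                     class2_genes = genes[11:20])
  # near-deterministic coupling drives Spearman toward +1
  m <- gen_expression_matrix(tr, em$sites, em$maps, corr_strength = 0.999,
                             seed = 2)
  expect_gt(spearman_rho(m[genes[1], ], em$maps$ALFF), 0.98)
  expect_lt(spearman_rho(m[genes[1], ], em$maps$GMD), -0.98)
  # Class-2 gene vs GMD map positive in essentially all seeds at 0.8
  signs <- vapply(1:50, function(s) {
    m <- gen_expression_matrix(tr, em$sites, em$maps, corr_strength = 0.8,
                               seed = s)
    sign(spearman_rho(m[genes[11], ], em$maps$GMD))
  }, numeric(1))
  expect_gte(sum(signs == 1), 49)
})

test_that("non-planted genes are uncorrelated with the maps on average", {
  em <- gen_effect_maps(60, seed = 4)
  genes <- sprintf("G%04d", 1:5)
  tr <- ground_truth(genes, class1_genes = genes[1])
  rhos <- vapply(1:100, function(s) {
    m <- gen_expression_matrix(tr, em$sites, em$maps, 0.8, seed = s)
    spearman_rho(m[genes[3], ], em$maps$ReHo)
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("developmental generator plants recoverable axis specificity", {
  genes <- sprintf("G%04d", 1:10)
  sp <- data.frame(gene_id = genes[1], axis = "region", level = "HIP")
  tr <- ground_truth(genes, specific_genes = sp)
  dev <- gen_dev_expression(tr, n_per_cell = 2, baseline = 0,
                            noise_sd = 1e-9, specific_shift = 1, seed = 1)
  expect_true(all(dev$expr >= 0))
  # zero baseline elsewhere: spatial delta profile, flat temporal profile
  expect_equal(dpi(axis_profile(dev, genes[1], "spatial")), 1,
               tolerance = 1e-6)
  expect_lt(dpi(axis_profile(dev, genes[1], "temporal")), 1e-6)
  # with realistic noise planted genes still dominate unplanted ones
  dev2 <- gen_dev_expression(tr, n_per_cell = 2, baseline = 5,
                             noise_sd = 1, specific_shift = 3, seed = 2)
  sdpi <- vapply(genes, function(g)
    dpi(axis_profile(dev2, g, "spatial")), numeric(1))
  expect_true(all(sdpi[1] > sdpi[-1]))
})

test_that("sex-biased planting is detectable at the stated power", {
  genes <- sprintf("G%04d", 1:5)
  tr <- ground_truth(genes,
                     sex_biased_genes = c(G0001 = "female", G0002 = "male"))
  hits <- vapply(1:10, function(s) {
    dev <- gen_dev_expression(tr, n_per_cell = 2, sex_shift = 1,
                              noise_sd = 1, seed = s)
    rec <- sex_de_genes(dev, genes, alpha = 0.01)
    "G0001" %in% rec$gene_id &&
      rec$direction[rec$gene_id == "G0001"] == "female_high"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("class-1 nodes sit on the network periphery", {
  st <- small_study(seed = 21L)
  g <- build_graph(st$edges, 900)
  topo <- compute_topology(g)
  c1 <- topo$degree[topo$gene_id %in% st$truth$class1_genes]
  ctrl <- topo$degree[!topo$gene_id %in% c(st$truth$class1_genes,
                                           st$truth$class2_genes)]
  expect_lt(mean(c1), mean(ctrl))
})

test_that("reference lists honour configured overlap rates", {
  tr <- default_truth(study_config(), seed = 2)
  refs <- gen_reference_lists(tr, c(class1 = 0.2, class2 = 0.1,
                                    control = 0.05), seed = 3)
  expect_equal(overlap_percentage(tr$class1_genes, refs$risk), 20,
               tolerance = 2)
  expect_equal(overlap_percentage(tr$class2_genes, refs$risk), 10,
               tolerance = 2)
  none <- gen_reference_lists(tr, c(class1 = 0, class2 = 0, control = 0.1),
                              seed = 4)
  expect_length(intersect(none$risk, tr$class1_genes), 0)
  full <- gen_reference_lists(tr, c(class1 = 1, class2 = 0, control = 0),
                              seed = 5)
  expect_true(all(tr$class1_genes %in% full$risk))
})
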