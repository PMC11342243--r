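# SPI and DPI: hand-computed values, bounds, invariances, axis profiles
# and class comparisons.

test_that("SPI is the cosine embedding with unit sum of squares", {
  p <- spi_profile(c(3, 4))
  expect_equal(p$values, c(0.6, 0.8))
  expect_equal(p$mean_spi, 0.7)
  # full concentration and uniform symmetry
  expect_equal(spi_profile(c(7, 0, 0))$values, c(1, 0, 0))
  expect_equal(spi_profile(rep(3, 9))$values, rep(1 / 3, 9))
  expect_error(spi_profile(c(1, -1)), "nonnegative")
  expect_error(spi_profile(c(0, 0, 0)), "all-zero")
  expect_error(spi_profile(5), "length >= 2")
})

test_that("DPI matches hand computations and its bounds", {
  expect_equal(dpi(c(3, 4)), 0.2)
  expect_equal(dpi(rep(2, 6)), 0)
  # delta profile gives exactly 1 for every length
  for (n in 2:50) expect_equal(dpi(c(1, rep(0, n - 1))), 1,
                               tolerance = 1e-12)
})

test_that("DPI is scale/permutation invariant, bounded, and monotone under mass transfer", {
  withr::with_seed(19, {
    for (i in 1:300) {
      n <- sample(2:100, 1)
      x <- runif(n)
      d <- dpi(x)
      expect_gte(d, 0)
      expect_lte(d, 1 + 1e-12)
      expect_equal(dpi(x * runif(1, 0.1, 50)), d, tolerance = 1e-10)
      expect_equal(dpi(sample(x)), d, tolerance = 1e-10)
      expect_equal(sum(spi_profile(x)$values^2), 1, tolerance = 1e-12)
    }
    # moving mass from a low coordinate to the argmax never decreases DPI
    for (i in 1:50) {
      x <- runif(sample(3:20, 1))
      lo <- which.min(x); hi <- which.max(x)
      if (lo == hi) next
      y <- x
      shift <- x[lo] * runif(1)
      y[lo] <- y[lo] - shift
      y[hi] <- y[hi] + shift
      expect_gte(dpi(y), dpi(x) - 1e-12)
    }
  })
})

test_that("axis profiles average per level with errors on missing levels", {
  genes <- sprintf("G%04d", 1:4)
  tr <- ground_truth(genes)
  dev <- gen_dev_expression(tr, n_per_cell = 2, seed = 3)
  # direct averaging oracle for the temporal profile
  g <- genes[2]
  prof <- axis_profile(dev, g, "temporal")
  byhand <- tapply(dev$expr[, g], dev$samples$period, mean)[dev$periods]
  expect_equal(unname(prof), as.vector(byhand))
  expect_identical(names(prof), dev$periods)
  expect_length(axis_profile(dev, g, "spatial"), 16L)
  # constant gene: both profiles uniform, DPI 0
  dev$expr[, genes[1]] <- 2
  expect_equal(dpi(axis_profile(dev, genes[1], "temporal")), 0)
  expect_equal(dpi(axis_profile(dev, genes[1], "spatial")), 0)
  expect_error(axis_profile(dev, "nope", "temporal"), "not in the set")
  # drop one period entirely
  dev2 <- dev
  keep <- dev2$samples$period != "infancy"
  dev2$samples <- dev2$samples[keep, ]
  dev2$expr <- dev2$expr[keep, ]
  expect_error(axis_profile(dev2, g, "temporal"), "infancy")
})

test_that("class DPI comparison separates planted region-specific classes", {
  st <- small_study(seed = 29L)
  cls <- data.frame(
    gene_id = st$truth$genes,
    class = ifelse(st$truth$genes %in% st$truth$class1_genes, "Class1",
                   ifelse(st$truth$genes %in% st$truth$class2_genes,
                          "Class2", "control")))
  res <- class_dpi_comparison(st$dev, cls)
  t_sp <- res$tests[res$tests$axis == "spatial" &
                      res$tests$comparison == "Class1_vs_control", ]
  expect_gt(t_sp$t, 0)
  expect_lt(t_sp$p, 0.001)
  t_tm <- res$tests[res$tests$axis == "temporal" &
                      res$tests$comparison == "Class1_vs_control", ]
  expect_lt(t_tm$t, 0)
  # identical gene sets -> t = 0 (self-comparison via equal groups)
  g <- st$truth$genes[1:10]
  cls0 <- data.frame(gene_id = rep(g, 3),
                     class = rep(c("Class1", "Class2", "control"),
                                 each = 10))
  res0 <- class_dpi_comparison(st$dev, cls0)
  expect_true(all(abs(res0$tests$t) < 1e-12))
})

test_that("overexpression grid recovers planted regions at 8 x 16 shape", {
  st <- small_study(seed = 33L)
  grid <- overexpression_grid(st$dev, st$truth$class1_genes,
                              setdiff(st$truth$genes,
                                      c(st$truth$class1_genes,
                                        st$truth$class2_genes)),
                              alpha = 0.01)
  expect_identical(dim(grid$t), c(8L, 16L))
  expect_identical(rownames(grid$t), dev_periods())
  expect_identical(colnames(grid$t), dev_regions())
  # class genes split across several target regions: planted columns are
  # collectively elevated relative to the others
  planted <- unique(st$truth$specific_genes$level[
    st$truth$specific_genes$gene_id %in% st$truth$class1_genes])
  other <- setdiff(colnames(grid$t), planted)
  expect_gt(mean(grid$t[, planted]), mean(grid$t[, other]))
  expect_gt(mean(grid$t[, planted] > 0), 0.9)
  # a class planted uniformly in one region lights up that column across
  # all periods
  genes <- sprintf("G%04d", 1:120)
  tr1 <- ground_truth(genes,
                      specific_genes = data.frame(gene_id = genes[1:20],
                                                  axis = "region",
                                                  level = "HIP"))
  dev1 <- gen_dev_expression(tr1, n_per_cell = 2, seed = 37)
  g1 <- overexpression_grid(dev1, genes[1:20], genes[21:120])
  expect_true(all(g1$t[, "HIP"] > 0))
  expect_true(all(g1$significant[, "HIP"]))
  expect_false(any(g1$significant[, "STR"]))
  # class vs itself: t = 0 everywhere
  g0 <- overexpression_grid(st$dev, st$truth$class1_genes,
                            st$truth$class1_genes)
  expect_true(all(g0$t == 0))
  expect_true(all(g0$p == 1))
})
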