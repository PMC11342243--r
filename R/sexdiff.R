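# Sex differences in developmental expression of gene classes.

#' Sex-differentially expressed genes
#'
#' Per gene, a two-sided two-sample t-test of expression in female versus
#' male samples, restricted to the periods sampled in both sexes
#' (corresponding periods) and pooled across them (one p-value per gene).
#' `direction` is `"female_high"` when the female mean is higher. Records
#' with p < `alpha` are returned; pass `alpha = 1` to obtain the full
#' table (e.g. for calibration).
#'
#' @param dev A `dev_expression` object.
#' @param genes Gene ids to test (default: all genes in `dev`).
#' @param alpha Retention threshold (default 0.01).
#' @param variant `"pooled"` or `"welch"`.
#' @return Data frame `gene_id`, `t`, `p`, `direction`, ordered by p.
#' @export
sex_de_genes <- function(dev, genes = colnames(dev$expr), alpha = 0.01,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (alpha <= 0 || alpha > 1) .stopf("alpha must be in (0, 1]")
  .check_dev(dev)
  genes <- intersect(genes, colnames(dev$expr))
  if (!length(genes)) .stopf("no requested genes present")
  sx <- dev$samples$sex
  if (!all(c("female", "male") %in% sx))
    .stopf("both sexes must be present in the sample set")
  shared <- intersect(unique(dev$samples$period[sx == "female"]),
                      unique(dev$samples$period[sx == "male"]))
  keep <- dev$samples$period %in% shared
  f <- dev$expr[keep & sx == "female", genes, drop = FALSE]
  m <- dev$expr[keep & sx == "male", genes, drop = FALSE]
  res <- .col_t_test(f, m, variant)
  out <- data.frame(gene_id = genes, t = res$t, p = res$p,
                    direction = ifelse(res$mean_diff > 0, "female_high",
                                       "male_high"))
  out <- out[out$p < alpha, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}

#' Per-class sex-bias percentages
#'
#' Among each class's sex-different genes, the percentage highly expressed
#' in females and in males (the two sum to 100% per class). Classes with
#' no sex-different genes are reported with `NA` percentages.
#'
#' @param records Data frame from [sex_de_genes()].
#' @param classes Classification data frame (`gene_id`, `class`).
#' @return Data frame `class`, `n`, `percent_female_high`,
#'   `percent_male_high`.
#' @export
sex_bias_percentages <- function(records, classes) {
  groups <- c("Class1", "Class2", "control")
  do.call(rbind, lapply(groups, function(g) {
    gs <- classes$gene_id[classes$class == g]
    rec <- records[records$gene_id %in% gs, , drop = FALSE]
    n <- nrow(rec)
    if (n == 0) {
      message("class ", g, " has no sex-different genes")
      return(data.frame(class = g, n = 0L,
                        percent_female_high = NA_real_,
                        percent_male_high = NA_real_))
    }
    pf <- 100 * mean(rec$direction == "female_high")
    data.frame(class = g, n = n, percent_female_high = pf,
               percent_male_high = 100 - pf)
  }))
}

#' Period-by-region sex-difference overexpression grid
#'
#' Within each (period, region) cell, computes each gene's female-minus-
#' male mean expression difference for the sex-different genes and for the
#' control genes, then contrasts the two gene groups with a two-sided
#' t-test. Positive t means the sex-different genes are more female-biased
#' than controls in that cell. Cells lacking samples of either sex are
#' `NA` (flagged missing).
#'
#' @param dev A `dev_expression` object.
#' @param sexdiff_genes,control_genes Character vectors of gene ids.
#' @param alpha Threshold for the `significant` grid (default 0.01).
#' @return List of period-by-region matrices `t`, `p`, `significant`.
#' @export
sex_overexpression_grid <- function(dev, sexdiff_genes, control_genes,
                                    alpha = 0.01) {
  .check_dev(dev)
  .check_prob(alpha, "alpha")
  sexdiff_genes <- intersect(sexdiff_genes, colnames(dev$expr))
  control_genes <- intersect(control_genes, colnames(dev$expr))
  if (!length(sexdiff_genes) || !length(control_genes))
    .stopf("both gene groups must be nonempty and present in `dev`")
  grid_t <- grid_p <- matrix(
    NA_real_, length(dev$periods), length(dev$regions),
    dimnames = list(dev$periods, dev$regions))
  for (pd in dev$periods) {
    for (rg in dev$regions) {
      cell <- dev$samples$period == pd & dev$samples$region == rg
      fi <- which(cell & dev$samples$sex == "female")
      mi <- which(cell & dev$samples$sex == "male")
      if (!length(fi) || !length(mi)) next
      dsex <- colMeans(dev$expr[fi, , drop = FALSE]) -
        colMeans(dev$expr[mi, , drop = FALSE])
      a <- dsex[sexdiff_genes]
      b <- dsex[control_genes]
      if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
        grid_t[pd, rg] <- 0; grid_p[pd, rg] <- 1
        next
      }
      tt <- stats::t.test(a, b)
      grid_t[pd, rg] <- unname(tt$statistic)
      grid_p[pd, rg] <- tt$p.value
    }
  }
  list(t = grid_t, p = grid_p, significant = grid_p < alpha)
}
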