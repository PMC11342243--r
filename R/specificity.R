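# Temporal-spatial expression specificity: the specificity index (SPI) and
# the dispersion index (DPI), plus class-level comparisons on developmental
# expression sets.

#' Specificity index profile of an expression profile
#'
#' For a nonnegative expression profile \eqn{X = (x_1, \dots, x_n)}, the
#' specificity index of sample \eqn{i} is the cosine of the angle between
#' \eqn{X} and the axis-embedded single-sample vector
#' \eqn{X_i = (0, \dots, x_i, \dots, 0)}:
#' \deqn{SPI_i = x_i / \lVert X \rVert_2 .}
#' An SPI near 1 means the gene's expression is concentrated in that sample.
#' The squared SPI values always sum to 1.
#'
#' @param x Nonnegative numeric vector, length >= 2, not all zero.
#' @return An object of class `spi_profile`: a list with elements `values`
#'   (the SPI vector), `n` and `mean_spi`.
#' @examples
#' spi_profile(c(3, 4))$values  # 0.6 0.8
#' @export
spi_profile <- function(x) {
  if (!is.numeric(x) || length(x) < 2L)
    .stopf("`x` must be a numeric vector of length >= 2")
  if (anyNA(x)) .stopf("`x` contains missing values")
  if (any(x < 0)) .stopf("SPI requires nonnegative expression values")
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) .stopf("SPI undefined for an all-zero profile")
  s <- x / nrm
  structure(list(values = s, n = length(s), mean_spi = mean(s)),
            class = "spi_profile")
}

#' @export
print.spi_profile <- function(x, ...) {
  cat("SPI profile: n =", x$n, ", mean SPI =", format(x$mean_spi), "\n")
  print(x$values, ...)
  invisible(x)
}

#' Dispersion index of an expression profile
#'
#' The dispersion index summarizes how concentrated an SPI profile is:
#' \deqn{DPI = \sqrt{ n \sum_i (SPI_i - \overline{SPI})^2 / (n - 1) } .}
#' It is 0 for a perfectly uniform profile, 1 for a profile expressed in a
#' single sample, and invariant to positive scaling of the input (so it is
#' unaffected by overall expression level and comparable across profile
#' lengths).
#'
#' @param x Nonnegative numeric vector (length >= 2, not all zero), or an
#'   `spi_profile`.
#' @return A single number in \[0, 1\].
#' @examples
#' dpi(c(1, 1, 1, 1))   # 0
#' dpi(c(1, 0, 0, 0))   # 1
#' dpi(c(3, 4))         # 0.2
#' @export
dpi <- function(x) {
  s <- if (inherits(x, "spi_profile")) x$values else spi_profile(x)$values
  n <- length(s)
  sqrt(n * sum((s - mean(s))^2) / (n - 1))
}

#' Per-axis expression profile of a gene
#'
#' Averages a gene's expression over the samples of each developmental
#' period (temporal axis, length 8 by default) or each brain region
#' (spatial axis, length 16 by default). Averaging to per-level means makes
#' the downstream DPI independent of unbalanced sampling across cells.
#'
#' @param dev A `dev_expression` object (see [gen_dev_expression()] /
#'   [read_dev_expression()]).
#' @param gene Gene identifier (must be a column of `dev$expr`).
#' @param axis `"temporal"` or `"spatial"`.
#' @return Named nonnegative numeric vector of per-level mean expression.
#' @export
axis_profile <- function(dev, gene, axis = c("temporal", "spatial")) {
  axis <- match.arg(axis)
  .check_dev(dev)
  if (!gene %in% colnames(dev$expr)) .stopf("gene '%s' not in the set", gene)
  fac <- .axis_factor(dev, axis)
  counts <- table(fac)
  if (any(counts == 0))
    .stopf("axis level(s) without samples: %s",
           paste(names(counts)[counts == 0], collapse = ", "))
  out <- rowsum(dev$expr[, gene], fac)[, 1L] / as.vector(counts)
  out[levels(fac)]
}

.axis_factor <- function(dev, axis) {
  if (axis == "temporal") factor(dev$samples$period, levels = dev$periods)
  else factor(dev$samples$region, levels = dev$regions)
}

# per-gene DPI along one axis for many genes at once
.axis_dpi <- function(dev, genes, axis) {
  fac <- .axis_factor(dev, axis)
  counts <- as.vector(table(fac))
  if (any(counts == 0)) .stopf("axis level(s) without samples")
  lm <- rowsum(dev$expr[, genes, drop = FALSE], fac) / counts  # levels x genes
  apply(lm, 2L, dpi)
}

#' Compare temporal and spatial DPI between gene classes
#'
#' Computes the temporal (per-period) and spatial (per-region) dispersion
#' index for every classified gene present in the developmental set, then
#' contrasts the gene classes with two-sided two-sample t-tests per axis
#' (Class 1 vs control, Class 2 vs control, Class 1 vs Class 2).
#'
#' @param dev A `dev_expression` object.
#' @param classes Gene classification data frame (columns `gene_id`,
#'   `class`) as produced by [classify_directional()].
#' @return List with `dpi` (per-gene data frame: gene_id, class,
#'   temporal_dpi, spatial_dpi) and `tests` (data frame: axis, comparison,
#'   t, p, mean_a, mean_b).
#' @export
class_dpi_comparison <- function(dev, classes) {
  .check_dev(dev)
  cls <- classes[classes$gene_id %in% colnames(dev$expr), , drop = FALSE]
  groups <- c("Class1", "Class2", "control")
  by_group <- lapply(groups, function(g) cls$gene_id[cls$class == g])
  names(by_group) <- groups
  if (any(lengths(by_group) < 2L))
    .stopf("need >= 2 genes per group in the developmental set")
  genes <- unlist(by_group, use.names = FALSE)
  per_gene <- data.frame(
    gene_id = genes,
    class = rep(groups, lengths(by_group)),
    temporal_dpi = .axis_dpi(dev, genes, "temporal"),
    spatial_dpi = .axis_dpi(dev, genes, "spatial"),
    row.names = NULL
  )
  pairs <- list(c("Class1", "control"), c("Class2", "control"),
                c("Class1", "Class2"))
  tests <- do.call(rbind, lapply(c("temporal", "spatial"), function(ax) {
    col <- paste0(ax, "_dpi")
    do.call(rbind, lapply(pairs, function(pr) {
      a <- per_gene[[col]][per_gene$class == pr[1]]
      b <- per_gene[[col]][per_gene$class == pr[2]]
      tt <- stats::t.test(a, b)
      data.frame(axis = ax, comparison = paste(pr, collapse = "_vs_"),
                 t = unname(tt$statistic), p = tt$p.value,
                 mean_a = mean(a), mean_b = mean(b))
    }))
  }))
  list(dpi = per_gene, tests = tests)
}

#' Period-by-region overexpression grid
#'
#' For every (period, region) cell, computes each gene's mean expression
#' over the cell's samples and contrasts class genes against control genes
#' with a two-sided two-sample t-test. Positive t means the class genes are
#' more highly expressed than controls in that cell.
#'
#' @param dev A `dev_expression` object.
#' @param class_genes,control_genes Character vectors of gene ids present
#'   in `dev`.
#' @param alpha Significance threshold for the `significant` grid
#'   (default 0.01).
#' @return List of period-by-region matrices `t`, `p` and `significant`.
#'   Cells without samples are `NA` (flagged missing, not an error).
#' @export
overexpression_grid <- function(dev, class_genes, control_genes,
                                alpha = 0.01) {
  .check_dev(dev)
  .check_prob(alpha, "alpha")
  class_genes <- intersect(class_genes, colnames(dev$expr))
  control_genes <- intersect(control_genes, colnames(dev$expr))
  if (!length(class_genes) || !length(control_genes))
    .stopf("both gene groups must be nonempty and present in `dev`")
  grid_t <- grid_p <- matrix(
    NA_real_, nrow = length(dev$periods), ncol = length(dev$regions),
    dimnames = list(dev$periods, dev$regions))
  for (pd in dev$periods) {
    for (rg in dev$regions) {
      idx <- which(dev$samples$period == pd & dev$samples$region == rg)
      if (!length(idx)) next
      a <- colMeans(dev$expr[idx, class_genes, drop = FALSE])
      b <- colMeans(dev$expr[idx, control_genes, drop = FALSE])
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
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

.check_dev <- function(dev) {
  if (!inherits(dev, "dev_expression"))
    .stopf("expected a `dev_expression` object")
  invisible(dev)
}
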