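# Reference-list comparison: differential expression on case-control
# expression tables, overlap percentages, and hypergeometric term
# enrichment with the count / enrichment-factor filters.

#' Differential expression by two-sided t-test
#'
#' Per-gene two-sided two-sample t-test between case and control sample
#' matrices; `direction` is `"down"` when the case mean is below the
#' control mean. Only genes with p < `alpha` are returned.
#'
#' @param case,control Gene x sample numeric matrices sharing rownames
#'   (>= 2 samples each).
#' @param alpha Retention threshold (default 0.01).
#' @param variant `"pooled"` or `"welch"`.
#' @return Data frame `gene_id`, `t`, `p`, `direction`, ordered by p.
#' @export
differential_expression <- function(case, control, alpha = 0.01,
                                    variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  .check_prob(alpha, "alpha")
  if (ncol(case) < 2 || ncol(control) < 2)
    .stopf("need at least 2 samples per group")
  if (!identical(rownames(case), rownames(control)))
    .stopf("case and control matrices must share gene rows")
  res <- .col_t_test(t(case), t(control), variant)
  out <- data.frame(gene_id = rownames(case), t = res$t, p = res$p,
                    direction = ifelse(res$mean_diff < 0, "down", "up"))
  out <- out[out$p < alpha, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}

#' Percentage of a gene class covered by a reference list
#'
#' `100 * |class ∩ reference| / |class|`, e.g. 54 risk genes among 4,089
#' control genes give 1.32%.
#'
#' @param class_genes Nonempty character vector.
#' @param reference Character vector.
#' @return A single percentage (full precision; report rounded to two
#'   decimals).
#' @export
overlap_percentage <- function(class_genes, reference) {
  if (!length(class_genes)) .stopf("empty gene class")
  100 * length(intersect(class_genes, reference)) / length(unique(class_genes))
}

#' Hypergeometric term enrichment with count and factor filters
#'
#' For each annotation term, computes the upper-tail (accumulative)
#' hypergeometric p-value of the overlap between the selected gene set and
#' the term's genes within the background, the enrichment factor
#' (observed / expected overlap fraction), and Benjamini-Hochberg adjusted
#' p-values across terms. A term passes when adjusted p < `alpha`, the
#' overlap count is at least `min_count`, and the factor exceeds
#' `min_factor` (defaults 0.01, 3, 1.5).
#'
#' @param selected Character vector, a subset of `background`.
#' @param terms Named list of character vectors (term -> gene set).
#' @param background Nonempty character vector of background genes.
#' @param alpha,min_count,min_factor Filter thresholds.
#' @return Data frame `term_id`, `count`, `set_size`, `bg_count`,
#'   `bg_size`, `enrichment_factor`, `p`, `p_adj`, `passes`, ordered by p.
#' @export
hypergeometric_enrichment <- function(selected, terms, background,
                                      alpha = 0.01, min_count = 3L,
                                      min_factor = 1.5) {
  if (!length(background)) .stopf("empty background")
  background <- unique(background)
  selected <- unique(selected)
  if (!all(selected %in% background))
    .stopf("selected genes must be a subset of the background")
  n_sel <- length(selected)
  n_bg <- length(background)
  rows <- lapply(names(terms), function(tm) {
    tg <- intersect(terms[[tm]], background)
    k <- length(intersect(tg, selected))
    K <- length(tg)
    p <- stats::phyper(k - 1L, K, n_bg - K, n_sel, lower.tail = FALSE)
    factor <- if (K == 0) 0 else (k / n_sel) / (K / n_bg)
    data.frame(term_id = tm, count = k, set_size = n_sel, bg_count = K,
               bg_size = n_bg, enrichment_factor = factor, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$passes <- out$p_adj < alpha & out$count >= min_count &
    out$enrichment_factor > min_factor
  out[order(out$p), , drop = FALSE]
}

#' Overlap percentages of each gene class against reference lists
#'
#' Tabulates [overlap_percentage()] (and the raw overlap counts, reported
#' alongside because percentages alone can hide small numerators) for
#' Class 1, Class 2 and control genes against each supplied reference
#' list.
#'
#' @param classes Classification data frame (`gene_id`, `class`).
#' @param references Named list of character vectors.
#' @return Data frame `reference`, `class`, `n_class`, `n_overlap`,
#'   `percent`.
#' @export
class_overlap_table <- function(classes, references) {
  groups <- list(Class1 = classes$gene_id[classes$class == "Class1"],
                 Class2 = classes$gene_id[classes$class == "Class2"],
                 control = classes$gene_id[classes$class == "control"])
  do.call(rbind, lapply(names(references), function(rf) {
    do.call(rbind, lapply(names(groups), function(g) {
      gs <- groups[[g]]
      data.frame(reference = rf, class = g, n_class = length(gs),
                 n_overlap = length(intersect(gs, references[[rf]])),
                 percent = if (length(gs))
                   overlap_percentage(gs, references[[rf]]) else NA_real_)
    }))
  }))
}
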