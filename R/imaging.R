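# Case-control contrast maps for the imaging indices, with
# Benjamini-Hochberg multiple-comparison control.

#' Per-site case-control difference map
#'
#' Two-sided two-sample t-test at every site. Positive t means higher
#' values in cases than in controls. Sites where both groups have zero
#' variance are handled degenerately: p = 0 if the group means differ,
#' p = 1 otherwise (reported via a message).
#'
#' @param dataset A `GroupImagingDataset`: list with `index_name`, `values`
#'   (subject x site matrix) and `group` (per-subject `"case"`/`"control"`),
#'   as produced by [gen_imaging_cohort()] or [read_imaging_dataset()].
#' @param variant `"pooled"` (Student, default) or `"welch"`.
#' @return A `DifferenceMap` data frame: `site_id`, `t`, `p`, with
#'   attribute `index_name`.
#' @export
group_difference_map <- function(dataset, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  v <- dataset$values
  g <- dataset$group
  if (!all(g %in% c("case", "control")))
    .stopf("group labels must be 'case' or 'control'")
  if (sum(g == "case") < 2 || sum(g == "control") < 2)
    .stopf("need at least 2 subjects per group")
  if (!all(is.finite(v))) .stopf("non-finite imaging values")
  res <- .col_t_test(v[g == "case", , drop = FALSE],
                     v[g == "control", , drop = FALSE], variant)
  sites <- colnames(v)
  if (is.null(sites)) sites <- sprintf("S%03d", seq_len(ncol(v)))
  out <- data.frame(site_id = sites, t = res$t, p = res$p)
  attr(out, "index_name") <- dataset$index_name
  out
}

#' Benjamini-Hochberg correction
#'
#' Step-up false-discovery-rate adjustment (with the usual enforced
#' monotonicity); a site is significant when its adjusted p falls below
#' `q`. The study's imaging threshold is q = 0.001.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param q Significance threshold on the adjusted p (default 0.001).
#' @return List with `p_adj` and logical `significant`.
#' @export
bh_correct <- function(p, q = 0.001) {
  if (!length(p)) .stopf("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) .stopf("p-values must lie in [0, 1]")
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, significant = p_adj < q)
}

#' Contrast maps for all four indices
#'
#' Convenience wrapper running [group_difference_map()] and [bh_correct()]
#' for each imaging index of a cohort.
#'
#' @param cohort Named list of `GroupImagingDataset`s (one per index).
#' @param variant Passed to [group_difference_map()].
#' @param q BH threshold (default 0.001).
#' @return Named list of data frames `site_id`, `t`, `p`, `p_adj`,
#'   `significant`.
#' @export
difference_maps <- function(cohort, variant = c("pooled", "welch"),
                            q = 0.001) {
  variant <- match.arg(variant)
  out <- lapply(cohort, function(ds) {
    dm <- group_difference_map(ds, variant)
    bh <- bh_correct(dm$p, q)
    dm$p_adj <- bh$p_adj
    dm$significant <- bh$significant
    attr(dm, "index_name") <- ds$index_name
    dm
  })
  names(out) <- names(cohort)
  out
}
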