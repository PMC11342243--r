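# Probe-level to gene-level expression processing: background filtering,
# representative-probe collapse, and normalization (donor-mean centering,
# scaled robust sigmoid, per-gene z-score).

#' Construct a probe table
#'
#' @param probe_id Unique probe identifiers.
#' @param gene_id Gene id per probe (a supplied probe-to-gene map).
#' @param values Probe x site numeric matrix of intensities.
#' @param flags Probe x site logical matrix: is the measure above
#'   background at that site.
#' @return An object of class `probe_table`.
#' @export
probe_table <- function(probe_id, gene_id, values, flags) {
  if (anyDuplicated(probe_id)) .stopf("probe ids must be unique")
  if (length(probe_id) != length(gene_id) ||
      nrow(values) != length(probe_id) || !identical(dim(values), dim(flags)))
    .stopf("probe_id, gene_id, values and flags must agree in shape")
  if (!is.logical(flags)) .stopf("flags must be logical")
  rownames(values) <- rownames(flags) <- probe_id
  structure(list(probe_id = probe_id, gene_id = gene_id, values = values,
                 flags = flags),
            class = "probe_table")
}

#' @export
print.probe_table <- function(x, ...) {
  cat("probe_table:", length(x$probe_id), "probes,",
      length(unique(x$gene_id)), "genes,", ncol(x$values), "sites\n")
  invisible(x)
}

#' Filter probes by background signal
#'
#' Drops probes whose expression fails to surpass background in strictly
#' more than half of the sites; a probe above background in exactly half of
#' the sites is retained (the rule only eliminates >50% failures).
#'
#' @param probes A `probe_table`.
#' @return The filtered `probe_table`.
#' @export
filter_probes <- function(probes) {
  stopifnot(inherits(probes, "probe_table"))
  if (length(probes$probe_id) == 0L) .stopf("empty probe table")
  frac <- rowMeans(probes$flags)
  keep <- frac >= 0.5
  probe_table(probes$probe_id[keep], probes$gene_id[keep],
              probes$values[keep, , drop = FALSE],
              probes$flags[keep, , drop = FALSE])
}

#' Collapse probes to one representative probe per gene
#'
#' For each gene the probe with the highest mean intensity across sites
#' (peak intensity) is kept; ties break to the lexicographically smallest
#' probe id so the collapse is deterministic. Genes with no surviving probe
#' are simply absent from the output (reported via a message).
#'
#' @param probes A filtered `probe_table`.
#' @return Gene x site numeric matrix, rows ordered by gene id, with
#'   attribute `representative_probe` naming the chosen probe per gene and
#'   attribute `normalized = FALSE`.
#' @export
select_representative_probe <- function(probes) {
  stopifnot(inherits(probes, "probe_table"))
  if (length(probes$probe_id) == 0L) .stopf("empty probe table")
  means <- rowMeans(probes$values)
  ord <- order(probes$gene_id, -means, probes$probe_id)
  first <- !duplicated(probes$gene_id[ord])
  pick <- ord[first]
  m <- probes$values[pick, , drop = FALSE]
  rownames(m) <- probes$gene_id[pick]
  attr(m, "representative_probe") <-
    stats::setNames(probes$probe_id[pick], probes$gene_id[pick])
  attr(m, "normalized") <- FALSE
  m
}

#' Scaled robust sigmoid normalization of one expression row
#'
#' Applies the robust sigmoid
#' \eqn{1 / (1 + \exp(-(x - \mathrm{median}) / (\mathrm{IQR}/1.35)))}
#' (IQR/1.35 is a robust SD estimate), then min-max rescales to \[0, 1\].
#' Order-preserving. A zero-IQR row is degenerate: an all-0.5 vector is
#' returned with a warning.
#'
#' @param x Numeric vector, length >= 2.
#' @return Numeric vector in \[0, 1\].
#' @export
srs_normalize <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) .stopf("need a numeric vector, n >= 2")
  iqr <- stats::IQR(x)
  if (iqr == 0) {
    warning("zero IQR: degenerate row, returning constant 0.5")
    return(rep(0.5, length(x)))
  }
  s <- 1 / (1 + exp(-(x - stats::median(x)) / (iqr / 1.35)))
  (s - min(s)) / (max(s) - min(s))
}

#' Normalize a gene x site expression matrix
#'
#' Three steps per gene row: (1) donor-mean centering, removing
#' between-donor offsets (donors contributing a single site are skipped,
#' with a message); (2) scaled robust sigmoid normalization; (3) z-scoring
#' across all sites (mean 0, SD 1). With a single donor, centering reduces
#' to global mean removal.
#'
#' @param m Gene x site numeric matrix.
#' @param donor_ids Donor label per site (length `ncol(m)`).
#' @return Normalized matrix with attribute `normalized = TRUE`.
#' @export
normalize_matrix <- function(m, donor_ids) {
  donor_ids <- as.character(donor_ids)
  if (length(donor_ids) != ncol(m))
    .stopf("need one donor label per site")
  counts <- table(donor_ids)
  singles <- names(counts)[counts < 2]
  if (length(singles))
    message("donor(s) with a single site, centering skipped: ",
            paste(singles, collapse = ", "))
  for (d in names(counts)[counts >= 2]) {
    idx <- donor_ids == d
    m[, idx] <- m[, idx, drop = FALSE] -
      rowMeans(m[, idx, drop = FALSE])
  }
  dn <- dimnames(m)
  m <- t(apply(m, 1L, srs_normalize))
  m <- (m - rowMeans(m)) / apply(m, 1L, stats::sd)
  dimnames(m) <- dn
  attr(m, "normalized") <- TRUE
  m
}
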