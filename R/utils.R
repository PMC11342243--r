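# Shared constants and small internal helpers.

#' Imaging index names
#'
#' The four per-site imaging indices handled throughout the package: three
#' resting-state functional measures (amplitude of low-frequency fluctuation,
#' its fractional variant, regional homogeneity) and one structural measure
#' (grey matter density).
#'
#' @return Character vector of length four.
#' @export
mdd_indices <- function() c("ALFF", "fALFF", "ReHo", "GMD")

#' @rdname mdd_indices
#' @export
functional_indices <- function() c("ALFF", "fALFF", "ReHo")

#' Default developmental period labels
#'
#' Eight ordered developmental periods spanning embryonic development to
#' adulthood, used to annotate developmental transcriptome samples.
#'
#' @return Character vector of length 8.
#' @export
dev_periods <- function() {
  c("early_fetal", "early_mid_fetal", "late_mid_fetal", "late_fetal",
    "infancy", "childhood", "adolescence", "adulthood")
}

#' Default brain region labels
#'
#' Sixteen brain regions: eleven neocortical areas plus amygdala,
#' hippocampus, striatum, mediodorsal thalamus and cerebellar cortex.
#'
#' @return Character vector of length 16.
#' @export
dev_regions <- function() {
  c("A1C", "AMY", "CBC", "DFC", "HIP", "IPC", "ITC", "M1C",
    "MD", "MFC", "OFC", "S1C", "STC", "STR", "V1C", "VFC")
}

# numeric tolerance used when comparing permuted statistics with observed ones
.rho_tol <- 1e-12

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0 || x >= 1)
    .stopf("`%s` must be a single number strictly between 0 and 1", name)
  invisible(x)
}

# rank-transform matrix rows (average ranks for ties), then centre and scale
# each row to unit Euclidean norm so that crossprod gives the Pearson
# correlation of ranks, i.e. Spearman's rho.
.row_rank_std <- function(m) {
  r <- t(apply(m, 1L, rank))
  if (nrow(m) == 1L) r <- matrix(r, nrow = 1L, dimnames = dimnames(m))
  r <- r - rowMeans(r)
  nrm <- sqrt(rowSums(r^2))
  bad <- nrm == 0
  nrm[bad] <- NA_real_
  out <- r / nrm
  attr(out, "degenerate") <- bad
  out
}

.rank_std_vec <- function(x) {
  r <- rank(x)
  r <- r - mean(r)
  nrm <- sqrt(sum(r^2))
  if (nrm == 0) return(NULL)
  r / nrm
}

# vectorized two-sample t-test over columns of two matrices (subjects x sites)
# sign convention: positive t means group a > group b.
# Zero-variance columns: p = 0 when the means differ, p = 1 otherwise.
.col_t_test <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  n1 <- nrow(a); n2 <- nrow(b)
  m1 <- colMeans(a); m2 <- colMeans(b)
  v1 <- pmax(0, (colSums(a^2) - n1 * m1^2) / (n1 - 1))
  v2 <- pmax(0, (colSums(b^2) - n2 * m2^2) / (n2 - 1))
  d <- m1 - m2
  if (variant == "pooled") {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(d))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- d / se
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se == 0
  if (any(degen)) {
    message(sum(degen), " site(s) with zero within-group variance; ",
            "p set to 0/1 by mean difference")
    t[degen] <- sign(d[degen]) * Inf
    t[degen & d == 0] <- 0
    p[degen] <- ifelse(d[degen] == 0, 1, 0)
  }
  list(t = t, p = p, mean_diff = d, df = df)
}
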