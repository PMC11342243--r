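# Expression-imaging association: Spearman correlation of per-gene spatial
# expression with case-control contrast maps, permutation p-values from
# site-label shuffling, and directional classification of selected genes.
#
# The permutation scheme shuffles the map across sites (equivalently the
# site labels); it deliberately does not preserve spatial autocorrelation
# (no spin-test surrogate), matching the naive permutation null of the
# analysis it implements.

#' Spearman correlation of two per-site vectors
#'
#' Spearman's rho with average ranks for ties. A constant input makes the
#' statistic undefined: `NA` is returned with a warning.
#'
#' @param x,y Numeric vectors aligned on >= 3 sites.
#' @return A single correlation in \[-1, 1\], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) .stopf("vectors must be aligned")
  if (length(x) < 3) .stopf("need at least 3 sites")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

# sample n_perm permutations of seq_len(n) under the current RNG state,
# returned as an n x n_perm index matrix
.perm_indices <- function(n, n_perm) {
  vapply(seq_len(n_perm), function(i) sample.int(n), integer(n))
}

#' Permutation p-value for one gene-map pair
#'
#' The map vector is randomly permuted across sites `n_perm` times; the
#' two-sided p-value uses the add-one estimator
#' \eqn{p = (1 + \#\{|\rho_{perm}| \ge |\rho_{obs}|\}) / (n_{perm} + 1)},
#' so p is never 0 and its smallest attainable value is
#' \eqn{1/(n_{perm}+1)} (with 10,000 permutations the threshold p < 0.001
#' is attainable exactly).
#'
#' @param expr Per-site expression vector.
#' @param map Per-site contrast values (same length).
#' @param n_perm Number of permutations (>= 1; default 10000).
#' @param seed Integer seed; results are reproducible given it.
#' @param gene_id,index_name Optional identifiers carried into the record.
#' @return An `AssociationRecord` data frame: `gene_id`, `index_name`,
#'   `rho`, `p_perm`, `n_perm`.
#' @export
permutation_pvalue <- function(expr, map, n_perm = 10000L, seed = 1L,
                               gene_id = NA_character_,
                               index_name = NA_character_) {
  if (n_perm < 1) .stopf("n_perm must be >= 1")
  rho <- spearman_rho(expr, map)
  if (is.na(rho))
    return(data.frame(gene_id = gene_id, index_name = index_name,
                      rho = NA_real_, p_perm = NA_real_, n_perm = n_perm))
  re <- .rank_std_vec(expr)
  rm_ <- .rank_std_vec(map)
  count <- withr::with_seed(seed, {
    perms <- .perm_indices(length(map), n_perm)
    rho_perm <- as.vector(crossprod(re, matrix(rm_[perms], nrow = length(rm_))))
    sum(abs(rho_perm) >= abs(rho) - .rho_tol)
  })
  data.frame(gene_id = gene_id, index_name = index_name, rho = rho,
             p_perm = (1 + count) / (n_perm + 1), n_perm = n_perm)
}

#' Identify depression-related genes
#'
#' Correlates every gene's spatial expression with the contrast map of each
#' imaging index (Spearman), derives permutation p-values, and selects the
#' genes whose expression is simultaneously associated with structure and
#' function: permutation p < alpha for GMD AND for at least one of ALFF,
#' fALFF, ReHo.
#'
#' By default one shared, seeded permutation set is used across genes
#' within each index (reproducible and fast); set
#' `share_permutations = FALSE` for independent per-gene permutations.
#'
#' @param expr Gene x site expression matrix (rownames = gene ids,
#'   colnames = site ids).
#' @param maps Named list with one element per index (ALFF, fALFF, ReHo,
#'   GMD): each either a `DifferenceMap` data frame (`site_id`, `t`) or a
#'   named numeric vector of per-site contrast values.
#' @param alpha Selection threshold on the permutation p (default 0.001).
#' @param n_perm Permutations per index (default 10000).
#' @param seed Integer seed (per-index substreams are derived from it).
#' @param share_permutations Share one permutation set across genes per
#'   index (default TRUE).
#' @return List with `records` (wide data frame: `gene_id`, then `rho_*`
#'   and `p_*` per index) and `selected` (character vector of gene ids).
#' @export
identify_depression_genes <- function(expr, maps, alpha = 0.001,
                                      n_perm = 10000L, seed = 1L,
                                      share_permutations = TRUE) {
  .check_prob(alpha, "alpha")
  if (n_perm < 1) .stopf("n_perm must be >= 1")
  if (!setequal(names(maps), mdd_indices()))
    .stopf("maps must contain exactly the indices %s",
           paste(mdd_indices(), collapse = ", "))
  sites <- colnames(expr)
  mapv <- lapply(maps, .map_values, sites = sites)
  R <- .row_rank_std(expr)
  degen <- attr(R, "degenerate")
  if (any(degen))
    warning(sum(degen), " constant gene row(s): association undefined (NA)")
  records <- data.frame(gene_id = rownames(expr))
  for (k in seq_along(mdd_indices())) {
    ix <- mdd_indices()[k]
    y <- .rank_std_vec(mapv[[ix]])
    if (is.null(y)) .stopf("contrast map for %s is constant", ix)
    rho_obs <- as.vector(R %*% y)
    counts <- withr::with_seed(seed + k, {
      if (share_permutations) {
        .perm_count_shared(R, y, abs(rho_obs), n_perm)
      } else {
        .perm_count_pergene(R, y, abs(rho_obs), n_perm)
      }
    })
    records[[paste0("rho_", ix)]] <- rho_obs
    records[[paste0("p_", ix)]] <- (1 + counts) / (n_perm + 1)
    records[[paste0("p_", ix)]][degen] <- NA_real_
    records[[paste0("rho_", ix)]][degen] <- NA_real_
  }
  sel <- records$p_GMD < alpha &
    (records$p_ALFF < alpha | records$p_fALFF < alpha |
       records$p_ReHo < alpha)
  sel[is.na(sel)] <- FALSE
  list(records = records, selected = records$gene_id[sel],
       alpha = alpha, n_perm = n_perm)
}

# counts of |rho_perm| >= |rho_obs| with one shared permutation stream;
# chunked so the genes x n_perm product stays small in memory
.perm_count_shared <- function(R, y, abs_obs, n_perm) {
  counts <- numeric(nrow(R))
  chunk <- max(1L, min(n_perm, floor(2e6 / max(1L, nrow(R)))))
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    perms <- .perm_indices(length(y), b)
    rho_perm <- abs(R %*% matrix(y[perms], nrow = length(y)))
    counts <- counts + rowSums(rho_perm >= abs_obs - .rho_tol)
    done <- done + b
  }
  counts
}

.perm_count_pergene <- function(R, y, abs_obs, n_perm) {
  vapply(seq_len(nrow(R)), function(i) {
    perms <- .perm_indices(length(y), n_perm)
    rho_perm <- abs(as.vector(R[i, ] %*%
                                matrix(y[perms], nrow = length(y))))
    sum(rho_perm >= abs_obs[i] - .rho_tol)
  }, numeric(1))
}

.map_values <- function(map, sites) {
  v <- if (is.data.frame(map)) stats::setNames(map$t, map$site_id) else map
  if (!is.null(names(v)) && !is.null(sites)) {
    missing <- setdiff(sites, names(v))
    if (length(missing))
      .stopf("contrast map lacks site(s): %s",
             paste(utils::head(missing, 5), collapse = ", "))
    v <- v[sites]
  } else if (length(v) != length(sites)) {
    .stopf("contrast map length does not match the expression sites")
  }
  unname(v)
}

#' Classify selected genes by directional effect
#'
#' Class 1: GMD correlation negative and every *significant* functional
#' correlation positive (genes with negative effect for grey matter
#' density, positive for function). Class 2 is the mirror image. Selected
#' genes whose significant functional correlations disagree in sign are
#' `unclassified` (they belong to neither class); non-selected genes are
#' `control`.
#'
#' @param records Wide association data frame from
#'   [identify_depression_genes()].
#' @param selected Character vector of selected gene ids.
#' @param alpha Significance threshold used for the per-index significance
#'   calls (default 0.001; use the selection alpha).
#' @return Data frame `gene_id`, `class` (factor: Class1, Class2,
#'   unclassified, control) plus the `rho_*`/`p_*` columns of `records`.
#' @export
classify_directional <- function(records, selected, alpha = 0.001) {
  need <- c(paste0("rho_", mdd_indices()), paste0("p_", mdd_indices()))
  if (!all(need %in% names(records)))
    .stopf("records missing column(s): %s",
           paste(setdiff(need, names(records)), collapse = ", "))
  if (!all(selected %in% records$gene_id))
    .stopf("selected gene(s) without records")
  cls <- rep("control", nrow(records))
  idx <- which(records$gene_id %in% selected)
  for (i in idx) {
    if (anyNA(records[i, need])) .stopf("missing record for selected gene %s",
                                        records$gene_id[i])
    sig <- vapply(functional_indices(),
                  function(ix) records[[paste0("p_", ix)]][i] < alpha,
                  logical(1))
    frho <- vapply(functional_indices(),
                   function(ix) records[[paste0("rho_", ix)]][i], numeric(1))
    gmd <- records$rho_GMD[i]
    cls[i] <- if (gmd < 0 && all(frho[sig] > 0)) "Class1"
    else if (gmd > 0 && all(frho[sig] < 0)) "Class2"
    else "unclassified"
  }
  out <- cbind(data.frame(gene_id = records$gene_id,
                          class = factor(cls, levels = c("Class1", "Class2",
                                                         "unclassified",
                                                         "control"))),
               records[, setdiff(names(records), "gene_id"), drop = FALSE])
  out
}
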