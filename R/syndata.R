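# Synthetic-data generators. Every pipeline input can be generated with
# known planted ground truth, so downstream recovery is testable without the
# consortium imaging data, the brain-wide microarray atlas, the developmental
# transcriptome, or the protein-interaction database the method was designed
# around. The generators only emulate the statistical structure the pipeline
# consumes (planted expression-map correlations, spatially/temporally
# specific genes, sex-biased genes, hub/periphery networks) -- never the
# underlying imaging geometry or batch structure.

#' Ground truth for a synthetic study
#'
#' Records which genes carry planted signal so recovery can be scored.
#'
#' @param genes Character vector: the full gene universe.
#' @param class1_genes,class2_genes Disjoint subsets of `genes`: genes whose
#'   spatial expression is planted to correlate positively (Class 1) or
#'   negatively (Class 2) with the functional contrast maps, with the
#'   opposite sign for grey matter density.
#' @param specific_genes Data frame with columns `gene_id`, `axis`
#'   (`"region"` or `"period"`), `level`: genes planted with elevated
#'   expression in one region (across all periods) or one period (across all
#'   regions).
#' @param sex_biased_genes Named character vector mapping gene id to
#'   `"female"` or `"male"` (the sex with elevated expression).
#' @param hub_genes Genes planted as network hubs.
#' @param effect_sizes Named list of generator effect sizes.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(genes, class1_genes = character(),
                         class2_genes = character(),
                         specific_genes = NULL,
                         sex_biased_genes = character(),
                         hub_genes = character(),
                         effect_sizes = list()) {
  if (length(intersect(class1_genes, class2_genes)))
    .stopf("class1_genes and class2_genes must be disjoint")
  if (is.null(specific_genes))
    specific_genes <- data.frame(gene_id = character(), axis = character(),
                                 level = character())
  planted <- c(class1_genes, class2_genes, specific_genes$gene_id,
               names(sex_biased_genes), hub_genes)
  if (!all(planted %in% genes))
    .stopf("planted gene id(s) missing from the gene universe: %s",
           paste(utils::head(setdiff(planted, genes), 5), collapse = ", "))
  if (!all(specific_genes$axis %in% c("region", "period")))
    .stopf("specific_genes$axis must be 'region' or 'period'")
  if (length(sex_biased_genes) &&
      !all(sex_biased_genes %in% c("female", "male")))
    .stopf("sex_biased_genes values must be 'female' or 'male'")
  structure(list(genes = genes, class1_genes = class1_genes,
                 class2_genes = class2_genes,
                 specific_genes = specific_genes,
                 sex_biased_genes = sex_biased_genes,
                 hub_genes = hub_genes, effect_sizes = effect_sizes),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$genes), "genes |",
      length(x$class1_genes), "Class1,", length(x$class2_genes), "Class2 |",
      nrow(x$specific_genes), "axis-specific |",
      length(x$sex_biased_genes), "sex-biased |",
      length(x$hub_genes), "hubs\n")
  invisible(x)
}

#' Default study configuration
#'
#' Desk-scale configuration echoing the real study's proportions: 200 sites,
#' 2,000 genes with 150 Class-1 and 200 Class-2 planted genes (the study's
#' atlas had ~15,700 genes over 1,280 cortical samples with 146/199 genes
#' per class), 100 subjects per imaging group, 4 developmental samples per
#' (period, region) cell (512 total, near the real 547).
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
study_config <- function(...) {
  cfg <- list(
    n_genes = 2000L, n_sites = 200L,
    n_class1 = 150L, n_class2 = 200L,
    n_per_group = 100L, noise_sd = 1,
    amplitude = 0.5, jitter_sd = 0.05,
    corr_strength = 0.8,
    n_per_cell = 4L, dev_baseline = 5, dev_noise_sd = 1,
    specific_shift = 3, sex_shift = 1,
    n_sex_class1 = 8L, n_sex_class2 = 9L, n_sex_control = 20L,
    n_period_specific = 100L,
    n_nodes = 1000L, hub_fraction = 0.05, mean_degree = 8,
    periphery_factor = 0.3, hub_factor = 6,
    overlap_rates = c(class1 = 0.2, class2 = 0.1, control = 0.05),
    n_terms = 40L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) .stopf("unknown config field(s): %s",
                          paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Build the default planted ground truth
#'
#' Gene ids are `G0001`..`G<n>`. Class assignments are sampled; every class
#' gene is planted region-specific (Class-1 targets drawn from neocortical
#' and cerebellar/thalamic regions, Class-2 from limbic regions), a subset
#' of control genes is planted period-specific (developmentally regulated
#' genes exist among real control genes and drive their temporal
#' dispersion), sex-biased genes are drawn per class, and hubs are drawn
#' from the control genes.
#'
#' @param config A [study_config()] list.
#' @param seed Integer seed; the truth is deterministic given it.
#' @return A `ground_truth` object.
#' @export
default_truth <- function(config = study_config(), seed = 1L) {
  withr::with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(config$n_genes))
    planted <- sample(genes, config$n_class1 + config$n_class2)
    class1 <- planted[seq_len(config$n_class1)]
    class2 <- planted[config$n_class1 + seq_len(config$n_class2)]
    controls <- setdiff(genes, planted)
    class1_regions <- c("VFC", "STC", "IPC", "OFC", "S1C", "M1C", "A1C",
                        "V1C", "MD", "CBC")
    class2_regions <- c("MFC", "ITC", "HIP", "AMY")
    specific <- rbind(
      data.frame(gene_id = class1, axis = "region",
                 level = sample(class1_regions, length(class1), TRUE)),
      data.frame(gene_id = class2, axis = "region",
                 level = sample(class2_regions, length(class2), TRUE)),
      data.frame(gene_id = sample(controls, config$n_period_specific),
                 axis = "period",
                 level = sample(dev_periods(), config$n_period_specific,
                                TRUE))
    )
    sex1 <- sample(class1, config$n_sex_class1)
    sex2 <- sample(class2, config$n_sex_class2)
    sexc <- sample(setdiff(controls, specific$gene_id),
                   config$n_sex_control)
    sex_bias <- c(
      stats::setNames(rep("female", length(sex1)), sex1),
      stats::setNames(sample(c("female", "male"), length(sex2), TRUE), sex2),
      stats::setNames(sample(c("female", "male"), length(sexc), TRUE), sexc)
    )
    hubs <- sample(setdiff(controls, names(sex_bias)),
                   max(1L, round(config$hub_fraction * config$n_nodes)))
    ground_truth(genes, class1, class2, specific, sex_bias, hubs,
                 effect_sizes = list(
                   corr_strength = config$corr_strength,
                   amplitude = config$amplitude,
                   specific_shift = config$specific_shift,
                   sex_shift = config$sex_shift))
  })
}

#' Generate per-site imaging effect maps
#'
#' The four indices share one latent spatial pattern `s`: the functional
#' indices shift cases by `+amplitude * s` and grey matter density by
#' `-amplitude * s` (functional increases co-locate with density decreases,
#' as in the observed contrast maps), plus independent per-index jitter.
#'
#' @param n_sites Number of cortical sites.
#' @param amplitude Effect amplitude in noise-SD units (default 0.5).
#' @param jitter_sd SD of per-index site jitter (default 0.05).
#' @param seed Integer seed.
#' @return List with `maps` (named list of per-site effect vectors, one per
#'   index) and `latent` (the shared pattern `s`).
#' @export
gen_effect_maps <- function(n_sites, amplitude = 0.5, jitter_sd = 0.05,
                            seed = 1L) {
  if (n_sites < 2) .stopf("need at least 2 sites")
  withr::with_seed(seed, {
    sites <- sprintf("S%03d", seq_len(n_sites))
    s <- stats::rnorm(n_sites)
    maps <- lapply(mdd_indices(), function(ix) {
      sgn <- if (ix == "GMD") -1 else 1
      stats::setNames(sgn * amplitude * s +
                        stats::rnorm(n_sites, sd = jitter_sd), sites)
    })
    names(maps) <- mdd_indices()
    list(maps = maps, latent = stats::setNames(s, sites), sites = sites)
  })
}

#' Generate a case-control imaging cohort
#'
#' Per index, subject-by-site values are iid Gaussian noise around a group
#' mean: the per-site effect map for cases, 0 for controls.
#'
#' @param n_sites Number of sites (>= 2).
#' @param n_per_group Subjects per group (>= 2).
#' @param effect_map Named list with one per-site effect vector for each of
#'   ALFF, fALFF, ReHo and GMD (see [gen_effect_maps()]).
#' @param noise_sd Positive noise SD.
#' @param seed Integer seed; datasets are deterministic given it.
#' @return Named list of `GroupImagingDataset`s, one per index: each a list
#'   with `index_name`, `values` (subject x site matrix) and `group`
#'   (per-subject `"case"`/`"control"`).
#' @export
gen_imaging_cohort <- function(n_sites, n_per_group, effect_map,
                               noise_sd = 1, seed = 1L) {
  if (n_sites < 2 || n_per_group < 2)
    .stopf("need n_sites >= 2 and n_per_group >= 2")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    .stopf("noise_sd must be positive")
  if (!setequal(names(effect_map), mdd_indices()))
    .stopf("effect_map must contain exactly the indices %s",
           paste(mdd_indices(), collapse = ", "))
  if (!all(lengths(effect_map) == n_sites))
    .stopf("every effect vector must have length n_sites")
  sites <- names(effect_map[[1]])
  if (is.null(sites)) sites <- sprintf("S%03d", seq_len(n_sites))
  n <- 2L * n_per_group
  group <- rep(c("case", "control"), each = n_per_group)
  subj <- sprintf("sub%04d", seq_len(n))
  withr::with_seed(seed, {
    out <- lapply(mdd_indices(), function(ix) {
      shift <- matrix(0, n, n_sites)
      shift[group == "case", ] <- matrix(effect_map[[ix]], n_per_group,
                                         n_sites, byrow = TRUE)
      v <- shift + matrix(stats::rnorm(n * n_sites, sd = noise_sd), n)
      dimnames(v) <- list(subj, sites)
      list(index_name = ix, values = v, group = group)
    })
    names(out) <- mdd_indices()
    out
  })
}

#' Generate a spatial expression matrix with planted map correlations
#'
#' Planted Class-1 genes mix a Gaussianized rank transform of the combined
#' effect map (mean of standardized functional maps minus the standardized
#' GMD map) into their site profile with weight `corr_strength`; Class-2
#' genes mix its negation; all other genes are independent noise. Using a
#' monotone rank transform controls the sign and magnitude of the
#' population Spearman correlation without assuming linearity.
#'
#' @param truth A `ground_truth` object.
#' @param sites Character vector of site ids (>= 3).
#' @param effect_map Named list of per-site effect vectors (as produced by
#'   [gen_effect_maps()]).
#' @param corr_strength Coupling strength strictly between 0 and 1.
#' @param seed Integer seed.
#' @return Gene x site numeric matrix (dimnames set). Values emulate an
#'   already-normalized atlas matrix and may be negative.
#' @export
gen_expression_matrix <- function(truth, sites, effect_map,
                                  corr_strength = 0.8, seed = 1L) {
  if (length(sites) < 3) .stopf("correlation undefined with < 3 sites")
  .check_prob(corr_strength, "corr_strength")
  if (!inherits(truth, "ground_truth")) .stopf("`truth` must be ground_truth")
  n <- length(sites)
  fun <- sapply(functional_indices(),
                function(ix) effect_map[[ix]][sites])
  gmd <- effect_map[["GMD"]][sites]
  comb <- rowMeans(cbind(apply(fun, 2, .z_or_zero), -.z_or_zero(gmd)))
  coupled <- stats::sd(comb) > 0
  if (!coupled && length(c(truth$class1_genes, truth$class2_genes)))
    message("effect maps are constant; planted genes generated as noise")
  g <- if (coupled) stats::qnorm((rank(comb) - 0.5) / n) else rep(0, n)
  cc <- if (coupled) corr_strength else 0
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(length(truth$genes) * n) * sqrt(1 - cc^2),
                nrow = length(truth$genes),
                dimnames = list(truth$genes, sites))
    if (cc > 0 && length(truth$class1_genes))
      m[truth$class1_genes, ] <- m[truth$class1_genes, , drop = FALSE] +
        matrix(cc * g, length(truth$class1_genes), n, byrow = TRUE)
    if (cc > 0 && length(truth$class2_genes))
      m[truth$class2_genes, ] <- m[truth$class2_genes, , drop = FALSE] -
        matrix(cc * g, length(truth$class2_genes), n, byrow = TRUE)
    idx <- !rownames(m) %in% c(truth$class1_genes, truth$class2_genes)
    m[idx, ] <- m[idx, , drop = FALSE] / sqrt(1 - cc^2)  # unit-SD nulls
    m
  })
}

.z_or_zero <- function(x) {
  s <- stats::sd(x)
  if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
}

#' Generate a developmental expression set
#'
#' Samples live on an 8-period by 16-region grid with `n_per_cell` samples
#' per cell, sexes alternating (both sexes present whenever
#' `n_per_cell >= 2`). Expression is Gaussian noise around a nonnegative
#' baseline, clamped at 0 (the dispersion index requires nonnegative
#' values). Region-specific planted genes gain `specific_shift` in their
#' target region across all periods; period-specific genes in their target
#' period across regions; sex-biased genes gain `sex_shift` in the labeled
#' sex.
#'
#' @param truth A `ground_truth` object.
#' @param periods Exactly 8 period labels (default [dev_periods()]).
#' @param regions Exactly 16 region labels (default [dev_regions()]).
#' @param n_per_cell Samples per (period, region) cell (>= 1).
#' @param baseline,noise_sd Baseline mean and noise SD.
#' @param specific_shift,sex_shift Planted effect sizes.
#' @param seed Integer seed.
#' @return A `dev_expression` object: list with `samples` (data frame:
#'   sample_id, period, region, sex), `expr` (sample x gene matrix),
#'   `periods`, `regions`.
#' @export
gen_dev_expression <- function(truth, periods = dev_periods(),
                               regions = dev_regions(), n_per_cell = 4L,
                               baseline = 5, noise_sd = 1,
                               specific_shift = 3, sex_shift = 1,
                               seed = 1L) {
  if (length(periods) != 8L) .stopf("exactly 8 period labels required")
  if (length(regions) != 16L) .stopf("exactly 16 region labels required")
  if (n_per_cell < 1L) .stopf("n_per_cell must be >= 1")
  grid <- expand.grid(period = periods, region = regions,
                      rep = seq_len(n_per_cell), stringsAsFactors = FALSE)
  samples <- data.frame(
    sample_id = sprintf("dev%04d", seq_len(nrow(grid))),
    period = grid$period, region = grid$region,
    sex = c("female", "male")[(grid$rep - 1L) %% 2L + 1L]
  )
  genes <- truth$genes
  withr::with_seed(seed, {
    expr <- baseline +
      matrix(stats::rnorm(nrow(samples) * length(genes), sd = noise_sd),
             nrow(samples), dimnames = list(samples$sample_id, genes))
    sp <- truth$specific_genes
    for (i in seq_len(nrow(sp))) {
      hit <- if (sp$axis[i] == "region") samples$region == sp$level[i]
             else samples$period == sp$level[i]
      expr[hit, sp$gene_id[i]] <- expr[hit, sp$gene_id[i]] + specific_shift
    }
    for (gn in names(truth$sex_biased_genes)) {
      hit <- samples$sex == truth$sex_biased_genes[[gn]]
      expr[hit, gn] <- expr[hit, gn] + sex_shift
    }
    expr <- pmax(expr, 0)
    structure(list(samples = samples, expr = expr, periods = periods,
                   regions = regions),
              class = "dev_expression")
  })
}

#' @export
print.dev_expression <- function(x, ...) {
  cat("dev_expression:", nrow(x$samples), "samples x", ncol(x$expr),
      "genes;", length(x$periods), "periods x", length(x$regions),
      "regions\n")
  invisible(x)
}

#' Generate a scored protein-interaction edge list
#'
#' Samples a weighted configuration-model graph: node weights determine
#' expected degree, with planted hub genes upweighted and Class-1 genes
#' downweighted so they land on the network periphery (interacting with few
#' other proteins). Edges retained by the study's confidence threshold get
#' scores in (900, 1000]; decoy edges at or below 900 are added so the
#' threshold is exercised.
#'
#' @param truth A `ground_truth` object.
#' @param n_nodes Number of nodes (>= 2); class genes are always included,
#'   the remainder sampled from the controls.
#' @param hub_fraction Fraction of nodes treated as hubs, in (0, 1) (used
#'   when `truth$hub_genes` is empty).
#' @param mean_degree Target mean degree of the thresholded graph.
#' @param periphery_factor,hub_factor Weight multipliers for Class-1 and
#'   hub nodes.
#' @param seed Integer seed.
#' @return Data frame `protein_a`, `protein_b`, `combined_score` (integer
#'   0-1000).
#' @export
gen_interaction_network <- function(truth, n_nodes = 1000L,
                                    hub_fraction = 0.05, mean_degree = 8,
                                    periphery_factor = 0.3, hub_factor = 6,
                                    seed = 1L) {
  if (n_nodes < 2) .stopf("need at least 2 nodes")
  if (hub_fraction <= 0 || hub_fraction >= 1)
    .stopf("hub_fraction must be in (0, 1)")
  classes <- c(truth$class1_genes, truth$class2_genes)
  if (n_nodes < length(classes))
    .stopf("n_nodes smaller than the number of planted class genes")
  withr::with_seed(seed, {
    pool <- setdiff(truth$genes, classes)
    hubs <- truth$hub_genes
    if (!length(hubs))
      hubs <- sample(pool, max(1L, round(hub_fraction * n_nodes)))
    extra <- sample(setdiff(pool, hubs),
                    n_nodes - length(classes) - length(hubs))
    nodes <- c(classes, hubs, extra)
    w <- stats::setNames(rep(1, length(nodes)), nodes)
    w[truth$class1_genes] <- periphery_factor
    w[hubs] <- hub_factor
    m <- round(mean_degree * n_nodes / 2)
    ends_a <- sample(nodes, 2L * m, replace = TRUE, prob = w)
    ends_b <- sample(nodes, 2L * m, replace = TRUE, prob = w)
    keep <- ends_a != ends_b
    a <- pmin(ends_a[keep], ends_b[keep])
    b <- pmax(ends_a[keep], ends_b[keep])
    dup <- duplicated(paste(a, b))
    a <- a[!dup][seq_len(min(m, sum(!dup)))]
    b <- b[!dup][seq_len(min(m, sum(!dup)))]
    real <- data.frame(protein_a = a, protein_b = b,
                       combined_score = sample(901:1000, length(a), TRUE))
    nd <- round(length(a) / 2)
    da <- sample(nodes, nd, replace = TRUE)
    db <- sample(nodes, nd, replace = TRUE)
    ok <- da != db
    decoy <- data.frame(protein_a = da[ok], protein_b = db[ok],
                        combined_score = sample(600:900, sum(ok), TRUE))
    out <- rbind(real, decoy)
    out[sample.int(nrow(out)), , drop = FALSE]
  })
}

#' Generate reference gene lists with configured class overlap
#'
#' Draws a GWAS-style risk list and per-tissue downregulated
#' differential-expression lists so that the fraction of each planted class
#' contained in a list matches the configured rate (Class 1 > Class 2 >
#' control by default, as the study observed).
#'
#' @param truth A `ground_truth` object.
#' @param overlap_rates Named numeric vector (`class1`, `class2`,
#'   `control`) of per-group inclusion rates in \[0, 1\].
#' @param tissues Tissue labels for the downregulated lists.
#' @param seed Integer seed.
#' @return List with `risk` (character vector) and `de_down` (named list of
#'   character vectors, one per tissue).
#' @export
gen_reference_lists <- function(truth,
                                overlap_rates = c(class1 = 0.2,
                                                  class2 = 0.1,
                                                  control = 0.05),
                                tissues = c("hippocampus",
                                            "prefrontal_cortex",
                                            "striatum"),
                                seed = 1L) {
  if (!all(c("class1", "class2", "control") %in% names(overlap_rates)))
    .stopf("overlap_rates needs entries class1, class2, control")
  if (any(overlap_rates < 0 | overlap_rates > 1))
    .stopf("overlap rates must be in [0, 1]")
  groups <- list(class1 = truth$class1_genes, class2 = truth$class2_genes,
                 control = setdiff(truth$genes, c(truth$class1_genes,
                                                  truth$class2_genes)))
  draw <- function() {
    unlist(lapply(names(groups), function(g) {
      k <- round(overlap_rates[[g]] * length(groups[[g]]))
      if (k > length(groups[[g]]))
        .stopf("requested overlap exceeds size of group %s", g)
      sample(groups[[g]], k)
    }), use.names = FALSE)
  }
  withr::with_seed(seed, {
    risk <- draw()
    de <- lapply(tissues, function(ts) draw())
    names(de) <- tissues
    list(risk = risk, de_down = de)
  })
}

#' Generate annotation term sets
#'
#' Random term-to-gene sets over the gene universe, with a few terms
#' enriched for Class-1 genes so enrichment filtering has planted signal.
#'
#' @param truth A `ground_truth` object.
#' @param n_terms Number of terms.
#' @param size_range Term size range.
#' @param n_enriched Number of Class-1-enriched terms.
#' @param seed Integer seed.
#' @return Named list of character vectors (a GMT-shaped structure).
#' @export
gen_term_sets <- function(truth, n_terms = 40L, size_range = c(10L, 60L),
                          n_enriched = 3L, seed = 1L) {
  withr::with_seed(seed, {
    out <- lapply(seq_len(n_terms), function(i) {
      sz <- sample(size_range[1]:size_range[2], 1L)
      if (i <= n_enriched && length(truth$class1_genes)) {
        k <- min(length(truth$class1_genes), ceiling(sz / 2))
        c(sample(truth$class1_genes, k),
          sample(setdiff(truth$genes, truth$class1_genes), sz - k))
      } else sample(truth$genes, sz)
    })
    names(out) <- sprintf("TERM%03d", seq_len(n_terms))
    out
  })
}

#' Simulate a full synthetic study
#'
#' Wires all generators together from one configuration and root seed
#' (named substreams per stage keep the stages independently reproducible).
#'
#' @param config A [study_config()] list.
#' @param seed Integer root seed.
#' @return List with `truth`, `effect`, `imaging`, `expr`, `dev`, `edges`,
#'   `refs`, `terms`, `config`, `seed`.
#' @export
simulate_study <- function(config = study_config(), seed = 1L) {
  truth <- default_truth(config, seed = seed)
  effect <- gen_effect_maps(config$n_sites, config$amplitude,
                            config$jitter_sd, seed = seed + 1L)
  imaging <- gen_imaging_cohort(config$n_sites, config$n_per_group,
                                effect$maps, config$noise_sd,
                                seed = seed + 2L)
  expr <- gen_expression_matrix(truth, effect$sites, effect$maps,
                                config$corr_strength, seed = seed + 3L)
  dev <- gen_dev_expression(truth, n_per_cell = config$n_per_cell,
                            baseline = config$dev_baseline,
                            noise_sd = config$dev_noise_sd,
                            specific_shift = config$specific_shift,
                            sex_shift = config$sex_shift,
                            seed = seed + 4L)
  edges <- gen_interaction_network(truth, config$n_nodes,
                                   config$hub_fraction, config$mean_degree,
                                   config$periphery_factor,
                                   config$hub_factor, seed = seed + 5L)
  refs <- gen_reference_lists(truth, config$overlap_rates,
                              seed = seed + 6L)
  terms <- gen_term_sets(truth, config$n_terms, seed = seed + 7L)
  list(truth = truth, effect = effect, imaging = imaging, expr = expr,
       dev = dev, edges = edges, refs = refs, terms = terms,
       config = config, seed = seed)
}
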