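# Protein-interaction network topology: thresholded graph construction and
# per-node degree, betweenness centrality and clustering coefficient, with
# class-vs-class comparisons.

#' Build the thresholded interaction graph
#'
#' Keeps edges with `combined_score` strictly above `threshold` (the
#' confidence scale runs 0-1000; the study used > 900), drops self-loops,
#' and collapses duplicate edges keeping the maximum score. The graph is
#' undirected and simple.
#'
#' @param edges Data frame with columns `protein_a`, `protein_b`,
#'   `combined_score`.
#' @param threshold Strict lower bound on retained scores (default 900).
#' @return An undirected `igraph` graph with edge attribute
#'   `combined_score`.
#' @export
build_graph <- function(edges, threshold = 900L) {
  need <- c("protein_a", "protein_b", "combined_score")
  if (!all(need %in% names(edges)))
    .stopf("edge table must have columns %s", paste(need, collapse = ", "))
  bad <- which(is.na(edges$protein_a) | is.na(edges$protein_b) |
                 !is.finite(edges$combined_score) |
                 edges$combined_score < 0 | edges$combined_score > 1000)
  if (length(bad))
    .stopf("malformed edge row(s): %s",
           paste(utils::head(bad, 5), collapse = ", "))
  keep <- edges$combined_score > threshold &
    edges$protein_a != edges$protein_b
  e <- edges[keep, need, drop = FALSE]
  g <- igraph::graph_from_data_frame(e, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                   edge.attr.comb = list(combined_score = "max"))
}

#' Per-node topology records
#'
#' Degree (incident edge count), betweenness centrality (unnormalized sum
#' over unordered node pairs of the fraction of shortest paths through the
#' node) and local clustering coefficient
#' (`2 * triangles / (deg * (deg - 1))`, 0 for degree < 2).
#'
#' @param g An `igraph` graph from [build_graph()].
#' @param normalized_betweenness Divide betweenness by the number of pairs
#'   not involving the node (default FALSE; only group comparisons are
#'   reported downstream, so the scale is a matter of convention).
#' @return Data frame `gene_id`, `degree`, `betweenness`, `clustering`.
#' @export
compute_topology <- function(g, normalized_betweenness = FALSE) {
  if (igraph::vcount(g) == 0)
    return(data.frame(gene_id = character(), degree = integer(),
                      betweenness = numeric(), clustering = numeric()))
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE,
                             normalized = normalized_betweenness)
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc[deg < 2] <- 0
  data.frame(gene_id = igraph::V(g)$name, degree = unname(deg),
             betweenness = unname(btw), clustering = cc,
             row.names = NULL)
}

#' Compare topology metrics between gene classes
#'
#' Two-sided two-sample t-tests per metric (degree, betweenness,
#' clustering) for Class 1 vs Class 2, Class 1 vs control and Class 2 vs
#' control. By default genes absent from the thresholded graph are
#' excluded (interaction coverage is partial; zero-filling would
#' manufacture signal); `include_missing_as_zero = TRUE` zero-fills them
#' instead.
#'
#' @param records Topology data frame from [compute_topology()].
#' @param classes Classification data frame (`gene_id`, `class`).
#' @param include_missing_as_zero Include classified genes missing from
#'   the graph with all-zero metrics (default FALSE).
#' @return Data frame `metric`, `comparison`, `t`, `p`, `mean_a`,
#'   `mean_b`, `n_a`, `n_b`.
#' @export
compare_topology <- function(records, classes,
                             include_missing_as_zero = FALSE) {
  groups <- c("Class1", "Class2", "control")
  metrics <- c("degree", "betweenness", "clustering")
  df <- merge(classes[classes$class %in% groups,
                      c("gene_id", "class"), drop = FALSE],
              records, by = "gene_id",
              all.x = include_missing_as_zero)
  if (include_missing_as_zero)
    for (m in metrics) df[[m]][is.na(df[[m]])] <- 0
  for (grp in groups)
    if (sum(df$class == grp) < 2)
      .stopf("group %s has fewer than 2 genes in the graph", grp)
  pairs <- list(c("Class1", "Class2"), c("Class1", "control"),
                c("Class2", "control"))
  do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(pairs, function(pr) {
      a <- df[[m]][df$class == pr[1]]
      b <- df[[m]][df$class == pr[2]]
      tt <- if (stats::sd(a) == 0 && stats::sd(b) == 0 &&
                mean(a) == mean(b))
        list(statistic = c(t = 0), p.value = 1)
      else stats::t.test(a, b)
      data.frame(metric = m, comparison = paste(pr, collapse = "_vs_"),
                 t = unname(tt$statistic), p = tt$p.value,
                 mean_a = mean(a), mean_b = mean(b),
                 n_a = length(a), n_b = length(b))
    }))
  }))
}
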