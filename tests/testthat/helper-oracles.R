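# Independent brute-force oracles and small shared fixtures. These stay
# independent of the implementation paths they check.

# exhaustive betweenness / clustering / degree from an adjacency matrix,
# enumerating all shortest paths per unordered pair (feasible for n <= 8)
brute_topology <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  paths_between <- function(s, t) {
    res <- list()
    best <- Inf
    rec <- function(path) {
      if (length(path) - 1L > best) return()
      v <- path[length(path)]
      if (v == t) {
        if (length(path) - 1L < best) {
          best <<- length(path) - 1L
          res <<- list(path)
        } else res[[length(res) + 1L]] <<- path
        return()
      }
      for (w in which(adj[v, ] == 1)) if (!(w %in% path)) rec(c(path, w))
    }
    rec(s)
    res[vapply(res, length, 1L) == best + 1L]
  }
  if (n >= 2) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      ps <- paths_between(s, t)
      if (!length(ps)) next
      for (p in ps) {
        inner <- p[-c(1L, length(p))]
        for (v in inner) btw[v] <- btw[v] + 1 / length(ps)
      }
    }
  }
  deg <- rowSums(adj)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] == 1)
    cc[v] <- if (length(nb) < 2) 0
    else sum(adj[nb, nb]) / (length(nb) * (length(nb) - 1))
  }
  list(degree = deg, betweenness = btw, clustering = cc)
}

# upper-tail hypergeometric probability from exact binomial coefficients
brute_hyper_tail <- function(k, term_in_bg, bg_size, set_size) {
  ks <- k:min(term_in_bg, set_size)
  sum(choose(term_in_bg, ks) *
        choose(bg_size - term_in_bg, set_size - ks)) /
    choose(bg_size, set_size)
}

# all permutations of 1..n (n <= 7)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (i in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = i)
    }
  }
  out
}

small_cfg <- function(...) {
  study_config(n_genes = 300L, n_sites = 60L, n_class1 = 20L,
               n_class2 = 25L, n_per_group = 30L, n_nodes = 150L,
               n_period_specific = 15L, n_sex_class1 = 4L,
               n_sex_class2 = 4L, n_sex_control = 6L, n_per_cell = 2L,
               ...)
}

small_study <- function(seed = 7L, ...) simulate_study(small_cfg(...), seed)

# a random undirected simple graph as adjacency + matching edge data frame
random_graph_fixture <- function(n, p_edge = 0.4) {
  adj <- matrix(0L, n, n)
  ids <- sprintf("N%02d", seq_len(n))
  edges <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (stats::runif(1) < p_edge) {
      adj[i, j] <- adj[j, i] <- 1L
      edges <- rbind(edges, data.frame(protein_a = ids[i],
                                       protein_b = ids[j],
                                       combined_score = 950L))
    }
  }
  list(adj = adj, edges = edges, ids = ids)
}
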