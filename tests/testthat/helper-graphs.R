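# fixtures built in code: abstract random graphs and small named graphs

# Erdos-Renyi mixed-species contact graph; every node its own molecule so
# all edges are intermolecular.
random_mixed_graph <- function(n, p = 3 / n, species = c("C180", "C182")) {
  sp <- sample(species, n, replace = TRUE)
  nodes <- data.frame(node = seq_len(n), species = sp,
                      molecule = seq_len(n) - 1L)
  edges <- matrix(integer(0), 0L, 2L)
  if (n >= 2L) {
    pr <- t(utils::combn(n, 2L))
    edges <- pr[stats::runif(nrow(pr)) < p, , drop = FALSE]
  }
  contact_graph(nodes, edges)
}

# graph from an explicit edge list over single-species nodes
graph_from_edges <- function(n, edges, species = "C182") {
  nodes <- data.frame(node = seq_len(n), species = rep(species, n),
                      molecule = seq_len(n) - 1L)
  contact_graph(nodes, edges)
}

# independent textbook Pearson correlation used as the statistics oracle
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

expect_counts_match_oracle <- function(g, modes, s) {
  for (nm in names(modes)) {
    fast <- count_pattern(g, modes[[nm]], s)
    slow <- brute_force_count(g, modes[[nm]], s)$count
    expect_identical(fast, as.integer(slow),
                     label = sprintf("count_pattern(%s)", nm),
                     expected.label = sprintf("oracle(%s)", nm))
  }
}
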