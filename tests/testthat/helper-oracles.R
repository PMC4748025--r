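# Independent oracles used to freeze expected values: brute-force modularity,
# exhaustive partition search, exhaustive Friedman permutation distribution.

# all set partitions of n items as restricted-growth membership vectors
.partition_cache <- new.env(parent = emptyenv())
all_partitions <- function(n) {
  key <- as.character(n)
  if (!is.null(.partition_cache[[key]])) return(.partition_cache[[key]])
  parts <- list(1L)
  if (n > 1) {
    for (i in 2:n) {
      parts <- unlist(lapply(parts, function(p) {
        lapply(seq_len(max(p) + 1L), function(lab) c(p, lab))
      }), recursive = FALSE)
    }
  }
  .partition_cache[[key]] <- parts
  parts
}

graph_adjacency <- function(g) {
  n <- igraph::vcount(g)
  A <- matrix(0, n, n)
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    w <- igraph::E(g)$weight
    if (is.null(w)) w <- rep(1, nrow(el))
    A[el] <- A[el] + w
    A[el[, 2:1, drop = FALSE]] <- A[el[, 2:1, drop = FALSE]] + w
  }
  A
}

# literal double-sum Q = (1/2m) sum_ij (A_ij - k_i k_j / 2m) delta(c_i, c_j)
brute_modularity <- function(A, mem) {
  m2 <- sum(A)
  if (m2 == 0) return(0)
  k <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(ncol(A))) {
      if (mem[i] == mem[j]) q <- q + A[i, j] - k[i] * k[j] / m2
    }
  }
  q / m2
}

# vectorised variant used where the double loop would dominate the runtime
brute_modularity_fast <- function(A, mem) {
  m2 <- sum(A)
  if (m2 == 0) return(0)
  k <- rowSums(A)
  same <- outer(mem, mem, "==")
  sum((A - outer(k, k) / m2)[same]) / m2
}

best_partition_modularity <- function(g) {
  A <- graph_adjacency(g)
  max(vapply(all_partitions(nrow(A)), function(p) brute_modularity_fast(A, p),
             numeric(1)))
}

random_small_graph <- function(n = NULL) {
  if (is.null(n)) n <- sample(4:8, 1)
  repeat {
    g <- igraph::sample_gnp(n, stats::runif(1, 0.3, 0.7))
    if (igraph::ecount(g) > 0) break
  }
  igraph::E(g)$weight <- sample(1:5, igraph::ecount(g), replace = TRUE)
  g
}

# exhaustive Friedman permutation p-value; statistic from stats::friedman.test
# (tie-corrected), table entries permuted within blocks and re-ranked
friedman_perm_oracle <- function(x) {
  n <- nrow(x); k <- ncol(x)
  stat_of <- function(tab) unname(stats::friedman.test(tab)$statistic)
  obs <- stat_of(x)
  perms <- as.matrix(expand.grid(rep(list(seq_len(factorial(k))), n)))
  pk <- perm_table(k)
  hits <- 0L
  for (r in seq_len(nrow(perms))) {
    tab <- t(vapply(seq_len(n), function(b) x[b, pk[perms[r, b], ]], numeric(k)))
    if (stat_of(tab) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / nrow(perms)
}

perm_table <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- perm_table(k - 1)
  do.call(rbind, lapply(seq_len(nrow(sub)), function(i) {
    t(vapply(seq_len(k),
             function(pos) as.integer(append(sub[i, ], k, after = pos - 1L)),
             integer(k)))
  }))
}
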