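# Weighted intersexual proximity networks: construction from scan samples,
# the size/density/degree metrics, Newman modularity, and two community
# detectors (walktrap; Potts-model simulated annealing).

#' Build a weighted intersexual proximity network from scans
#'
#' Nodes are the focal females and the males observed near them; an edge
#' connects a female-male dyad with weight equal to the number of scans in
#' which the dyad was within the radius. `"two_m"` uses the 2-m ring only;
#' `"five_m"` uses the union of both rings (the cumulative "within 5 m"
#' relation). Individuals never within radius of anyone are absent from the
#' network, so node counts may differ between the two radii.
#'
#' @param scans scan data.frame (see [validate_scans()]).
#' @param radius `"two_m"` or `"five_m"`.
#' @param window optional `c(first_day, last_day)` study-day interval.
#' @param roster optional roster used to attach a `sex` vertex attribute.
#' @return an [igraph::graph] with edge attribute `weight`, graph attributes
#'   `radius_class` and `window`, and vertex attribute `sex` when a roster is
#'   given.
#' @export
build_network <- function(scans, radius = c("two_m", "five_m"), window = NULL,
                          roster = NULL) {
  radius <- match.arg(radius)
  scans <- validate_scans(scans, roster)
  if (!is.null(window)) {
    scans <- scans[scans$day >= window[1] & scans$day <= window[2], ]
  }
  if (nrow(scans) == 0) stop("empty-network error: no scans in window", call. = FALSE)
  rings <- ring_split(scans$males_2m)
  if (radius == "five_m") {
    r5 <- ring_split(scans$males_5m)
    rings <- mapply(function(a, b) unique(c(a, b)), rings, r5, SIMPLIFY = FALSE)
  }
  n_per <- lengths(rings)
  if (sum(n_per) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    edges <- data.frame(female = rep(scans$focal_female, n_per),
                        male = unlist(rings), stringsAsFactors = FALSE)
    agg <- stats::aggregate(list(weight = rep(1L, nrow(edges))),
                            by = edges[c("female", "male")], FUN = sum)
    g <- igraph::graph_from_data_frame(agg, directed = FALSE)
  }
  if (!is.null(roster)) {
    igraph::V(g)$sex <- roster$sex[match(igraph::V(g)$name, roster$id)]
  }
  g <- igraph::set_graph_attr(g, "radius_class", radius)
  if (!is.null(window)) g <- igraph::set_graph_attr(g, "window", window)
  g
}

#' Unweighted density of a proximity network
#'
#' The fraction of possible dyads that are connected,
#' `n_dyads / (n_nodes * (n_nodes - 1) / 2)`, ignoring edge weights. On the
#' 28-node/91-edge and 24-node/48-edge field networks this reproduces the
#' printed 0.24 and 0.17.
#'
#' @param network an igraph network.
#' @return density in `[0, 1]`.
#' @export
net_density <- function(network) {
  n <- igraph::vcount(network)
  if (n < 2) stop("undefined-metric error: density needs >= 2 nodes", call. = FALSE)
  igraph::ecount(network) / (n * (n - 1) / 2)
}

#' Degree statistics of a proximity network
#'
#' Degree is the unweighted count of incident edges; strength is the sum of
#' incident edge weights, reported separately.
#'
#' @param network an igraph network.
#' @return list with `degree` (named), `strength` (named), `range`
#'   (`c(min, max)`) and `mean` (`2 * n_dyads / n_nodes`).
#' @export
degree_stats <- function(network) {
  if (igraph::vcount(network) == 0) stop("empty network", call. = FALSE)
  deg <- igraph::degree(network)
  str <- igraph::strength(network, weights = igraph::E(network)$weight)
  list(degree = deg, strength = str, range = range(deg),
       mean = 2 * igraph::ecount(network) / igraph::vcount(network))
}

membership_vector <- function(network, partition) {
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(igraph::vcount(network)))
  if (!is.null(names(partition))) {
    miss <- setdiff(nodes, names(partition))
    if (length(miss)) stop(sprintf("partition error: node(s) %s not covered",
                                   paste(miss, collapse = ", ")), call. = FALSE)
    partition <- partition[nodes]
  } else if (length(partition) != length(nodes)) {
    stop("partition error: membership length != node count", call. = FALSE)
  }
  as.integer(factor(partition))
}

#' Newman modularity of a partition on a weighted network
#'
#' `Q = (1 / 2m) * sum_ij (A_ij - k_i * k_j / 2m) * delta(c_i, c_j)` with
#' weighted adjacency `A`, node strengths `k` and total edge weight `m`.
#'
#' @param network an igraph network with edge `weight`s (missing weights are
#'   taken as 1).
#' @param partition membership vector, either named by node or in vertex
#'   order; every node must be covered.
#' @return Q in `[-1, 1]`.
#' @export
modularity_q <- function(network, partition) {
  mem <- membership_vector(network, partition)
  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(network))
  m <- sum(w)
  if (m == 0) return(0)
  el <- igraph::as_edgelist(network, names = FALSE)
  k <- igraph::strength(network, weights = w)
  same <- mem[el[, 1]] == mem[el[, 2]]
  within <- sum(w[same]) / m
  expected <- sum(vapply(split(k, mem), sum, numeric(1))^2) / (2 * m)^2
  within - expected
}

#' Walktrap community detection
#'
#' Agglomerative community detection from short-random-walk distances
#' (t-step transition probabilities, Ward-style merges). The merge dendrogram
#' is cut at the level maximising [modularity_q()]; ties are broken toward
#' fewer communities. Components are handled independently (the optimal cut
#' within each component is chosen against the global modularity), so the
#' result is deterministic and no community spans components. A graph with no
#' edges yields singleton communities.
#'
#' @param network an igraph network.
#' @param steps random-walk length t.
#' @return list with `membership` (named integer vector, labels contiguous
#'   from 1), `n_communities`, `modularity`, and `merges` per component.
#' @export
walktrap_partition <- function(network, steps = 4) {
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) {
    nodes <- as.character(seq_len(igraph::vcount(network)))
    igraph::V(network)$name <- nodes
  }
  w <- igraph::E(network)$weight
  if (is.null(w)) igraph::E(network)$weight <- 1
  m_total <- sum(igraph::E(network)$weight)

  comps <- igraph::decompose(network)
  membership <- stats::setNames(integer(length(nodes)), nodes)
  merges <- list()
  offset <- 0L
  for (comp in comps) {
    cn <- igraph::V(comp)$name
    if (igraph::vcount(comp) == 1 || igraph::ecount(comp) == 0) {
      membership[cn] <- offset + seq_along(cn)
      offset <- offset + length(cn)
      next
    }
    wt <- igraph::cluster_walktrap(comp, steps = steps,
                                   weights = igraph::E(comp)$weight,
                                   membership = FALSE)
    # pick the cut maximising the component's contribution to global Q
    best <- NULL; best_q <- -Inf; best_k <- Inf
    for (k in seq_len(igraph::vcount(comp))) {
      memk <- tryCatch(igraph::cut_at(wt, no = k), error = function(e) NULL)
      if (is.null(memk)) next
      q <- component_q(comp, memk, m_total)
      if (q > best_q + 1e-12 || (q > best_q - 1e-12 && k < best_k)) {
        best <- memk; best_q <- q; best_k <- k
      }
    }
    membership[cn] <- offset + as.integer(factor(best))
    merges[[length(merges) + 1]] <- wt$merges
    offset <- offset + max(as.integer(factor(best)))
  }
  membership <- stats::setNames(as.integer(factor(membership)), nodes)
  list(membership = membership,
       n_communities = length(unique(membership)),
       modularity = modularity_q(network, membership),
       merges = merges)
}

# contribution of one component's partition to global modularity, given the
# global total edge weight
component_q <- function(comp, mem, m_total) {
  w <- igraph::E(comp)$weight
  el <- igraph::as_edgelist(comp, names = FALSE)
  k <- igraph::strength(comp, weights = w)
  same <- mem[el[, 1]] == mem[el[, 2]]
  sum(w[same]) / m_total -
    sum(vapply(split(k, mem), sum, numeric(1))^2) / (2 * m_total)^2
}

#' Potts-model community detection by simulated annealing
#'
#' Minimises the Reichardt-Bornholdt Potts Hamiltonian
#' `H = -sum_{i<j} (A_ij - gamma * k_i k_j / 2m) * delta(c_i, c_j)`;
#' at `gamma = 1` this is equivalent to maximising Newman modularity.
#' Single-node label moves under geometric cooling, best of `restarts`
#' independent runs (each run seeded from `seed`, so results are
#' reproducible), followed by a greedy local-search polish to a single-move
#' local optimum.
#'
#' @param network an igraph network.
#' @param gamma resolution parameter, must be positive. Small gamma favours
#'   coarse partitions (as `gamma -> 0` a single community is optimal).
#' @param seed integer seed.
#' @param restarts independent annealing restarts.
#' @param t0,t_min,cooling initial temperature, final temperature, geometric
#'   cooling factor per sweep.
#' @return list with `membership` (named, labels contiguous from 1),
#'   `n_communities`, `modularity` (at `gamma = 1` scaling) and `hamiltonian`.
#' @export
potts_partition <- function(network, gamma = 1, seed = 1, restarts = 20,
                            t0 = 1, t_min = 1e-3, cooling = 0.95) {
  if (gamma <= 0) stop("configuration error: gamma must be positive", call. = FALSE)
  n <- igraph::vcount(network)
  if (n == 0) stop("empty network", call. = FALSE)
  nodes <- igraph::V(network)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, igraph::ecount(network))
  A <- matrix(0, n, n)
  if (igraph::ecount(network) > 0) {
    el <- igraph::as_edgelist(network, names = FALSE)
    A[el] <- A[el] + w
    A[el[, 2:1, drop = FALSE]] <- A[el[, 2:1, drop = FALSE]] + w
  }
  k <- rowSums(A)
  m <- sum(w)
  # coupling matrix: J_ij = A_ij - gamma * k_i k_j / 2m (null model), J_ii = 0
  J <- if (m > 0) A - gamma * outer(k, k) / (2 * m) else A
  diag(J) <- 0

  energy <- function(mem) {
    -sum(J[outer(mem, mem, "==")]) / 2
  }
  local_polish <- function(mem) {
    repeat {
      improved <- FALSE
      for (i in seq_len(n)) {
        labs <- unique(c(mem, max(mem) + 1L))
        # gain of moving i to label l: sum of J[i, j] over j in l (j != i)
        gains <- vapply(labs, function(l) sum(J[i, mem == l & seq_len(n) != i]),
                        numeric(1))
        cur <- gains[match(mem[i], labs)]
        best <- which.max(gains)
        if (gains[best] > cur + 1e-12) {
          mem[i] <- labs[best]
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    mem
  }

  best_mem <- NULL; best_e <- Inf
  for (r in seq_len(restarts)) {
    set.seed(derive_seed(seed, paste0("potts", r)))
    mem <- sample.int(max(2L, min(n, 8L)), n, replace = TRUE)
    temp <- t0
    while (temp > t_min) {
      for (step in seq_len(10L * n)) {
        i <- sample.int(n, 1)
        new_lab <- sample.int(max(mem) + 1L, 1)
        if (new_lab == mem[i]) next
        others <- seq_len(n) != i
        d_e <- sum(J[i, mem == mem[i] & others]) - sum(J[i, mem == new_lab & others])
        if (d_e < 0 || stats::runif(1) < exp(-d_e / temp)) {
          mem[i] <- new_lab
          mem <- as.integer(factor(mem))
        }
      }
      temp <- temp * cooling
    }
    mem <- local_polish(mem)
    e <- energy(mem)
    if (e < best_e - 1e-12) {
      best_e <- e
      best_mem <- mem
    }
  }
  best_mem <- as.integer(factor(best_mem))
  names(best_mem) <- nodes
  list(membership = best_mem,
       n_communities = length(unique(best_mem)),
       modularity = modularity_q(network, best_mem),
       hamiltonian = best_e)
}

#' Pairing success of a partition against primary-male assignments
#'
#' The fraction of females assigned to the same community as their primary
#' male. With a single-community partition the metric is trivially 1 and
#' uninformative; it discriminates only for multi-community partitions.
#'
#' @param network an igraph network.
#' @param partition membership vector (named by node or in vertex order).
#' @param primaries named character vector, female id -> primary male id.
#' @return fraction in `[0, 1]`; females whose primary male is absent from the
#'   network count as failures (with a warning naming them).
#' @export
pairing_success <- function(network, partition, primaries) {
  mem <- membership_vector(network, partition)
  nodes <- igraph::V(network)$name
  names(mem) <- nodes
  females <- intersect(names(primaries), nodes)
  if (length(females) == 0) stop("no females from `primaries` in the network", call. = FALSE)
  missing_m <- females[!(primaries[females] %in% nodes)]
  if (length(missing_m)) {
    warning(sprintf("primary male absent from network for: %s (counted as failures)",
                    paste(missing_m, collapse = ", ")), call. = FALSE)
  }
  ok <- vapply(females, function(f) {
    pm <- primaries[[f]]
    pm %in% nodes && mem[[f]] == mem[[pm]]
  }, logical(1))
  mean(ok)
}

#' Network metrics report
#'
#' @param network an igraph network.
#' @param partitions optional named list of membership vectors for which to
#'   report modularity and community counts.
#' @return one-row data.frame with `n_nodes`, `n_dyads`, `degree_min`,
#'   `degree_max`, `degree_mean`, `density` and, per partition `p`,
#'   `modularity_p` and `n_communities_p`.
#' @export
network_metrics <- function(network, partitions = list()) {
  ds <- degree_stats(network)
  out <- data.frame(n_nodes = igraph::vcount(network),
                    n_dyads = igraph::ecount(network),
                    degree_min = ds$range[1], degree_max = ds$range[2],
                    degree_mean = ds$mean, density = net_density(network))
  for (nm in names(partitions)) {
    out[[paste0("modularity_", nm)]] <- modularity_q(network, partitions[[nm]])
    out[[paste0("n_communities_", nm)]] <-
      length(unique(membership_vector(network, partitions[[nm]])))
  }
  out
}

#' Export a network as an edge-list CSV or GraphML
#'
#' @param network an igraph network.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edgelist_csv <- function(network, path) {
  el <- igraph::as_edgelist(network)
  w <- igraph::E(network)$weight
  if (is.null(w)) w <- rep(1, nrow(el))
  write_table(data.frame(from = el[, 1], to = el[, 2], weight = w,
                         stringsAsFactors = FALSE), path)
}

#' @rdname write_edgelist_csv
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(network, path, format = "graphml")
  invisible(path)
}
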