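# Independent oracles used to freeze expected values. Each is a direct,
# brute-force evaluation kept free of the package's own code paths.

# Exact distribution of the multi-list overlap count under uniform sampling
# without replacement: enumerates every combination of subsets (each subset
# of a given size is equally likely). Returns P(total >= x) for all x.
# Feasible for universes <= 8 genes and <= 3 lists.
exact_overlap_tail <- function(n, sizes) {
  subsets <- lapply(sizes, function(s) utils::combn(n, s, simplify = FALSE))
  counts <- integer(n + 1)  # counts[t + 1] = #combinations with total t
  idx <- rep(1L, length(sizes))
  nsub <- vapply(subsets, length, integer(1))
  repeat {
    tab <- tabulate(unlist(mapply(function(ss, i) ss[[i]], subsets, idx,
                                  SIMPLIFY = FALSE)), nbins = n)
    t <- sum(tab >= 2)
    counts[t + 1] <- counts[t + 1] + 1L
    j <- 1L
    while (j <= length(idx)) {
      idx[j] <- idx[j] + 1L
      if (idx[j] <= nsub[j]) break
      idx[j] <- 1L
      j <- j + 1L
    }
    if (j > length(idx)) break
  }
  p <- counts / sum(counts)
  vapply(0:n, function(x) sum(p[(x + 1):(n + 1)]), numeric(1))
}

# Exact probability that successive renormalized weighted draws without
# replacement select exactly the set `s` (order ignored): sums the product
# w_i / remaining-weight over every ordering of s.
exact_weighted_subset_prob <- function(s, weights) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  total <- sum(weights)
  sum(vapply(perms(s), function(ord) {
    rem <- total
    pr <- 1
    for (g in ord) {
      pr <- pr * weights[g] / rem
      rem <- rem - weights[g]
    }
    pr
  }, numeric(1)))
}

# Brute-force betweenness: BFS from every source gives shortest-path counts
# sigma(s, .) and distances; pair dependencies are accumulated directly.
# `adj` is a symmetric 0/1 matrix. Returns raw (unnormalized) scores.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist[s, s] <- 0
    sigma[s, s] <- 1
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (u in which(adj[v, ] == 1)) {
          if (dist[s, u] == Inf) {
            dist[s, u] <- d
            nxt <- c(nxt, u)
          }
          if (dist[s, u] == d) sigma[s, u] <- sigma[s, u] + sigma[s, v]
        }
      }
      frontier <- unique(nxt)
    }
  }
  bw <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(dist[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t])
        bw[v] <- bw[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  bw
}

# Direct TOM evaluation by the defining sums (no matrix algebra).
brute_tom <- function(adj) {
  n <- nrow(adj)
  a <- adj
  diag(a) <- 0
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, -c(i, j)] * a[-c(i, j), j])
    ki <- sum(a[i, -i])
    kj <- sum(a[j, -j])
    tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  tom
}

# Ingest a synthetic study set through the canonical pipeline up to the
# per-gene support table; used by several test files.
run_support_pipeline <- function(sim) {
  recs <- do.call(rbind, lapply(names(sim$studies), function(s)
    as_deg_records(sim$studies[[s]], study_id = s,
                   schema = deg_schema(log2fc = "fold_change"))))
  filt <- apply_significance_filter(recs)
  mapped <- map_gene_ids(filt, gene_id_map(sim$id_map))
  merged <- suppressWarnings(merge_within_study(mapped$records))
  tabulate_gene_support(merged)
}

# 5-clique helper for MCODE fixtures
clique_edges <- function(members, score = 900) {
  pairs <- utils::combn(members, 2)
  data.frame(node1 = pairs[1, ], node2 = pairs[2, ], combined_score = score,
             stringsAsFactors = FALSE)
}
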