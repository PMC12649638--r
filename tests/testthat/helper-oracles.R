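# Independent reference implementations used as oracles. These deliberately
# use the slowest, most direct formulation of each definition.

# Naive O(n^3) Ward.D2: full pairwise scan each step, Lance-Williams update
# on squared distances, unsquared heights, lowest-id-pair tie rule. Tracks
# the canonical partition after every merge.
naive_ward <- function(D) {
  n <- nrow(D)
  d2 <- D^2
  act <- rep(TRUE, n)
  ids <- seq_len(n)
  sizes <- rep(1, n)
  members <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1)
  partitions <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    best <- Inf; bi <- NA; bj <- NA; bpair <- c(Inf, Inf)
    for (i in seq_len(n - 1)) {
      if (!act[i]) next
      for (j in (i + 1):n) {
        if (!act[j]) next
        v <- d2[i, j]
        pair <- sort(c(ids[i], ids[j]))
        take <- v < best ||
          (v == best && (pair[1] < bpair[1] ||
                           (pair[1] == bpair[1] && pair[2] < bpair[2])))
        if (take) { best <- v; bi <- i; bj <- j; bpair <- pair }
      }
    }
    heights[step] <- sqrt(best)
    for (k in seq_len(n)) {
      if (!act[k] || k == bi || k == bj) next
      d2[bi, k] <- d2[k, bi] <-
        ((sizes[bi] + sizes[k]) * d2[bi, k] +
           (sizes[bj] + sizes[k]) * d2[bj, k] -
           sizes[k] * best) / (sizes[bi] + sizes[bj] + sizes[k])
    }
    members[[bi]] <- c(members[[bi]], members[[bj]])
    sizes[bi] <- sizes[bi] + sizes[bj]
    ids[bi] <- n + step
    act[bj] <- FALSE
    partitions[[step]] <- canonical_partition(members[act])
  }
  list(height = heights, partitions = unlist(partitions))
}

canonical_partition <- function(member_list) {
  paste(sort(vapply(member_list,
                    function(m) paste(sort(m), collapse = ","),
                    character(1))),
        collapse = ";")
}

# replay a ward_linkage merge table into per-step canonical partitions
linkage_partitions <- function(linkage) {
  n <- linkage$n
  members <- lapply(seq_len(n), identity)
  node_members <- vector("list", n - 1)
  alive <- rep(TRUE, n)          # leaves still singleton clusters
  top <- logical(n - 1)          # merge steps that are current cluster tops
  out <- character(n - 1)
  for (s in seq_len(n - 1)) {
    get <- function(ch) {
      if (ch < 0) { alive[-ch] <<- FALSE; list(-ch) }
      else { top[ch] <<- FALSE; list(node_members[[ch]]) }
    }
    node_members[[s]] <- c(get(linkage$merge[s, 1])[[1]],
                           get(linkage$merge[s, 2])[[1]])
    top[s] <- TRUE
    current <- c(lapply(which(alive), identity), node_members[which(top)])
    out[s] <- canonical_partition(current)
  }
  out
}

# brute-force Benjamini-Hochberg step-up from its definition
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m),
               function(i) min(1, min(ps[i:m] * m / (i:m))),
               numeric(1))
  q <- numeric(m)
  q[o] <- qs
  q
}

# exhaustive hypergeometric upper tail P(X >= k) by enumerating all
# n-subsets of a universe of size N with the first K elements marked
brute_hyper <- function(N, K, n, k) {
  sets <- utils::combn(N, n)
  hits <- colSums(sets <= K)
  mean(hits >= k)
}

# scaled 13-module size profile used by the reduced test simulations
scaled_sizes_2000 <- function() {
  sizes <- round(default_module_sizes() * 2000 / 5000)
  sizes[1] <- sizes[1] + (2000L - sum(sizes))
  sizes
}
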