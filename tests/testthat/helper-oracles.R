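# Independent oracles, coded separately from the package paths they check.

random_seq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# Per-site pure-R site-pair counts (character comparison, no matrix encoding).
oracle_site_counts <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  keep <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[keep]; bv <- bv[keep]
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  differ <- av != bv
  ts <- sum(differ & purine[av] == purine[bv])
  list(valid = length(av), ts = ts, tv = sum(differ) - ts)
}

# Textbook K2P from the counts, via log1p (a different code path than the
# package's log()-based formula).
oracle_k2p <- function(a, b, min_overlap = 1) {
  cc <- oracle_site_counts(a, b)
  if (cc$valid < min_overlap) return(NA_real_)
  P <- cc$ts / cc$valid
  Q <- cc$tv / cc$valid
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log1p(-(2 * P + Q)) - 0.25 * log1p(-2 * Q)
}

# Brute-force per-species maximum intraspecific distance (double loop).
oracle_mpd <- function(d, species) {
  out <- list()
  for (sp in unique(species)) {
    idx <- which(species == sp)
    if (length(idx) < 2) next
    best <- NA_real_
    for (i in idx) for (j in idx) {
      if (i < j && !is.na(d[i, j])) {
        best <- max(best, d[i, j], na.rm = TRUE)
      }
    }
    if (!is.na(best)) out[[sp]] <- best
  }
  out
}

# Brute-force nearest neighbour per species (double loop over specimens).
oracle_nn <- function(d, species) {
  out <- list()
  for (sp in unique(species)) {
    idx <- which(species == sp)
    best <- Inf; best_sp <- NA_character_
    for (i in idx) for (j in seq_along(species)) {
      if (species[j] != sp && !is.na(d[i, j])) {
        if (d[i, j] < best ||
            (d[i, j] == best && species[j] < best_sp)) {
          best <- d[i, j]; best_sp <- species[j]
        }
      }
    }
    if (is.finite(best)) out[[sp]] <- list(nn = best_sp, dist = best)
  }
  out
}

# ---- exhaustive NJ oracle machinery -----------------------------------
# Unrooted trees as edge lists: leaves 1..n, internal nodes negative ids.

new_tree3 <- function() {
  list(edges = rbind(c(-1, 1), c(-1, 2), c(-1, 3)), next_int = -2L)
}

insert_leaf <- function(tr, leaf, edge_row) {
  u <- tr$edges[edge_row, 1]; v <- tr$edges[edge_row, 2]
  w <- tr$next_int
  edges <- rbind(tr$edges[-edge_row, , drop = FALSE],
                 c(u, w), c(w, v), c(w, leaf))
  list(edges = edges, next_int = w - 1L)
}

# All unrooted binary topologies on n leaves (3 -> 1, 4 -> 3, 5 -> 15 ...).
all_topologies <- function(n) {
  trees <- list(new_tree3())
  for (leaf in seq(4, length.out = max(0, n - 3))) {
    trees <- unlist(lapply(trees, function(tr) {
      lapply(seq_len(nrow(tr$edges)), function(e) insert_leaf(tr, leaf, e))
    }), recursive = FALSE)
  }
  trees
}

random_topology <- function(n) {
  tr <- new_tree3()
  for (leaf in seq(4, length.out = max(0, n - 3))) {
    tr <- insert_leaf(tr, leaf, sample(nrow(tr$edges), 1))
  }
  tr
}

# Leaf-pair x edge incidence (is edge e on the path i~j?), via adjacency walk.
edge_paths <- function(edges, n) {
  nodes <- unique(as.vector(edges))
  adj <- lapply(setNames(nodes, nodes), function(x) integer(0))
  for (e in seq_len(nrow(edges))) {
    u <- as.character(edges[e, 1]); v <- as.character(edges[e, 2])
    adj[[u]] <- c(adj[[u]], e); adj[[v]] <- c(adj[[v]], e)
  }
  other_end <- function(e, x) {
    if (edges[e, 1] == x) edges[e, 2] else edges[e, 1]
  }
  path_from <- function(start) {
    # DFS recording the edge path from `start` to every node
    paths <- list(); paths[[as.character(start)]] <- integer(0)
    stack <- start
    while (length(stack)) {
      x <- stack[[1]]; stack <- stack[-1]
      for (e in adj[[as.character(x)]]) {
        y <- other_end(e, x)
        if (is.null(paths[[as.character(y)]])) {
          paths[[as.character(y)]] <- c(paths[[as.character(x)]], e)
          stack <- c(stack, y)
        }
      }
    }
    paths
  }
  pairs <- t(utils::combn(n, 2))
  X <- matrix(0, nrow(pairs), nrow(edges))
  for (r in seq_len(nrow(pairs))) {
    p <- path_from(pairs[r, 1])[[as.character(pairs[r, 2])]]
    X[r, p] <- 1
  }
  list(pairs = pairs, X = X)
}

# Path-distance matrix of an edge-list tree with given branch lengths.
tree_distances <- function(tr, lengths, n) {
  ep <- edge_paths(tr$edges, n)
  d <- matrix(0, n, n)
  dv <- as.vector(ep$X %*% lengths)
  for (r in seq_len(nrow(ep$pairs))) {
    d[ep$pairs[r, 1], ep$pairs[r, 2]] <- dv[r]
    d[ep$pairs[r, 2], ep$pairs[r, 1]] <- dv[r]
  }
  d
}

# Least-squares fit of branch lengths for a fixed topology; returns RSS.
ls_fit_topology <- function(tr, D, n) {
  ep <- edge_paths(tr$edges, n)
  y <- D[ep$pairs]
  fit <- stats::lm.fit(ep$X, y)
  sum(fit$residuals^2)
}

# Exhaustive search: topology with minimal least-squares residual.
exhaustive_best_topology <- function(D) {
  n <- nrow(D)
  stopifnot(n <= 6)
  trees <- all_topologies(n)
  rss <- vapply(trees, ls_fit_topology, numeric(1), D = D, n = n)
  trees[[which.min(rss)]]
}

# Canonical split set of an edge-list tree (bipartitions from internal
# edges; each split keyed by the side not containing leaf 1).
splits_of_tree <- function(tr, n) {
  comp_leaves <- function(edges, start) {
    seen <- start; stack <- start
    while (length(stack)) {
      x <- stack[[1]]; stack <- stack[-1]
      nb <- c(edges[edges[, 1] == x, 2], edges[edges[, 2] == x, 1])
      new <- setdiff(nb, seen)
      seen <- c(seen, new); stack <- c(stack, new)
    }
    sort(seen[seen > 0])
  }
  out <- character(0)
  for (e in seq_len(nrow(tr$edges))) {
    u <- tr$edges[e, 1]; v <- tr$edges[e, 2]
    if (u > 0 || v > 0) next        # trivial split
    rest <- tr$edges[-e, , drop = FALSE]
    side <- comp_leaves(rest, v)
    if (1 %in% side) side <- setdiff(seq_len(n), side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      out <- c(out, paste(side, collapse = ","))
    }
  }
  sort(unique(out))
}

# Split set of an ape phylo whose tips are labelled "1".."n".
# Descendant tip sets are accumulated from the edge matrix directly.
splits_of_phylo <- function(tree) {
  n <- length(tree$tip.label)
  tips_below <- function(node) {
    if (node <= n) return(as.integer(tree$tip.label[node]))
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  out <- character(0)
  for (node in seq(n + 1, n + tree$Nnode)) {
    side <- sort(tips_below(node))
    if (1 %in% side) side <- setdiff(seq_len(n), side)
    if (length(side) >= 2 && length(side) <= n - 2) {
      out <- c(out, paste(side, collapse = ","))
    }
  }
  sort(unique(out))
}

# Path-length matrix of a phylo with tips "1".."n", via its edge list
# (independent of ape).
phylo_distances <- function(tree) {
  n <- length(tree$tip.label)
  edges <- cbind(-(tree$edge[, 1] - n), ifelse(tree$edge[, 2] > n,
                                               -(tree$edge[, 2] - n),
                                               as.integer(tree$tip.label[tree$edge[, 2]])))
  tr <- list(edges = edges)
  tree_distances(tr, tree$edge.length, n)
}
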