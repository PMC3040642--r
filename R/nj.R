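#' Neighbour-joining tree from a distance matrix
#'
#' Saitou–Nei neighbour joining on a complete distance matrix, returning
#' an unrooted binary tree as an ape-compatible `phylo` object. The
#' implementation is deterministic across platforms: ties in the
#' Q criterion are broken by the lexicographically smallest label pair,
#' and negative branch lengths are clamped to zero with the deficit
#' transferred to the sister branch so leaf-to-leaf path lengths are
#' preserved. On an additive matrix the tree reproduces every input
#' distance exactly (up to floating point).
#'
#' @param m A `k2p_dist` object or a symmetric numeric matrix with
#'   dimnames; at least 3 labels, no missing entries (subset the library
#'   to a complete block first — missing distances are not imputed).
#' @return A `phylo` object (tips labelled by specimen id).
#' @examples
#' d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' tr <- build_nj(d)
#' @export
build_nj <- function(m) {
  d <- if (inherits(m, "k2p_dist")) m$d else as.matrix(m)
  n <- nrow(d)
  if (n < 3) abort("Neighbour joining needs at least 3 labels")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("t", seq_len(n))
  }
  if (any(is.na(d))) {
    abort(paste0("Distance matrix has missing entries; subset to a ",
                 "complete submatrix before building a tree"))
  }
  if (max(abs(d - t(d))) > 1e-12) abort("Distance matrix must be symmetric")

  labels <- rownames(d)
  # active nodes: phylo ids; tips 1..n, internal ids assigned in join order
  act <- seq_len(n)
  key <- labels                     # lexicographic sort key per active node
  next_id <- n + 1L
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  D <- d

  while (length(act) > 3) {
    r <- length(act)
    rs <- rowSums(D)
    Q <- (r - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    # deterministic tie-break: smallest (sorted) label-pair key
    keys <- apply(cand, 1, function(ij) {
      k <- sort(c(key[ij[1]], key[ij[2]]))
      paste(k, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]

    dij <- D[i, j]
    bi <- 0.5 * dij + (rs[i] - rs[j]) / (2 * (r - 2))
    bj <- dij - bi
    # clamp negatives, moving the deficit to the sister branch
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)

    u <- next_id; next_id <- next_id + 1L
    parent <- c(parent, u, u)
    child <- c(child, act[i], act[j])
    elen <- c(elen, bi, bj)

    newd <- pmax(0.5 * (D[i, ] + D[j, ] - dij), 0)
    keep <- setdiff(seq_len(r), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newd[keep]),
               c(newd[keep], 0))
    act <- c(act[keep], u)
    key <- c(key[keep], min(key[c(i, j)]))
  }

  # final three nodes join at one internal vertex (the unrooted trifurcation)
  v <- next_id
  b1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  parent <- c(parent, v, v, v)
  child <- c(child, act[1], act[2], act[3])
  elen <- c(elen, b1, b2, b3)

  canonical_phylo(parent, child, elen, labels, root = v, n_tips = n)
}

# Renumber internal nodes in preorder from the root join so the edge
# matrix satisfies ape's cladewise conventions (root = n_tips + 1).
canonical_phylo <- function(parent, child, elen, labels, root, n_tips) {
  kids <- split(seq_along(parent), parent)
  new_id <- integer(max(c(parent, child)))
  new_id[seq_len(n_tips)] <- seq_len(n_tips)
  counter <- n_tips
  edge <- matrix(0L, nrow = length(parent), ncol = 2)
  edge_len <- numeric(length(parent))
  k <- 0L
  visit <- function(node) {
    counter <<- counter + 1L
    new_id[node] <<- counter
    for (e in kids[[as.character(node)]]) {
      ch <- child[e]
      k <<- k + 1L
      row <- k
      if (ch > n_tips) {
        edge[row, 1] <<- new_id[node]
        visit(ch)
        edge[row, 2] <<- new_id[ch]
      } else {
        edge[row, 1] <<- new_id[node]
        edge[row, 2] <<- ch
      }
      edge_len[row] <<- elen[e]
    }
  }
  visit(root)
  tr <- list(edge = edge, edge.length = edge_len,
             tip.label = labels, Nnode = counter - n_tips)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  tr
}

#' Serialize a tree to Newick
#'
#' Writes a `phylo` tree as a Newick string with branch lengths at a
#' fixed precision. Labels containing whitespace are underscore-escaped
#' per Newick convention.
#'
#' @param tree A `phylo` object.
#' @param precision Significant digits for branch lengths (default 10).
#' @return A single Newick string, terminated by `";"`.
#' @export
to_newick <- function(tree, precision = 10) {
  stopifnot(inherits(tree, "phylo"))
  n_tips <- length(tree$tip.label)
  root <- n_tips + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  lab <- gsub("\\s+", "_", tree$tip.label)
  fmt <- function(x) sprintf("%.*g", precision, x)
  rec <- function(node) {
    if (node <= n_tips) return(lab[node])
    parts <- vapply(kids[[as.character(node)]], function(e) {
      paste0(rec(tree$edge[e, 2]), ":", fmt(tree$edge.length[e]))
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  paste0(rec(root), ";")
}

#' Write a tree (or trees) to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path (conventionally `.nwk`).
#' @param precision Significant digits for branch lengths.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path, precision = 10) {
  writeLines(to_newick(tree, precision), path)
  invisible(path)
}
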