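#' Count comparable sites, transitions and transversions for one pair
#'
#' Compares two equal-length aligned sequences position by position under
#' pairwise deletion: a site contributes only when both sequences carry an
#' unambiguous A/C/G/T there. Differing sites are split into transitions
#' (A<->G, C<->T) and transversions (all other base pairs). Partial IUPAC
#' ambiguity codes (R, Y, ...) are skipped like N and gaps rather than
#' probabilistically resolved.
#'
#' @param a,b Character scalars: aligned sequences of equal length.
#' @return A one-row tibble with `n_valid`, `n_transitions`,
#'   `n_transversions`.
#' @examples
#' count_site_pairs("ACGT", "GCGT")  # one A<->G transition over 4 sites
#' @export
count_site_pairs <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b)) {
    abort("Sequences must have equal aligned length")
  }
  enc <- encode_sequences(c(a, b))
  cc <- .pair_counts_all(enc)
  tibble::tibble(n_valid = cc$valid[1, 2],
                 n_transitions = cc$transitions[1, 2],
                 n_transversions = cc$transversions[1, 2])
}

# Integer-encode sequences for the compiled counter: A=1 C=2 G=3 T=4,
# everything else (gaps, N, partial ambiguities) 0.
encode_sequences <- function(seqs) {
  L <- unique(nchar(seqs))
  stopifnot(length(L) == 1)
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  enc <- match(chars, c("A", "C", "G", "T"), nomatch = 0L)
  dim(enc) <- dim(chars)
  storage.mode(enc) <- "integer"
  enc
}

#' Kimura 2-parameter distance from site-pair counts
#'
#' Computes `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` where
#' `P = n_transitions / n_valid` and `Q = n_transversions / n_valid`.
#' Returns `NA` (a missing, not infinite, distance) when the pair has
#' fewer than `min_overlap` comparable sites, or when either logarithm
#' argument is non-positive (saturation). Vectorised over the counts.
#'
#' @param n_valid,n_transitions,n_transversions Integer vectors of site
#'   counts, as produced by [count_site_pairs()].
#' @param min_overlap Minimum number of comparable sites for a defined
#'   distance (default 0 here; [k2p_pairwise()] defaults to 300).
#' @return Numeric vector of distances as proportions (`NA` = missing).
#' @examples
#' k2p_distance(658, 1, 0) * 100  # one transition in 658 bp -> ~0.152%
#' @export
k2p_distance <- function(n_valid, n_transitions, n_transversions,
                         min_overlap = 0) {
  if (is.data.frame(n_valid)) {
    cc <- n_valid
    n_transversions <- cc$n_transversions
    n_transitions <- cc$n_transitions
    n_valid <- cc$n_valid
  }
  stopifnot(all(n_transitions + n_transversions <= n_valid, na.rm = TRUE))
  P <- n_transitions / n_valid
  Q <- n_transversions / n_valid
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  ok <- n_valid >= pmax(min_overlap, 1L) & a1 > 0 & a2 > 0
  ok[is.na(ok)] <- FALSE
  d <- rep(NA_real_, length(P))
  d[ok] <- -0.5 * log(a1[ok]) - 0.25 * log(a2[ok])
  # exact-zero guard: identical overlapping sites give exactly 0
  d[ok & n_transitions == 0 & n_transversions == 0] <- 0
  d
}

#' Pairwise K2P distance matrix for a barcode library
#'
#' Applies [count_site_pairs()] and [k2p_distance()] to every unordered
#' pair of records and assembles a symmetric distance matrix together
#' with per-pair comparable-site counts. Pairs whose overlap falls below
#' `min_overlap` and saturated pairs (log argument <= 0) are recorded as
#' missing and never enter downstream minimum/maximum statistics.
#'
#' @param lib A `barcode_library` tibble (at least 2 records).
#' @param min_overlap Minimum comparable sites per pair (default 300);
#'   below it a distance is treated as missing rather than unreliable —
#'   this protects sharing detection from short-overlap artefacts.
#' @return An object of class `k2p_dist`: a list with `d` (distance
#'   matrix, proportions), `overlap`, `transitions`, `transversions`
#'   (integer matrices), `labels`, `species`, `genus`, `region`,
#'   `min_overlap`, and counts of short-overlap and saturated pairs.
#' @seealso [tidy.k2p_dist()] for the long pair table; `as.matrix()` and
#'   `as.dist()` methods are provided.
#' @export
k2p_pairwise <- function(lib, min_overlap = 300) {
  stopifnot(inherits(lib, "barcode_library"))
  if (nrow(lib) < 2) {
    abort("Need at least 2 records to compute pairwise distances")
  }
  enc <- encode_sequences(lib$sequence)
  cc <- .pair_counts_all(enc)
  d <- matrix(k2p_distance(as.vector(cc$valid),
                           as.vector(cc$transitions),
                           as.vector(cc$transversions),
                           min_overlap = min_overlap),
              nrow = nrow(lib))
  diag(d) <- 0
  up <- upper.tri(d)
  n_short <- sum(cc$valid[up] < min_overlap)
  n_saturated <- sum(is.na(d[up]) & cc$valid[up] >= min_overlap)
  if (all(is.na(d[up]))) {
    abort("All pairwise distances are missing (overlap/saturation)")
  }
  dimnames(d) <- list(lib$specimen_id, lib$specimen_id)
  structure(
    list(d = d,
         overlap = cc$valid,
         transitions = cc$transitions,
         transversions = cc$transversions,
         labels = lib$specimen_id,
         species = setNames(lib$species, lib$specimen_id),
         genus = setNames(lib$genus, lib$specimen_id),
         region = setNames(lib$region, lib$specimen_id),
         min_overlap = min_overlap,
         n_short_overlap = n_short,
         n_saturated = n_saturated),
    class = "k2p_dist"
  )
}

#' @export
print.k2p_dist <- function(x, ...) {
  n <- length(x$labels)
  cat("K2P distance matrix: ", n, " specimens, ",
      length(unique(x$species)), " species\n",
      "missing pairs: ", x$n_short_overlap, " short-overlap (<",
      x$min_overlap, " sites), ", x$n_saturated, " saturated\n", sep = "")
  invisible(x)
}

#' @export
as.matrix.k2p_dist <- function(x, ...) x$d

#' @export
as.dist.k2p_dist <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' Long pair table of a K2P distance matrix
#'
#' @param x A `k2p_dist` object.
#' @param ... Unused.
#' @return A tibble with one row per unordered specimen pair: ids,
#'   species, genera, the distance (`NA` if missing), the comparable-site
#'   overlap, and convenience logicals `conspecific` and `congeneric`.
#' @export
tidy.k2p_dist <- function(x, ...) {
  n <- length(x$labels)
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  tibble::tibble(
    id1 = x$labels[i],
    id2 = x$labels[j],
    species1 = unname(x$species[i]),
    species2 = unname(x$species[j]),
    genus1 = unname(x$genus[i]),
    genus2 = unname(x$genus[j]),
    distance = x$d[idx],
    overlap = x$overlap[idx],
    conspecific = .data$species1 == .data$species2,
    congeneric = .data$genus1 == .data$genus2
  )
}

#' Export a distance matrix as square TSV or PHYLIP
#'
#' @param m A `k2p_dist` object.
#' @param path Output path.
#' @param format `"tsv"` (square, labelled, header row) or `"phylip"`
#'   (square PHYLIP distance format; labels truncated/padded to 10
#'   characters as the format requires).
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path, format = c("tsv", "phylip")) {
  format <- match.arg(format)
  d <- m$d
  if (format == "tsv") {
    df <- tibble::as_tibble(d)
    df <- tibble::add_column(df, specimen_id = m$labels, .before = 1)
    readr::write_tsv(df, path, na = "NA")
  } else {
    lab <- formatC(substr(m$labels, 1, 10), width = -10)
    lines <- c(sprintf("%5d", nrow(d)),
               vapply(seq_len(nrow(d)), function(i) {
                 paste0(lab[i], paste(sprintf("%.6f", d[i, ]),
                                      collapse = " "))
               }, character(1)))
    writeLines(lines, path)
  }
  invisible(path)
}
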