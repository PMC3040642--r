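# Build a barcode_library by writing a FASTA to a tempfile and reading it
# back, so fixtures exercise the reader itself.
lib_from <- function(seqs, species, ids = NULL, region = NULL,
                     alignment_length = max(nchar(seqs))) {
  ids <- ids %||% sprintf("s%02d", seq_along(seqs))
  headers <- if (is.null(region)) {
    paste(ids, species, sep = "|")
  } else {
    paste(ids, species, region, sep = "|")
  }
  fa <- withr::local_tempfile(fileext = ".fasta",
                              .local_envir = parent.frame())
  writeLines(rbind(paste0(">", headers), seqs), fa)
  read_barcode_fasta(fa, alignment_length = alignment_length)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Construct a k2p_dist object directly from a distance matrix, for
# distance-level audit tests where exact pairwise values matter.
dist_obj <- function(d, species, ids = NULL, overlap = 658L) {
  n <- nrow(d)
  ids <- ids %||% sprintf("s%02d", seq_len(n))
  dimnames(d) <- list(ids, ids)
  ov <- matrix(as.integer(overlap), n, n)
  structure(
    list(d = d, overlap = ov,
         transitions = matrix(0L, n, n), transversions = matrix(0L, n, n),
         labels = ids,
         species = stats::setNames(species, ids),
         genus = stats::setNames(sub(" .*", "", species), ids),
         region = stats::setNames(rep(NA_character_, n), ids),
         min_overlap = 1L, n_short_overlap = 0L, n_saturated = 0L),
    class = "k2p_dist"
  )
}

# Symmetrise helper for hand-written matrices given as upper triangles.
sym <- function(n, entries) {
  d <- matrix(0, n, n)
  d[upper.tri(d)] <- entries
  d[lower.tri(d)] <- t(d)[lower.tri(d)]
  d
}

# Cluster jackknife SE of a mean over pairwise values: leave out one
# cluster at a time (clusters indexed by both pair endpoints).
jackknife_se <- function(vals, cl1, cl2 = cl1) {
  cls <- unique(c(cl1, cl2))
  G <- length(cls)
  m <- vapply(cls, function(g) mean(vals[cl1 != g & cl2 != g]), numeric(1))
  sqrt((G - 1) / G * sum((m - mean(m))^2))
}
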