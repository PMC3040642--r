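IUPAC_CHARS <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Read a barcode library from FASTA
#'
#' Reads COI barcode sequences whose FASTA headers carry structured
#' specimen metadata, and returns a tidy barcode library: one row per
#' specimen with columns `specimen_id`, `species`, `genus`, `region`,
#' `sequence` and `length`. Sequences are upper-cased and right-padded
#' with `'-'` (or trimmed, with a warning) to a common alignment length,
#' so that every sequence spans the same positions. `length` counts
#' non-gap characters; ambiguity codes (including `N`) count toward the
#' length and are excluded pair-by-pair at distance time.
#'
#' @param path Path to a FASTA file. Wrapped or single-line sequences are
#'   both accepted.
#' @param delim Single character separating header fields (default `"|"`).
#' @param fields Character vector naming the header fields in order. Must
#'   contain `"specimen_id"` and `"species"`; `"region"` is optional and
#'   missing trailing fields are tolerated.
#' @param alignment_length Common nominal alignment length in positions
#'   (default 658, the full-length COI-5' amplicon).
#'
#' @return A tibble of class `barcode_library` with attribute
#'   `alignment_length`.
#'
#' @details Headers must parse into at least the `specimen_id` and
#'   `species` fields; the species name must be a binomial (at least two
#'   whitespace-separated tokens). Malformed headers, duplicated specimen
#'   ids, sequence characters outside the IUPAC nucleotide alphabet
#'   (plus `-`), and empty files are hard errors naming the offending
#'   entry.
#'
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1|Thera variata|BY", "ACGTACGT",
#'              ">s2|Thera britannica|BY", "ACGAACGT"), fa)
#' lib <- read_barcode_fasta(fa, alignment_length = 8)
#' lib
#' @export
read_barcode_fasta <- function(path, delim = "|",
                               fields = c("specimen_id", "species", "region"),
                               alignment_length = 658) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  stopifnot(is.character(fields), all(c("specimen_id", "species") %in% fields))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) {
    abort(paste0("FASTA file contains no sequences: ", path))
  }
  headers <- names(seqs)
  parts <- strsplit(headers, delim, fixed = TRUE)

  meta <- purrr::imap(parts, function(p, i) {
    p <- trimws(p)
    if (length(p) < 2 || any(p[1:2] == "")) {
      abort(paste0("Malformed FASTA header (need at least specimen_id",
                   delim, "species): '", headers[[i]], "'"))
    }
    vals <- setNames(rep(NA_character_, length(fields)), fields)
    k <- min(length(p), length(fields))
    vals[seq_len(k)] <- p[seq_len(k)]
    if (is.na(vals[["species"]]) ||
        length(strsplit(vals[["species"]], "\\s+")[[1]]) < 2) {
      abort(paste0("Species name is not a binomial in header: '",
                   headers[[i]], "'"))
    }
    vals
  })
  specimen_id <- vapply(meta, `[[`, character(1), "specimen_id")
  species <- vapply(meta, `[[`, character(1), "species")
  region <- if ("region" %in% fields) {
    vapply(meta, `[[`, character(1), "region")
  } else {
    rep(NA_character_, length(meta))
  }
  dup <- specimen_id[duplicated(specimen_id)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate specimen_id in library: ",
                 paste(unique(dup), collapse = ", ")))
  }

  sequence <- toupper(as.character(seqs))
  bad <- !grepl(paste0("^[", paste(IUPAC_CHARS, collapse = ""), "]*$"),
                sequence)
  if (any(bad)) {
    abort(paste0("Sequence contains non-IUPAC characters in entry '",
                 headers[which(bad)[1]], "'"))
  }

  new_barcode_library(
    tibble::tibble(specimen_id = unname(specimen_id),
                   species = unname(species),
                   genus = genus_of(species),
                   region = unname(region),
                   sequence = unname(sequence)),
    alignment_length = alignment_length
  )
}

# Normalise sequences to alignment_length positions, recompute non-gap
# lengths, and stamp the class/attribute. Used by the reader and the
# simulator so both produce identical containers.
new_barcode_library <- function(df, alignment_length) {
  stopifnot(alignment_length >= 1)
  nch <- nchar(df$sequence)
  if (any(nch > alignment_length)) {
    warn(paste0(sum(nch > alignment_length), " sequence(s) longer than ",
                alignment_length, " positions were trimmed"))
    df$sequence <- substr(df$sequence, 1L, alignment_length)
    nch <- nchar(df$sequence)
  }
  pad <- alignment_length - nch
  if (any(pad > 0)) {
    df$sequence <- paste0(df$sequence,
                          strrep("-", pad))
  }
  df$length <- nchar(gsub("-", "", df$sequence, fixed = TRUE))
  if (any(df$length == 0)) {
    abort("Library contains an all-gap (zero-length) sequence")
  }
  df <- tibble::as_tibble(df)[, c("specimen_id", "species", "genus",
                                  "region", "sequence", "length")]
  attr(df, "alignment_length") <- alignment_length
  class(df) <- c("barcode_library", class(df))
  df
}

#' Alignment length of a barcode library
#' @param lib A `barcode_library` tibble.
#' @return Integer number of alignment positions every sequence spans.
#' @export
alignment_length <- function(lib) {
  attr(lib, "alignment_length")
}

#' Filter a barcode library by sequence length
#'
#' Retains records whose non-gap length is at least `min_len`, preserving
#' record order. This implements the usual barcode length classes: e.g.
#' `min_len = 500` keeps the analyzable records, `min_len = 658` the
#' full-length amplicons (a tolerance class of >= 640 is a common
#' compromise that avoids off-by-trim artifacts).
#'
#' @param lib A `barcode_library` tibble.
#' @param min_len Minimum number of non-gap characters (>= 1).
#' @return A new `barcode_library` with the retained records.
#' @export
filter_by_length <- function(lib, min_len) {
  stopifnot(inherits(lib, "barcode_library"), min_len >= 1)
  keep <- lib$length >= min_len
  if (!any(keep)) {
    abort(paste0("No records of length >= ", min_len,
                 "; nothing left to analyze"))
  }
  out <- lib[keep, ]
  attr(out, "alignment_length") <- alignment_length(lib)
  class(out) <- class(lib)
  out
}

#' Write a barcode library to FASTA
#'
#' Headers are re-assembled as `specimen_id|species|region` (the region
#' field is dropped when absent); sequences are wrapped at 80 columns and
#' keep their `'-'` padding, so `read_barcode_fasta()` round-trips the
#' library exactly.
#'
#' @param lib A `barcode_library` tibble.
#' @param path Output file path.
#' @param delim Header field separator (default `"|"`).
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(lib, path, delim = "|") {
  stopifnot(inherits(lib, "barcode_library"))
  headers <- ifelse(is.na(lib$region),
                    paste(lib$specimen_id, lib$species, sep = delim),
                    paste(lib$specimen_id, lib$species, lib$region,
                          sep = delim))
  x <- Biostrings::BStringSet(lib$sequence)
  names(x) <- headers
  tryCatch(
    Biostrings::writeXStringSet(x, filepath = path, width = 80L),
    error = function(e) abort(paste0("Cannot write FASTA to '", path, "': ",
                                     conditionMessage(e)))
  )
  invisible(path)
}

#' Write a report table as TSV
#'
#' Thin wrapper that writes a tibble as UTF-8 TSV with an explicit header
#' row; an empty tibble yields a header-only file.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(x, path) {
  tryCatch(readr::write_tsv(x, path, na = ""),
           error = function(e) abort(paste0("Cannot write TSV to '", path,
                                            "': ", conditionMessage(e))))
  invisible(path)
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("A barcode library: ", nrow(x), " specimens, ",
      length(unique(x$species)), " species, alignment length ",
      alignment_length(x), "\n", sep = "")
  NextMethod()
}
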