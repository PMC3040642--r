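#' Audit a barcode library
#'
#' Runs the complete barcode-gap audit on a library: pairwise K2P
#' distances, per-species maximum intraspecific distance (MPD) and
#' nearest neighbour, global divergence summaries, barcode-sharing and
#' deep-split detection, the low-divergence species-pair table, the
#' species resolution rate, and the NN/MPD histograms in 0.5% classes.
#'
#' @param lib A `barcode_library` tibble (see [read_barcode_fasta()] or
#'   [simulate_library()]).
#' @param min_overlap Minimum comparable sites per pair (default 300).
#' @param deep_split_threshold Deep-split screen as a proportion
#'   (default 0.02 = 2%); species are flagged strictly above it.
#' @param low_divergence_window Length-2 numeric, the half-open
#'   `(lower, upper]` window (proportions) for the low-divergence pair
#'   table; default `c(0.01, 0.04)`.
#' @return An object of class `barcode_audit`, a list with elements
#'   `species` (per-species audit table with flags), `global_stats`,
#'   `sharing`, `low_divergence`, `deep_splits`, `resolution`,
#'   `nn_hist`, `mpd_hist`, `dist` (the `k2p_dist`), and `params`.
#'   Use [tidy()] for the species table, [glance()] for a one-row
#'   summary, and [autoplot()] for the barcode-gap histograms.
#'
#' @details Flags per species: `SINGLETON` (one specimen; excluded from
#'   MPD and intraspecific means but kept in NN analysis), `SHARING`
#'   (nearest neighbour at distance exactly 0), `DEEP_SPLIT`
#'   (MPD strictly above the threshold), `LOW_DIVERGENCE` (nearest
#'   neighbour within the window). The `intraspecific_excl_deep` stratum
#'   of `global_stats` removes all specimens of `DEEP_SPLIT` species,
#'   reproducing the usual with/without-deep-splits contrast in mean
#'   intraspecific variation.
#' @export
audit_library <- function(lib, min_overlap = 300,
                          deep_split_threshold = 0.02,
                          low_divergence_window = c(0.01, 0.04)) {
  stopifnot(inherits(lib, "barcode_library"),
            length(low_divergence_window) == 2)
  m <- k2p_pairwise(lib, min_overlap = min_overlap)
  audit_distances(m, deep_split_threshold = deep_split_threshold,
                  low_divergence_window = low_divergence_window)
}

#' Audit a precomputed K2P distance matrix
#'
#' Same as [audit_library()] but starting from a `k2p_dist` object.
#'
#' @inheritParams audit_library
#' @param m A `k2p_dist` object.
#' @return A `barcode_audit` object; see [audit_library()].
#' @export
audit_distances <- function(m, deep_split_threshold = 0.02,
                            low_divergence_window = c(0.01, 0.04)) {
  stopifnot(inherits(m, "k2p_dist"))
  pt <- tidy(m)
  deep <- detect_deep_splits(m, threshold = deep_split_threshold,
                             .pairs = pt)
  nn <- suppressWarnings(nearest_neighbours(m, .pairs = pt))
  sharing <- detect_sharing(m, .pairs = pt)
  lowdiv <- low_divergence_pairs(m, lower = low_divergence_window[1],
                                 upper = low_divergence_window[2],
                                 .pairs = pt)
  deep_species <- deep$species[deep$deep_split]
  gstats <- divergence_summary(m, exclude_species = deep_species,
                               .pairs = pt)
  res <- resolution_rate(m, .pairs = pt)

  counts <- table(m$species)
  species <- tibble::tibble(species = sort(unique(m$species)),
                            n_specimens = as.integer(counts[species])) |>
    dplyr::left_join(dplyr::select(deep, "species", "mpd", "n_subclusters",
                                   "support"),
                     by = "species") |>
    dplyr::left_join(nn, by = "species") |>
    dplyr::mutate(
      singleton = .data$n_specimens == 1,
      sharing = !is.na(.data$nn_distance) & .data$nn_distance == 0,
      deep_split = !is.na(.data$mpd) &
        .data$mpd > deep_split_threshold,
      low_divergence = !is.na(.data$nn_distance) &
        .data$nn_distance > low_divergence_window[1] &
        .data$nn_distance <= low_divergence_window[2],
      flags = purrr::pmap_chr(
        list(.data$singleton, .data$sharing, .data$deep_split,
             .data$low_divergence),
        function(si, sh, ds, ld) {
          paste(c("SINGLETON"[si], "SHARING"[sh], "DEEP_SPLIT"[ds],
                  "LOW_DIVERGENCE"[ld]), collapse = ";")
        })
    )

  structure(
    list(species = species,
         global_stats = gstats,
         sharing = sharing,
         low_divergence = lowdiv,
         deep_splits = deep,
         resolution = res,
         nn_hist = distance_histogram(nn$nn_distance),
         mpd_hist = distance_histogram(deep$mpd),
         dist = m,
         params = list(min_overlap = m$min_overlap,
                       deep_split_threshold = deep_split_threshold,
                       low_divergence_window = low_divergence_window)),
    class = "barcode_audit"
  )
}

#' @export
print.barcode_audit <- function(x, ...) {
  g <- x$global_stats
  pct <- function(s) {
    r <- g[g$stratum == s, ]
    if (r$n == 0) return("--")
    paste0(format_percent(r$mean, 2), "% (n=", r$n, ")")
  }
  cat("Barcode library audit\n",
      "  specimens: ", length(x$dist$labels),
      ", species: ", nrow(x$species), "\n",
      "  mean interspecific:            ", pct("interspecific_all"), "\n",
      "  mean congeneric interspecific: ", pct("interspecific_congeneric"),
      "\n",
      "  mean intraspecific:            ", pct("intraspecific_all"), "\n",
      "  ... excluding deep splits:     ", pct("intraspecific_excl_deep"),
      "\n",
      "  sharing species pairs: ", nrow(x$sharing),
      ", deep splits: ", sum(x$species$deep_split, na.rm = TRUE),
      ", low-divergence pairs: ", nrow(x$low_divergence), "\n",
      "  resolution rate: ",
      format_percent(x$resolution$fraction, 1), "%\n", sep = "")
  invisible(x)
}

#' Tidy a barcode audit
#'
#' @param x A `barcode_audit` object.
#' @param ... Unused.
#' @return The per-species audit tibble: specimen counts, MPD, nearest
#'   neighbour, subcluster count and flags.
#' @export
tidy.barcode_audit <- function(x, ...) {
  x$species
}

#' One-row summary of a barcode audit
#'
#' @param x A `barcode_audit` object.
#' @param ... Unused.
#' @return A one-row tibble with specimen/species counts, the four
#'   stratum means (as proportions), anomaly counts and the resolution
#'   rate.
#' @export
glance.barcode_audit <- function(x, ...) {
  g <- function(s) x$global_stats$mean[x$global_stats$stratum == s]
  tibble::tibble(
    n_specimens = length(x$dist$labels),
    n_species = nrow(x$species),
    mean_interspecific = g("interspecific_all"),
    mean_congeneric = g("interspecific_congeneric"),
    mean_intraspecific = g("intraspecific_all"),
    mean_intraspecific_excl_deep = g("intraspecific_excl_deep"),
    n_sharing_pairs = nrow(x$sharing),
    n_deep_splits = sum(x$species$deep_split, na.rm = TRUE),
    n_low_divergence_pairs = nrow(x$low_divergence),
    resolution_rate = x$resolution$fraction,
    n_missing_pairs = x$dist$n_short_overlap + x$dist$n_saturated
  )
}
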