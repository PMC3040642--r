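#' Maximum intraspecific pairwise distance (MPD) per species
#'
#' For every species with at least two specimens, the maximum defined
#' K2P distance among its conspecific specimen pairs — the standard
#' summary of intraspecific variation in barcode-gap analysis. Singletons
#' are omitted (they carry no intraspecific comparison); species whose
#' conspecific pairs are all missing are omitted with a warning.
#'
#' @param m A `k2p_dist` object.
#' @param .pairs Optional precomputed `tidy(m)` pair table, to avoid
#'   rebuilding it across audit steps (internal reuse).
#' @return A tibble with `species`, `n_specimens`, `mpd` (proportion) and
#'   `n_pairs` (defined conspecific comparisons), sorted by species.
#' @export
max_intraspecific <- function(m, .pairs = NULL) {
  pt <- .pairs %||% tidy(m)
  counts <- table(m$species)
  intra <- dplyr::filter(pt, .data$conspecific)
  res <- intra |>
    dplyr::group_by(species = .data$species1) |>
    dplyr::summarise(mpd = if (all(is.na(.data$distance))) NA_real_
                     else max(.data$distance, na.rm = TRUE),
                     n_pairs = sum(!is.na(.data$distance)),
                     .groups = "drop") |>
    dplyr::mutate(n_specimens = as.integer(counts[.data$species]),
                  .after = "species")
  dropped <- res$species[is.na(res$mpd)]
  if (length(dropped) > 0) {
    warn(paste0("All conspecific pairs missing for: ",
                paste(dropped, collapse = ", "), "; omitted from MPD"))
    res <- dplyr::filter(res, !is.na(.data$mpd))
  }
  dplyr::arrange(res, .data$species)
}

#' Nearest-neighbour species and distance
#'
#' For every species, the minimum defined K2P distance over all
#' heterospecific specimen pairs and the species attaining it (ties in
#' distance broken by the lexicographically smallest neighbour name).
#' This is the "nearest neighbour" axis of the barcode gap. Species with
#' no defined heterospecific pair are omitted with a warning.
#'
#' @param m A `k2p_dist` object (at least 2 species).
#' @inheritParams max_intraspecific
#' @return A tibble with `species`, `nn_species`, `nn_distance`
#'   (proportion).
#' @export
nearest_neighbours <- function(m, .pairs = NULL) {
  if (length(unique(m$species)) < 2) {
    abort("Nearest-neighbour analysis needs at least 2 species")
  }
  pt <- .pairs %||% tidy(m)
  inter <- dplyr::filter(pt, !.data$conspecific, !is.na(.data$distance))
  both <- dplyr::bind_rows(
    dplyr::select(inter, species = "species1", nn_species = "species2",
                  nn_distance = "distance"),
    dplyr::select(inter, species = "species2", nn_species = "species1",
                  nn_distance = "distance")
  )
  res <- both |>
    dplyr::group_by(.data$species) |>
    dplyr::arrange(.data$nn_distance, .data$nn_species, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$species)
  missing <- setdiff(unique(m$species), res$species)
  if (length(missing) > 0) {
    warn(paste0("No defined heterospecific pair for: ",
                paste(missing, collapse = ", "), "; omitted from NN table"))
  }
  res
}

#' Global divergence summary by stratum
#'
#' Mean, standard error and number of comparisons for four strata of
#' defined pairwise distances: all interspecific pairs, congeneric
#' interspecific pairs, all intraspecific pairs, and intraspecific pairs
#' after removing every specimen of `exclude_species` (conventionally the
#' deep-split species, whose inclusion inflates apparent intraspecific
#' variation). The SE is the descriptive sample SD divided by sqrt(n)
#' over pairwise comparisons; comparisons are not independent, so it
#' understates uncertainty and is reported for comparability only.
#'
#' @param m A `k2p_dist` object.
#' @param exclude_species Character vector of species removed (specimens
#'   and all) from the fourth stratum.
#' @return A tibble with `stratum`, `mean`, `se`, `n`, `se_defined`.
#'   An empty stratum has `mean = NA`, `n = 0`; a single-comparison
#'   stratum reports `se = 0` with `se_defined = FALSE`.
#' @inheritParams max_intraspecific
#' @export
divergence_summary <- function(m, exclude_species = character(),
                               .pairs = NULL) {
  pt <- dplyr::filter(.pairs %||% tidy(m), !is.na(.data$distance))
  strata <- list(
    interspecific_all = pt$distance[!pt$conspecific],
    interspecific_congeneric =
      pt$distance[!pt$conspecific & pt$congeneric],
    intraspecific_all = pt$distance[pt$conspecific],
    intraspecific_excl_deep =
      pt$distance[pt$conspecific & !(pt$species1 %in% exclude_species)]
  )
  purrr::imap(strata, function(x, nm) {
    n <- length(x)
    tibble::tibble(
      stratum = nm,
      mean = if (n > 0) mean(x) else NA_real_,
      se = if (n >= 2) stats::sd(x) / sqrt(n) else if (n == 1) 0 else NA_real_,
      n = n,
      se_defined = n >= 2
    )
  }) |> purrr::list_rbind()
}

#' Detect barcode sharing between species
#'
#' Finds every heterospecific specimen pair at a defined distance of
#' exactly zero — identical barcodes assigned to different species — and
#' aggregates them by species pair. Reporting the specimen-level evidence
#' lets regular, repeated sharing be distinguished from a one-off
#' identical pair.
#'
#' @param m A `k2p_dist` object.
#' @return A tibble with `species1 < species2`, `n_specimen_pairs`, and a
#'   list-column `specimen_pairs` of two-column specimen-id tibbles.
#'   Zero rows when no sharing exists.
#' @inheritParams max_intraspecific
#' @export
detect_sharing <- function(m, .pairs = NULL) {
  pt <- .pairs %||% tidy(m)
  hits <- dplyr::filter(pt, !.data$conspecific, !is.na(.data$distance),
                        .data$distance == 0)
  if (nrow(hits) == 0) {
    return(tibble::tibble(species1 = character(), species2 = character(),
                          n_specimen_pairs = integer(),
                          specimen_pairs = list()))
  }
  hits <- hits |>
    dplyr::mutate(
      sp_a = pmin(.data$species1, .data$species2),
      sp_b = pmax(.data$species1, .data$species2),
      id_a = ifelse(.data$species1 == .data$sp_a, .data$id1, .data$id2),
      id_b = ifelse(.data$species1 == .data$sp_a, .data$id2, .data$id1)
    )
  hits |>
    dplyr::group_by(species1 = .data$sp_a, species2 = .data$sp_b) |>
    dplyr::summarise(
      n_specimen_pairs = dplyr::n(),
      specimen_pairs = list(tibble::tibble(id1 = id_a, id2 = id_b)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$species1, .data$species2)
}

# Minimum defined distance per unordered species pair.
species_pair_minima <- function(m, .pairs = NULL) {
  pt <- dplyr::filter(.pairs %||% tidy(m), !.data$conspecific,
                      !is.na(.data$distance))
  pt |>
    dplyr::mutate(sp_a = pmin(.data$species1, .data$species2),
                  sp_b = pmax(.data$species1, .data$species2)) |>
    dplyr::group_by(species1 = .data$sp_a, species2 = .data$sp_b) |>
    dplyr::summarise(min_distance = min(.data$distance), .groups = "drop")
}

#' Species pairs in a low-divergence window
#'
#' Lists the species pairs whose minimum interspecific distance lies in
#' the half-open window `(lower, upper]` — the screen behind the classic
#' "1.0 to 4.0%" low-divergence table. Pairs are unordered and
#' deduplicated, sorted ascending by distance, and the distance is also
#' rendered as a percentage at one decimal (half-up).
#'
#' @param m A `k2p_dist` object.
#' @param lower,upper Window bounds as proportions,
#'   `0 <= lower < upper`; defaults 0.01 and 0.04.
#' @return A tibble with `species1`, `species2`, `min_distance`
#'   (proportion) and `min_pd_percent` (character, 1 decimal).
#' @inheritParams max_intraspecific
#' @export
low_divergence_pairs <- function(m, lower = 0.01, upper = 0.04,
                                 .pairs = NULL) {
  stopifnot(lower >= 0, lower < upper)
  species_pair_minima(m, .pairs = .pairs) |>
    dplyr::filter(.data$min_distance > lower,
                  .data$min_distance <= upper) |>
    dplyr::arrange(.data$min_distance, .data$species1, .data$species2) |>
    dplyr::mutate(min_pd_percent = format_percent(.data$min_distance, 1))
}

# Single-linkage connected components among one species' specimens:
# specimens joined whenever their defined distance is <= threshold.
single_linkage_components <- function(ids, d, threshold) {
  n <- length(ids)
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (!is.na(d[i, j]) && d[i, j] <= threshold && comp[i] != comp[j]) {
        comp[comp == comp[j]] <- comp[i]
      }
    }
  }
  split(ids, match(comp, unique(comp)))
}

#' Detect deep intraspecific splits
#'
#' Flags species whose maximum intraspecific distance strictly exceeds
#' `threshold` (default 2%), the standard screen for possible cryptic
#' diversity, and partitions each species' specimens into haplotype
#' subclusters: connected components of single linkage at the threshold.
#' A flagged species is classified by whether every subcluster holds
#' multiple individuals (`"multiple_individuals"`) or at least one
#' subcluster is a lone specimen (`"single_outlier"`).
#'
#' @param m A `k2p_dist` object.
#' @param threshold Proportion, > 0 (default 0.02). A species at exactly
#'   the threshold is not flagged.
#' @return A tibble over species with >= 2 specimens: `species`, `mpd`,
#'   `deep_split` (logical), `n_subclusters`, `min_subcluster_size`,
#'   `support` (classification above, `NA` when not flagged) and
#'   list-column `subclusters` (specimen-id character vectors; regions
#'   can be joined back from the library for geographic reading).
#' @inheritParams max_intraspecific
#' @export
detect_deep_splits <- function(m, threshold = 0.02, .pairs = NULL) {
  stopifnot(threshold > 0)
  mpd <- max_intraspecific(m, .pairs = .pairs)
  subcl <- purrr::map(mpd$species, function(sp) {
    ids <- m$labels[m$species == sp]
    single_linkage_components(ids, m$d[ids, ids, drop = FALSE], threshold)
  })
  mpd |>
    dplyr::mutate(
      deep_split = .data$mpd > threshold,
      n_subclusters = purrr::map_int(subcl, length),
      min_subcluster_size =
        purrr::map_int(subcl, ~ min(lengths(.x))),
      support = dplyr::case_when(
        !deep_split ~ NA_character_,
        min_subcluster_size >= 2 ~ "multiple_individuals",
        TRUE ~ "single_outlier"
      ),
      subclusters = subcl
    )
}

#' Species-level resolution rate of a barcode library
#'
#' A species is diagnosable when its minimum interspecific distance is
#' strictly positive, i.e. no conspecific specimen shares an identical
#' barcode with any heterospecific specimen. The rate is the fraction of
#' species (among those with a computable nearest neighbour) that are
#' diagnosable.
#'
#' @param m A `k2p_dist` object (>= 2 species).
#' @return A one-row tibble: `n_species`, `n_diagnosable`, `fraction`.
#' @inheritParams max_intraspecific
#' @export
resolution_rate <- function(m, .pairs = NULL) {
  nn <- suppressWarnings(nearest_neighbours(m, .pairs = .pairs))
  tibble::tibble(
    n_species = nrow(nn),
    n_diagnosable = sum(nn$nn_distance > 0),
    fraction = n_diagnosable / n_species
  )
}

#' Histogram of distances in fixed percent classes
#'
#' Bins distances into `[k*w, (k+1)*w)` classes (default width 0.5%),
#' the conventional rendering of nearest-neighbour and MPD
#' distributions. Bin counts sum to the number of values.
#'
#' @param values Numeric distances as proportions (finite, >= 0).
#' @param bin_width Bin width as a proportion (default 0.005 = 0.5%).
#' @return A tibble with `bin_lower_pct`, `bin_upper_pct`, `count`;
#'   zero rows for empty input. Empty interior bins are included.
#' @export
distance_histogram <- function(values, bin_width = 0.005) {
  stopifnot(bin_width > 0)
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    return(tibble::tibble(bin_lower_pct = numeric(),
                          bin_upper_pct = numeric(),
                          count = integer()))
  }
  stopifnot(all(is.finite(values)), all(values >= 0))
  k <- floor(values / bin_width)
  counts <- table(factor(k, levels = 0:max(k)))
  tibble::tibble(
    bin_lower_pct = as.numeric(names(counts)) * bin_width * 100,
    bin_upper_pct = (as.numeric(names(counts)) + 1) * bin_width * 100,
    count = as.integer(counts)
  )
}
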