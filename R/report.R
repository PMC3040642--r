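#' Write the audit report bundle
#'
#' Emits the audit as plain-text artifacts in `dir`: per-species table,
#' low-divergence pair table, sharing pairs, deep splits, global
#' statistics (JSON), the NN and MPD histograms (0.5% classes), and a
#' `manifest.json` referencing every emitted file together with the run
#' parameters. Output is deterministic — stable sort orders and fixed
#' rounding — so re-rendering the same audit is byte-identical.
#'
#' Distances in the TSVs are rendered as percentages at one decimal
#' (half-up); global statistics keep two decimals.
#'
#' @param audit A `barcode_audit` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
write_audit_report <- function(audit, dir) {
  stopifnot(inherits(audit, "barcode_audit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  species <- audit$species |>
    dplyr::mutate(mpd_percent = format_percent(.data$mpd, 1),
                  nn_percent = format_percent(.data$nn_distance, 1)) |>
    dplyr::select("species", "n_specimens", "mpd_percent", "nn_species",
                  "nn_percent", "n_subclusters", "flags")
  write_report_tsv(species, p("species_audit.tsv"))

  write_report_tsv(
    dplyr::select(audit$low_divergence, "species1", "species2",
                  "min_pd_percent"),
    p("low_divergence_pairs.tsv"))

  sharing <- audit$sharing |>
    dplyr::mutate(specimen_pairs = purrr::map_chr(
      .data$specimen_pairs,
      ~ paste(.x$id1, .x$id2, sep = "~", collapse = ";"))) |>
    dplyr::select("species1", "species2", "n_specimen_pairs",
                  "specimen_pairs")
  write_report_tsv(sharing, p("sharing_pairs.tsv"))

  deep <- audit$deep_splits |>
    dplyr::filter(.data$deep_split) |>
    dplyr::mutate(mpd_percent = format_percent(.data$mpd, 1),
                  subclusters = purrr::map_chr(
                    .data$subclusters,
                    ~ paste(purrr::map_chr(.x, paste, collapse = ","),
                            collapse = " | "))) |>
    dplyr::select("species", "n_specimens", "mpd_percent",
                  "n_subclusters", "support", "subclusters")
  write_report_tsv(deep, p("deep_splits.tsv"))

  gstats <- purrr::pmap(audit$global_stats,
                        function(stratum, mean, se, n, se_defined) {
    list(mean_percent = if (is.na(mean)) NA else
           as.numeric(format_percent(mean, 2)),
         se_percent = if (is.na(se)) NA else
           as.numeric(format_percent(se, 2)),
         n = n, se_defined = se_defined)
  })
  names(gstats) <- audit$global_stats$stratum
  gstats$resolution_rate_percent <-
    as.numeric(format_percent(audit$resolution$fraction, 2))
  jsonlite::write_json(gstats, p("global_stats.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, na = "null")

  write_report_tsv(audit$nn_hist, p("nn_hist.tsv"))
  write_report_tsv(audit$mpd_hist, p("mpd_hist.tsv"))

  manifest <- list(
    files = c("species_audit.tsv", "low_divergence_pairs.tsv",
              "sharing_pairs.tsv", "deep_splits.tsv", "global_stats.json",
              "nn_hist.tsv", "mpd_hist.tsv"),
    parameters = audit$params,
    counts = list(
      n_specimens = length(audit$dist$labels),
      n_species = nrow(audit$species),
      n_short_overlap_pairs = audit$dist$n_short_overlap,
      n_saturated_pairs = audit$dist$n_saturated
    ),
    package_version = as.character(utils::packageVersion("barcodeaudit"))
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
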