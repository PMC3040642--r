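#' Configuration for a synthetic barcode library
#'
#' Bundles and validates the parameters of [simulate_library()]. The
#' defaults emulate a well-curated temperate-moth COI library: deep
#' interspecific divergence (~13% K2P across genera, ~10% within
#' genera), very low intraspecific variation (~0.2%), and a small number
#' of injected anomalies — exact barcode sharing between species pairs
#' and deep intraspecific splits (~4.4% between conspecific haplotype
#' clusters).
#'
#' @param n_species Number of species (>= 2).
#' @param specimens_per_species Specimens per species; a single integer
#'   or a length-2 range sampled uniformly per species.
#' @param seq_length Alignment length in bp (default 658, >= 100).
#' @param kappa Transition/transversion rate ratio (default 4, typical
#'   for insect mitochondrial COI).
#' @param target_interspecific_d Expected cross-genus K2P distance
#'   (default 0.13).
#' @param target_congeneric_d Expected within-genus, between-species
#'   distance (default 0.10); must not exceed the interspecific target.
#' @param species_per_genus Species per genus (default 3).
#' @param target_intraspecific_d Expected conspecific distance
#'   (default 0.002).
#' @param n_sharing_pairs Species pairs in which one specimen of the
#'   recipient receives the donor's exact haplotype (default 0).
#' @param n_deep_splits Species split into two haplotype clusters
#'   (default 0).
#' @param deep_split_d Separation between deep-split cluster centroids
#'   (default 0.044).
#' @param low_divergence_d Optional numeric vector; each value plants one
#'   congeneric species pair whose centroids sit at that distance
#'   (e.g. `c(0.014, 0.027)`).
#' @param n_short_records Records truncated to `short_length` non-gap
#'   positions (default 0), for exercising length filters.
#' @param short_length Length of truncated records (default 450).
#' @param seed Integer seed; the whole library is reproducible from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_species = 50,
                       specimens_per_species = 3,
                       seq_length = 658,
                       kappa = 4,
                       target_interspecific_d = 0.13,
                       target_congeneric_d = 0.10,
                       species_per_genus = 3,
                       target_intraspecific_d = 0.002,
                       n_sharing_pairs = 0,
                       n_deep_splits = 0,
                       deep_split_d = 0.044,
                       low_divergence_d = numeric(),
                       n_short_records = 0,
                       short_length = 450,
                       seed = 1) {
  cfg <- list(n_species = as.integer(n_species),
              specimens_per_species = as.integer(specimens_per_species),
              seq_length = as.integer(seq_length),
              kappa = kappa,
              target_interspecific_d = target_interspecific_d,
              target_congeneric_d = target_congeneric_d,
              species_per_genus = as.integer(species_per_genus),
              target_intraspecific_d = target_intraspecific_d,
              n_sharing_pairs = as.integer(n_sharing_pairs),
              n_deep_splits = as.integer(n_deep_splits),
              deep_split_d = deep_split_d,
              low_divergence_d = low_divergence_d,
              n_short_records = as.integer(n_short_records),
              short_length = as.integer(short_length),
              seed = as.integer(seed))
  props <- c(cfg$target_interspecific_d, cfg$target_congeneric_d,
             cfg$target_intraspecific_d, cfg$deep_split_d,
             cfg$low_divergence_d)
  if (any(props <= 0 | props >= 0.75)) {
    abort("All distance targets must lie in (0, 0.75)")
  }
  if (cfg$target_congeneric_d > cfg$target_interspecific_d) {
    abort("target_congeneric_d must not exceed target_interspecific_d")
  }
  if (cfg$n_species < 2) abort("n_species must be >= 2")
  if (cfg$seq_length < 100) abort("seq_length must be >= 100")
  if (!length(cfg$specimens_per_species) %in% c(1, 2) ||
      any(cfg$specimens_per_species < 1)) {
    abort("specimens_per_species must be a positive integer or range")
  }
  if (cfg$kappa <= 0) abort("kappa must be positive")
  if (cfg$n_sharing_pairs < 0 || cfg$n_deep_splits < 0) {
    abort("Anomaly counts must be non-negative")
  }
  if (cfg$n_sharing_pairs > cfg$n_species %/% 2) {
    abort("n_sharing_pairs exceeds the number of disjoint species pairs")
  }
  if (cfg$n_deep_splits + 2 * cfg$n_sharing_pairs +
        2 * length(cfg$low_divergence_d) > cfg$n_species) {
    abort("More planted anomalies than species to carry them")
  }
  structure(cfg, class = "sim_config")
}

# K2P per-site substitution probabilities after total distance d with
# ts/tv ratio kappa: with alpha*t = kappa*d/(kappa+2), beta*t = d/(kappa+2),
#   P(t) = 1/4 + 1/4 exp(-4 beta t) - 1/2 exp(-2 (alpha+beta) t)
#   Q(t) = 1/2 - 1/2 exp(-4 beta t)
# so the expected estimated K2P distance of the mutated copy is exactly d.
k2p_site_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  P <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  Q <- 0.5 - 0.5 * exp(-4 * bt)
  c(P = P, Q = Q)
}

#' Evolve a sequence to a target K2P distance
#'
#' Mutates each unambiguous A/C/G/T site independently with the
#' closed-form K2P substitution probabilities for total distance `d` and
#' transition/transversion ratio `kappa`: a site becomes its transition
#' partner with probability `P(d)` and each transversion partner with
#' probability `Q(d)/2`. Gap and ambiguity characters are carried over
#' unchanged. Uses the current RNG state; wrap in [withr::with_seed()]
#' (as [simulate_library()] does) for reproducibility.
#'
#' @param seq Character scalar sequence.
#' @param d Target K2P distance (proportion, `0 <= d < 0.75`).
#' @param kappa Transition/transversion rate ratio (> 0).
#' @return The mutated sequence (same length).
#' @export
evolve_sequence <- function(seq, d, kappa = 4) {
  stopifnot(length(seq) == 1, is.character(seq), kappa > 0)
  if (d < 0 || d >= 0.75) {
    abort("Target distance d must lie in [0, 0.75)")
  }
  if (d == 0) return(seq)
  pq <- k2p_site_probs(d, kappa)
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", C = "T", G = "A", T = "C")
  transv1 <- c(A = "C", C = "A", G = "C", T = "A")
  transv2 <- c(A = "T", C = "G", G = "T", T = "G")
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  ok <- ch %in% bases
  n <- sum(ok)
  fate <- sample.int(4L, n, replace = TRUE,
                     prob = c(1 - pq["P"] - pq["Q"], pq["P"],
                              pq["Q"] / 2, pq["Q"] / 2))
  cur <- ch[ok]
  cur[fate == 2L] <- transition[cur[fate == 2L]]
  cur[fate == 3L] <- transv1[cur[fate == 3L]]
  cur[fate == 4L] <- transv2[cur[fate == 4L]]
  ch[ok] <- cur
  paste(ch, collapse = "")
}

random_sequence <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

#' Simulate a barcode library with known ground truth
#'
#' Generates a library of `n_species` species arranged in genera on a
#' star-shaped phylogeny: genus ancestors radiate from a root at depth
#' `(interspecific - congeneric)/2`, species centroids from their genus
#' ancestor at depth `congeneric/2`, and specimens from their species
#' centroid at depth `intraspecific/2` — so expected pairwise K2P
#' distances hit the three targets. Anomalies are then injected:
#'
#' * deep splits — the species receives a second centroid at
#'   `deep_split_d` from the first, with roughly half its specimens (at
#'   least one) drawn from it; the two clusters are tagged with distinct
#'   region labels, emulating geographically structured lineages;
#' * barcode sharing — one specimen of the recipient species is replaced
#'   by an exact copy of a donor specimen's haplotype (distance 0);
#' * low-divergence pairs — a congeneric pair's second centroid is
#'   regenerated at the requested small distance from the first;
#' * short records — the chosen records are truncated to `short_length`
#'   positions (gap-padded), for exercising length filters.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `library` (a `barcode_library` tibble) and
#'   `truth`, itself a list of tibbles: `species` (genus, centroid,
#'   per-species targets, deep-split status), `sharing` (donor,
#'   recipient and the specimen ids involved), `deep_splits` (species
#'   and cluster sizes), `low_divergence` (planted pair and target),
#'   `short_records` (specimen ids truncated), plus the `config`.
#' @export
simulate_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_library_impl(cfg))
}

simulate_library_impl <- function(cfg) {
  S <- cfg$n_species
  spg <- cfg$species_per_genus
  n_genera <- ceiling(S / spg)
  genus_names <- sprintf("Genus%03d", seq_len(n_genera))
  genus_idx <- rep(seq_len(n_genera), each = spg)[seq_len(S)]
  species_names <- unlist(lapply(seq_len(n_genera), function(g) {
    k <- sum(genus_idx == g)
    sprintf("%s species%02d", genus_names[g], seq_len(k))
  }))

  root <- random_sequence(cfg$seq_length)
  genus_depth <- (cfg$target_interspecific_d - cfg$target_congeneric_d) / 2
  genus_anc <- vapply(seq_len(n_genera), function(g) {
    evolve_sequence(root, genus_depth, cfg$kappa)
  }, character(1))
  # depths are chosen so expected *specimen-level* distances hit the
  # targets: conspecific = intra, congeneric = 2*(cong-intra)/2 + intra
  # = cong, cross-genus = (inter-cong) + cong = inter (K2P distances are
  # additive along a lineage path).
  centroid_depth <- max(0, (cfg$target_congeneric_d -
                              cfg$target_intraspecific_d) / 2)
  centroid <- vapply(seq_len(S), function(s) {
    evolve_sequence(genus_anc[genus_idx[s]], centroid_depth, cfg$kappa)
  }, character(1))

  k_rng <- cfg$specimens_per_species
  n_spec <- if (length(k_rng) == 1) rep(k_rng, S) else
    sample(seq(k_rng[1], k_rng[2]), S, replace = TRUE)

  # choose disjoint species sets for the planted anomalies
  multi <- which(n_spec >= 2)
  if (cfg$n_deep_splits > length(multi)) {
    abort("Not enough multi-specimen species to carry the deep splits")
  }
  deep_sp <- sort(sample(multi, cfg$n_deep_splits))
  pool <- setdiff(seq_len(S), deep_sp)
  sharing <- NULL
  if (cfg$n_sharing_pairs > 0) {
    recip_pool <- intersect(pool, multi)
    if (2 * cfg$n_sharing_pairs > length(pool) ||
        cfg$n_sharing_pairs > length(recip_pool)) {
      abort("Not enough species left to carry the sharing pairs")
    }
    recipient <- sample(recip_pool, cfg$n_sharing_pairs)
    donor <- sample(setdiff(pool, recipient), cfg$n_sharing_pairs)
    sharing <- tibble::tibble(donor = donor, recipient = recipient)
    pool <- setdiff(pool, c(donor, recipient))
  }
  lowdiv <- NULL
  if (length(cfg$low_divergence_d) > 0) {
    # congeneric pairs: re-derive species B's centroid from species A's
    genera_pool <- split(pool, genus_idx[pool])
    genera_pool <- genera_pool[lengths(genera_pool) >= 2]
    if (length(genera_pool) < length(cfg$low_divergence_d)) {
      abort("Not enough free congeneric pairs for low_divergence_d")
    }
    picked <- sample(length(genera_pool))[seq_along(cfg$low_divergence_d)]
    lowdiv <- purrr::imap(cfg$low_divergence_d, function(dd, k) {
      pair <- sort(genera_pool[[picked[k]]])[1:2]
      centroid[pair[2]] <<- evolve_sequence(centroid[pair[1]], dd,
                                            cfg$kappa)
      tibble::tibble(species1 = species_names[pair[1]],
                     species2 = species_names[pair[2]],
                     target_d = dd)
    }) |> purrr::list_rbind()
    pool <- setdiff(pool, NA)
  }

  # second centroids and cluster assignment for the deep splits
  centroid2 <- rep(NA_character_, S)
  cluster2_n <- integer(S)
  for (s in deep_sp) {
    centroid2[s] <- evolve_sequence(centroid[s], cfg$deep_split_d,
                                    cfg$kappa)
    cluster2_n[s] <- max(1L, n_spec[s] %/% 2L)
  }

  regions <- c("AlpsEast", "AlpsWest", "NorthHills", "Danube")
  tip_depth <- cfg$target_intraspecific_d / 2
  rows <- vector("list", S)
  counter <- 0L
  for (s in seq_len(S)) {
    ids <- sprintf("SIM%05d", counter + seq_len(n_spec[s]))
    counter <- counter + n_spec[s]
    from2 <- seq_len(n_spec[s]) > (n_spec[s] - cluster2_n[s])
    seqs <- vapply(seq_len(n_spec[s]), function(k) {
      base <- if (from2[k]) centroid2[s] else centroid[s]
      evolve_sequence(base, tip_depth, cfg$kappa)
    }, character(1))
    reg <- if (s %in% deep_sp) {
      ifelse(from2, regions[2], regions[1])
    } else {
      sample(regions, n_spec[s], replace = TRUE)
    }
    rows[[s]] <- tibble::tibble(specimen_id = ids,
                                species = species_names[s],
                                genus = genus_names[genus_idx[s]],
                                region = reg,
                                sequence = seqs,
                                cluster = ifelse(from2, 2L, 1L))
  }
  lib <- purrr::list_rbind(rows)

  sharing_truth <- tibble::tibble(donor = character(),
                                  recipient = character(),
                                  donor_specimen = character(),
                                  recipient_specimen = character())
  if (!is.null(sharing)) {
    sharing_truth <- purrr::pmap(sharing, function(donor, recipient) {
      don_ids <- lib$specimen_id[lib$species == species_names[donor]]
      rec_ids <- lib$specimen_id[lib$species == species_names[recipient]]
      lib$sequence[lib$specimen_id == rec_ids[1]] <<-
        lib$sequence[lib$specimen_id == don_ids[1]]
      tibble::tibble(donor = species_names[donor],
                     recipient = species_names[recipient],
                     donor_specimen = don_ids[1],
                     recipient_specimen = rec_ids[1])
    }) |> purrr::list_rbind()
  }

  short_truth <- tibble::tibble(specimen_id = character())
  if (cfg$n_short_records > 0) {
    if (cfg$n_short_records > nrow(lib)) {
      abort("n_short_records exceeds the number of specimens")
    }
    if (cfg$short_length >= cfg$seq_length) {
      abort("short_length must be below seq_length")
    }
    sel <- sort(sample(nrow(lib), cfg$n_short_records))
    lib$sequence[sel] <- substr(lib$sequence[sel], 1L, cfg$short_length)
    short_truth <- tibble::tibble(specimen_id = lib$specimen_id[sel])
  }

  truth <- list(
    species = tibble::tibble(
      species = species_names,
      genus = genus_names[genus_idx],
      n_specimens = n_spec,
      centroid = centroid,
      target_intraspecific_d = cfg$target_intraspecific_d,
      deep_split = seq_len(S) %in% deep_sp,
      deep_split_d = ifelse(seq_len(S) %in% deep_sp, cfg$deep_split_d,
                            NA_real_)
    ),
    sharing = sharing_truth,
    deep_splits = tibble::tibble(
      species = species_names[deep_sp],
      n_cluster1 = n_spec[deep_sp] - cluster2_n[deep_sp],
      n_cluster2 = cluster2_n[deep_sp]
    ),
    low_divergence = lowdiv %||%
      tibble::tibble(species1 = character(), species2 = character(),
                     target_d = numeric()),
    short_records = short_truth,
    config = cfg
  )

  library <- new_barcode_library(
    dplyr::select(lib, -"cluster"),
    alignment_length = cfg$seq_length
  )
  list(library = library, truth = truth)
}
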