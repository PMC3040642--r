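test_that("MPD takes the maximum conspecific distance and omits singletons", {
  # species X: three specimens at {0.001, 0.002, 0.045}; Y: two identical;
  # Z: singleton; all cross-species distances 0.12
  d <- matrix(0.12, 6, 6)
  diag(d) <- 0
  d[1, 2] <- d[2, 1] <- 0.001
  d[1, 3] <- d[3, 1] <- 0.002
  d[2, 3] <- d[3, 2] <- 0.045
  d[4, 5] <- d[5, 4] <- 0
  sp <- c("Xestia ashworthii", "Xestia ashworthii", "Xestia ashworthii",
          "Yezognophos vittaria", "Yezognophos vittaria",
          "Zamacra flabellaria")
  m <- dist_obj(d, sp)
  mpd <- max_intraspecific(m)
  expect_equal(mpd$species,
               c("Xestia ashworthii", "Yezognophos vittaria"))
  expect_equal(mpd$mpd, c(0.045, 0))
  expect_equal(mpd$n_specimens, c(3L, 2L))

  # all conspecific pairs missing -> omitted with a warning
  d2 <- d
  d2[1, 2] <- d2[2, 1] <- NA
  d2[1, 3] <- d2[3, 1] <- NA
  d2[2, 3] <- d2[3, 2] <- NA
  expect_warning(mpd2 <- max_intraspecific(dist_obj(d2, sp)),
                 "Xestia ashworthii")
  expect_equal(mpd2$species, "Yezognophos vittaria")
})

test_that("nearest neighbours select the minimal heterospecific pair with lexicographic ties", {
  # two species: symmetric NN at the closest specimen pair
  d <- sym(4, c(0.001, 0.011, 0.013, 0.012, 0.014, 0.002))
  sp <- c("Thera variata", "Thera variata",
          "Thera britannica", "Thera britannica")
  nn <- nearest_neighbours(dist_obj(d, sp))
  expect_equal(nn$nn_distance, c(0.011, 0.011))
  expect_equal(nn$nn_species, c("Thera variata", "Thera britannica"))

  # three species with min distances AB=0.02 AC=0.05 BC=0.03
  d3 <- sym(3, c(0.02, 0.05, 0.03))
  sp3 <- c("Aa aa", "Bb bb", "Cc cc")
  nn3 <- nearest_neighbours(dist_obj(d3, sp3))
  expect_equal(nn3$nn_species, c("Bb bb", "Aa aa", "Bb bb"))
  expect_equal(nn3$nn_distance, c(0.02, 0.02, 0.03))

  # exact tie broken towards the lexicographically smaller species
  d4 <- sym(3, c(0.02, 0.02, 0.05))
  nn4 <- nearest_neighbours(dist_obj(d4, c("Mm mm", "Bb bb", "Cc cc")))
  expect_equal(nn4$nn_species[nn4$species == "Mm mm"], "Bb bb")
})

test_that("nearest neighbours and MPD agree with a brute-force double loop", {
  sim <- simulate_library(sim_config(n_species = 16,
                                     specimens_per_species = 3,
                                     n_deep_splits = 2, seed = 13))
  m <- k2p_pairwise(sim$library)
  sp <- unname(m$species)

  nn <- nearest_neighbours(m)
  ref_nn <- oracle_nn(m$d, sp)
  expect_equal(nrow(nn), length(ref_nn))
  for (s in nn$species) {
    expect_equal(nn$nn_distance[nn$species == s], ref_nn[[s]]$dist)
    expect_equal(nn$nn_species[nn$species == s], ref_nn[[s]]$nn)
  }

  mpd <- max_intraspecific(m)
  ref_mpd <- oracle_mpd(m$d, sp)
  expect_equal(nrow(mpd), length(ref_mpd))
  for (s in mpd$species) {
    expect_equal(mpd$mpd[mpd$species == s], ref_mpd[[s]])
  }
})

test_that("divergence strata partition the defined comparisons", {
  # 2 species x 1 specimen at 0.10: single interspecific comparison
  m1 <- dist_obj(sym(2, 0.10), c("Aa aa", "Bb bb"))
  g1 <- divergence_summary(m1)
  r <- g1[g1$stratum == "interspecific_all", ]
  expect_equal(r$mean, 0.10)
  expect_equal(r$n, 1L)
  expect_equal(r$se, 0)
  expect_false(r$se_defined)
  expect_equal(g1$n[g1$stratum == "intraspecific_all"], 0L)
  expect_true(is.na(g1$mean[g1$stratum == "intraspecific_all"]))

  # intraspecific stratum {0, 0, 0.03}: mean 0.01; exclusion removes the
  # deep-split species entirely
  d <- sym(5, c(0, 0.12, 0.12, 0.11,
                0.12, 0.12, 0.11,
                0.03, 0.13,
                0.13))
  sp <- c("Aa aa", "Aa aa", "Bb bb", "Bb bb", "Cc cc")
  d[3, 4] <- d[4, 3] <- 0.03
  m2 <- dist_obj(d, sp)
  g2 <- divergence_summary(m2, exclude_species = "Bb bb")
  expect_equal(g2$mean[g2$stratum == "intraspecific_all"],
               mean(c(0, 0.03)))
  expect_equal(g2$mean[g2$stratum == "intraspecific_excl_deep"], 0)
  expect_equal(g2$n[g2$stratum == "intraspecific_excl_deep"], 1L)

  # partition property on a simulated library
  sim <- simulate_library(sim_config(n_species = 12, seed = 2))
  m <- k2p_pairwise(sim$library)
  g <- divergence_summary(m)
  n_def <- sum(!is.na(tidy(m)$distance))
  expect_equal(g$n[g$stratum == "interspecific_all"] +
                 g$n[g$stratum == "intraspecific_all"], n_def)
})

test_that("barcode sharing is detected exactly at zero distance with specimen evidence", {
  d <- sym(4, c(0.002, 0, 0.11, 0.11, 0.002, 0.10))
  d[2, 3] <- d[3, 2] <- 0      # one identical cross-species haplotype
  d[1, 3] <- d[3, 1] <- 0.11
  sp <- c("Chlorissa viridata", "Chlorissa viridata",
          "Chlorissa cloraria", "Chlorissa cloraria")
  sh <- detect_sharing(dist_obj(d, sp))
  expect_equal(nrow(sh), 1)
  expect_equal(sh$species1, "Chlorissa cloraria")
  expect_equal(sh$species2, "Chlorissa viridata")
  expect_equal(sh$n_specimen_pairs, 1L)
  expect_equal(sh$specimen_pairs[[1]]$id1, "s03")
  expect_equal(sh$specimen_pairs[[1]]$id2, "s02")

  # negative control: no zero heterospecific distance
  sh0 <- detect_sharing(dist_obj(sym(2, 0.05), c("Aa aa", "Bb bb")))
  expect_equal(nrow(sh0), 0)

  # zero distance from a missing pair is not sharing
  dna <- sym(2, NA_real_)
  expect_equal(nrow(detect_sharing(dist_obj(dna, c("Aa aa", "Bb bb")))), 0)
})

test_that("the low-divergence window is half-open, deduplicated and sorted", {
  d <- sym(4, c(0.011, 0.04, 0.095, 0.041, 0.10, 0.009))
  sp <- c("Thera variata", "Thera britannica",
          "Entephria flavata", "Perizoma affinitata")
  m <- dist_obj(d, sp)
  tab <- low_divergence_pairs(m, lower = 0.01, upper = 0.04)
  # 0.009 (below), 0.011 (in), 0.040 (boundary, in), 0.041 (out)
  expect_equal(tab$min_distance, c(0.011, 0.04))
  expect_equal(tab$min_pd_percent, c("1.1", "4.0"))
  expect_true(!is.unsorted(tab$min_distance))
  # the pair below `lower` is excluded (strict >)
  expect_false(any(tab$min_distance <= 0.01))
  expect_error(low_divergence_pairs(m, lower = 0.04, upper = 0.01))
})

test_that("deep splits use a strict threshold and single-linkage subclusters", {
  # MPD exactly at the threshold is not flagged
  d <- sym(2, 0.02)
  m <- dist_obj(d, rep("Aa aa", 2))
  ds <- detect_deep_splits(m, threshold = 0.02)
  expect_false(ds$deep_split)

  # clusters {a,b} and {c}: cross 0.05, within 0.001 -> single outlier
  d2 <- sym(3, c(0.001, 0.05, 0.05))
  ds2 <- detect_deep_splits(dist_obj(d2, rep("Aa aa", 3)), 0.02)
  expect_true(ds2$deep_split)
  expect_equal(ds2$n_subclusters, 2L)
  expect_equal(ds2$support, "single_outlier")
  expect_equal(sort(unname(lengths(ds2$subclusters[[1]]))), c(1L, 2L))

  # both clusters with multiple individuals
  d3 <- sym(4, c(0.001, 0.05, 0.05, 0.05, 0.05, 0.001))
  ds3 <- detect_deep_splits(dist_obj(d3, rep("Aa aa", 4)), 0.02)
  expect_equal(ds3$support, "multiple_individuals")
  expect_equal(ds3$n_subclusters, 2L)

  # chaining: a-b 0.015, b-c 0.015, a-c 0.03 is ONE single-linkage cluster
  d4 <- sym(3, c(0.015, 0.03, 0.015))
  ds4 <- detect_deep_splits(dist_obj(d4, rep("Aa aa", 3)), 0.02)
  expect_true(ds4$deep_split)      # mpd 0.03 > 0.02
  expect_equal(ds4$n_subclusters, 1L)

  # flag set is monotone non-increasing in the threshold
  sim <- simulate_library(sim_config(n_species = 20, n_deep_splits = 4,
                                     seed = 17))
  m5 <- k2p_pairwise(sim$library)
  flagged <- lapply(c(0.01, 0.02, 0.03, 0.05),
                    function(th) {
                      dd <- detect_deep_splits(m5, th)
                      dd$species[dd$deep_split]
                    })
  for (k in 1:3) expect_true(all(flagged[[k + 1]] %in% flagged[[k]]))
})

test_that("resolution rate counts species with positive minimum interspecific distance", {
  m <- dist_obj(sym(2, 0.05), c("Aa aa", "Bb bb"))
  expect_equal(resolution_rate(m)$fraction, 1)

  # one sharing pair among three species: only the third is diagnosable
  d <- sym(3, c(0, 0.1, 0.1))
  r <- resolution_rate(dist_obj(d, c("Aa aa", "Bb bb", "Cc cc")))
  expect_equal(r$n_diagnosable, 1L)
  expect_equal(r$fraction, 1 / 3)
})

test_that("distance histograms conserve counts in half-percent classes", {
  h <- distance_histogram(c(0.001, 0.003, 0.006))
  expect_equal(h$count, c(2L, 1L))
  expect_equal(h$bin_lower_pct, c(0, 0.5))
  expect_equal(h$bin_upper_pct, c(0.5, 1.0))

  expect_equal(nrow(distance_histogram(numeric())), 0)

  set.seed(3)
  x <- runif(137, 0, 0.2)
  h2 <- distance_histogram(x)
  expect_equal(sum(h2$count), 137L)
  # left-closed binning: a value exactly on a boundary goes right
  h3 <- distance_histogram(c(0.005))
  expect_equal(h3$count[h3$bin_lower_pct == 0.5], 1L)
})

test_that("removing a specimen cannot raise MPD or lower NN distance", {
  sim <- simulate_library(sim_config(n_species = 10,
                                     specimens_per_species = 3,
                                     n_deep_splits = 1, seed = 23))
  lib <- sim$library
  m <- k2p_pairwise(lib)
  mpd0 <- max_intraspecific(m)
  nn0 <- nearest_neighbours(m)
  set.seed(5)
  for (drop in sample(nrow(lib), 4)) {
    lib2 <- lib[-drop, ]
    attr(lib2, "alignment_length") <- alignment_length(lib)
    m2 <- k2p_pairwise(lib2)
    mpd2 <- suppressWarnings(max_intraspecific(m2))
    nn2 <- suppressWarnings(nearest_neighbours(m2))
    for (s in intersect(mpd2$species, mpd0$species)) {
      expect_lte(mpd2$mpd[mpd2$species == s], mpd0$mpd[mpd0$species == s])
    }
    for (s in intersect(nn2$species, nn0$species)) {
      expect_gte(nn2$nn_distance[nn2$species == s],
                 nn0$nn_distance[nn0$species == s])
    }
  }
})

test_that("audit flags follow their definitions and tidy/glance summarise them", {
  sim <- simulate_library(sim_config(n_species = 25, n_sharing_pairs = 1,
                                     n_deep_splits = 2,
                                     low_divergence_d = 0.025, seed = 29))
  a <- audit_library(sim$library)
  tab <- tidy(a)
  expect_s3_class(tab, "tbl_df")
  expect_equal(nrow(tab), 25)
  m <- a$dist
  nn <- suppressWarnings(nearest_neighbours(m))
  mpd <- max_intraspecific(m)
  for (i in seq_len(nrow(tab))) {
    s <- tab$species[i]
    has <- function(f) grepl(f, tab$flags[i])
    expect_equal(has("SINGLETON"), tab$n_specimens[i] == 1)
    if (s %in% nn$species) {
      expect_equal(has("SHARING"), nn$nn_distance[nn$species == s] == 0)
    }
    if (s %in% mpd$species) {
      expect_equal(has("DEEP_SPLIT"),
                   mpd$mpd[mpd$species == s] > 0.02)
    }
  }
  gl <- glance(a)
  expect_equal(gl$n_species, 25)
  expect_equal(gl$n_sharing_pairs, 1L)
  expect_equal(gl$n_deep_splits, sum(tab$deep_split, na.rm = TRUE))
  # histograms conserve their species counts
  expect_equal(sum(a$nn_hist$count), nrow(nn))
  expect_equal(sum(a$mpd_hist$count), nrow(mpd))
  # autoplot returns a ggplot without error
  expect_s3_class(autoplot(a), "ggplot")
  expect_s3_class(plot_barcode_gap(a), "ggplot")
})
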