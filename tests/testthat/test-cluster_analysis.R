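sites_at <- function(pos, chrom = "chr1") {
  as_site_set(data.frame(chrom = chrom, pos = as.integer(pos),
                         strand = "+", coverage = 30L, ipd_ratio = 5,
                         meth_fraction = 0.5, context = NA,
                         stringsAsFactors = FALSE))
}

test_that("cluster detection finds dense windows and rejects sparse ones", {
  # 10 sites within 10 bp: one cluster holding all of them
  d <- detect_clusters(sites_at(1:10))
  expect_equal(nrow(d$clusters), 1L)
  expect_equal(d$clusters$n_sites, 10L)
  expect_false(anyNA(d$site_cluster))
  # 9 sites inside 500 bp: no cluster
  d9 <- detect_clusters(sites_at(seq(1, 481, by = 60)))
  expect_equal(nrow(d9$clusters), 0L)
  expect_true(all(is.na(d9$site_cluster)))
  expect_error(detect_clusters(sites_at(1:10), window = 0), "positive")
})

test_that("strands are pooled per genomic position for density", {
  # 5 positions, both strands each: 10 site records in 5 bp
  df <- expand.grid(pos = 1:5, strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  s <- as_site_set(data.frame(chrom = "chr1", pos = df$pos,
                              strand = df$strand, coverage = 30L,
                              ipd_ratio = 5, meth_fraction = 0.5,
                              context = NA))
  d <- detect_clusters(s)
  expect_equal(nrow(d$clusters), 1L)
  expect_equal(d$clusters$n_sites, 10L)
})

test_that("detection equals the brute-force window oracle on random layouts", {
  set.seed(77)
  mismatches <- 0L
  for (i in 1:120) {
    n <- sample(10:200, 1)
    span <- sample(c(800L, 2000L, 10000L), 1)
    pos <- sort(sample.int(span, n))
    s <- sites_at(pos)
    min_sites <- sample(3:10, 1)
    window <- sample(c(50L, 200L, 500L), 1)
    got <- detect_clusters(s, window, min_sites)
    oracle <- brute_force_clusters(s$pos, window, min_sites)
    if (!identical(!is.na(got$site_cluster), oracle$member) ||
        nrow(got$clusters) != oracle$n_clusters) {
      mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("tightening the definition never adds clustered sites", {
  set.seed(13)
  s <- sites_at(sort(sample.int(5000L, 150)))
  n_clustered <- function(window, min_sites) {
    sum(!is.na(detect_clusters(s, window, min_sites)$site_cluster))
  }
  expect_gte(n_clustered(500, 5), n_clustered(250, 5))
  expect_gte(n_clustered(500, 5), n_clustered(500, 8))
})

test_that("cluster statistics report spacing and A/T content", {
  # sites at 1, 5, 9, ..., 37: successive distances all 4
  s <- sites_at(seq(1, 37, by = 4))
  d <- detect_clusters(s)
  genome <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 600)))
  st <- cluster_stats(d, s, genome)
  expect_equal(st$median_distance, 4)
  expect_equal(st$per_cluster$at_fraction, 1)  # all-A region
  expect_error(cluster_stats(d, s, Biostrings::DNAStringSet(
    c(chr1 = strrep("A", 100)))), "outside")
})

test_that("generator cluster regions are recovered with their A/T content", {
  cfg <- sim_config(seed = 33, n_clusters = 8L)
  sim <- generate_genome(cfg)
  truth <- plant_m6dA(sim, cfg)
  ts <- as_site_set(data.frame(
    truth[c("chrom", "pos", "strand")], coverage = 30L, ipd_ratio = 5,
    meth_fraction = truth$true_fraction, context = NA))
  d <- detect_clusters(ts)
  expect_gte(nrow(d$clusters), 6L)  # most planted regions recovered
  st <- cluster_stats(d, ts, sim$genome)
  expect_lt(abs(st$median_at_fraction - 0.67), 0.05)
  # planted cluster sites are flagged as clustered
  clustered_keys <- site_key(ts)[!is.na(d$site_cluster)]
  truth_keys <- paste(truth$chrom, truth$pos, truth$strand, sep = ":")
  recall <- mean(truth_keys[truth$in_cluster] %in% clustered_keys)
  expect_gte(recall, 0.9)
})

test_that("cluster abundance permutation p reaches the attainable floor", {
  cfg <- sim_config(seed = 34)
  sim <- generate_genome(cfg)
  truth <- plant_m6dA(sim, cfg)
  ts <- as_site_set(data.frame(
    truth[c("chrom", "pos", "strand")], coverage = 30L, ipd_ratio = 5,
    meth_fraction = truth$true_fraction, context = NA))
  u <- shuffle_universe(sim$genome)
  ab <- cluster_abundance_pvalue(ts, u, n_perm = 200L, seed = 6)
  expect_gte(ab$observed, 0.05)      # planted clusters hold ~9% of sites
  expect_equal(ab$p_value, 1 / 200)  # no null draw reaches the observed
  expect_error(cluster_abundance_pvalue(ts, u, n_perm = 0L), "n_perm")
})

test_that("cluster and single m6dA are compared by proportion and rank tests", {
  cfg <- sim_config(seed = 35)
  sim <- generate_genome(cfg)
  truth <- plant_m6dA(sim, cfg)
  ts <- as_site_set(data.frame(
    truth[c("chrom", "pos", "strand")], coverage = 30L, ipd_ratio = 5,
    meth_fraction = truth$true_fraction, context = NA))
  d <- detect_clusters(ts)
  a <- assign_features(ts, sim$annotation)
  cmp <- compare_cluster_vs_single(ts, d, a)
  expect_equal(nrow(cmp$feature_tests), 7L)
  # the generator draws cluster-site fractions from a low-shifted Beta:
  # the rank-sum test must see the difference
  expect_lt(cmp$fraction_test$median_difference, 0)
  expect_lt(cmp$fraction_test$p_value, 0.01)
})
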