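test_that("the generator is deterministic per seed and stage-independent", {
  cfg <- sim_config(seed = 50)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$truth$genes, g2$truth$genes)
  t1 <- plant_m6dA(g1, cfg)
  t2 <- plant_m6dA(g2, cfg)
  expect_identical(t1, t2)
  # different seed, different draws
  g3 <- generate_genome(sim_config(seed = 51))
  expect_false(identical(as.character(g1$genome),
                         as.character(g3$genome)))
})

test_that("a zero-gene configuration yields purely intergenic space", {
  cfg <- sim_config(seed = 52, n_genes = 0L, n_clusters = 0L)
  sim <- generate_genome(cfg)
  expect_equal(nrow(sim$annotation$transcripts), 0L)
  s <- SiteSet("chr1", 5000L, "+", 30L, 5, 0.5)
  expect_equal(as.character(assign_features(s, sim$annotation)$feature),
               "intergenic")
})

test_that("cluster regions realize the configured A/T enrichment", {
  # >= 10 kb of cluster sequence: 20 regions of 500 bp
  cfg <- sim_config(seed = 53, n_clusters = 20L)
  sim <- generate_genome(cfg)
  cl <- sim$truth$cluster_regions
  expect_equal(nrow(cl), 20L)
  expect_gte(sum(cl$end - cl$start + 1L), 10000L)
  at <- vapply(seq_len(nrow(cl)), function(i) {
    v <- Biostrings::subseq(sim$genome[[cl$chrom[i]]], cl$start[i],
                            cl$end[i])
    sum(Biostrings::letterFrequency(v, c("A", "T"))) / length(v)
  }, numeric(1))
  pooled <- sum(at * (cl$end - cl$start + 1)) / sum(cl$end - cl$start + 1)
  expect_lt(abs(pooled - 0.67), 0.05)
})

test_that("null planting matches background dinucleotide composition", {
  cfg <- sim_config(seed = 54, motif_bias = 1,
                    feature_bias = c(promoter = 1, utr5 = 1, utr3 = 1,
                                     exon = 1, intron = 1, downstream = 1,
                                     intergenic = 1),
                    m6dA_density = 3e-3, n_clusters = 0L)
  sim <- generate_genome(cfg)
  truth <- plant_m6dA(sim, cfg)
  u <- shuffle_universe(sim$genome)
  udf <- do.call(rbind, lapply(names(u), function(ch) {
    cbind(chrom = ch, u[[ch]])
  }))
  nb <- m6dAtools:::strand_neighbors(
    strsplit(as.character(sim$genome[["chr1"]]), "")[[1]],
    udf$pos[udf$chrom == "chr1"], udf$strand[udf$chrom == "chr1"])
  bg_rate <- mean(nb$up == "G" | nb$down == "G")
  n <- nrow(truth)
  expect_lt(abs(mean(truth$motif) - bg_rate),
            4 * sqrt(bg_rate * (1 - bg_rate) / n))
})

test_that("a pure spike configuration plants only fully methylated sites", {
  cfg <- sim_config(seed = 55, fraction_spike = 1, n_clusters = 0L)
  truth <- plant_m6dA(generate_genome(cfg), cfg)
  expect_true(all(truth$true_fraction == 1))
})

test_that("simulated kinetics have the constructed IPD expectations", {
  cfg <- sim_config(seed = 56, n_clusters = 0L, m6dA_density = 1e-3,
                    delta = log(4), spot_check_density = 1e-3)
  sim <- generate_genome(cfg)
  truth <- plant_m6dA(sim, cfg)
  truth$true_fraction <- rep(c(0, 1), length.out = nrow(truth))
  kin <- simulate_kinetics(truth, sim, cfg)
  m <- merge(as.data.frame(kin$sites), truth,
             by = c("chrom", "pos", "strand"))
  # fraction 0 -> ratio near 1; fraction 1 with delta = log 4 -> near 4
  expect_lt(abs(mean(m$ipd_ratio[m$true_fraction == 0]) - 1), 0.05)
  expect_lt(abs(mean(m$ipd_ratio[m$true_fraction == 1]) - 4), 0.2)
  # spot checks exist beyond the planted sites and are unmethylated
  spots <- kin$sites[!site_key(kin$sites) %in%
                       paste(truth$chrom, truth$pos, truth$strand,
                             sep = ":"), ]
  expect_gt(nrow(spots), 100L)
  expect_lt(stats::median(spots$ipd_ratio), 1.2)
})

test_that("planted fractions are recovered through calling", {
  cfg <- sim_config(seed = 57, n_clusters = 0L, m6dA_density = 1e-3,
                    spot_check_density = 0)
  sim <- generate_genome(cfg)
  truth <- plant_m6dA(sim, cfg)
  kin <- simulate_kinetics(truth, sim, cfg)
  m <- merge(as.data.frame(kin$sites), truth,
             by = c("chrom", "pos", "strand"))
  rmse <- sqrt(mean((m$meth_fraction - m$true_fraction)^2))
  expect_lte(rmse, 0.08)
})

test_that("haplotype simulation respects dilution and tagging structure", {
  cfg <- sim_config(seed = 58, hap_n_sites = 150L, hap_restricted = 1)
  sim <- generate_genome(cfg)
  expect_error(
    simulate_haplotypes(sim, sim_config(seed = 1, snp_rate = 0)),
    "snp_rate")
  hap <- simulate_haplotypes(sim, cfg)
  expect_true(all(hap$truth$restricted))
  # every restricted site is methylated on exactly one haplotype
  expect_true(all((hap$truth$hp1_fraction == 0) !=
                    (hap$truth$hp2_fraction == 0) |
                    (hap$truth$hp1_fraction == 0 &
                       hap$truth$hp2_fraction == 0)))
  sp <- split_and_call_by_haplotype(
    hap$molecules,
    calling_params(mu0 = cfg$mu0, sigma = cfg$sigma, delta = cfg$delta))
  tab <- sp$table
  # dilution: diploid fraction about half the methylated-haplotype fraction
  truth_key <- paste(hap$truth$chrom, hap$truth$pos, hap$truth$strand,
                     sep = ":")
  full <- truth_key[pmax(hap$truth$hp1_fraction,
                         hap$truth$hp2_fraction) == 1]
  rows <- tab[tab$key %in% full & !is.na(tab$d_fraction), ]
  expect_gt(nrow(rows), 10L)
  expect_lt(stats::median(abs(rows$d_fraction - 0.5)), 0.12)
  # coverage bookkeeping: haplotype + untagged molecules = diploid coverage
  mol_key <- paste(hap$molecules$chrom, hap$molecules$pos,
                   hap$molecules$strand, sep = ":")
  expect_equal(unname(tab$d_coverage[match(names(table(mol_key)),
                                           tab$key)]),
               as.integer(table(mol_key)))
})

test_that("trio generation plants inheritance over a conserved baseline", {
  cfg <- sim_config(seed = 59)
  sim <- generate_genome(cfg)
  u <- shuffle_universe(sim$genome)
  tr <- simulate_trio(sim, cfg, universe = u)
  expect_setequal(names(tr$members), c("mother", "father", "son"))
  res <- trio_analysis(tr$members, tr$total_coverages, n_perm = 100L,
                       seed = 2)
  # parent-parent overlap is above chance (permutation floor) and the
  # child's overlap with each parent far exceeds it
  expect_equal(res$pair_overlap$p_value, rep(0.01, 3))
  ov <- res$pair_overlap$overlap
  expect_gt(ov[2], 5 * ov[1])
  expect_gt(ov[3], 5 * ov[1])
})

test_that("expression generator links TPM and allele bias to methylation", {
  cfg0 <- sim_config(seed = 60, expr_effect = 0)
  genes <- sprintf("g%03d", 1:300)
  has <- rep(c(TRUE, FALSE), 150)
  e0 <- simulate_expression(genes, has, cfg0)
  p0 <- ranksum_test(e0$expression$tpm[has],
                     e0$expression$tpm[!has])$p_value
  expect_gt(p0, 0.001)  # no planted effect: no extreme signal expected
  cfg1 <- sim_config(seed = 60, expr_effect = 1)
  e1 <- simulate_expression(genes, has, cfg1)
  expect_gt(stats::median(e1$expression$tpm[has]),
            stats::median(e1$expression$tpm[!has]))
  # ASE genes drawn entirely from the differentially methylated set
  dm <- genes[1:50]
  e2 <- simulate_expression(genes, has, sim_config(seed = 61, ase_link = 1),
                            diffmeth_genes = dm, n_ase = 30L)
  expect_true(all(e2$truth$ase_genes %in% dm))
})
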