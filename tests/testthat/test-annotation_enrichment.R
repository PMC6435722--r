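make_site <- function(pos, strand = "+") {
  SiteSet("chr1", as.integer(pos), strand, 30L, 5, 0.5)
}

test_that("feature assignment follows the documented precedence", {
  ann <- tiny_annotation()
  # 500 bp upstream of geneA's TSS (5000) -> promoter
  expect_equal(as.character(assign_features(make_site(4500), ann)$feature),
               "promoter")
  # inside geneA's exon 2 but also within geneB's promoter -> promoter wins
  a <- assign_features(make_site(7800), ann)
  expect_equal(as.character(a$feature), "promoter")
  expect_equal(a$gene_id, "geneB")
  # between geneA's exons -> intron
  expect_equal(as.character(assign_features(make_site(6500), ann)$feature),
               "intron")
  # > 1 kb from any transcript -> intergenic
  expect_equal(as.character(assign_features(make_site(18000), ann)$feature),
               "intergenic")
  # within 1 kb past the transcript end -> downstream
  expect_equal(as.character(assign_features(make_site(13000), ann)$feature),
               "downstream")
  expect_error(assign_features(make_site(25000), ann), "bounds")
})

test_that("feature assignment partitions every site exactly once", {
  ann <- tiny_annotation()
  set.seed(4)
  pos <- sample.int(20000L, 300)
  s <- as_site_set(data.frame(chrom = "chr1", pos = pos, strand = "+",
                              coverage = 30L, ipd_ratio = 5,
                              meth_fraction = 0.5, context = NA))
  a <- assign_features(s, ann)
  expect_equal(nrow(a), nrow(s))
  expect_false(anyNA(a$feature))
  expect_equal(sum(table(a$feature)), nrow(s))
})

test_that("chromosome m6dA/dA ratios count strand-specific dA", {
  # 100 bp chromosome of repeated ACGT: 25 A (+) and 25 T (+ strand, i.e.
  # A on -) -> 50 strand-specific dA; 2 sites -> 4%
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep("ACGT", 25), collapse = "")))
  s <- as_site_set(data.frame(chrom = "chr1", pos = c(1L, 5L),
                              strand = "+", coverage = 30L, ipd_ratio = 5,
                              meth_fraction = 0.5, context = NA))
  r <- chromosome_m6dA_dA(s, genome)
  expect_equal(r$dA, 50L)
  expect_equal(r$pct, 4)
  expect_equal(chromosome_m6dA_dA(SiteSet(), genome)$pct, 0)
  expect_error(chromosome_m6dA_dA(
    SiteSet("chrX", 1L, "+", 30L, 5, 0.5), genome), "absent")
})

test_that("bin profiles tile the chromosome and sum to the totals", {
  set.seed(9)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 20000, replace = TRUE), collapse = "")))
  s <- random_sites(60, max_pos = 20000, seed = 2)
  bp <- bin_profile(s, genome, n_bins = 20L)
  expect_equal(nrow(bp), 20L)
  expect_equal(bp$start[1], 1L)
  expect_equal(bp$end[20], 20000L)
  expect_true(all(bp$start[-1] == bp$end[-20] + 1L))
  expect_equal(sum(bp$m6dA), nrow(s))
  expect_equal(sum(bp$dA), chromosome_m6dA_dA(s, genome)$dA)
  # single bin reproduces the chromosome-wide value
  one <- bin_profile(s, genome, n_bins = 1L)
  expect_equal(one$pct, chromosome_m6dA_dA(s, genome)$pct)
  # sites confined to the first half leave the second half empty
  first_half <- as_site_set(as.data.frame(s)[s$pos <= 10000, ])
  bp2 <- bin_profile(first_half, genome, n_bins = 20L)
  expect_true(all(bp2$m6dA[11:20] == 0L))
  expect_error(bin_profile(s, genome, n_bins = 30000L), "exceeds")
})

test_that("fold enrichment detects planted feature bias and is calibrated", {
  cfg <- sim_config(seed = 21, n_genes = 30L,
                    chrom_sizes = c(chr1 = 150000L, chr2 = 150000L))
  sim <- generate_genome(cfg)
  u <- shuffle_universe(sim$genome)
  udf <- do.call(rbind, lapply(names(u), function(ch) {
    cbind(chrom = ch, u[[ch]])
  }))
  lab <- m6dAtools:::label_positions(udf$chrom, udf$pos, sim$annotation)

  # planting restricted to exons: exon fold > 1 and intergenic fold < 1,
  # both at the permutation floor
  set.seed(5)
  ex_idx <- sample(which(lab$feature == "exon"), 300)
  s <- as_site_set(data.frame(
    chrom = udf$chrom[ex_idx], pos = udf$pos[ex_idx],
    strand = udf$strand[ex_idx], coverage = 30L, ipd_ratio = 5,
    meth_fraction = 0.5, context = NA))
  enr <- feature_fold_enrichment(s, sim$annotation, sim$genome,
                                 n_perm = 1000L, seed = 3, universe = u)
  expect_gt(enr$fold[enr$feature == "exon"], 1)
  expect_lt(enr$fold[enr$feature == "intergenic"], 1)
  expect_equal(enr$p_value[enr$feature == "exon"], 0.001)
  expect_equal(enr$p_value[enr$feature == "intergenic"], 0.001)

  # uniform planting: folds near 1, p-values not extreme
  unif_idx <- sample(nrow(udf), 2000)
  s0 <- as_site_set(data.frame(
    chrom = udf$chrom[unif_idx], pos = udf$pos[unif_idx],
    strand = udf$strand[unif_idx], coverage = 30L, ipd_ratio = 5,
    meth_fraction = 0.5, context = NA))
  enr0 <- feature_fold_enrichment(s0, sim$annotation, sim$genome,
                                  n_perm = 300L, seed = 4, universe = u)
  big <- enr0$dA > 5000  # only features with enough dA to be stable
  expect_true(all(abs(enr0$fold[big] - 1) < 0.25))
})
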