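make_hap_mols <- function(f1, f2, cov_per_hap = 30L, seed = 1L,
                          delta = log(6)) {
  # one molecule table over length(f1) sites with balanced, fully tagged
  # haplotype coverage and per-haplotype methylation fractions f1/f2
  set.seed(seed)
  n <- length(f1)
  idx <- rep(seq_len(n), each = 2L * cov_per_hap)
  hp <- rep(rep(1:2, each = cov_per_hap), n)
  f <- ifelse(hp == 1L, f1[idx], f2[idx])
  z <- rbinom(length(idx), 1L, f)
  data.frame(
    chrom = "chr1", pos = idx * 100L, strand = "+",
    molecule_id = paste0("m", seq_along(idx)),
    mean_log_ipd = rnorm(length(idx), z * delta, 0.5 / sqrt(10)),
    n_passes = 10L, haplotype = paste0("HP", hp),
    stringsAsFactors = FALSE)
}

test_that("haplotype-split calling separates one-haplotype methylation", {
  mols <- make_hap_mols(f1 = rep(1, 30), f2 = rep(0, 30), seed = 2)
  sp <- split_and_call_by_haplotype(mols, calling_params())
  tab <- sp$table
  expect_gt(min(tab$hp1_fraction), 0.9)
  expect_lt(max(tab$hp2_fraction), 0.1)
  expect_true(all(abs(tab$d_fraction - 0.5) < 0.2))
  expect_true(all(tab$called_hp1))
  expect_false(any(tab$called_hp2))
  expect_error(
    split_and_call_by_haplotype(
      transform(mols, haplotype = "untagged"), calling_params()),
    "untagged")
})

test_that("identical haplotypes give symmetric fractions", {
  f <- runif(40, 0.3, 1)
  mols <- make_hap_mols(f1 = f, f2 = f, seed = 3)
  tab <- split_and_call_by_haplotype(mols, calling_params())$table
  expect_lt(stats::median(abs(tab$hp1_fraction - tab$hp2_fraction)), 0.15)
})

test_that("exclusivity partitions call sets and counts the shared core", {
  a <- random_sites(50, seed = 5)
  ex <- haplotype_exclusivity(a, a)
  expect_equal(ex$both, 50L)
  expect_equal(ex$hp1_only + ex$hp2_only, 0L)
  b <- random_sites(30, max_pos = 10000L, seed = 6, chrom = "chr2")
  ex2 <- haplotype_exclusivity(a, b)
  expect_equal(ex2$both, 0L)
  expect_equal(ex2$exclusive_fraction, 1)
})

test_that("diploid-on-haplotype regression recovers construction weights", {
  set.seed(10)
  h1 <- runif(500)
  h2 <- runif(500)
  d <- 0.5 * h1 + 0.5 * h2 + rnorm(500, 0, 0.05)
  fit <- regress_diploid_on_haplotypes(
    data.frame(d_fraction = d, hp1_fraction = h1, hp2_fraction = h2))
  est <- fit$coefficients$estimate
  expect_lt(abs(est[2] - 0.5), 0.05)
  expect_lt(abs(est[3] - 0.5), 0.05)
  expect_lt(abs(est[1]), 0.05)
  # diploid equal to HP1 alone
  fit2 <- regress_diploid_on_haplotypes(
    data.frame(d_fraction = h1 + rnorm(500, 0, 0.01),
               hp1_fraction = h1, hp2_fraction = h2))
  est2 <- fit2$coefficients$estimate
  expect_lt(abs(est2[2] - 1), 0.05)
  expect_lt(abs(est2[3]), 0.05)
  expect_error(regress_diploid_on_haplotypes(
    data.frame(d_fraction = h1[1:50], hp1_fraction = h1[1:50],
               hp2_fraction = h1[1:50])), "collinear")
})

test_that("differential gene methylation is symmetric and detects shifts", {
  ann <- tiny_annotation()
  # all inside geneA territory (geneB's promoter begins at 7500)
  pos <- seq(5000L, 7400L, by = 100L)
  mk <- function(frac) {
    as_site_set(data.frame(chrom = "chr1", pos = pos, strand = "+",
                           coverage = 50L, ipd_ratio = 5,
                           meth_fraction = frac, context = NA))
  }
  a <- mk(0.8)
  b <- mk(0.2)
  res <- differential_gene_methylation(a, b, ann)
  expect_equal(res$gene_id, "geneA")
  expect_lt(res$p_value, 1e-10)
  swapped <- differential_gene_methylation(b, a, ann)
  expect_equal(res$p_value, swapped$p_value)
  same <- differential_gene_methylation(a, a, ann)
  expect_equal(same$p_value, 1)
  # hand-checkable single-position table: 80/100 vs 20/100
  one <- function(frac) {
    as_site_set(data.frame(chrom = "chr1", pos = 5500L, strand = "+",
                           coverage = 100L, ipd_ratio = 5,
                           meth_fraction = frac, context = NA))
  }
  r1 <- differential_gene_methylation(one(0.8), one(0.2), ann)
  expect_equal(
    r1$p_value,
    stats::pchisq(yates_chisq_oracle(80, 100, 20, 100), 1,
                  lower.tail = FALSE))
})

test_that("trio analysis applies half-coverage filters and permutation", {
  # identical call sets across the family: overlaps equal the set size
  base <- random_sites(80, max_pos = 50000, seed = 21)
  pool <- random_sites(400, max_pos = 50000, seed = 22)
  pool <- as_site_set(transform(as.data.frame(pool), ipd_ratio = 1.1,
                                coverage = 15L))
  member <- function() {
    called <- transform(as.data.frame(base), coverage = 40L,
                        ipd_ratio = 6)
    pl <- as.data.frame(pool)
    pl <- pl[!site_key(pl) %in% site_key(called), ]
    as_site_set(rbind(called, pl))
  }
  members <- list(mother = member(), father = member(), son = member())
  res <- trio_analysis(members, c(mother = 27, father = 29, son = 67),
                       n_perm = 50L, seed = 1)
  expect_equal(res$coverage_filters,
               c(mother = 14L, father = 15L, son = 34L))
  expect_equal(res$pair_overlap$overlap, rep(80L, 3))
  expect_equal(res$pair_overlap$p_value, rep(1 / 50, 3))
  # per-member coverage-filter override is honored
  res2 <- trio_analysis(members, c(mother = 27, father = 29, son = 67),
                        coverage_filters = c(mother = 14L, father = 15L,
                                             son = 33L),
                        n_perm = 0L)
  expect_equal(res2$coverage_filters[["son"]], 33L)
})
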