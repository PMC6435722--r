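# Independent oracles and small fixture builders shared across tests.
# Oracles are deliberately naive (enumeration / brute force) and share no
# code with the implementation paths they check.

# Brute-force cluster membership: enumerate every window anchored at a
# site position, mark windows holding >= min_sites, and flag sites covered
# by any qualifying window. Component count = number of maximal runs of
# union coverage. Positions need not be sorted or unique.
brute_force_clusters <- function(pos, window = 500L, min_sites = 10L) {
  n <- length(pos)
  member <- rep(FALSE, n)
  qual_lo <- integer(0)
  qual_hi <- integer(0)
  for (i in seq_len(n)) {
    lo <- pos[i]
    hi <- pos[i] + window - 1L
    if (sum(pos >= lo & pos <= hi) >= min_sites) {
      qual_lo <- c(qual_lo, lo)
      qual_hi <- c(qual_hi, hi)
      member <- member | (pos >= lo & pos <= hi)
    }
  }
  n_comp <- 0L
  if (length(qual_lo)) {
    o <- order(qual_lo)
    qual_lo <- qual_lo[o]
    qual_hi <- qual_hi[o]
    cur_hi <- -Inf
    for (j in seq_along(qual_lo)) {
      if (qual_lo[j] > cur_hi) {   # strictly beyond: overlapping merges only
        n_comp <- n_comp + 1L
        cur_hi <- qual_hi[j]
      } else {
        cur_hi <- max(cur_hi, qual_hi[j])
      }
    }
  }
  list(member = member, n_clusters = n_comp)
}

# Exhaustive hypergeometric upper tail by direct summation of the mass
# function (valid for small universes).
hyper_tail_oracle <- function(size_a, size_b, overlap, universe) {
  xs <- overlap:min(size_a, size_b)
  sum(choose(size_a, xs) * choose(universe - size_a, size_b - xs) /
        choose(universe, size_b))
}

# Textbook continuity-corrected chi-squared for a 2x2 table given as
# successes/totals per group.
yates_chisq_oracle <- function(x1, n1, x2, n2) {
  a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
  N <- n1 + n2
  num <- N * (abs(a * d - b * c) - N / 2)^2
  num / ((a + b) * (c + d) * (a + c) * (b + d))
}

# A tiny deterministic two-gene annotation on one 20 kb chromosome:
# geneA (+) with two exons, geneB (+) placed so that geneA's promoter
# overlaps geneB's exon territory in fixture tests.
tiny_annotation <- function() {
  tx <- data.frame(
    gene_id = c("geneA", "geneB"), chrom = "chr1", strand = c("+", "+"),
    start = c(5000L, 8500L), end = c(7999L, 12499L),
    stringsAsFactors = FALSE)
  ex <- data.frame(
    gene_id = c("geneA", "geneA", "geneB"), chrom = "chr1",
    start = c(5000L, 7000L, 8500L), end = c(5999L, 7999L, 12499L),
    stringsAsFactors = FALSE)
  genome_annotation(tx, ex, seqlengths = c(chr1 = 20000L))
}

# Deterministic random site_set on a single chromosome.
random_sites <- function(n, max_pos = 10000L, seed = 1L, chrom = "chr1") {
  set.seed(seed)
  pos <- sort(sample.int(max_pos, n))
  as_site_set(data.frame(
    chrom = chrom, pos = pos,
    strand = sample(c("+", "-"), n, replace = TRUE),
    coverage = 30L, ipd_ratio = 5, meth_fraction = runif(n),
    context = NA_character_, stringsAsFactors = FALSE))
}

# Random 41-base contexts with an A center, deterministic per seed.
random_contexts <- function(n, seed = 1L) {
  set.seed(seed)
  flank <- function() {
    replicate(n, paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                       collapse = ""))
  }
  paste0(flank(), "A", flank())
}
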