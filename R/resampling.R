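#' Build a strand-specific deoxyadenosine shuffle universe
#'
#' Permutation tests in this package shuffle m6dA sites over the positions
#' where m6dA could occur at all: every strand-specific adenosine (an `A` on
#' the plus strand, a `T` in the plus-strand sequence for the minus strand).
#' The universe indexes those positions per chromosome, optionally excluding
#' masked regions (e.g. a centromere track).
#'
#' @param genome a `DNAStringSet`.
#' @param exclude optional `GRanges` of regions to drop from the universe.
#' @return a list of class `shuffle_universe`: per chromosome, a data frame
#'   of `pos`, `strand` sorted by position then strand.
#' @export
shuffle_universe <- function(genome, exclude = NULL) {
  stopifnot(methods::is(genome, "DNAStringSet"))
  out <- lapply(names(genome), function(chrom) {
    s <- genome[[chrom]]
    plus <- Biostrings::start(Biostrings::matchPattern("A", s))
    minus <- Biostrings::start(Biostrings::matchPattern("T", s))
    df <- data.frame(
      pos = c(plus, minus),
      strand = rep(c("+", "-"), c(length(plus), length(minus))),
      stringsAsFactors = FALSE
    )
    if (!is.null(exclude)) {
      ex <- exclude[as.character(GenomeInfoDb::seqnames(exclude)) == chrom]
      if (length(ex)) {
        hit <- IRanges::overlapsAny(
          IRanges::IRanges(df$pos, width = 1L), IRanges::ranges(ex))
        df <- df[!hit, , drop = FALSE]
      }
    }
    df <- df[order(df$pos, df$strand), , drop = FALSE]
    rownames(df) <- NULL
    df
  })
  names(out) <- names(genome)
  structure(out, class = "shuffle_universe")
}

#' Shuffle site locations over the dA universe
#'
#' Draws, independently per chromosome, the observed number of sites from
#' that chromosome's universe positions without replacement, so
#' per-chromosome site counts are preserved on every draw and strand is
#' sampled with the chromosome's dA strand composition. Deterministic per
#' seed.
#'
#' @param sites a `site_set`.
#' @param universe a [shuffle_universe()].
#' @param seed integer seed.
#' @return a `site_set` of shuffled locations (kinetic columns `NA`).
#' @export
shuffle_sites <- function(sites, universe, seed) {
  stopifnot(is_site_set(sites), inherits(universe, "shuffle_universe"))
  counts <- table(sites$chrom)
  missing <- setdiff(names(counts), names(universe))
  if (length(missing)) {
    stop("universe lacks chromosome(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  with_seed(seed, {
    picks <- lapply(names(counts), function(chrom) {
      u <- universe[[chrom]]
      n <- counts[[chrom]]
      if (n > nrow(u)) {
        stop(sprintf("more sites (%d) than universe positions (%d) on %s",
                     n, nrow(u), chrom), call. = FALSE)
      }
      i <- sample.int(nrow(u), n)
      data.frame(chrom = chrom, pos = u$pos[i], strand = u$strand[i],
                 stringsAsFactors = FALSE)
    })
    as_site_set(do.call(rbind, picks))
  })
}

#' Empirical p-value from permutation null draws
#'
#' Uses the `(b + 1) / N` convention, where `b` counts null draws at least
#' as extreme as the observed statistic, capped at 1. With 1,000 shuffles
#' and no exceedances this yields the attainable minimum of 0.001.
#'
#' @param observed observed statistic.
#' @param null_draws numeric vector of null statistics.
#' @param alternative `"greater"` (null >= observed is extreme), `"less"`,
#'   or `"two.sided"` (on the absolute deviation from the null mean).
#' @return empirical p-value in `[1/N, 1]`.
#' @export
#' @examples
#' empirical_pvalue(10, rep(1, 1000))   # 0.001
empirical_pvalue <- function(observed, null_draws,
                             alternative = c("greater", "less",
                                             "two.sided")) {
  alternative <- match.arg(alternative)
  stop_if_not_scalar_number(observed, "observed")
  n <- length(null_draws)
  if (n == 0L) stop("empty null distribution", call. = FALSE)
  b <- switch(alternative,
    greater = sum(null_draws >= observed),
    less = sum(null_draws <= observed),
    two.sided = {
      center <- mean(null_draws)
      sum(abs(null_draws - center) >= abs(observed - center))
    })
  min(1, (b + 1) / n)
}

#' Exact site overlap between two site sets
#'
#' Counts sites matching on the full `(chrom, pos, strand)` key.
#'
#' @param a,b site_sets.
#' @return integer overlap count.
#' @export
overlap_exact <- function(a, b) {
  length(intersect(site_key(a), site_key(b)))
}

#' Windowed overlap between two site sets
#'
#' Each set's sites are expanded by `flank` bp on both sides and merged;
#' the overlap regions are the intersections of the two merged interval
#' sets. Reports the number of shared regions and how many members of each
#' set fall inside them.
#'
#' @param a,b site_sets.
#' @param flank bp added on each side of a site (default 250, i.e. 500 bp
#'   windows).
#' @return list with `regions` (count), `members_a`, `members_b`, and the
#'   shared regions as a `GRanges`.
#' @export
overlap_windowed <- function(a, b, flank = 250L) {
  expand <- function(s) {
    gr <- sites_as_granges(s, stranded = FALSE)
    GenomicRanges::reduce(gr + flank, ignore.strand = TRUE)
  }
  ga <- expand(a)
  gb <- expand(b)
  shared <- GenomicRanges::intersect(ga, gb, ignore.strand = TRUE)
  in_shared <- function(s) {
    sum(IRanges::overlapsAny(sites_as_granges(s, stranded = FALSE), shared,
                             ignore.strand = TRUE))
  }
  list(regions = length(shared), members_a = in_shared(a),
       members_b = in_shared(b), shared = shared)
}

#' Proportions test (Pearson's chi-squared)
#'
#' Thin contract over [stats::prop.test()]: on 2x2 tables the Yates
#' continuity correction is applied, matching the R default the downstream
#' analyses assume.
#'
#' @param successes vector of success counts per group.
#' @param totals vector of trial counts per group.
#' @param correct apply continuity correction on 2-group tables.
#' @return list with `statistic`, `p_value`, `estimate`.
#' @export
proportions_test <- function(successes, totals, correct = TRUE) {
  if (any(successes < 0) || any(totals < 0) || any(successes > totals)) {
    stop("invalid counts for proportions test", call. = FALSE)
  }
  ht <- suppressWarnings(stats::prop.test(successes, totals,
                                          correct = correct))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       estimate = unname(ht$estimate))
}

#' Fisher's exact test on a 2x2 table
#'
#' @param table22 2x2 integer matrix.
#' @param alternative sidedness, default two-sided.
#' @return list with `odds_ratio`, `p_value`.
#' @export
fisher_exact <- function(table22, alternative = "two.sided") {
  stopifnot(is.matrix(table22), all(dim(table22) == c(2L, 2L)))
  if (any(table22 < 0)) stop("negative counts", call. = FALSE)
  ht <- stats::fisher.test(table22, alternative = alternative)
  list(odds_ratio = unname(ht$estimate), p_value = ht$p.value)
}

#' Hypergeometric test for the overlap of two gene sets
#'
#' Upper-tail probability of observing at least `overlap` common elements
#' between a set of size `size_a` and one of size `size_b` drawn from a
#' universe of `universe` elements.
#'
#' @param size_a,size_b set sizes.
#' @param overlap observed overlap.
#' @param universe universe size.
#' @return p-value.
#' @export
hypergeometric_overlap <- function(size_a, size_b, overlap, universe) {
  stopifnot(size_a >= 0, size_b >= 0, overlap >= 0,
            universe >= max(size_a, size_b), overlap <= min(size_a, size_b))
  stats::phyper(overlap - 1, size_a, universe - size_a, size_b,
                lower.tail = FALSE)
}

#' Wilcoxon rank-sum test
#'
#' @param x,y numeric samples.
#' @param alternative sidedness, default two-sided.
#' @return list with `statistic`, `p_value`.
#' @export
ranksum_test <- function(x, y, alternative = "two.sided") {
  ht <- suppressWarnings(stats::wilcox.test(x, y,
                                            alternative = alternative))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Two-sided exact binomial test
#'
#' @param k successes.
#' @param n trials.
#' @param p0 null success probability.
#' @return p-value.
#' @export
binomial_two_sided <- function(k, n, p0 = 0.5) {
  stopifnot(n >= k, k >= 0)
  stats::binom.test(k, n, p = p0, alternative = "two.sided")$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' @param p numeric vector of p-values.
#' @return vector of q-values (same order as input).
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}
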