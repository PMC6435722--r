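#' Detect dense m6dA clusters
#'
#' A cluster is a region of `window` bp (default 500) containing at least
#' `min_sites` m6dA (default 10). Candidate windows are anchored at every
#' site position (strands pooled per genomic position); windows holding at
#' least `min_sites` sites are merged when they overlap, and every site
#' inside a merged span is a cluster member. Remaining sites are "single"
#' m6dA. The procedure is deterministic and equals exhaustive window
#' enumeration.
#'
#' @param sites a `site_set`.
#' @param window window width in bp.
#' @param min_sites minimum sites per window.
#' @return list of class `m6dA_clusters` with `clusters` (data frame:
#'   `cluster_id`, `chrom`, `start`, `end`, `n_sites`) and `site_cluster`
#'   (integer cluster id per input site row, `NA` for single sites).
#' @export
detect_clusters <- function(sites, window = 500L, min_sites = 10L) {
  stopifnot(is_site_set(sites))
  if (window <= 0L || min_sites <= 0L) {
    stop("window and min_sites must be positive", call. = FALSE)
  }
  site_cluster <- rep(NA_integer_, nrow(sites))
  clusters <- list()
  next_id <- 1L
  for (chrom in unique(sites$chrom)) {
    rows <- which(sites$chrom == chrom)
    p <- sites$pos[rows]         # already sorted within chrom
    ub <- findInterval(p + window - 1L, p)
    lb <- findInterval(p - 1L, p)
    qual <- which(ub - lb >= min_sites)
    if (!length(qual)) next
    merged <- IRanges::reduce(
      IRanges::IRanges(p[qual], p[qual] + window - 1L), min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(IRanges::IRanges(p, width = 1L), merged)
    site_cluster[rows[S4Vectors::queryHits(hit)]] <-
      next_id - 1L + S4Vectors::subjectHits(hit)
    clusters[[length(clusters) + 1L]] <- data.frame(
      cluster_id = next_id - 1L + seq_along(merged), chrom = chrom,
      start = IRanges::start(merged), end = IRanges::end(merged),
      n_sites = tabulate(S4Vectors::subjectHits(hit), nbins = length(merged)),
      stringsAsFactors = FALSE)
    next_id <- next_id + length(merged)
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else {
    data.frame(cluster_id = integer(), chrom = character(),
               start = integer(), end = integer(), n_sites = integer(),
               stringsAsFactors = FALSE)
  }
  structure(list(clusters = clusters, site_cluster = site_cluster,
                 window = as.integer(window),
                 min_sites = as.integer(min_sites)),
            class = "m6dA_clusters")
}

#' @export
print.m6dA_clusters <- function(x, ...) {
  cat(sprintf("%d m6dA cluster(s); %d clustered / %d single site(s)\n",
              nrow(x$clusters), sum(!is.na(x$site_cluster)),
              sum(is.na(x$site_cluster))))
  invisible(x)
}

#' Per-cluster sequence and spacing statistics
#'
#' For each cluster: the A/T fraction of the merged span and the median
#' distance between successive member positions. Also reports the global
#' medians (pooled over clusters for distances).
#'
#' @param detected result of [detect_clusters()].
#' @param sites the `site_set` the clusters were detected on.
#' @param genome a `DNAStringSet`.
#' @return list with `per_cluster` (data frame adding `at_fraction` and
#'   `median_distance`), `median_at_fraction` and `median_distance`
#'   (global, pooled successive distances).
#' @export
cluster_stats <- function(detected, sites, genome) {
  stopifnot(inherits(detected, "m6dA_clusters"), is_site_set(sites))
  cl <- detected$clusters
  if (nrow(cl) == 0L) {
    return(list(per_cluster = cbind(cl, at_fraction = numeric(),
                                    median_distance = numeric()),
                median_at_fraction = NA_real_, median_distance = NA_real_))
  }
  missing <- setdiff(unique(cl$chrom), names(genome))
  if (length(missing)) {
    stop("cluster chromosome(s) absent from genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(cl$end > Biostrings::width(genome)[
        match(cl$chrom, names(genome))])) {
    stop("cluster span outside genome", call. = FALSE)
  }
  at <- vapply(seq_len(nrow(cl)), function(i) {
    v <- Biostrings::subseq(genome[[cl$chrom[i]]], cl$start[i], cl$end[i])
    sum(Biostrings::letterFrequency(v, c("A", "T"))) / length(v)
  }, numeric(1))
  dists <- lapply(cl$cluster_id, function(id) {
    p <- sort(sites$pos[which(detected$site_cluster == id)])
    diff(p)
  })
  cl$at_fraction <- at
  cl$median_distance <- vapply(dists, function(d) {
    if (length(d)) stats::median(d) else NA_real_
  }, numeric(1))
  list(per_cluster = cl,
       median_at_fraction = stats::median(at),
       median_distance = stats::median(unlist(dists)))
}

#' Permutation p-value for m6dA cluster abundance
#'
#' The statistic is the fraction of sites falling in clusters. Null draws
#' shuffle the site locations over the dA universe and re-run the same
#' cluster detection; the empirical p-value uses the `(b + 1) / N`
#' convention, so 1,000 permutations give an attainable minimum of 0.001.
#'
#' @param sites a `site_set`.
#' @param universe a [shuffle_universe()].
#' @param window,min_sites cluster definition (see [detect_clusters()]).
#' @param n_perm number of shuffles.
#' @param seed integer seed.
#' @return list with `observed` (clustered fraction), `null` (vector),
#'   `p_value`.
#' @export
cluster_abundance_pvalue <- function(sites, universe, window = 500L,
                                     min_sites = 10L, n_perm = 1000L,
                                     seed = 1L) {
  if (n_perm < 1L) stop("n_perm must be >= 1", call. = FALSE)
  frac_clustered <- function(s) {
    d <- detect_clusters(s, window, min_sites)
    mean(!is.na(d$site_cluster))
  }
  obs <- frac_clustered(sites)
  null <- vapply(seq_len(n_perm), function(i) {
    frac_clustered(shuffle_sites(sites, universe,
                                 substream_seed(seed, paste0("clshuf", i))))
  }, numeric(1))
  list(observed = obs, null = null,
       p_value = empirical_pvalue(obs, null, "greater"))
}

#' Compare cluster m6dA with single m6dA
#'
#' Tests whether clustered and single m6dA differ in (i) their placement
#' across genomic features, via a continuity-corrected 2x2 proportions test
#' per feature, and (ii) their methylated fraction, via a two-sided
#' Wilcoxon rank-sum test with the difference of medians as effect size.
#'
#' @param sites a `site_set`.
#' @param detected result of [detect_clusters()] on `sites`.
#' @param assignments result of [assign_features()] on `sites`.
#' @return list with `feature_tests` (data frame per feature) and
#'   `fraction_test` (medians, difference, Wilcoxon p).
#' @export
compare_cluster_vs_single <- function(sites, detected, assignments) {
  clustered <- !is.na(detected$site_cluster)
  if (!any(clustered) || all(clustered)) {
    stop("need both clustered and single sites to compare", call. = FALSE)
  }
  n_c <- sum(clustered)
  n_s <- sum(!clustered)
  feat <- assignments$feature
  ft <- lapply(feature_levels, function(f) {
    x_c <- sum(feat[clustered] == f)
    x_s <- sum(feat[!clustered] == f)
    pt <- proportions_test(c(x_c, x_s), c(n_c, n_s))
    data.frame(feature = f, cluster_count = x_c, single_count = x_s,
               cluster_prop = x_c / n_c, single_prop = x_s / n_s,
               statistic = pt$statistic, p_value = pt$p_value,
               stringsAsFactors = FALSE)
  })
  mf_c <- sites$meth_fraction[clustered]
  mf_s <- sites$meth_fraction[!clustered]
  rs <- ranksum_test(mf_c, mf_s)
  list(feature_tests = do.call(rbind, ft),
       fraction_test = list(median_cluster = stats::median(mf_c),
                            median_single = stats::median(mf_s),
                            median_difference = stats::median(mf_c) -
                              stats::median(mf_s),
                            p_value = rs$p_value))
}
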