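feature_levels <- c("promoter", "utr5", "utr3", "exon", "intron",
                    "downstream", "intergenic")

# Label genomic positions by feature under the package precedence rule:
# promoter > 5'UTR > 3'UTR > exon > intron > downstream > intergenic,
# ties within a feature broken by lowest gene_id.
label_positions <- function(chrom, pos, annotation) {
  sl <- annotation$seqlengths
  bad_chrom <- setdiff(unique(chrom), names(sl))
  if (length(bad_chrom)) {
    stop("position(s) on chromosome(s) absent from annotation: ",
         paste(bad_chrom, collapse = ", "), call. = FALSE)
  }
  if (any(pos < 1L | pos > sl[chrom])) {
    stop("position beyond chromosome bounds", call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = names(sl)),
    ranges = IRanges::IRanges(pos, width = 1L), seqlengths = sl)
  n <- length(gr)
  label <- rep(NA_character_, n)
  gene <- rep(NA_character_, n)
  for (f in setdiff(feature_levels, "intergenic")) {
    open <- which(is.na(label))
    if (!length(open)) break
    feat <- annotation$features[[f]]
    if (length(feat) == 0L) next
    hits <- GenomicRanges::findOverlaps(gr[open], feat,
                                        ignore.strand = TRUE)
    if (length(hits) == 0L) next
    qh <- S4Vectors::queryHits(hits)
    gh <- S4Vectors::subjectHits(hits)
    gids <- S4Vectors::mcols(feat)$gene_id[gh]
    ord <- order(qh, gids)  # lowest gene_id wins on overlap ties
    keep <- ord[!duplicated(qh[ord])]
    label[open[qh[keep]]] <- f
    gene[open[qh[keep]]] <- gids[keep]
  }
  label[is.na(label)] <- "intergenic"
  data.frame(feature = factor(label, levels = feature_levels),
             gene_id = gene, stringsAsFactors = FALSE)
}

#' Assign m6dA sites to genomic features
#'
#' Each site gets exactly one feature label, chosen by the precedence
#' promoter > 5'UTR > 3'UTR > exon > intron > downstream (up to 1 kb past
#' the transcript end) > intergenic. When several transcripts of the same
#' precedence level overlap a site, the lowest gene id wins, so the
#' assignment is deterministic. Strand is ignored for feature placement:
#' features are positional, while sites remain strand-specific records.
#'
#' @param sites a `site_set`.
#' @param annotation a [genome_annotation()].
#' @return data frame with `chrom`, `pos`, `strand`, `feature`, `gene_id`,
#'   one row per site in site order.
#' @export
assign_features <- function(sites, annotation) {
  stopifnot(is_site_set(sites), inherits(annotation, "genome_annotation"))
  lab <- label_positions(sites$chrom, sites$pos, annotation)
  cbind(sites[c("chrom", "pos", "strand")], lab)
}

#' Per-chromosome m6dA/dA percentage
#'
#' For each chromosome, the number of called m6dA sites (both strands)
#' divided by the number of strand-specific deoxyadenosine positions (`A`
#' count plus `T` count of the plus-strand sequence), as a percentage.
#'
#' @param sites a `site_set` of called sites.
#' @param genome a `DNAStringSet`.
#' @return data frame with `chrom`, `m6dA`, `dA`, `pct`.
#' @export
chromosome_m6dA_dA <- function(sites, genome) {
  stopifnot(is_site_set(sites))
  missing <- setdiff(unique(sites$chrom), names(genome))
  if (length(missing)) {
    stop("chromosome(s) absent from genome: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  da <- Biostrings::letterFrequency(genome, c("A", "T"))
  da_total <- rowSums(da)
  m <- table(factor(sites$chrom, levels = names(genome)))
  data.frame(chrom = names(genome), m6dA = as.integer(m),
             dA = as.integer(da_total),
             pct = 100 * as.integer(m) / as.integer(da_total),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Binned m6dA/dA profile along chromosomes
#'
#' Splits each chromosome into `n_bins` equal-width half-open bins (the
#' last bin absorbs the remainder) and reports the m6dA/dA percentage per
#' bin. With `n_bins = 1` the single bin reproduces the chromosome-wide
#' value of [chromosome_m6dA_dA()].
#'
#' @param sites a `site_set`.
#' @param genome a `DNAStringSet`.
#' @param n_bins number of bins per chromosome (default 200).
#' @return data frame with `chrom`, `bin`, `start`, `end`, `m6dA`, `dA`,
#'   `pct`.
#' @export
bin_profile <- function(sites, genome, n_bins = 200L) {
  stopifnot(is_site_set(sites), n_bins >= 1L)
  out <- lapply(names(genome), function(chrom) {
    len <- Biostrings::width(genome[chrom])
    if (n_bins > len) {
      stop(sprintf("n_bins (%d) exceeds length of %s (%d)", n_bins, chrom,
                   len), call. = FALSE)
    }
    width <- len %/% n_bins
    start <- 1L + (seq_len(n_bins) - 1L) * width
    end <- c(start[-1L] - 1L, len)
    v <- Biostrings::Views(genome[[chrom]], start = start, end = end)
    da <- rowSums(Biostrings::letterFrequency(v, c("A", "T")))
    p <- sites$pos[sites$chrom == chrom]
    cnt <- tabulate(findInterval(p, start), nbins = n_bins)
    data.frame(chrom = chrom, bin = seq_len(n_bins), start = start,
               end = end, m6dA = cnt, dA = as.integer(da),
               pct = ifelse(da > 0, 100 * cnt / da, NA_real_),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fold enrichment of m6dA across genomic features
#'
#' For each feature, fold enrichment is the feature's m6dA/dA ratio divided
#' by the genome-wide m6dA/dA ratio; 1 means the feature carries its
#' expected share. Significance comes from a permutation test: site
#' locations are shuffled over the strand-specific dA universe `n_perm`
#' times and the two-sided empirical p-value of `|fold - 1|` is reported
#' per feature. Because shuffling resamples universe positions uniformly
#' without replacement, the permutation is performed directly on the
#' universe's precomputed feature labels, which is equivalent and fast.
#'
#' @param sites a `site_set` of called sites.
#' @param annotation a [genome_annotation()].
#' @param genome a `DNAStringSet`.
#' @param n_perm number of shuffles (default 1000).
#' @param seed integer seed.
#' @param universe optional precomputed [shuffle_universe()].
#' @return data frame with `feature`, `m6dA`, `dA`, `fold`, `p_value`
#'   (`fold` is `NA` for features with no dA in the universe).
#' @export
feature_fold_enrichment <- function(sites, annotation, genome,
                                    n_perm = 1000L, seed = 1L,
                                    universe = NULL) {
  stopifnot(is_site_set(sites), n_perm >= 1L)
  universe <- universe %||% shuffle_universe(genome)
  uchrom <- rep(names(universe), vapply(universe, nrow, integer(1)))
  upos <- unlist(lapply(universe, `[[`, "pos"), use.names = FALSE)
  ulab <- label_positions(uchrom, upos, annotation)$feature
  da_f <- table(ulab)

  obs_lab <- assign_features(sites, annotation)$feature
  m_f <- table(obs_lab)
  n <- nrow(sites)
  total_rate <- n / length(ulab)

  fold_of <- function(counts) {
    f <- (as.numeric(counts) / as.numeric(da_f)) / total_rate
    f[as.numeric(da_f) == 0] <- NA_real_
    f
  }
  obs_fold <- fold_of(m_f)

  null_folds <- with_seed(substream_seed(seed, "feature_fold"), {
    vapply(seq_len(n_perm), function(i) {
      lab <- ulab[sample.int(length(ulab), n)]
      fold_of(table(lab))
    }, numeric(length(feature_levels)))
  })

  p <- vapply(seq_along(feature_levels), function(i) {
    if (is.na(obs_fold[i])) return(NA_real_)
    empirical_pvalue(abs(obs_fold[i] - 1), abs(null_folds[i, ] - 1),
                     alternative = "greater")
  }, numeric(1))

  data.frame(feature = feature_levels, m6dA = as.integer(m_f),
             dA = as.integer(da_f), fold = obs_fold, p_value = p,
             stringsAsFactors = FALSE)
}
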