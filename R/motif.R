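check_contexts <- function(ctx, what) {
  if (length(ctx) == 0L) stop(what, " context set is empty", call. = FALSE)
  if (any(nchar(ctx) != 41L)) {
    stop(what, " contexts must be 41 bases", call. = FALSE)
  }
  if (any(substr(ctx, 21L, 21L) != "A")) {
    stop(what, " context with center base != A", call. = FALSE)
  }
  invisible(ctx)
}

# TRUE where the k-mer occurs in the context at an offset covering the
# central methylated A (position 21).
kmer_at_center <- function(ctx, kmer) {
  k <- nchar(kmer)
  hit <- rep(FALSE, length(ctx))
  for (st in (21L - k + 1L):21L) {
    hit <- hit | substr(ctx, st, st + k - 1L) == kmer
  }
  hit
}

#' Dinucleotide enrichment of m6dA sequence contexts
#'
#' A site "has" dinucleotide XY when XY equals either the immediate
#' upstream neighbor followed by the methylated A, or the methylated A
#' followed by the immediate downstream neighbor. Each of the 16
#' dinucleotides is tested by a two-sided Fisher's exact test of presence
#' in the called (foreground) contexts against the failed-filter null
#' contexts. Multiple testing across the 16 motifs is handled by
#' Bonferroni at `alpha` (the `significant` column).
#'
#' @param foreground 41-base contexts of called sites.
#' @param null 41-base contexts of the failed-filter null set.
#' @param alpha family-wise significance level (default 0.05).
#' @return data frame, one row per dinucleotide: presence counts in both
#'   sets, odds ratio, Fisher `p_value`, Bonferroni-adjusted
#'   `p_adjusted`, and `significant`.
#' @export
dinucleotide_enrichment <- function(foreground, null, alpha = 0.05) {
  check_contexts(foreground, "foreground")
  check_contexts(null, "null")
  bases <- c("A", "C", "G", "T")
  motifs <- as.vector(outer(bases, bases, paste0))
  fg_up <- paste0(substr(foreground, 20L, 20L), "A")
  fg_dn <- paste0("A", substr(foreground, 22L, 22L))
  nl_up <- paste0(substr(null, 20L, 20L), "A")
  nl_dn <- paste0("A", substr(null, 22L, 22L))
  res <- lapply(motifs, function(m) {
    fw <- sum(fg_up == m | fg_dn == m)
    nw <- sum(nl_up == m | nl_dn == m)
    tab <- matrix(c(fw, length(foreground) - fw,
                    nw, length(null) - nw), nrow = 2L, byrow = TRUE)
    ft <- fisher_exact(tab)
    data.frame(motif = m, fg_with = fw, fg_without = length(foreground) - fw,
               null_with = nw, null_without = length(null) - nw,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  out$significant <- out$p_adjusted <= alpha
  out[order(out$p_value), ]
}

# All merged (k+1)-mers from ordered pairs of k-mers overlapping by k-1.
merge_kmers <- function(kmers) {
  k <- nchar(kmers[1])
  out <- character(0)
  for (a in kmers) for (b in kmers) {
    if (a != b && substr(a, 2L, k) == substr(b, 1L, k - 1L)) {
      out <- c(out, paste0(a, substr(b, k, k)))
    }
  }
  unique(out)
}

#' Combine overlapping significant dinucleotides into longer motifs
#'
#' Ordered pairs of significant dinucleotides that overlap by one base are
#' merged into 3-mers (GA + AG gives GAG; AG + GA gives AGA); overlapping
#' 3-mers are chained once more into 4-mers. Each combined motif is tested
#' for presence at an offset covering the methylated A (so the motif spans
#' the central base) by the same Fisher contrast of foreground against the
#' failed-filter null set.
#'
#' The exact window construction around the methylated A admits more than
#' one reading; this "merged core covering the central A" form is the
#' package default and a windowed-occurrence mode is available in
#' [motif_presence()].
#'
#' @param dinuc_result output of [dinucleotide_enrichment()].
#' @param foreground,null 41-base context sets.
#' @param alpha significance level selecting dinucleotides to combine.
#' @return data frame like [dinucleotide_enrichment()]'s, one row per
#'   combined motif; zero rows when fewer than two significant
#'   dinucleotides overlap.
#' @export
combine_4mers <- function(dinuc_result, foreground, null, alpha = 0.05) {
  check_contexts(foreground, "foreground")
  check_contexts(null, "null")
  sig <- dinuc_result$motif[dinuc_result$p_adjusted <= alpha]
  empty <- data.frame(motif = character(), fg_with = integer(),
                      fg_without = integer(), null_with = integer(),
                      null_without = integer(), odds_ratio = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (length(sig) < 2L) return(empty)
  cores3 <- merge_kmers(sig)
  cores <- c(cores3, if (length(cores3) >= 2L) merge_kmers(cores3))
  cores <- cores[vapply(cores, function(m) {
    grepl("A", m, fixed = TRUE)
  }, logical(1))]
  if (!length(cores)) return(empty)
  res <- lapply(cores, function(m) {
    fw <- sum(kmer_at_center(foreground, m))
    nw <- sum(kmer_at_center(null, m))
    tab <- matrix(c(fw, length(foreground) - fw,
                    nw, length(null) - nw), nrow = 2L, byrow = TRUE)
    ft <- fisher_exact(tab)
    data.frame(motif = m, fg_with = fw, fg_without = length(foreground) - fw,
               null_with = nw, null_without = length(null) - nw,
               odds_ratio = ft$odds_ratio, p_value = ft$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out[order(out$p_value), ]
}

#' Motif presence in contexts
#'
#' Two modes: `"center"` (default elsewhere in the package) requires the
#' motif to cover the central methylated A; `"window"` accepts an
#' occurrence anywhere in the 41-base context.
#'
#' @param contexts 41-base contexts.
#' @param motif motif string.
#' @param mode `"center"` or `"window"`.
#' @return logical vector.
#' @export
motif_presence <- function(contexts, motif, mode = c("center", "window")) {
  mode <- match.arg(mode)
  check_contexts(contexts, "motif_presence")
  if (mode == "center") {
    kmer_at_center(contexts, motif)
  } else {
    grepl(motif, contexts, fixed = TRUE)
  }
}
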