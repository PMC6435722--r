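#' Expression by m6dA status of a genomic feature
#'
#' Splits genes by whether at least one called m6dA falls in the named
#' feature of the gene (promoter, exon or intron panels; `"any"` pools all
#' genic features) and compares TPM between the groups with a two-sided
#' Wilcoxon rank-sum test. Being rank-based, the comparison is invariant
#' to monotone rescaling of the expression unit.
#'
#' @param expression data frame with `gene_id` and `tpm`.
#' @param assignments result of [assign_features()] on the called sites.
#' @param feature one of `"promoter"`, `"utr5"`, `"utr3"`, `"exon"`,
#'   `"intron"`, `"downstream"`, or `"any"`.
#' @return list with group sizes, medians, and `p_value`.
#' @export
tpm_by_m6dA_status <- function(expression, assignments,
                               feature = c("any", "promoter", "utr5",
                                           "utr3", "exon", "intron",
                                           "downstream")) {
  feature <- match.arg(feature)
  stopifnot(all(c("gene_id", "tpm") %in% names(expression)))
  sel <- if (feature == "any") {
    !is.na(assignments$gene_id)
  } else {
    assignments$feature == feature & !is.na(assignments$gene_id)
  }
  meth_genes <- unique(assignments$gene_id[sel])
  has <- expression$gene_id %in% meth_genes
  if (!any(has) || all(has)) {
    stop("one of the m6dA status groups is empty for feature '", feature,
         "'", call. = FALSE)
  }
  x <- expression$tpm[has]
  y <- expression$tpm[!has]
  rs <- ranksum_test(x, y)
  list(feature = feature, n_with = sum(has), n_without = sum(!has),
       median_with = stats::median(x), median_without = stats::median(y),
       p_value = rs$p_value)
}

#' Allele-specific expression test
#'
#' Per gene with phased allele counts, a two-sided exact binomial test of
#' the haplotype-1 count against an equal 50:50 split, BH-adjusted across
#' tested genes. Genes below the depth floor are not tested (the floor
#' keeps low-information genes from diluting the FDR correction).
#'
#' @param counts data frame with `gene_id`, `hap1_count`, `hap2_count`.
#' @param min_depth minimum total allele count for a gene to be tested
#'   (default 20).
#' @param q_threshold ASE call threshold on the BH q-value (default 0.05).
#' @return list with `table` (per-gene counts, `p_value`, `q_value`,
#'   `ase`) and `ase_genes`.
#' @export
ase_test <- function(counts, min_depth = 20L, q_threshold = 0.05) {
  stopifnot(all(c("gene_id", "hap1_count", "hap2_count") %in%
                  names(counts)))
  if (any(counts$hap1_count < 0 | counts$hap2_count < 0)) {
    stop("negative allele counts", call. = FALSE)
  }
  total <- counts$hap1_count + counts$hap2_count
  tab <- counts[total >= max(1L, min_depth), , drop = FALSE]
  total <- tab$hap1_count + tab$hap2_count
  if (nrow(tab) == 0L) {
    stop("no genes at or above the depth floor", call. = FALSE)
  }
  tab$p_value <- vapply(seq_len(nrow(tab)), function(i) {
    binomial_two_sided(tab$hap1_count[i], total[i])
  }, numeric(1))
  tab$q_value <- bh_adjust(tab$p_value)
  tab$ase <- tab$q_value <= q_threshold
  rownames(tab) <- NULL
  list(table = tab, ase_genes = tab$gene_id[tab$ase])
}

#' Overlap of ASE genes and differentially methylated genes
#'
#' Upper-tail hypergeometric test of the overlap between the
#' allele-specific-expression gene set and the haplotype-differentially
#' methylated gene set within a common gene universe.
#'
#' @param ase_genes character vector of ASE genes.
#' @param diffmeth_genes character vector of differentially methylated
#'   genes.
#' @param universe character vector of all eligible genes.
#' @return list with `overlap`, set sizes, `universe_size`, `p_value`.
#' @export
ase_diffmeth_overlap <- function(ase_genes, diffmeth_genes, universe) {
  ase_genes <- unique(ase_genes)
  diffmeth_genes <- unique(diffmeth_genes)
  universe <- unique(universe)
  if (!all(ase_genes %in% universe) || !all(diffmeth_genes %in% universe)) {
    stop("gene sets must be subsets of the universe", call. = FALSE)
  }
  k <- length(intersect(ase_genes, diffmeth_genes))
  list(overlap = k, n_ase = length(ase_genes),
       n_diffmeth = length(diffmeth_genes),
       universe_size = length(universe),
       p_value = hypergeometric_overlap(length(ase_genes),
                                        length(diffmeth_genes), k,
                                        length(universe)))
}
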