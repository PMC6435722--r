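#' Haplotype-split site calling
#'
#' Applies site calling independently to the HP1-tagged, HP2-tagged and
#' pooled (diploid: tagged plus untagged) molecule sets, then assembles the
#' per-site call table. A site is `included` when it is called in the
#' diploid analysis and has at least `hap_min_coverage` molecules on each
#' haplotype, mirroring the per-haplotig 20x inclusion rule. Untagged
#' molecules contribute to the diploid call only.
#'
#' @param molecules molecule table (see [call_sites()]) with a `haplotype`
#'   column in `{"HP1", "HP2", "untagged"}`.
#' @param params a [calling_params()].
#' @param genome optional `DNAStringSet` for contexts.
#' @param hap_min_coverage per-haplotype coverage floor for inclusion
#'   (default the diploid `min_coverage`).
#' @return list with `diploid`, `hp1`, `hp2` (each a list of `called` and
#'   `null` site_sets plus the raw `sites` summaries) and `table`, the
#'   per-site call table with fractions/coverages for all three analyses,
#'   call flags and the `included` flag.
#' @export
split_and_call_by_haplotype <- function(molecules, params = calling_params(),
                                        genome = NULL,
                                        hap_min_coverage = NULL) {
  stopifnot(is.data.frame(molecules))
  hp <- molecules$haplotype %||% rep("untagged", nrow(molecules))
  if (!any(hp %in% c("HP1", "HP2"))) {
    stop("all molecules untagged: nothing to split by haplotype",
         call. = FALSE)
  }
  hap_min_coverage <- as.integer(hap_min_coverage %||% params$min_coverage)
  call_one <- function(sub) {
    sites <- call_sites(sub, params, genome)
    c(filter_sites(sites, params), list(sites = sites))
  }
  diploid <- call_one(molecules)
  hp1 <- call_one(molecules[hp == "HP1", , drop = FALSE])
  hp2 <- call_one(molecules[hp == "HP2", , drop = FALSE])

  keys <- unique(c(site_key(diploid$sites), site_key(hp1$sites),
                   site_key(hp2$sites)))
  pick <- function(res, keys, col) {
    i <- match(keys, site_key(res$sites))
    res$sites[[col]][i]
  }
  tab <- data.frame(
    key = keys,
    d_fraction = pick(diploid, keys, "meth_fraction"),
    d_coverage = pick(diploid, keys, "coverage"),
    hp1_fraction = pick(hp1, keys, "meth_fraction"),
    hp1_coverage = pick(hp1, keys, "coverage"),
    hp2_fraction = pick(hp2, keys, "meth_fraction"),
    hp2_coverage = pick(hp2, keys, "coverage"),
    called_d = keys %in% site_key(diploid$called),
    called_hp1 = keys %in% site_key(hp1$called),
    called_hp2 = keys %in% site_key(hp2$called),
    stringsAsFactors = FALSE
  )
  tab$hp1_coverage[is.na(tab$hp1_coverage)] <- 0L
  tab$hp2_coverage[is.na(tab$hp2_coverage)] <- 0L
  tab$included <- tab$called_d &
    tab$hp1_coverage >= hap_min_coverage &
    tab$hp2_coverage >= hap_min_coverage
  list(diploid = diploid, hp1 = hp1, hp2 = hp2, table = tab)
}

#' Haplotype exclusivity of m6dA calls
#'
#' Partitions the union of the two per-haplotype call sets into HP1-only,
#' HP2-only and shared sites. When a shuffle universe is supplied, the
#' significance of the observed shared count is assessed by permuting the
#' HP2 calls over the universe `n_perm` times (two-sided would be
#' meaningless here; small overlaps are the interesting tail, so the
#' reported `p_greater` and `p_less` give both directions).
#'
#' @param hp1,hp2 called site_sets for the two haplotypes.
#' @param universe optional [shuffle_universe()].
#' @param n_perm shuffles (default 1000).
#' @param seed integer seed.
#' @return list with `hp1_only`, `hp2_only`, `both`,
#'   `exclusive_fraction`, and permutation p-values when a universe is
#'   given.
#' @export
haplotype_exclusivity <- function(hp1, hp2, universe = NULL,
                                  n_perm = 1000L, seed = 1L) {
  both <- overlap_exact(hp1, hp2)
  out <- list(hp1_only = nrow(hp1) - both, hp2_only = nrow(hp2) - both,
              both = both)
  union_n <- nrow(hp1) + nrow(hp2) - both
  out$exclusive_fraction <- if (union_n > 0) {
    (out$hp1_only + out$hp2_only) / union_n
  } else NA_real_
  if (!is.null(universe) && nrow(hp1) && nrow(hp2)) {
    null <- vapply(seq_len(n_perm), function(i) {
      overlap_exact(hp1, shuffle_sites(hp2, universe,
                                       substream_seed(seed,
                                                      paste0("hexcl", i))))
    }, numeric(1))
    out$p_greater <- empirical_pvalue(both, null, "greater")
    out$p_less <- empirical_pvalue(both, null, "less")
  }
  out
}

#' Regress diploid methylated fraction on haplotype fractions
#'
#' Ordinary least squares of the diploid fraction on the two haplotype
#' fractions with intercept; under balanced haplotype coverage the diploid
#' fraction is the mean of the haplotype fractions and the coefficients
#' recover (0.5, 0.5). Coefficient significance is by two-sided t-test.
#'
#' @param table a haplotype call table (see
#'   [split_and_call_by_haplotype()]) or any data frame with
#'   `d_fraction`, `hp1_fraction`, `hp2_fraction`; only `included` rows
#'   are used when the flag is present.
#' @return list with `coefficients` (summary table) and the fitted `model`.
#' @export
regress_diploid_on_haplotypes <- function(table) {
  df <- as.data.frame(table)
  if (!is.null(df$included)) df <- df[df$included, , drop = FALSE]
  df <- df[stats::complete.cases(
    df[c("d_fraction", "hp1_fraction", "hp2_fraction")]), , drop = FALSE]
  if (nrow(df) < 3L) {
    stop("need at least 3 complete included sites for regression",
         call. = FALSE)
  }
  if (stats::sd(df$hp1_fraction) == 0 || stats::sd(df$hp2_fraction) == 0 ||
      abs(stats::cor(df$hp1_fraction, df$hp2_fraction)) > 0.9999) {
    stop("collinear or degenerate design: haplotype fractions carry no ",
         "independent variation", call. = FALSE)
  }
  fit <- stats::lm(d_fraction ~ hp1_fraction + hp2_fraction, data = df)
  coefs <- summary(fit)$coefficients
  list(coefficients = data.frame(
         term = rownames(coefs), estimate = coefs[, 1],
         std_error = coefs[, 2], t_value = coefs[, 3],
         p_value = coefs[, 4], row.names = NULL,
         stringsAsFactors = FALSE),
       model = fit)
}

#' Differential gene methylation between two samples
#'
#' For each gene, the methylated-cell count (fraction times coverage,
#' rounded half up) and the coverage are summed over the union of
#' methylated positions assigned to the gene in either sample; the two
#' proportions are compared with a continuity-corrected chi-squared test
#' and p-values are BH-adjusted across genes. Genes with zero coverage in
#' a sample are excluded.
#'
#' @param sample_a,sample_b called site_sets for the two samples.
#' @param annotation a [genome_annotation()].
#' @return data frame per gene: methylated counts and coverages in both
#'   samples, proportions, `p_value` and `q_value`.
#' @export
differential_gene_methylation <- function(sample_a, sample_b, annotation) {
  gene_sums <- function(sites, keys) {
    i <- match(keys, site_key(sites))
    j <- ifelse(is.na(i), 1L, i)
    meth <- methylated_cell_count(sites$meth_fraction[j],
                                  sites$coverage[j])
    cov <- sites$coverage[j]
    meth[is.na(i)] <- 0L
    cov[is.na(i)] <- 0L
    list(meth = meth, cov = cov)
  }
  ann_a <- assign_features(sample_a, annotation)
  ann_b <- assign_features(sample_b, annotation)
  keys <- c(site_key(sample_a), site_key(sample_b))
  genes <- c(ann_a$gene_id, ann_b$gene_id)
  keep <- !is.na(genes) & !duplicated(keys)
  keys <- keys[keep]
  genes <- genes[keep]
  if (!length(keys)) {
    stop("no sites assigned to genes in either sample", call. = FALSE)
  }
  sa <- gene_sums(sample_a, keys)
  sb <- gene_sums(sample_b, keys)
  agg <- function(x) as.vector(tapply(x, genes, sum))
  out <- data.frame(
    gene_id = sort(unique(genes)),
    meth_a = agg(sa$meth), cov_a = agg(sa$cov),
    meth_b = agg(sb$meth), cov_b = agg(sb$cov),
    stringsAsFactors = FALSE
  )
  excluded <- out$cov_a == 0L | out$cov_b == 0L
  if (any(excluded)) {
    message(sum(excluded), " gene(s) excluded with zero coverage in one ",
            "sample")
    out <- out[!excluded, , drop = FALSE]
  }
  out$prop_a <- out$meth_a / out$cov_a
  out$prop_b <- out$meth_b / out$cov_b
  out$p_value <- vapply(seq_len(nrow(out)), function(i) {
    proportions_test(c(out$meth_a[i], out$meth_b[i]),
                     c(out$cov_a[i], out$cov_b[i]))$p_value
  }, numeric(1))
  out$q_value <- bh_adjust(out$p_value)
  rownames(out) <- NULL
  out
}

#' Family-trio m6dA overlap and relatedness analysis
#'
#' Each family member's candidate sites are filtered with a per-individual
#' coverage threshold of half the member's total sequencing coverage,
#' rounded half up (SMRT coverage is strand-specific, so a strand sees half
#' the total), and the common IPD-ratio filter. Pairwise exact overlaps of
#' the called sets are tested by permutation: equal-size random site sets
#' are drawn from each member's failed-filter pool `n_perm` times. The
#' relatedness question — is the parent-child overlap larger than the
#' parent-parent overlap? — is answered per parent by the asymmetric
#' two-proportion test: overlap(mother, father)/n(parent) against
#' overlap(parent, son)/n(son), which accounts for the son's larger call
#' set.
#'
#' @param members named list of three raw `site_set`s: `mother`, `father`,
#'   `son`, carrying coverage and IPD ratios.
#' @param total_coverages named numeric vector of each member's total
#'   sequencing coverage (e.g. `c(mother = 27, father = 29, son = 67)`).
#' @param params base [calling_params()]; per-member coverage thresholds
#'   override `min_coverage`.
#' @param coverage_filters optional named integer vector overriding the
#'   derived per-member thresholds.
#' @param n_perm permutations for overlap significance; `0` skips the
#'   permutation test.
#' @param seed integer seed.
#' @return list with `called` (named list of filtered site_sets), `totals`,
#'   `pair_overlap` (data frame with counts and permutation p), and
#'   `relatedness` (data frame, one row per parent).
#' @export
trio_analysis <- function(members, total_coverages,
                          params = calling_params(),
                          coverage_filters = NULL, n_perm = 1000L,
                          seed = 1L) {
  stopifnot(all(c("mother", "father", "son") %in% names(members)))
  who <- c("mother", "father", "son")
  filters <- coverage_filters %||%
    stats::setNames(round_half_up(total_coverages[who] / 2), who)
  split <- lapply(who, function(w) {
    p <- params
    p$min_coverage <- as.integer(filters[[w]])
    p$null_min_coverage <- min(p$null_min_coverage, p$min_coverage)
    filter_sites(members[[w]], p)
  })
  names(split) <- who
  called <- lapply(split, `[[`, "called")
  pools <- lapply(split, `[[`, "null")
  for (w in who) {
    if (nrow(pools[[w]]) < nrow(called[[w]])) {
      stop(sprintf("failed-filter pool for %s (%d) smaller than call set ",
                   w, nrow(pools[[w]])),
           sprintf("(%d)", nrow(called[[w]])), call. = FALSE)
    }
  }
  pairs <- list(c("mother", "father"), c("mother", "son"),
                c("father", "son"))
  ov <- vapply(pairs, function(p) {
    overlap_exact(called[[p[1]]], called[[p[2]]])
  }, numeric(1))
  pv <- rep(NA_real_, length(pairs))
  if (n_perm >= 1L) {
    draw <- function(w, i) {
      pool <- pools[[w]]
      k <- nrow(called[[w]])
      with_seed(substream_seed(seed, paste0("trio_", w, "_", i)), {
        pool[sample.int(nrow(pool), k), , drop = FALSE]
      })
    }
    null <- vapply(seq_len(n_perm), function(i) {
      sets <- lapply(who, draw, i = i)
      names(sets) <- who
      vapply(pairs, function(p) {
        length(intersect(site_key(sets[[p[1]]]), site_key(sets[[p[2]]])))
      }, numeric(1))
    }, numeric(length(pairs)))
    pv <- vapply(seq_along(pairs), function(j) {
      empirical_pvalue(ov[j], null[j, ], "greater")
    }, numeric(1))
  }
  totals <- vapply(called, nrow, integer(1))
  ov_mf <- ov[1]; ov_ms <- ov[2]; ov_fs <- ov[3]
  rel <- do.call(rbind, list(
    data.frame(parent = "mother",
               prop_parents = ov_mf / totals[["mother"]],
               prop_child = ov_ms / totals[["son"]],
               p_value = proportions_test(
                 c(ov_mf, ov_ms),
                 c(totals[["mother"]], totals[["son"]]))$p_value,
               stringsAsFactors = FALSE),
    data.frame(parent = "father",
               prop_parents = ov_mf / totals[["father"]],
               prop_child = ov_fs / totals[["son"]],
               p_value = proportions_test(
                 c(ov_mf, ov_fs),
                 c(totals[["father"]], totals[["son"]]))$p_value,
               stringsAsFactors = FALSE)
  ))
  list(called = called, pools = pools, totals = totals,
       coverage_filters = filters,
       pair_overlap = data.frame(
         pair = vapply(pairs, paste, "", collapse = "-"),
         overlap = as.integer(ov), p_value = pv,
         stringsAsFactors = FALSE),
       relatedness = rel)
}
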