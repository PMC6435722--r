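#' Simulation configuration
#'
#' Parameters of the ground-truthed synthetic dataset generator. One master
#' `seed` drives independent named substreams per stage
#' ([substream_seed()]), so regenerating one stage never perturbs another.
#'
#' The defaults describe a desk-scale genome with the statistical structure
#' the analysis assumes: a small multi-chromosome genome with annotated
#' genes; m6dA planted on strand-specific adenosines with feature bias
#' (enriched in genic features, depleted intergenic) and AG/GA motif bias;
#' a per-site methylated-fraction mixture with a spike at 1.0
#' (`fraction_spike`) over a broad Beta body; AT-rich dense clusters;
#' log-normal per-molecule IPDs whose methylated log-shift `delta` puts
#' fully methylated sites at an expected IPD ratio of `exp(delta) >= 4`;
#' haplotype-restricted methylation; trio inheritance over a conserved
#' common pool; and expression positively tied to genic m6dA with
#' allele-specific expression linked to haplotype-differential methylation.
#'
#' @param seed master integer seed.
#' @param chrom_sizes named integer vector of chromosome lengths.
#' @param n_genes number of genes to pack (non-overlapping).
#' @param exons_per_gene,exon_size,intron_size integer ranges (min, max).
#' @param utr5_size,utr3_size UTR widths carved from terminal exons.
#' @param gc_content background GC fraction.
#' @param m6dA_density planted sites per strand-specific dA.
#' @param fraction_spike weight of the spike at fraction 1.0.
#' @param fraction_beta shape parameters of the Beta body.
#' @param motif_bias odds multiplier for AG/GA contexts.
#' @param feature_bias named placement-odds multipliers over features.
#' @param n_clusters,cluster_span,cluster_sites,cluster_at dense-cluster
#'   count, span (bp), sites per span, and A/T fraction of cluster
#'   sequence.
#' @param cluster_fraction_beta Beta parameters for cluster-site fractions
#'   (shifted low: clustered m6dA are less homogeneously methylated).
#' @param coverage_mean,coverage_min per-site molecule coverage model
#'   (Poisson mean with a lower clamp).
#' @param n_passes circular-consensus passes per molecule.
#' @param mu0,sigma,delta log-IPD kinetic model (see [calling_params()]).
#' @param spot_check_density unmethylated dA emitted per universe position
#'   (the failed-filter/null material).
#' @param snp_rate heterozygous SNP rate for phasing.
#' @param tag_rate fraction of molecules carrying a haplotype tag.
#' @param hap_restricted proportion of haplotype sites methylated on
#'   exactly one haplotype.
#' @param hap_n_sites number of sites in the haplotype simulation.
#' @param trio_inheritance probability the child inherits a parental site.
#' @param trio_n_sites called sites per family member.
#' @param trio_conserved,trio_conserved_p size of the conserved common
#'   site pool and each member's inclusion probability (the above-chance
#'   baseline overlap between unrelated individuals).
#' @param trio_pool_factor failed-filter pool size as a multiple of the
#'   call-set size.
#' @param expr_baseline,expr_effect,expr_sd log-TPM model: baseline, added
#'   effect when a gene carries m6dA, and noise SD.
#' @param ase_depth,ase_bias,ase_link allele-count depth, hap1 share in
#'   ASE genes, and the probability an ASE gene is drawn from the
#'   differentially methylated set.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_sizes = c(chr1 = 200000L, chr2 = 200000L,
                                       chr3 = 200000L),
                       n_genes = 45L,
                       exons_per_gene = c(2L, 6L),
                       exon_size = c(150L, 400L),
                       intron_size = c(200L, 1500L),
                       utr5_size = 50L, utr3_size = 100L,
                       gc_content = 0.41,
                       m6dA_density = 2e-3,
                       fraction_spike = 0.15,
                       fraction_beta = c(2, 2),
                       motif_bias = 1,
                       feature_bias = c(promoter = 2, utr5 = 1.5,
                                        utr3 = 1.5, exon = 2, intron = 1.5,
                                        downstream = 1, intergenic = 0.5),
                       n_clusters = 6L, cluster_span = 500L,
                       cluster_sites = 12L, cluster_at = 0.67,
                       cluster_fraction_beta = c(2, 4),
                       coverage_mean = 40, coverage_min = 5L,
                       n_passes = 10L,
                       mu0 = 0, sigma = 0.5, delta = log(6),
                       spot_check_density = 1e-3,
                       snp_rate = 1e-3, tag_rate = 0.8,
                       hap_restricted = 0.7, hap_n_sites = 600L,
                       trio_inheritance = 0.5, trio_n_sites = 2000L,
                       trio_conserved = 200L, trio_conserved_p = 0.5,
                       trio_pool_factor = 3,
                       expr_baseline = 2, expr_effect = 1, expr_sd = 1,
                       ase_depth = 100L, ase_bias = 0.8, ase_link = 1) {
  cfg <- as.list(environment())
  probs <- c(gc_content, fraction_spike, spot_check_density, snp_rate,
             tag_rate, hap_restricted, trio_inheritance, trio_conserved_p,
             ase_bias, ase_link, m6dA_density)
  if (any(probs < 0 | probs > 1)) {
    stop("all probability parameters must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(sigma > 0, delta > 0, coverage_mean > 0,
            all(chrom_sizes > 0), n_passes >= 1)
  structure(cfg, class = "sim_config")
}

sample_range <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

#' Generate a synthetic genome and annotation
#'
#' Draws random chromosome sequences at the configured GC content, packs
#' non-overlapping genes (exons separated by introns, terminal-exon UTRs),
#' and rewrites a set of intergenic cluster regions with elevated A/T
#' content. Deterministic per seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (`DNAStringSet`), `annotation`
#'   ([genome_annotation()]), and `truth` (gene table and cluster regions).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "genome"), {
    sizes <- config$chrom_sizes
    p <- base_probs(config$gc_content)
    seqs <- lapply(sizes, function(L) {
      paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(sizes)

    # pack genes left to right with random intergenic gaps
    genes <- list()
    exons <- list()
    gid <- 0L
    per_chrom <- table(factor(
      rep(names(sizes), length.out = config$n_genes), names(sizes)))
    for (chrom in names(sizes)) {
      want <- per_chrom[[chrom]]
      cursor <- 2000L
      placed <- 0L
      while (placed < want) {
        n_ex <- sample_range(1L, config$exons_per_gene)
        ex_w <- sample_range(n_ex, config$exon_size)
        in_w <- if (n_ex > 1L) sample_range(n_ex - 1L, config$intron_size)
                else integer(0)
        span <- sum(ex_w) + sum(in_w)
        gap <- sample(2000:6000, 1L)
        start <- cursor + gap
        if (start + span + 2000L > sizes[[chrom]]) {
          stop(sprintf(
            "infeasible gene packing: only %d of %d genes fit on %s",
            placed, want, chrom), call. = FALSE)
        }
        gid <- gid + 1L
        id <- sprintf("gene%03d", gid)
        strand <- sample(c("+", "-"), 1L)
        ex_start <- start + cumsum(c(0L, utils::head(ex_w, -1L) + in_w))
        genes[[id]] <- data.frame(
          gene_id = id, chrom = chrom, strand = strand, start = start,
          end = start + span - 1L, stringsAsFactors = FALSE)
        exons[[id]] <- data.frame(
          gene_id = id, chrom = chrom, start = as.integer(ex_start),
          end = as.integer(ex_start + ex_w - 1L), stringsAsFactors = FALSE)
        cursor <- start + span
        placed <- placed + 1L
      }
    }
    tx <- if (length(genes)) do.call(rbind, genes) else {
      data.frame(gene_id = character(), chrom = character(),
                 strand = character(), start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    }
    ex <- if (length(exons)) do.call(rbind, exons) else {
      data.frame(gene_id = character(), chrom = character(),
                 start = integer(), end = integer(),
                 stringsAsFactors = FALSE)
    }
    rownames(tx) <- rownames(ex) <- NULL

    # UTRs carved from the terminal exons, strand-aware
    utr5 <- utr3 <- list()
    for (id in tx$gene_id) {
      e <- ex[ex$gene_id == id, , drop = FALSE]
      g <- tx[tx$gene_id == id, ]
      first <- e[which.min(e$start), ]
      last <- e[which.max(e$end), ]
      w5 <- min(config$utr5_size, first$end - first$start)
      w3 <- min(config$utr3_size, last$end - last$start)
      if (g$strand == "+") {
        utr5[[id]] <- data.frame(gene_id = id, chrom = g$chrom,
                                 start = first$start,
                                 end = first$start + w5 - 1L)
        utr3[[id]] <- data.frame(gene_id = id, chrom = g$chrom,
                                 start = last$end - w3 + 1L, end = last$end)
      } else {
        utr5[[id]] <- data.frame(gene_id = id, chrom = g$chrom,
                                 start = last$end - w5 + 1L, end = last$end)
        utr3[[id]] <- data.frame(gene_id = id, chrom = g$chrom,
                                 start = first$start,
                                 end = first$start + w3 - 1L)
      }
    }
    bindf <- function(l) if (length(l)) do.call(rbind, l) else NULL

    # AT-rich cluster regions in intergenic space, rewritten in place
    cluster_regions <- NULL
    if (config$n_clusters > 0L) {
      occupied <- GenomicRanges::GRanges(
        factor(tx$chrom, names(sizes)),
        IRanges::IRanges(pmax(1L, tx$start - 2500L), tx$end + 2500L))
      regions <- list()
      tries <- 0L
      while (length(regions) < config$n_clusters && tries < 2000L) {
        tries <- tries + 1L
        chrom <- sample(names(sizes), 1L)
        start <- sample.int(sizes[[chrom]] - config$cluster_span - 100L, 1L)
        cand <- GenomicRanges::GRanges(
          factor(chrom, names(sizes)),
          IRanges::IRanges(start, start + config$cluster_span - 1L))
        prev <- if (length(regions)) {
          do.call(c, regions)
        } else GenomicRanges::GRanges()
        if (length(occupied) &&
            any(IRanges::overlapsAny(cand, occupied))) next
        if (length(prev) && any(IRanges::overlapsAny(cand + 600L, prev))) {
          next
        }
        regions[[length(regions) + 1L]] <- cand
      }
      if (length(regions) < config$n_clusters) {
        stop("could not place the requested cluster regions", call. = FALSE)
      }
      at <- config$cluster_at
      pc <- c(A = at / 2, C = (1 - at) / 2, G = (1 - at) / 2, T = at / 2)
      glist <- as.list(as.character(genome))
      for (r in regions) {
        chrom <- as.character(GenomeInfoDb::seqnames(r))
        st <- GenomicRanges::start(r)
        en <- GenomicRanges::end(r)
        repl <- paste(sample(names(pc), en - st + 1L, replace = TRUE,
                             prob = pc), collapse = "")
        s <- glist[[chrom]]
        glist[[chrom]] <- paste0(substr(s, 1L, st - 1L), repl,
                                 substr(s, en + 1L, nchar(s)))
      }
      genome <- Biostrings::DNAStringSet(unlist(glist))
      names(genome) <- names(sizes)
      rg <- do.call(c, regions)
      cluster_regions <- data.frame(
        chrom = as.character(GenomeInfoDb::seqnames(rg)),
        start = GenomicRanges::start(rg), end = GenomicRanges::end(rg),
        stringsAsFactors = FALSE)
    }

    annotation <- genome_annotation(tx, ex, bindf(utr5), bindf(utr3),
                                    seqlengths = sizes)
    list(genome = genome, annotation = annotation,
         truth = list(genes = tx, cluster_regions = cluster_regions))
  })
}

# neighbor bases of strand-specific dA positions, read on the site strand
strand_neighbors <- function(seq_chars, pos, strand) {
  n <- length(seq_chars)
  up_pos <- ifelse(strand == "+", pos - 1L, pos + 1L)
  dn_pos <- ifelse(strand == "+", pos + 1L, pos - 1L)
  grab <- function(p) {
    out <- rep("N", length(p))
    ok <- p >= 1L & p <= n
    out[ok] <- seq_chars[p[ok]]
    out
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  up <- grab(up_pos)
  dn <- grab(dn_pos)
  neg <- strand == "-"
  up[neg] <- comp[up[neg]]
  dn[neg] <- comp[dn[neg]]
  list(up = up, down = dn)
}

#' Plant true m6dA sites on a synthetic genome
#'
#' Sites are placed only on strand-specific adenosines. Placement odds are
#' multiplied by the configured feature bias of the position's label and by
#' `motif_bias` when the immediate-neighbor dinucleotide is GA or AG. True
#' methylated fractions are drawn from the spike-plus-Beta mixture;
#' designated cluster regions additionally receive `cluster_sites` sites
#' per span with low-shifted fractions.
#'
#' @param sim result of [generate_genome()].
#' @param config a [sim_config()].
#' @return data frame of true sites: `chrom`, `pos`, `strand`,
#'   `true_fraction`, `feature`, `motif` (AG/GA flag), `in_cluster`,
#'   `context`.
#' @export
plant_m6dA <- function(sim, config) {
  genome <- sim$genome
  annotation <- sim$annotation
  with_seed(substream_seed(config$seed, "plant"), {
    universe <- shuffle_universe(genome)
    udf <- do.call(rbind, lapply(names(universe), function(chrom) {
      u <- universe[[chrom]]
      nb <- strand_neighbors(strsplit(as.character(genome[[chrom]]),
                                      "")[[1]], u$pos, u$strand)
      data.frame(chrom = chrom, pos = u$pos, strand = u$strand,
                 motif = nb$up == "G" | nb$down == "G",
                 stringsAsFactors = FALSE)
    }))
    udf$feature <- label_positions(udf$chrom, udf$pos, annotation)$feature
    fb <- config$feature_bias[as.character(udf$feature)]
    w <- fb * ifelse(udf$motif, config$motif_bias, 1)
    n_sites <- round_half_up(config$m6dA_density * nrow(udf))
    if (n_sites > nrow(udf)) {
      stop("m6dA density too high for available dA positions",
           call. = FALSE)
    }
    pick <- sample.int(nrow(udf), n_sites, prob = w)
    sites <- udf[pick, , drop = FALSE]
    sites$in_cluster <- FALSE
    spike <- stats::runif(n_sites) < config$fraction_spike
    frac <- stats::rbeta(n_sites, config$fraction_beta[1],
                         config$fraction_beta[2])
    frac[spike] <- 1
    sites$true_fraction <- frac

    cl <- sim$truth$cluster_regions
    if (!is.null(cl) && nrow(cl)) {
      extra <- lapply(seq_len(nrow(cl)), function(i) {
        inside <- udf$chrom == cl$chrom[i] & udf$pos >= cl$start[i] &
          udf$pos <= cl$end[i]
        idx <- which(inside)
        k <- min(length(idx), config$cluster_sites)
        sel <- udf[sample(idx, k), , drop = FALSE]
        sel$in_cluster <- TRUE
        sel$true_fraction <- stats::rbeta(
          k, config$cluster_fraction_beta[1],
          config$cluster_fraction_beta[2])
        sel
      })
      sites <- rbind(sites, do.call(rbind, extra))
    }
    sites <- sites[!duplicated(paste(sites$chrom, sites$pos,
                                     sites$strand)), , drop = FALSE]
    sites <- sites[order(sites$chrom, sites$pos, sites$strand), ,
                   drop = FALSE]
    rownames(sites) <- NULL
    sites$context <- extract_context(genome, sites$chrom, sites$pos,
                                     sites$strand)
    sites[c("chrom", "pos", "strand", "true_fraction", "feature", "motif",
            "in_cluster", "context")]
  })
}

simulate_molecules_at <- function(pos_df, fractions, config,
                                  coverage = NULL, prefix = "mol") {
  n <- nrow(pos_df)
  cov <- coverage %||%
    pmax(config$coverage_min, stats::rpois(n, config$coverage_mean))
  total <- sum(cov)
  idx <- rep.int(seq_len(n), cov)
  z <- stats::rbinom(total, 1L, fractions[idx])
  mean_log_ipd <- stats::rnorm(
    total, config$mu0 + z * config$delta,
    config$sigma / sqrt(config$n_passes))
  data.frame(
    chrom = pos_df$chrom[idx], pos = pos_df$pos[idx],
    strand = pos_df$strand[idx],
    molecule_id = paste0(prefix, seq_len(total)),
    mean_log_ipd = mean_log_ipd, n_passes = config$n_passes,
    methylated = as.logical(z),
    stringsAsFactors = FALSE)
}

#' Simulate per-molecule kinetics for true sites
#'
#' Every molecule covering a site is methylated with probability equal to
#' the site's true fraction; methylated molecules draw their mean log IPD
#' from `Normal(mu0 + delta, sigma^2 / n_passes)` and unmethylated ones
#' from `Normal(mu0, sigma^2 / n_passes)`. Unmethylated spot-check
#' positions are emitted at `spot_check_density` over the dA universe with
#' a broad coverage range, supplying the failed-filter material the motif
#' null set and trio permutation pools are built from. Per-site summaries
#' are produced by [call_sites()] (coverage, IPD ratio, EM fraction).
#'
#' @param truth true site table from [plant_m6dA()].
#' @param sim result of [generate_genome()] (for contexts and the
#'   universe).
#' @param config a [sim_config()].
#' @return list with `molecules` (per-molecule table) and `sites`
#'   (unfiltered per-site summary `site_set`).
#' @export
simulate_kinetics <- function(truth, sim, config) {
  with_seed(substream_seed(config$seed, "kinetics"), {
    mols <- simulate_molecules_at(truth, truth$true_fraction, config,
                                  prefix = "m")
    universe <- shuffle_universe(sim$genome)
    usize <- sum(vapply(universe, nrow, integer(1)))
    n_spot <- round_half_up(config$spot_check_density * usize)
    if (n_spot > 0L) {
      udf <- do.call(rbind, lapply(names(universe), function(chrom) {
        cbind(chrom = chrom, universe[[chrom]])
      }))
      udf <- udf[!paste(udf$chrom, udf$pos, udf$strand) %in%
                   paste(truth$chrom, truth$pos, truth$strand), ,
                 drop = FALSE]
      spots <- udf[sample.int(nrow(udf), min(n_spot, nrow(udf))), ,
                   drop = FALSE]
      # wide coverage range so the spot checks populate the null set
      spot_cov <- pmax(1L, stats::rpois(nrow(spots),
                                        config$coverage_mean / 2))
      mols <- rbind(mols,
                    simulate_molecules_at(spots, rep(0, nrow(spots)),
                                          config, coverage = spot_cov,
                                          prefix = "s"))
    }
    params <- calling_params(mu0 = config$mu0, sigma = config$sigma,
                             delta = config$delta)
    sites <- call_sites(mols, params, genome = sim$genome)
    list(molecules = mols, sites = sites)
  })
}

#' Simulate phased haplotypes with haplotype-restricted methylation
#'
#' Picks sites on the dA universe and makes a configured proportion of
#' them methylated on exactly one haplotype (the rest methylated on
#' both). Haplotype methylation status is binary: a haplotype is a single
#' chromosome copy, so a mark present on it is carried by every molecule
#' from that copy. Tagged molecules are simulated per haplotype (each
#' molecule comes from HP1 or HP2 with equal probability and keeps its
#' tag with probability `tag_rate`), along with a phased heterozygous SNP
#' table for plumbing.
#'
#' @param sim result of [generate_genome()].
#' @param config a [sim_config()]; `snp_rate` must be positive.
#' @return list with `molecules` (tagged molecule table), `snps` (phased
#'   SNP data frame), and `truth` (per-site haplotype fractions and the
#'   restriction flag).
#' @export
simulate_haplotypes <- function(sim, config) {
  if (config$snp_rate <= 0) {
    stop("snp_rate must be positive when haplotyping is simulated ",
         "(no phasing information otherwise)", call. = FALSE)
  }
  genome <- sim$genome
  with_seed(substream_seed(config$seed, "haplotypes"), {
    # phased heterozygous SNPs
    snps <- do.call(rbind, lapply(names(genome), function(chrom) {
      L <- Biostrings::width(genome[chrom])
      n <- stats::rbinom(1L, L, config$snp_rate)
      pos <- sort(sample.int(L, n))
      ref <- substring(as.character(genome[[chrom]]), pos, pos)
      alt <- vapply(ref, function(r) {
        sample(setdiff(c("A", "C", "G", "T"), r), 1L)
      }, "")
      data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
                 genotype = "0|1", stringsAsFactors = FALSE)
    }))
    rownames(snps) <- NULL

    universe <- shuffle_universe(genome)
    udf <- do.call(rbind, lapply(names(universe), function(chrom) {
      cbind(chrom = chrom, universe[[chrom]])
    }))
    n <- min(config$hap_n_sites, nrow(udf))
    sel <- udf[sample.int(nrow(udf), n), , drop = FALSE]
    # haplotype methylation status is binary: one haplotype is one
    # chromosome copy, so a mark present on it is carried by every
    # molecule originating from that copy; population heterogeneity
    # enters through the restricted/shared mixture and molecule noise
    restricted <- stats::runif(n) < config$hap_restricted
    on_hp1 <- stats::runif(n) < 0.5
    f1 <- ifelse(restricted & !on_hp1, 0, 1)
    f2 <- ifelse(restricted & on_hp1, 0, 1)

    cov <- pmax(2L * config$coverage_min,
                stats::rpois(n, 2 * config$coverage_mean))
    total <- sum(cov)
    idx <- rep.int(seq_len(n), cov)
    hp <- stats::rbinom(total, 1L, 0.5) + 1L          # molecule haplotype
    f_mol <- ifelse(hp == 1L, f1[idx], f2[idx])
    z <- stats::rbinom(total, 1L, f_mol)
    mols <- data.frame(
      chrom = sel$chrom[idx], pos = sel$pos[idx], strand = sel$strand[idx],
      molecule_id = paste0("h", seq_len(total)),
      mean_log_ipd = stats::rnorm(total, config$mu0 + z * config$delta,
                                  config$sigma / sqrt(config$n_passes)),
      n_passes = config$n_passes,
      haplotype = ifelse(stats::runif(total) < config$tag_rate,
                         paste0("HP", hp), "untagged"),
      stringsAsFactors = FALSE)
    truth <- data.frame(chrom = sel$chrom, pos = sel$pos,
                        strand = sel$strand, hp1_fraction = f1,
                        hp2_fraction = f2, restricted = restricted,
                        stringsAsFactors = FALSE)
    rownames(truth) <- NULL
    list(molecules = mols, snps = snps, truth = truth)
  })
}

# site table whose rows pass (called) or fail (pool) the coverage/IPD
# filters by construction
make_member_table <- function(called_pos, pool_pos, filter_cov, config) {
  mk <- function(df, cov, ratio, frac) {
    data.frame(chrom = df$chrom, pos = df$pos, strand = df$strand,
               coverage = cov, ipd_ratio = ratio, meth_fraction = frac,
               context = NA_character_, stringsAsFactors = FALSE)
  }
  nc <- nrow(called_pos)
  np <- nrow(pool_pos)
  spike <- stats::runif(nc) < config$fraction_spike
  frac <- stats::rbeta(nc, config$fraction_beta[1], config$fraction_beta[2])
  frac[spike] <- 1
  called <- mk(called_pos,
               filter_cov + stats::rpois(nc, 10),
               exp(config$delta + stats::rnorm(nc, 0, 0.05)),
               frac)
  # pool rows keep >= 11x coverage but fail the IPD-ratio filter
  pool <- mk(pool_pos,
             sample(11:max(12L, filter_cov + 10L), np, replace = TRUE),
             exp(stats::rnorm(np, 0, 0.3)),
             stats::rbeta(np, 1, 4))
  tab <- rbind(called, pool)
  tab <- tab[!duplicated(paste(tab$chrom, tab$pos, tab$strand)), ,
             drop = FALSE]
  as_site_set(tab)
}

#' Simulate a family trio of m6dA site tables
#'
#' Parents draw their called sites from the dA universe plus a conserved
#' common pool (the above-chance overlap of unrelated individuals); the
#' child inherits each parental site independently with probability
#' `trio_inheritance` and fills up with independent noise sites. Each
#' member also gets a failed-filter pool (adequate coverage, low IPD
#' ratio) for the permutation null of [trio_analysis()].
#'
#' @param sim result of [generate_genome()].
#' @param config a [sim_config()].
#' @param total_coverages named total sequencing coverages; the derived
#'   per-member strand-specific filter is half, rounded half up.
#' @return list with `members` (named raw site_sets), `total_coverages`,
#'   and `truth` (conserved/inherited keys).
#' @export
simulate_trio <- function(sim, config,
                          total_coverages = c(mother = 27, father = 29,
                                              son = 67),
                          universe = NULL) {
  genome <- sim$genome
  universe <- universe %||% shuffle_universe(genome)
  with_seed(substream_seed(config$seed, "trio"), {
    udf <- do.call(rbind, lapply(names(universe), function(chrom) {
      cbind(chrom = chrom, universe[[chrom]])
    }))
    ukey <- paste(udf$chrom, udf$pos, udf$strand)
    n <- config$trio_n_sites
    conserved <- sample.int(nrow(udf), config$trio_conserved)

    draw_parent <- function() {
      take <- conserved[stats::runif(length(conserved)) <
                          config$trio_conserved_p]
      rest <- sample(setdiff(seq_len(nrow(udf)), take),
                     max(0L, n - length(take)))
      sort(unique(c(take, rest)))
    }
    mother <- draw_parent()
    father <- draw_parent()
    inh_m <- mother[stats::runif(length(mother)) < config$trio_inheritance]
    inh_f <- father[stats::runif(length(father)) < config$trio_inheritance]
    # the son is distributed like a parent (conserved pool + independent
    # noise) with inherited parental sites layered on top, so zero
    # inheritance makes parent-son overlap exchangeable with parent-parent
    son_base <- draw_parent()
    inh <- unique(c(inh_m, inh_f))
    son <- if (length(inh) >= n) {
      sort(sample(inh, n))
    } else {
      sort(unique(c(inh, sample(setdiff(son_base, inh),
                                n - length(inh)))))
    }

    picks <- list(mother = mother, father = father, son = son)
    members <- lapply(names(picks), function(w) {
      filt <- round_half_up(total_coverages[[w]] / 2)
      pool_n <- round_half_up(config$trio_pool_factor * length(picks[[w]]))
      pool <- sample(setdiff(seq_len(nrow(udf)), picks[[w]]), pool_n)
      make_member_table(udf[picks[[w]], , drop = FALSE],
                        udf[pool, , drop = FALSE], filt, config)
    })
    names(members) <- names(picks)
    list(members = members, total_coverages = total_coverages,
         truth = list(conserved = ukey[conserved],
                      inherited_from_mother = ukey[inh_m],
                      inherited_from_father = ukey[inh_f]))
  })
}

#' Simulate gene expression tied to m6dA status
#'
#' Log TPM is `expr_baseline + expr_effect * has_m6dA + noise`; phased
#' allele counts are binomial at depth `ase_depth` with hap1 share
#' `ase_bias` for ASE genes and 0.5 otherwise. ASE genes are drawn from
#' the differentially methylated set with probability `ase_link` (and
#' from the remaining genes otherwise), which plants the overlap between
#' allele-specific expression and haplotype-differential methylation.
#'
#' @param genes character vector of gene ids.
#' @param has_m6dA logical vector: does the gene carry at least one m6dA?
#' @param config a [sim_config()].
#' @param diffmeth_genes genes with haplotype-differential methylation.
#' @param n_ase number of ASE genes (default 20% of genes, capped by
#'   availability).
#' @return list with `expression` (gene_id, tpm, hap1_count, hap2_count)
#'   and `truth` (`ase_genes`).
#' @export
simulate_expression <- function(genes, has_m6dA, config,
                                diffmeth_genes = character(),
                                n_ase = NULL) {
  stopifnot(length(genes) == length(has_m6dA))
  with_seed(substream_seed(config$seed, "expression"), {
    n <- length(genes)
    log_tpm <- config$expr_baseline + config$expr_effect * has_m6dA +
      stats::rnorm(n, 0, config$expr_sd)
    n_ase <- n_ase %||% max(1L, round_half_up(0.2 * n))
    n_ase <- min(n_ase, n)
    from_dm <- stats::runif(n_ase) < config$ase_link
    n_dm <- min(sum(from_dm), length(diffmeth_genes))
    pool_other <- setdiff(genes, diffmeth_genes)
    n_other <- min(n_ase - n_dm, length(pool_other))
    ase_genes <- c(
      if (n_dm > 0L) sample(diffmeth_genes, n_dm),
      if (n_other > 0L) sample(pool_other, n_other))
    p1 <- ifelse(genes %in% ase_genes, config$ase_bias, 0.5)
    hap1 <- stats::rbinom(n, config$ase_depth, p1)
    list(expression = data.frame(
           gene_id = genes, tpm = exp(log_tpm), hap1_count = hap1,
           hap2_count = config$ase_depth - hap1,
           stringsAsFactors = FALSE),
         truth = list(ase_genes = ase_genes))
  })
}

#' Simulate a complete dataset bundle on disk
#'
#' Runs every generator stage under one seed and writes the bundle:
#' `genome.fa`, `annotation.gff3`, `kinetics.tsv` (tabular site
#' summaries), `molecules.tsv`, `hap_molecules.tsv`, `snps.tsv`,
#' `expression.tsv` and `truth.json`. Every file re-parses through the
#' package readers.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisible list of the in-memory pieces.
#' @export
simulate_dataset <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_genome(config)
  truth <- plant_m6dA(sim, config)
  kin <- simulate_kinetics(truth, sim, config)
  hap <- simulate_haplotypes(sim, config)
  ann <- sim$annotation
  called <- filter_sites(kin$sites, calling_params(
    mu0 = config$mu0, sigma = config$sigma, delta = config$delta))$called
  assignments <- assign_features(called, ann)
  genes <- ann$transcripts$gene_id
  has <- genes %in% assignments$gene_id
  expr <- simulate_expression(genes, has, config)

  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  write_annotation(ann, file.path(dir, "annotation.gff3"))
  write_modifications(kin$sites, file.path(dir, "kinetics.tsv"), "tabular")
  utils::write.table(kin$molecules, file.path(dir, "molecules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(hap$molecules, file.path(dir, "hap_molecules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(hap$snps, file.path(dir, "snps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(expr$expression, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(config),
         genes = sim$truth$genes,
         cluster_regions = sim$truth$cluster_regions,
         sites = truth[c("chrom", "pos", "strand", "true_fraction",
                         "feature", "motif", "in_cluster")],
         haplotype_sites = hap$truth,
         ase_genes = expr$truth$ase_genes),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(list(sim = sim, truth = truth, kinetics = kin,
                 haplotypes = hap, expression = expr))
}
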