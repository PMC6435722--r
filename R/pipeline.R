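#' Pipeline configuration
#'
#' Paths, parameters and stage toggles for [run_pipeline()]. Either point
#' the config at existing inputs (`genome`, `annotation`, `kinetics`
#' tabular site summaries, optional `hap_molecules` and `expression`
#' tables) or set `simulate = TRUE` to generate the bundle first.
#'
#' @param out_dir output directory.
#' @param genome,annotation,kinetics,hap_molecules,expression input paths
#'   (ignored when `simulate = TRUE`).
#' @param simulate generate inputs with [simulate_dataset()] first.
#' @param sim a [sim_config()] used when simulating.
#' @param params a [calling_params()].
#' @param n_perm permutations for all resampling tests (default 1000).
#' @param seed master integer seed.
#' @param stages character subset of
#'   `c("call", "annotate", "motif", "clusters", "haplotype",
#'   "expression")`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, genome = NULL, annotation = NULL,
                            kinetics = NULL, hap_molecules = NULL,
                            expression = NULL, simulate = FALSE,
                            sim = sim_config(), params = calling_params(),
                            n_perm = 1000L, seed = 1L,
                            stages = c("call", "annotate", "motif",
                                       "clusters", "haplotype",
                                       "expression")) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

#' Run the m6dA characterization pipeline
#'
#' Executes the requested stages in dependency order — site calling and
#' filtering, feature annotation and enrichment, motif analysis against
#' the failed-filter null set, cluster detection and characterization,
#' haplotype-split calling with the diploid-on-haplotypes regression, and
#' the expression link — writing tab-separated tables, modification files
#' and a JSON run manifest (seed, parameters, outputs) to
#' `config$out_dir`. Outputs are deterministic per seed.
#'
#' @param config a [pipeline_config()].
#' @return invisible list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character()
  emit <- function(df, name) {
    outputs[[name]] <<- write_tsv(df, file.path(config$out_dir, name))
  }
  results <- list()

  if (config$simulate) {
    sim_dir <- file.path(config$out_dir, "simulated")
    bundle <- simulate_dataset(config$sim, sim_dir)
    genome <- bundle$sim$genome
    annotation <- bundle$sim$annotation
    sites <- bundle$kinetics$sites
    hap_mols <- bundle$haplotypes$molecules
    expr <- bundle$expression$expression
  } else {
    if (is.null(config$genome) || is.null(config$kinetics)) {
      stop("pipeline needs genome and kinetics inputs (or simulate=TRUE)",
           call. = FALSE)
    }
    genome <- read_genome(config$genome)
    annotation <- if (!is.null(config$annotation)) {
      read_annotation(config$annotation,
                      seqlengths = Biostrings::width(genome))
    }
    sites <- read_modifications(config$kinetics, "tabular")
    hap_mols <- if (!is.null(config$hap_molecules)) {
      utils::read.delim(config$hap_molecules, stringsAsFactors = FALSE)
    }
    expr <- if (!is.null(config$expression)) {
      utils::read.delim(config$expression, stringsAsFactors = FALSE)
    }
  }

  need <- function(stage, what, ok) {
    if (!ok) {
      stop(sprintf("stage '%s' requires %s", stage, what), call. = FALSE)
    }
  }
  universe <- shuffle_universe(genome)

  parts <- NULL
  if ("call" %in% config$stages) {
    parts <- filter_sites(sites, config$params)
    write_modifications(parts$called,
                        file.path(config$out_dir, "called.gff3"),
                        "gff3-mod")
    write_modifications(parts$null,
                        file.path(config$out_dir, "null_set.gff3"),
                        "gff3-mod")
    results$called <- parts$called
    results$null <- parts$null
  }

  if ("annotate" %in% config$stages) {
    need("annotate", "an annotation", !is.null(annotation))
    need("annotate", "the call stage", !is.null(parts))
    assignments <- assign_features(parts$called, annotation)
    emit(assignments, "feature_assignments.tsv")
    emit(chromosome_m6dA_dA(parts$called, genome), "chromosome_ratio.tsv")
    enr <- feature_fold_enrichment(parts$called, annotation, genome,
                                   n_perm = config$n_perm,
                                   seed = config$seed,
                                   universe = universe)
    emit(enr, "feature_enrichment.tsv")
    results$assignments <- assignments
    results$enrichment <- enr
  }

  if ("motif" %in% config$stages) {
    need("motif", "the call stage", !is.null(parts))
    fg <- parts$called$context[!is.na(parts$called$context)]
    nl <- parts$null$context[!is.na(parts$null$context)]
    need("motif", "contexts on called and null sites",
         length(fg) > 0 && length(nl) > 0)
    motifs <- dinucleotide_enrichment(fg, nl)
    emit(motifs, "motif_dinucleotides.tsv")
    combined <- combine_4mers(motifs, fg, nl)
    if (nrow(combined)) emit(combined, "motif_combined.tsv")
    results$motifs <- motifs
    results$motifs_combined <- combined
  }

  if ("clusters" %in% config$stages) {
    need("clusters", "the call stage", !is.null(parts))
    det <- detect_clusters(parts$called)
    st <- cluster_stats(det, parts$called, genome)
    emit(st$per_cluster, "clusters.tsv")
    ab <- cluster_abundance_pvalue(parts$called, universe,
                                   n_perm = config$n_perm,
                                   seed = config$seed)
    results$clusters <- det
    results$cluster_stats <- st
    results$cluster_abundance <- ab
  }

  if ("haplotype" %in% config$stages) {
    need("haplotype", "haplotype-tagged molecules", !is.null(hap_mols))
    split <- split_and_call_by_haplotype(hap_mols, config$params, genome)
    emit(split$table, "haplotype_calls.tsv")
    excl <- haplotype_exclusivity(split$hp1$called, split$hp2$called)
    reg <- tryCatch(regress_diploid_on_haplotypes(split$table),
                    error = function(e) NULL)
    if (!is.null(reg)) emit(reg$coefficients, "haplotype_regression.tsv")
    results$haplotype <- split
    results$exclusivity <- excl
    results$regression <- reg
  }

  if ("expression" %in% config$stages) {
    need("expression", "an expression table", !is.null(expr))
    need("expression", "the annotate stage", !is.null(results$assignments))
    tpm <- tryCatch(
      tpm_by_m6dA_status(expr, results$assignments, "any"),
      error = function(e) {
        message("expression comparison skipped: ", conditionMessage(e))
        NULL
      })
    ase <- if (all(c("hap1_count", "hap2_count") %in% names(expr))) {
      ase_test(expr)
    }
    if (!is.null(ase)) emit(ase$table, "ase.tsv")
    results$tpm_comparison <- tpm
    results$ase <- ase
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("m6dAtools")),
    seed = config$seed, n_perm = config$n_perm,
    stages = config$stages,
    params = unclass(config$params),
    simulated = config$simulate,
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, file.path(config$out_dir,
                                           "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
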