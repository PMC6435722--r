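#' Site-calling parameters
#'
#' Thresholds and kinetic-model parameters for turning molecule-level IPD
#' observations into called m6dA sites. The defaults reproduce the standard
#' filters: a called site needs at least 20 distinct molecules on its strand
#' (`min_coverage = 20`) and an IPD ratio of at least 4
#' (`min_ipd_ratio = 4`); sites failing those filters but with at least 11x
#' coverage (`null_min_coverage = 11`) form the motif null set, where the
#' coverage floor still permits fraction estimation. Both thresholds are
#' inclusive; the boundary convention is configurable because prose
#' statements of such filters are often ambiguous between ">" and ">=".
#'
#' `mu0` is the mean log IPD of unmodified adenosines (the kinetic
#' reference), `sigma` the per-pass log-IPD standard deviation, and `delta`
#' the additive log-IPD shift of a methylated base, so a fully methylated
#' site has expected IPD ratio `exp(delta)`.
#'
#' @param min_coverage minimum per-strand molecule coverage for a call.
#' @param min_ipd_ratio minimum IPD ratio for a call.
#' @param null_min_coverage minimum coverage for the failed-filter null set.
#' @param mu0,sigma,delta kinetic model parameters (log-IPD scale).
#' @return a list of class `calling_params`.
#' @export
calling_params <- function(min_coverage = 20L, min_ipd_ratio = 4,
                           null_min_coverage = 11L, mu0 = 0, sigma = 0.5,
                           delta = log(6)) {
  stopifnot(min_coverage >= 1, min_ipd_ratio > 0,
            null_min_coverage <= min_coverage, sigma > 0, delta > 0)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_ipd_ratio = as.numeric(min_ipd_ratio),
                 null_min_coverage = as.integer(null_min_coverage),
                 mu0 = mu0, sigma = sigma, delta = delta),
            class = "calling_params")
}

#' IPD ratio of a site from molecule observations
#'
#' The IPD ratio is the multiplicative deviation of a site's observed
#' inter-pulse durations from the unmodified expectation:
#' `exp(mean(mean_log_ipd) - mu0)`.
#'
#' @param mean_log_ipd per-molecule mean log IPDs at the site.
#' @param mu0 unmodified mean log IPD.
#' @return positive scalar ratio.
#' @export
#' @examples
#' compute_ipd_ratio(rep(log(4), 10), mu0 = 0)   # 4
compute_ipd_ratio <- function(mean_log_ipd, mu0 = 0) {
  if (length(mean_log_ipd) == 0L) {
    stop("no molecule observations at site", call. = FALSE)
  }
  exp(mean(mean_log_ipd) - mu0)
}

#' Estimate the methylated fraction of a site by mixture EM
#'
#' Per-molecule mean log IPDs are modeled as a two-component normal mixture
#' with component means fixed at `mu0` (unmethylated) and `mu0 + delta`
#' (methylated) and per-molecule standard deviation `sigma / sqrt(n_passes)`
#' (multi-pass circular sequencing averages down the per-pass noise). Only
#' the mixing weight is free; it is estimated by EM to tolerance `1e-8`.
#' The returned fraction is the posterior-weighted share of the methylated
#' component (equal to the converged weight), clamped to `[0, 1]`; the
#' methylated molecule count is `round_half_up(fraction * coverage)`.
#'
#' @param mean_log_ipd per-molecule mean log IPDs.
#' @param n_passes per-molecule pass counts (recycled).
#' @param params a [calling_params()].
#' @param tol EM convergence tolerance on the weight.
#' @param max_iter maximum EM iterations.
#' @return list with `fraction`, `meth_count`, `coverage`, `iterations`.
#' @export
estimate_methylated_fraction <- function(mean_log_ipd, n_passes = 1L,
                                         params = calling_params(),
                                         tol = 1e-8, max_iter = 500L) {
  n <- length(mean_log_ipd)
  if (n == 0L) stop("no molecule observations at site", call. = FALSE)
  if (params$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (any(n_passes < 1L)) stop("n_passes must be >= 1", call. = FALSE)
  sd_i <- params$sigma / sqrt(rep_len(n_passes, n))
  # log densities under each fixed-mean component
  ll0 <- stats::dnorm(mean_log_ipd, params$mu0, sd_i, log = TRUE)
  ll1 <- stats::dnorm(mean_log_ipd, params$mu0 + params$delta, sd_i,
                      log = TRUE)
  w <- 0.5
  for (it in seq_len(max_iter)) {
    # responsibilities on the log scale for numerical stability
    a <- log(w) + ll1
    b <- log1p(-w) + ll0
    m <- pmax(a, b)
    r <- exp(a - m) / (exp(a - m) + exp(b - m))
    w_new <- mean(r)
    if (abs(w_new - w) < tol) {
      w <- w_new
      break
    }
    w <- w_new
    if (it == max_iter) {
      stop(sprintf(paste0("EM did not converge in %d iterations ",
                          "(n=%d, last weight %.6f)"), max_iter, n, w),
           call. = FALSE)
    }
  }
  frac <- min(1, max(0, w))
  list(fraction = frac,
       meth_count = methylated_cell_count(frac, n),
       coverage = n, iterations = it)
}

#' Method-of-moments methylated fraction from an IPD ratio
#'
#' Fallback estimator for site summaries without per-molecule data: under
#' the additive log-IPD shift model the site IPD ratio at methylated
#' fraction f is approximately `1 + f * (exp(delta) - 1)` on the raw-IPD
#' scale, giving `f = (ratio - 1) / (exp(delta) - 1)`, clamped to `[0, 1]`.
#'
#' @param ipd_ratio observed site IPD ratio(s).
#' @param delta methylated log-IPD shift.
#' @return fraction(s) in `[0, 1]`.
#' @export
fraction_from_ipd_ratio <- function(ipd_ratio, delta = log(6)) {
  pmin(1, pmax(0, (ipd_ratio - 1) / (exp(delta) - 1)))
}

#' Methylated-cell count at a site
#'
#' The number of methylated molecules ("cells") at a position is the
#' methylated fraction times the coverage, rounded half up.
#'
#' @param fraction methylated fraction in `[0, 1]`.
#' @param coverage molecule coverage, `>= 0`.
#' @return integer count in `[0, coverage]`.
#' @export
#' @examples
#' methylated_cell_count(0.75, 40)  # 30
methylated_cell_count <- function(fraction, coverage) {
  if (any(is.na(fraction)) || any(fraction < 0 | fraction > 1)) {
    stop("fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(coverage < 0)) stop("coverage must be >= 0", call. = FALSE)
  pmin(as.integer(coverage), round_half_up(fraction * coverage))
}

#' Share of fully methylated sites
#'
#' A site is fully (homogeneously) methylated when every molecule covering
#' it carries the mark, i.e. its methylated fraction is exactly 1 after
#' parsing. Reports the count and the percentage of the site set.
#'
#' @param sites a `site_set` with `meth_fraction` populated.
#' @return list with `n_full`, `n_total`, `pct`.
#' @export
fully_methylated_summary <- function(sites) {
  stopifnot(is_site_set(sites))
  mf <- sites$meth_fraction
  if (anyNA(mf)) stop("meth_fraction missing on some sites", call. = FALSE)
  n_full <- sum(mf == 1)
  list(n_full = n_full, n_total = nrow(sites),
       pct = 100 * n_full / nrow(sites))
}

#' Partition sites into called m6dA and the failed-filter null set
#'
#' Called sites satisfy `coverage >= min_coverage` and
#' `ipd_ratio >= min_ipd_ratio`. Sites failing either filter but with
#' `coverage >= null_min_coverage` form the null set used as motif
#' background; candidates below the null floor are discarded. The partition
#' is exhaustive over candidates and the two sets are disjoint.
#'
#' @param sites a `site_set` with `coverage` and `ipd_ratio` populated.
#' @param params a [calling_params()].
#' @return list with `called` and `null` site_sets.
#' @export
filter_sites <- function(sites, params = calling_params()) {
  stopifnot(is_site_set(sites))
  if (nrow(sites) == 0L) {
    return(list(called = sites, null = sites))
  }
  if (anyNA(sites$coverage)) {
    stop("filter_sites needs coverage on every site", call. = FALSE)
  }
  # a missing IPD ratio (e.g. a zero-coverage record) can never qualify
  pass <- sites$coverage >= params$min_coverage &
    !is.na(sites$ipd_ratio) & sites$ipd_ratio >= params$min_ipd_ratio
  nullset <- !pass & sites$coverage >= params$null_min_coverage
  list(called = as_site_set(sites[pass, , drop = FALSE]),
       null = as_site_set(sites[nullset, , drop = FALSE]))
}

#' Call sites from molecule-level observations
#'
#' Groups molecule observations by site key, computes coverage (distinct
#' molecules), the IPD ratio and the EM methylated fraction for each site,
#' and returns the per-site summaries as a `site_set`. Contexts are attached
#' from `genome` when supplied.
#'
#' @param molecules data frame with columns `chrom`, `pos`, `strand`,
#'   `molecule_id`, `mean_log_ipd`, `n_passes` (and optionally `haplotype`).
#' @param params a [calling_params()].
#' @param genome optional `DNAStringSet` for context extraction.
#' @return a `site_set` of per-site summaries (unfiltered).
#' @export
call_sites <- function(molecules, params = calling_params(), genome = NULL) {
  stopifnot(is.data.frame(molecules))
  needed <- c("chrom", "pos", "strand", "mean_log_ipd")
  if (!all(needed %in% names(molecules))) {
    stop("molecule table needs columns ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(molecules) == 0L) return(SiteSet())
  np <- molecules$n_passes %||% rep(1L, nrow(molecules))
  key <- paste(molecules$chrom, molecules$pos, molecules$strand, sep = ":")
  idx <- split(seq_len(nrow(molecules)), key)
  res <- lapply(idx, function(i) {
    est <- estimate_methylated_fraction(molecules$mean_log_ipd[i], np[i],
                                        params)
    c(coverage = length(i),
      ipd_ratio = compute_ipd_ratio(molecules$mean_log_ipd[i], params$mu0),
      fraction = est$fraction)
  })
  first <- vapply(idx, function(i) i[[1L]], integer(1))
  m <- do.call(rbind, res)
  sites <- data.frame(
    chrom = molecules$chrom[first],
    pos = molecules$pos[first],
    strand = molecules$strand[first],
    coverage = as.integer(m[, "coverage"]),
    ipd_ratio = m[, "ipd_ratio"],
    meth_fraction = m[, "fraction"],
    context = NA_character_,
    stringsAsFactors = FALSE
  )
  if (!is.null(genome)) {
    sites$context <- extract_context(genome, sites$chrom, sites$pos,
                                     sites$strand)
  }
  as_site_set(sites)
}
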