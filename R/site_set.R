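#' m6dA site sets
#'
#' A `site_set` is the package's central container: a data frame with one row
#' per strand-specific adenosine carrying SMRT kinetic evidence. Because SMRT
#' sequencing reads each strand separately, the two strands of one genomic
#' position are always distinct sites; the key of a site is
#' `(chrom, pos, strand)`.
#'
#' Columns:
#' \describe{
#'   \item{chrom}{chromosome name.}
#'   \item{pos}{1-based position of the adenosine.}
#'   \item{strand}{`"+"` or `"-"`.}
#'   \item{coverage}{number of distinct molecules covering the site on that
#'     strand.}
#'   \item{ipd_ratio}{observed/expected inter-pulse duration, dimensionless,
#'     `>= 0`.}
#'   \item{meth_fraction}{fraction of molecules called methylated, in
#'     `[0, 1]`. A fully methylated site is exactly `1`.}
#'   \item{context}{41-base sequence around the site (20 bases each side,
#'     site at position 21), oriented to the site's strand so the center base
#'     is always `A`; may be `NA`.}
#' }
#'
#' Rows are kept sorted by `(chrom, pos, strand)` and keys are unique, so
#' iteration order is deterministic.
#'
#' @param chrom,pos,strand,coverage,ipd_ratio,meth_fraction,context site
#'   fields, recycled to a common length.
#' @return a `data.frame` of class `site_set`.
#' @export
#' @examples
#' SiteSet(chrom = "chr1", pos = c(100L, 250L), strand = "+",
#'         coverage = 25L, ipd_ratio = 4.2, meth_fraction = c(0.8, 1))
SiteSet <- function(chrom = character(), pos = integer(), strand = character(),
                    coverage = integer(), ipd_ratio = numeric(),
                    meth_fraction = numeric(), context = NA_character_) {
  n <- max(length(chrom), length(pos), length(strand))
  if (length(chrom) == 0L) n <- 0L
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    strand = rep_len(as.character(strand), n),
    coverage = rep_len(as.integer(coverage), n),
    ipd_ratio = rep_len(as.numeric(ipd_ratio), n),
    meth_fraction = rep_len(as.numeric(meth_fraction), n),
    context = rep_len(as.character(context), n),
    stringsAsFactors = FALSE
  )
  as_site_set(df)
}

#' Coerce a data frame to a site_set
#'
#' Validates invariants, sorts by `(chrom, pos, strand)` and checks key
#' uniqueness.
#'
#' @param df data frame with at least `chrom`, `pos`, `strand`; missing
#'   kinetic columns are filled with `NA`.
#' @return a `site_set`.
#' @export
as_site_set <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("chrom", "pos", "strand")
  if (!all(needed %in% names(df))) {
    stop("a site_set needs columns chrom, pos, strand", call. = FALSE)
  }
  for (col in c("coverage", "ipd_ratio", "meth_fraction")) {
    if (is.null(df[[col]])) df[[col]] <- NA_real_
  }
  if (is.null(df[["context"]])) df[["context"]] <- NA_character_
  df <- df[c("chrom", "pos", "strand", "coverage", "ipd_ratio",
             "meth_fraction", "context")]
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$strand <- as.character(df$strand)
  df$coverage <- as.integer(df$coverage)
  df$ipd_ratio <- as.numeric(df$ipd_ratio)
  df$meth_fraction <- as.numeric(df$meth_fraction)
  df$context <- as.character(df$context)
  validate_site_fields(df)
  df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  keys <- site_key(df)
  if (anyDuplicated(keys)) {
    stop("duplicate (chrom, pos, strand) keys in site_set", call. = FALSE)
  }
  class(df) <- c("site_set", "data.frame")
  df
}

validate_site_fields <- function(df) {
  if (!all(df$strand %in% c("+", "-"))) {
    bad <- unique(setdiff(df$strand, c("+", "-")))
    stop("unknown strand symbol(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cov <- df$coverage[!is.na(df$coverage)]
  if (any(cov < 0L)) stop("coverage must be >= 0", call. = FALSE)
  ipd <- df$ipd_ratio[!is.na(df$ipd_ratio)]
  if (any(ipd < 0)) stop("ipd_ratio must be >= 0", call. = FALSE)
  mf <- df$meth_fraction[!is.na(df$meth_fraction)]
  if (any(mf < 0 | mf > 1)) {
    stop("meth_fraction must lie in [0, 1]", call. = FALSE)
  }
  ctx <- df$context[!is.na(df$context)]
  if (length(ctx)) {
    if (any(nchar(ctx) != 41L)) {
      stop("context must be 41 bases when present", call. = FALSE)
    }
    if (any(substr(ctx, 21L, 21L) != "A")) {
      stop("context center base must be A on the site's strand",
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Site keys
#'
#' @param sites a `site_set` (or data frame with the key columns).
#' @return character vector `"chrom:pos:strand"`, one per row.
#' @export
site_key <- function(sites) {
  paste(sites$chrom, sites$pos, sites$strand, sep = ":")
}

is_site_set <- function(x) inherits(x, "site_set")

# GRanges view of the site positions (width-1 ranges, strand kept).
sites_as_granges <- function(sites, stranded = TRUE) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$pos, width = 1L),
    strand = if (stranded) sites$strand else "*"
  )
}

#' @export
print.site_set <- function(x, ...) {
  cat(sprintf("site_set with %d site(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  NextMethod()
}
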