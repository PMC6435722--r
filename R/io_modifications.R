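#' Read a base-modifications file into a site_set
#'
#' Two dialects are supported. `"gff3-mod"` is the GFF3-style modifications
#' dialect produced by SMRT kinetic callers: one feature line per site with
#' 1-based inclusive coordinates and the kinetic evidence in the attributes
#' column (`coverage`, `IPDRatio`, `frac`, `context`). `"tabular"` is the
#' package's versioned tab-separated dialect (UTF-8, fixed header
#' `chrom pos strand coverage ipd_ratio meth_fraction context`, 1-based
#' positions).
#'
#' Fraction fields are normalized to `[0, 1]` on read: a `frac` value above 1
#' is interpreted as a percentage and divided by 100, so a "100% methylated
#' fraction" always parses to exactly `1.0`.
#'
#' @param path file to read.
#' @param dialect `"tabular"` or `"gff3-mod"`.
#' @return a [SiteSet()].
#' @seealso [write_modifications()]
#' @export
read_modifications <- function(path, dialect = c("tabular", "gff3-mod")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "tabular") {
    read_modifications_tabular(path)
  } else {
    read_modifications_gff3(path)
  }
}

read_modifications_tabular <- function(path) {
  header <- c("chrom", "pos", "strand", "coverage", "ipd_ratio",
              "meth_fraction", "context")
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (!identical(names(df), header)) {
    stop("tabular modifications file must have header: ",
         paste(header, collapse = " "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(SiteSet())
  pos <- suppressWarnings(as.integer(df$pos))
  cov <- suppressWarnings(as.integer(df$coverage))
  ipd <- suppressWarnings(as.numeric(df$ipd_ratio))
  mf <- suppressWarnings(as.numeric(df$meth_fraction))
  bad <- which(is.na(pos) | (is.na(ipd) & df$ipd_ratio != "NA") |
                 (is.na(mf) & df$meth_fraction != "NA"))
  if (length(bad)) {
    stop(sprintf("malformed record at line %d of %s", bad[1] + 1L, path),
         call. = FALSE)
  }
  mf <- normalize_fraction(mf)
  ctx <- df$context
  ctx[ctx %in% c("", ".", "NA")] <- NA_character_
  as_site_set(data.frame(chrom = df$chrom, pos = pos, strand = df$strand,
                         coverage = cov, ipd_ratio = ipd,
                         meth_fraction = mf, context = ctx,
                         stringsAsFactors = FALSE))
}

read_modifications_gff3 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) return(SiteSet())
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    stop(sprintf("malformed record at line %d of %s (expected 9 fields)",
                 which(!startsWith(lines, "#") & nzchar(lines))[which(nf != 9L)[1]],
                 path), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  attr_get <- function(attrs, key) {
    pat <- paste0("(?:^|;)", key, "=([^;]*)")
    mt <- regmatches(attrs, regexec(pat, attrs))
    vapply(mt, function(x) if (length(x) == 2L) x[2] else NA_character_, "")
  }
  attrs <- m[, 9L]
  pos <- suppressWarnings(as.integer(m[, 4L]))
  if (anyNA(pos)) {
    stop(sprintf("malformed record at line %d of %s (bad start coordinate)",
                 which(is.na(pos))[1], path), call. = FALSE)
  }
  strand <- m[, 7L]
  cov <- suppressWarnings(as.integer(attr_get(attrs, "coverage")))
  ipd <- suppressWarnings(as.numeric(attr_get(attrs, "IPDRatio")))
  frac <- suppressWarnings(as.numeric(attr_get(attrs, "frac")))
  ctx <- attr_get(attrs, "context")
  ctx[is.na(ctx) | ctx %in% c("", ".")] <- NA_character_
  as_site_set(data.frame(chrom = m[, 1L], pos = pos, strand = strand,
                         coverage = cov, ipd_ratio = ipd,
                         meth_fraction = normalize_fraction(frac),
                         context = ctx, stringsAsFactors = FALSE))
}

normalize_fraction <- function(x) {
  pct <- !is.na(x) & x > 1
  x[pct] <- x[pct] / 100
  x
}

#' Write a site_set to a modifications file
#'
#' Output is deterministic (sites are stored sorted) and round-trips through
#' [read_modifications()] bit-exactly: numeric fields are written with 17
#' significant digits.
#'
#' @param sites a `site_set`.
#' @param path output file.
#' @param dialect `"tabular"` or `"gff3-mod"`.
#' @return `path`, invisibly.
#' @export
write_modifications <- function(sites, path,
                                dialect = c("tabular", "gff3-mod")) {
  dialect <- match.arg(dialect)
  stopifnot(is_site_set(sites))
  fmt <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- "NA"
    out
  }
  if (dialect == "tabular") {
    header <- "chrom\tpos\tstrand\tcoverage\tipd_ratio\tmeth_fraction\tcontext"
    ctx <- ifelse(is.na(sites$context), "NA", sites$context)
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s",
                    sites$chrom, sites$pos, sites$strand,
                    ifelse(is.na(sites$coverage), "NA",
                           as.character(sites$coverage)),
                    fmt(sites$ipd_ratio), fmt(sites$meth_fraction), ctx)
    writeLines(c(header, body), path)
  } else {
    header <- c("##gff-version 3",
                "##source m6dAtools modifications dialect")
    ctx <- ifelse(is.na(sites$context), ".", sites$context)
    attrs <- sprintf("coverage=%s;context=%s;IPDRatio=%s;frac=%s",
                     ifelse(is.na(sites$coverage), "NA",
                            as.character(sites$coverage)),
                     ctx, fmt(sites$ipd_ratio), fmt(sites$meth_fraction))
    body <- sprintf("%s\tm6dAtools\tm6dA\t%d\t%d\t.\t%s\t.\t%s",
                    sites$chrom, sites$pos, sites$pos, sites$strand, attrs)
    writeLines(c(header, body), path)
  }
  invisible(path)
}
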