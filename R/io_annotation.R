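#' Gene annotation with derived features
#'
#' A `genome_annotation` bundles transcript records with the derived feature
#' intervals that site annotation uses. Promoters are the 1 kb immediately
#' upstream of the transcription start site (strand-aware); introns are the
#' gaps between a transcript's exons; the downstream region is the 1 kb past
#' the transcript end; intergenic space is the complement of everything
#' else. All intervals are 1-based closed, the GRanges convention.
#'
#' @param transcripts data frame with `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (transcript span, 1-based closed). The TSS is `start` on `+` and
#'   `end` on `-`.
#' @param exons data frame with `gene_id`, `chrom`, `start`, `end`.
#' @param utr5,utr3 optional data frames shaped like `exons` giving 5' and 3'
#'   untranslated regions.
#' @param seqlengths named integer vector of chromosome lengths.
#' @param promoter_width upstream promoter width in bp (default 1000).
#' @param downstream_width downstream region width in bp (default 1000).
#' @return an object of class `genome_annotation`.
#' @export
genome_annotation <- function(transcripts, exons, utr5 = NULL, utr3 = NULL,
                              seqlengths, promoter_width = 1000L,
                              downstream_width = 1000L) {
  stopifnot(is.data.frame(transcripts), is.data.frame(exons),
            !is.null(names(seqlengths)))
  seqlengths <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  empty_feat <- function() {
    data.frame(gene_id = character(), chrom = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  }
  utr5 <- utr5 %||% empty_feat()
  utr3 <- utr3 %||% empty_feat()

  # every exon must lie inside its transcript span
  if (nrow(exons)) {
    tx <- transcripts[match(exons$gene_id, transcripts$gene_id), ]
    if (anyNA(tx$gene_id)) {
      stop("exon references unknown gene_id", call. = FALSE)
    }
    if (any(exons$start < tx$start | exons$end > tx$end)) {
      stop("exon outside its transcript span", call. = FALSE)
    }
  }

  mk_gr <- function(df) {
    GenomicRanges::GRanges(
      seqnames = factor(df$chrom, levels = names(seqlengths)),
      ranges = IRanges::IRanges(df$start, df$end),
      gene_id = df$gene_id,
      seqlengths = seqlengths
    )
  }

  tss <- ifelse(transcripts$strand == "+", transcripts$start,
                transcripts$end)
  plus <- transcripts$strand == "+"
  prom <- data.frame(
    gene_id = transcripts$gene_id,
    chrom = transcripts$chrom,
    start = ifelse(plus, pmax(1L, tss - promoter_width), tss + 1L),
    end = ifelse(plus, tss - 1L,
                 pmin(seqlengths[transcripts$chrom], tss + promoter_width)),
    stringsAsFactors = FALSE
  )
  prom <- prom[prom$end >= prom$start, , drop = FALSE]

  down <- data.frame(
    gene_id = transcripts$gene_id,
    chrom = transcripts$chrom,
    start = ifelse(plus, transcripts$end + 1L,
                   pmax(1L, transcripts$start - downstream_width)),
    end = ifelse(plus,
                 pmin(seqlengths[transcripts$chrom],
                      transcripts$end + downstream_width),
                 transcripts$start - 1L),
    stringsAsFactors = FALSE
  )
  down <- down[down$end >= down$start & down$start >= 1L, , drop = FALSE]

  # introns: per transcript, span minus exons
  introns <- empty_feat()
  if (nrow(exons)) {
    intron_list <- lapply(split(exons, exons$gene_id), function(ex) {
      txr <- transcripts[transcripts$gene_id == ex$gene_id[1], ]
      span <- IRanges::IRanges(txr$start, txr$end)
      gaps <- IRanges::setdiff(span, IRanges::IRanges(ex$start, ex$end))
      if (length(gaps) == 0L) return(NULL)
      data.frame(gene_id = ex$gene_id[1], chrom = txr$chrom,
                 start = IRanges::start(gaps), end = IRanges::end(gaps),
                 stringsAsFactors = FALSE)
    })
    intron_list <- intron_list[!vapply(intron_list, is.null, TRUE)]
    if (length(intron_list)) introns <- do.call(rbind, intron_list)
  }

  tx_spans <- data.frame(gene_id = transcripts$gene_id,
                         chrom = transcripts$chrom,
                         start = transcripts$start, end = transcripts$end,
                         stringsAsFactors = FALSE)
  features <- list(
    promoter = mk_gr(prom), utr5 = mk_gr(utr5), utr3 = mk_gr(utr3),
    exon = mk_gr(exons), intron = mk_gr(introns), downstream = mk_gr(down)
  )
  genic <- GenomicRanges::reduce(c(
    GenomicRanges::granges(features$promoter),
    GenomicRanges::granges(features$downstream),
    GenomicRanges::granges(mk_gr(tx_spans))
  ))
  intergenic <- GenomicRanges::gaps(genic)
  intergenic <- intergenic[S4Vectors::decode(
    GenomicRanges::strand(intergenic)) == "*"]
  S4Vectors::mcols(intergenic)$gene_id <- NA_character_
  features$intergenic <- intergenic

  structure(
    list(transcripts = cbind(transcripts, tss = as.integer(tss)),
         exons = exons, utr5 = utr5, utr3 = utr3,
         seqlengths = seqlengths, features = features,
         promoter_width = as.integer(promoter_width),
         downstream_width = as.integer(downstream_width)),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf(
    "genome_annotation: %d transcripts, %d exons on %d chromosome(s)\n",
    nrow(x$transcripts), nrow(x$exons), length(x$seqlengths)))
  invisible(x)
}

#' Read a gene annotation from GFF3/GTF
#'
#' Transcript spans, exons and UTRs are taken from the file; promoters,
#' introns, downstream regions and intergenic space are derived on load (see
#' [genome_annotation()]). Chromosome lengths are taken from
#' `##sequence-region` headers or, if absent, from `seqlengths`.
#'
#' @param path GFF3/GTF file.
#' @param seqlengths optional named integer vector of chromosome lengths.
#' @param promoter_width promoter width in bp.
#' @return a [genome_annotation()].
#' @export
read_annotation <- function(path, seqlengths = NULL, promoter_width = 1000L) {
  gr <- rtracklayer::import(path)
  sl <- GenomeInfoDb::seqlengths(gr)
  if (all(is.na(sl))) {
    # fall back to the ##sequence-region directives
    hdr <- grep("^##sequence-region", readLines(path, n = 1000L),
                value = TRUE)
    if (length(hdr)) {
      parts <- strsplit(hdr, "\\s+")
      sl <- stats::setNames(
        vapply(parts, function(x) as.integer(x[4]), integer(1)),
        vapply(parts, function(x) x[2], ""))
    } else if (!is.null(seqlengths)) {
      sl <- seqlengths
    } else {
      stop("no ##sequence-region headers; supply seqlengths",
           call. = FALSE)
    }
  }
  md <- S4Vectors::mcols(gr)
  gid <- if (!is.null(md$gene_id)) as.character(md$gene_id)
         else as.character(md$Parent)
  type <- as.character(md$type)
  take <- function(types) {
    sel <- type %in% types
    data.frame(
      gene_id = gid[sel],
      chrom = as.character(GenomeInfoDb::seqnames(gr)[sel]),
      strand = as.character(GenomicRanges::strand(gr)[sel]),
      start = GenomicRanges::start(gr)[sel],
      end = GenomicRanges::end(gr)[sel],
      stringsAsFactors = FALSE
    )
  }
  tx <- take(c("transcript", "mRNA"))
  if (nrow(tx) == 0L) tx <- take("gene")
  exons <- take("exon")[, -3L]
  utr5 <- take(c("five_prime_UTR", "5UTR"))[, -3L]
  utr3 <- take(c("three_prime_UTR", "3UTR"))[, -3L]
  genome_annotation(tx[, c("gene_id", "chrom", "strand", "start", "end")],
                    exons, utr5, utr3, seqlengths = sl,
                    promoter_width = promoter_width)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return a [Biostrings::DNAStringSet] named by the first token of each
#'   header.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read a BED interval file
#'
#' BED's 0-based half-open coordinates are converted to the internal 1-based
#' closed convention (`"chr1 10 20"` becomes positions 11..20).
#'
#' @param path BED3/BED4/BED6 file.
#' @return a `GRanges`.
#' @export
read_regions <- function(path) {
  rtracklayer::import(path, format = "BED")
}

# 41-base strand-oriented context around pos (center = index 21); positions
# beyond the chromosome edge are padded with N.
extract_context <- function(genome, chrom, pos, strand, flank = 20L) {
  seqs <- genome[chrom]
  len <- Biostrings::width(seqs)
  lo <- pmax(1L, pos - flank)
  hi <- pmin(len, pos + flank)
  core <- as.character(Biostrings::subseq(seqs, start = lo, end = hi))
  pad_l <- strrep("N", lo - (pos - flank))
  pad_r <- strrep("N", (pos + flank) - hi)
  ctx <- paste0(pad_l, core, pad_r)
  neg <- strand == "-"
  if (any(neg)) {
    ctx[neg] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(ctx[neg])))
  }
  unname(ctx)
}

#' Write a genome annotation to GFF3
#'
#' @param annotation a [genome_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  sl <- annotation$seqlengths
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(sl), sl))
  tx <- annotation$transcripts
  row_of <- function(df, type, strand) {
    sprintf("%s\tm6dAtools\t%s\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s",
            df$chrom, type, df$start, df$end, strand,
            paste0(df$gene_id, ".", type, seq_len(nrow(df))), df$gene_id)
  }
  if (nrow(tx)) {
    strand_of <- function(df) tx$strand[match(df$gene_id, tx$gene_id)]
    lines <- c(lines,
               row_of(tx, "transcript", tx$strand),
               if (nrow(annotation$exons))
                 row_of(annotation$exons, "exon", strand_of(annotation$exons)),
               if (nrow(annotation$utr5))
                 row_of(annotation$utr5, "five_prime_UTR",
                        strand_of(annotation$utr5)),
               if (nrow(annotation$utr3))
                 row_of(annotation$utr3, "three_prime_UTR",
                        strand_of(annotation$utr3)))
  }
  writeLines(lines, path)
  invisible(path)
}
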