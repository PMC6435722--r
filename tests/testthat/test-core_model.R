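test_that("site_set constructor enforces the domain invariants", {
  s <- SiteSet(chrom = "chr1", pos = c(200L, 100L), strand = "+",
               coverage = 25L, ipd_ratio = 4.2, meth_fraction = 0.8)
  expect_s3_class(s, "site_set")
  expect_equal(s$pos, c(100L, 200L))  # deterministic ordering
  expect_error(SiteSet("chr1", 1L, "?", 10L, 1, 0.5), "strand")
  expect_error(SiteSet("chr1", 1L, "+", 10L, 1, 1.5), "meth_fraction")
  expect_error(SiteSet("chr1", 1L, "+", -1L, 1, 0.5), "coverage")
  expect_error(
    as_site_set(data.frame(chrom = "chr1", pos = c(5L, 5L), strand = "+",
                           coverage = 10L, ipd_ratio = 1,
                           meth_fraction = 0.1)),
    "duplicate")
  bad_ctx <- paste0(strrep("C", 20), "G", strrep("C", 20))
  expect_error(SiteSet("chr1", 1L, "+", 10L, 1, 0.5, bad_ctx), "center")
})

test_that("modification files round-trip bit-exactly in both dialects", {
  set.seed(42)
  n <- 50L
  ctx <- random_contexts(n, seed = 9)
  s <- as_site_set(data.frame(
    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    pos = sample.int(100000L, n), strand = sample(c("+", "-"), n, TRUE),
    coverage = sample.int(60L, n),
    ipd_ratio = exp(rnorm(n)), meth_fraction = runif(n),
    context = ctx, stringsAsFactors = FALSE))
  for (dialect in c("tabular", "gff3-mod")) {
    path <- withr::local_tempfile()
    write_modifications(s, path, dialect)
    s2 <- read_modifications(path, dialect)
    expect_identical(as.data.frame(s), as.data.frame(s2),
                     info = dialect)
  }
})

test_that("empty inputs and coordinate conventions behave as documented", {
  path <- withr::local_tempfile()
  write_modifications(SiteSet(), path, "gff3-mod")
  expect_equal(nrow(read_modifications(path, "gff3-mod")), 0L)

  # a site at pos = 1 is written with GFF start coordinate 1 (1-based file
  # and internal conventions coincide for GFF dialects)
  s <- SiteSet("chr1", 1L, "+", 25L, 4.2, 0.8)
  write_modifications(s, path, "gff3-mod")
  line <- grep("^chr1", readLines(path), value = TRUE)
  expect_equal(strsplit(line, "\t")[[1]][4], "1")
  expect_equal(read_modifications(path, "gff3-mod")$pos, 1L)

  # percent-convention fractions normalize to [0, 1]
  writeLines(c("##gff-version 3",
               "chr1\tx\tm6dA\t101\t101\t.\t+\t.\tcoverage=25;IPDRatio=4.2;frac=80"),
             path)
  got <- read_modifications(path, "gff3-mod")
  expect_equal(got$pos, 101L)
  expect_equal(got$meth_fraction, 0.8)

  # malformed record names its line
  writeLines(c("chrom\tpos\tstrand\tcoverage\tipd_ratio\tmeth_fraction\tcontext",
               "chr1\toops\t+\t10\t1\t0.5\tNA"), path)
  expect_error(read_modifications(path, "tabular"), "line 2")
})

test_that("BED intervals map to the internal 1-based closed convention", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tregion1", path)
  r <- read_regions(path)
  expect_equal(GenomicRanges::start(r), 11L)
  expect_equal(GenomicRanges::end(r), 20L)
})

test_that("annotation derives promoters, introns and intergenic space", {
  ann <- tiny_annotation()
  # 1 kb upstream of the TSS, not including the TSS itself
  prom <- ann$features$promoter
  pa <- prom[S4Vectors::mcols(prom)$gene_id == "geneA"]
  expect_equal(GenomicRanges::start(pa), 4000L)
  expect_equal(GenomicRanges::end(pa), 4999L)
  # two adjacent exons produce exactly the gap between them as intron
  intr <- ann$features$intron
  ia <- intr[S4Vectors::mcols(intr)$gene_id == "geneA"]
  expect_equal(GenomicRanges::start(ia), 6000L)
  expect_equal(GenomicRanges::end(ia), 6999L)
  # exon escaping its transcript span is rejected
  bad_ex <- data.frame(gene_id = "geneA", chrom = "chr1",
                       start = 4000L, end = 5999L)
  expect_error(
    genome_annotation(ann$transcripts[1:2, 1:5], bad_ex,
                      seqlengths = c(chr1 = 20000L)),
    "outside")
})

test_that("minus-strand promoters sit downstream of the transcript end", {
  tx <- data.frame(gene_id = "g1", chrom = "chr1", strand = "-",
                   start = 2000L, end = 4000L)
  ex <- data.frame(gene_id = "g1", chrom = "chr1",
                   start = 2000L, end = 4000L)
  ann <- genome_annotation(tx, ex, seqlengths = c(chr1 = 10000L))
  prom <- ann$features$promoter
  expect_equal(GenomicRanges::start(prom), 4001L)
  expect_equal(GenomicRanges::end(prom), 5000L)
  expect_equal(ann$transcripts$tss, 4000L)
})

test_that("annotation round-trips through GFF3", {
  ann <- tiny_annotation()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_annotation(ann, path)
  ann2 <- read_annotation(path)
  expect_equal(ann2$transcripts[names(ann$transcripts)],
               ann$transcripts, ignore_attr = TRUE)
  expect_equal(ann2$seqlengths, ann$seqlengths)
  for (f in names(ann$features)) {
    expect_equal(as.data.frame(ann2$features[[f]])[1:4],
                 as.data.frame(ann$features[[f]])[1:4], info = f)
  }
})

test_that("context extraction is strand-oriented and edge-padded", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep(c("A", "C", "G", "T"), length.out = 100), collapse = "")))
  ctx_fun <- m6dAtools:::extract_context
  ctx <- ctx_fun(genome, "chr1", 1L, "+")
  expect_equal(nchar(ctx), 41L)
  expect_equal(substr(ctx, 1, 20), strrep("N", 20))
  expect_equal(substr(ctx, 21, 21), "A")
  # on the minus strand the center must read A where the plus strand has T
  ctx_m <- ctx_fun(genome, "chr1", 4L, "-")
  expect_equal(substr(ctx_m, 21, 21), "A")
})
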