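maf_header <- paste("Hugo_Symbol", "Chromosome", "Start_Position",
                    "End_Position", "Reference_Allele", "Tumor_Seq_Allele2",
                    "Variant_Classification", "Variant_Type",
                    "Tumor_Sample_Barcode", "Transcript_ID", sep = "\t")

maf_row <- function(gene, chrom, pos, ref, alt, class, type, sample,
                    tx = "TX1") {
  paste(gene, chrom, pos, pos, ref, alt, class, type, sample, tx,
        sep = "\t")
}

test_that("MAF reading keeps SNVs, rejects indels, maps consequences", {
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines(c(maf_header,
               maf_row("TP53", "chr17", 7675000, "C", "T",
                       "Nonsense_Mutation", "SNP", "S1"),
               maf_row("KRAS", "chr12", 25245350, "-", "A", "Frame_Shift_Ins",
                       "INS", "S1"),
               maf_row("EGFR", "chr7", 55191822, "G", "G", "Silent", "SNP",
                       "S1"),
               maf_row("PTEN", "chr10", 87933147, "A", "G", "Silent", "SNP",
                       "S2"),
               maf_row("BRAF", "chr7", 140753336, "A", "T",
                       "Splice_Site", "SNP", "S2"),
               maf_row("NRAS", "chr1", 114713908, "T", "C",
                       "Totally_Unknown", "SNP", "S2")), f)
  v <- read_variants(f, "maf")
  # the insertion and the ref==alt row are rejected
  expect_equal(nrow(v), 4L)
  expect_equal(attr(v, "n_rejected"), 2L)
  expect_equal(v$consequence[v$gene == "TP53"], "PTV")
  expect_equal(v$consequence[v$gene == "PTEN"], "silent")
  expect_equal(v$consequence[v$gene == "BRAF"], "splice")
  expect_equal(v$consequence[v$gene == "NRAS"], "other")
  expect_equal(v$pos[v$gene == "TP53"], 7675000L)
})

test_that("missing MAF columns are reported by name", {
  f <- withr::local_tempfile(fileext = ".maf")
  writeLines(c("Hugo_Symbol\tChromosome", "TP53\tchr17"), f)
  expect_error(read_variants(f, "maf"), "Start_Position")
})

test_that("VCF rows parse to 1-based SNV records", {
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chr1,length=1000>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chr1\t100\t.\tA\tG\t50\tPASS\tGENE=TP53;SAMPLE=S1",
               "chr1\t200\t.\tC\tT,G\t50\tPASS\t.",
               "chr1\t300\t.\tCT\tC\t50\tPASS\t."), f)
  v <- read_variants(f, "vcf")
  expect_equal(nrow(v), 1L)
  expect_equal(attr(v, "n_rejected"), 2L)  # multi-allelic + deletion
  expect_equal(v$pos, 100L)
  expect_equal(v$ref_allele, "A")
  expect_equal(v$alt_allele, "G")
  expect_equal(v$gene, "TP53")
})

test_that("GTF transcripts are ordered in transcription direction", {
  f <- withr::local_tempfile(fileext = ".gtf")
  attrs <- function(tx) sprintf('gene_id "G1"; transcript_id "%s";', tx)
  writeLines(c(
    paste("chr1", "test", "exon", 100, 200, ".", "+", ".", attrs("TPLUS"),
          sep = "\t"),
    paste("chr1", "test", "exon", 300, 400, ".", "+", ".", attrs("TPLUS"),
          sep = "\t"),
    paste("chr1", "test", "CDS", 150, 200, ".", "+", 0, attrs("TPLUS"),
          sep = "\t"),
    paste("chr1", "test", "CDS", 300, 350, ".", "+", 0, attrs("TPLUS"),
          sep = "\t"),
    paste("chr2", "test", "exon", 100, 200, ".", "-", ".", attrs("TMINUS"),
          sep = "\t"),
    paste("chr2", "test", "exon", 300, 400, ".", "-", ".", attrs("TMINUS"),
          sep = "\t"),
    paste("chr3", "test", "exon", 10, 90, ".", "+", ".", attrs("TNC"),
          sep = "\t")), f)
  models <- read_gene_models(f)
  expect_equal(models$TPLUS$exons$start[1], 100)
  expect_equal(models$TPLUS$cds_start, 150)
  expect_equal(models$TPLUS$cds_end, 350)
  # minus strand: first exon in transcription order is the rightmost
  expect_equal(models$TMINUS$exons$start[1], 300)
  expect_true(models$TPLUS$coding)
  expect_false(models$TNC$coding)
  expect_true(models$TNC$single_exon)
})

test_that("tabular inputs validate and BED converts to 1-based", {
  d <- withr::local_tempdir()
  pur <- file.path(d, "purity.tsv")
  writeLines(c("sample_id\tESTIMATE\tABSOLUTE\tLUMP\tIHC\tCPE",
               "S1\t0.7\t0.65\tNA\tNA\t0.68"), pur)
  p <- read_input_table(pur, "purity")
  expect_equal(sum(!is.na(p[1, c("ESTIMATE", "ABSOLUTE", "LUMP", "IHC",
                                 "CPE")])), 3L)

  bad <- file.path(d, "bad_purity.tsv")
  writeLines(c("sample_id\tESTIMATE\tABSOLUTE\tLUMP\tIHC\tCPE",
               "S1\t1.7\t0.65\tNA\tNA\t0.68"), bad)
  expect_error(read_input_table(bad, "purity"), "\\[0, 1\\]")

  bed <- file.path(d, "regions.bed")
  writeLines("chr1\t0\t10", bed)
  gr <- read_input_table(bed, "bed")
  expect_equal(GenomicRanges::start(gr), 1L)
  expect_equal(GenomicRanges::end(gr), 10L)

  seg <- file.path(d, "segments.tsv")
  writeLines(c("sample_id\tchrom\tstart\tend\tsegment_mean",
               "S1\tchr1\t500\t100\t0.2"), seg)
  expect_error(read_input_table(seg, "segments"), "start > end")

  cnt <- file.path(d, "counts.tsv")
  writeLines(c(paste("sample_id", "chrom", "pos", "ref_allele",
                     "alt_allele", "Nex_ref", "Nex_var", "Ntr_ref",
                     "Ntr_var", "Tex_ref", "Tex_var", "Ttr_ref", "Ttr_var",
                     sep = "\t"),
               "S1\tchr1\t100\tA\tG\t10\t0\t10\t0\t-5\t5\t10\t5"), cnt)
  expect_error(read_input_table(cnt, "counts"), "negative")
})

test_that("result tables round-trip bit-exactly", {
  tab <- tibble::tibble(gene = c("A", "B"), v_rd = c(1.23456789012345, 2),
                        n = c(3L, 5L), label = c("x", NA))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_result_tsv(tab, f, "roundtrip test")
  back <- read_result_tsv(f)
  expect_identical(back$gene, tab$gene)
  expect_identical(back$v_rd, tab$v_rd)   # full double precision survives
  expect_equal(back$n, tab$n)
  expect_identical(back$label, tab$label)
})

sam_lines <- function(reads, mapq = 60) {
  c("@HD\tVN:1.6\tSO:coordinate",
    "@SQ\tSN:chr1\tLN:1000",
    vapply(seq_along(reads), function(i) {
      paste(sprintf("r%03d", i), 0, "chr1", 95, mapq, "10M", "*", 0, 0,
            reads[[i]], strrep("I", 10), sep = "\t")
    }, ""))
}

make_bam <- function(lines, dir) {
  sam <- tempfile(tmpdir = dir, fileext = ".sam")
  writeLines(lines, sam)
  bam <- Rsamtools::asBam(sam, sub("\\.sam$", "", sam),
                          overwrite = TRUE, indexDestination = TRUE)
  bam
}

test_that("pileup counts match the constructed alignments", {
  d <- withr::local_tempdir()
  # reads start at 95 with 10M: position 100 is base 6 of the read
  base_at <- function(b) paste0("AACCT", b, "GGTT")
  reads <- c(rep(list(base_at("A")), 7), rep(list(base_at("G")), 3),
             rep(list(base_at("T")), 2))  # third base must be ignored
  bam <- make_bam(sam_lines(reads), d)
  site <- list(chrom = "chr1", pos = 100L, ref_allele = "A",
               alt_allele = "G")
  q <- pileup_quad_counts(list(Nex = bam, Ntr = bam, Tex = bam, Ttr = bam),
                          site)
  expect_equal(q$Tex_ref, 7L)
  expect_equal(q$Tex_var, 3L)
  expect_equal(q$Nex_ref + q$Nex_var, 10L)  # T reads in neither count

  low <- make_bam(sam_lines(reads, mapq = 5), d)
  q0 <- pileup_quad_counts(list(Nex = low, Ntr = low, Tex = low,
                                Ttr = low), site,
                           min_mapping_quality = 20)
  expect_equal(q0$Tex_ref, 0L)
  expect_equal(q0$Tex_var, 0L)

  site_bad <- list(chrom = "chr9", pos = 100L, ref_allele = "A",
                   alt_allele = "G")
  expect_error(pileup_quad_counts(list(Nex = bam, Ntr = bam, Tex = bam,
                                       Ttr = bam), site_bad), "Nex")
})
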