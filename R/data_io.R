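#' MAF Variant_Classification to consequence mapping
#'
#' Explicit, editable mapping from the GDC MAF `Variant_Classification`
#' vocabulary to the consequence classes used throughout the pipeline.
#' Splice-annotated variants map to `"splice"` and are excluded from the
#' allele-frequency analyses by the variant filter cascade; categories with
#' no protein-level interpretation map to `"other"`.
#'
#' @return a tibble with columns `variant_classification` and `consequence`.
#' @export
maf_consequence_map <- function() {
  tibble::tribble(
    ~variant_classification, ~consequence,
    "Nonsense_Mutation",     "PTV",
    "Missense_Mutation",     "missense",
    "Silent",                "silent",
    "Splice_Site",           "splice",
    "Splice_Region",         "splice",
    "Nonstop_Mutation",      "other",
    "Translation_Start_Site","other",
    "RNA",                   "other",
    "IGR",                   "other",
    "Intron",                "other",
    "5'UTR",                 "other",
    "3'UTR",                 "other",
    "5'Flank",               "other",
    "3'Flank",               "other"
  )
}

#' Read somatic variants from a MAF or VCF file
#'
#' Only bi-allelic single nucleotide substitutions are retained: indels and
#' multi-allelic rows are rejected and their count logged (and recorded in the
#' `n_rejected` attribute of the result). Coordinates are 1-based.
#'
#' @param path file path.
#' @param dialect `"maf"` (GDC tab-separated dialect) or `"vcf"`.
#' @param consequence_map mapping table as returned by
#'   [maf_consequence_map()]; unlisted classifications map to `"other"`.
#' @return tibble with columns `sample_id`, `cancer_type`, `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`, `gene`, `transcript_id`, `consequence`,
#'   `is_cgc` plus any recognised pathogenicity columns present in the input
#'   (`fathmm_score`, `fathmm_label`, `polyphen_score`, `cadd_score`,
#'   `gerp_score`). `cancer_type` and `is_cgc` are `NA` until joined to the
#'   sample table and CGC list downstream.
#' @export
read_variants <- function(path, dialect = c("maf", "vcf"),
                          consequence_map = maf_consequence_map()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) ase_stop(paste0("variant file not found: ", path))
  if (dialect == "maf") {
    read_variants_maf(path, consequence_map)
  } else {
    read_variants_vcf(path)
  }
}

valid_snv <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  ref %in% bases & alt %in% bases & ref != alt
}

read_variants_maf <- function(path, consequence_map) {
  maf <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  required <- c("Hugo_Symbol", "Chromosome", "Start_Position",
                "Reference_Allele", "Tumor_Seq_Allele2",
                "Variant_Classification", "Tumor_Sample_Barcode")
  missing <- setdiff(required, names(maf))
  if (length(missing) > 0)
    ase_stop(paste0("MAF is missing required column(s): ",
                    paste(missing, collapse = ", ")))
  if (nrow(maf) > 0 && !is.numeric(maf$Start_Position))
    ase_stop(paste0("unparseable Start_Position first at line ",
                    which(is.na(suppressWarnings(
                      as.numeric(maf$Start_Position))))[1] + 1L))

  is_snv <- valid_snv(maf$Reference_Allele, maf$Tumor_Seq_Allele2)
  if ("Variant_Type" %in% names(maf))
    is_snv <- is_snv & maf$Variant_Type == "SNP"
  n_rejected <- sum(!is_snv)
  if (n_rejected > 0)
    ase_log(n_rejected, " non-SNV (indel/multi-allelic) row(s) rejected from ",
            basename(path))
  maf <- maf[is_snv, , drop = FALSE]

  cons <- consequence_map$consequence[
    match(maf$Variant_Classification, consequence_map$variant_classification)]
  cons[is.na(cons)] <- "other"

  out <- tibble::tibble(
    sample_id = as.character(maf$Tumor_Sample_Barcode),
    cancer_type = NA_character_,
    chrom = as.character(maf$Chromosome),
    pos = as.integer(maf$Start_Position),
    ref_allele = maf$Reference_Allele,
    alt_allele = maf$Tumor_Seq_Allele2,
    gene = as.character(maf$Hugo_Symbol),
    transcript_id = if ("Transcript_ID" %in% names(maf))
      as.character(maf$Transcript_ID) else NA_character_,
    consequence = cons,
    is_cgc = NA
  )
  patho <- intersect(c("fathmm_score", "fathmm_label", "polyphen_score",
                       "cadd_score", "gerp_score"), names(maf))
  for (col in patho) out[[col]] <- maf[[col]]
  attr(out, "n_rejected") <- n_rejected
  out
}

read_variants_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    ase_stop("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    out <- tibble::tibble(sample_id = character(), cancer_type = character(),
                          chrom = character(), pos = integer(),
                          ref_allele = character(), alt_allele = character(),
                          gene = character(), transcript_id = character(),
                          consequence = character(), is_cgc = logical())
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  is_snv <- !multi & valid_snv(fix$REF, fix$ALT)
  n_rejected <- sum(!is_snv)
  if (n_rejected > 0)
    ase_log(n_rejected, " non-SNV row(s) rejected from ", basename(path))
  fix <- fix[is_snv, , drop = FALSE]
  info_field <- function(key) {
    m <- regmatches(fix$INFO, regexpr(paste0("(?<=", key, "=)[^;]+"),
                                      fix$INFO, perl = TRUE))
    out <- rep(NA_character_, nrow(fix))
    has <- grepl(paste0(key, "="), fix$INFO, fixed = TRUE)
    out[has] <- m
    out
  }
  gene <- info_field("GENE")
  sample <- info_field("SAMPLE")
  cons <- info_field("CONSEQ")
  cons[is.na(cons)] <- "other"
  out <- tibble::tibble(
    sample_id = sample, cancer_type = NA_character_,
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref_allele = fix$REF, alt_allele = fix$ALT,
    gene = gene, transcript_id = NA_character_,
    consequence = cons, is_cgc = NA
  )
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Read transcript models from a GTF file
#'
#' Builds one transcript model per transcript from `exon` and `CDS` features.
#' Exons are stored in transcription (5' to 3') order; on the minus strand the
#' first exon is therefore the rightmost genomic interval. Transcripts without
#' CDS features are retained but flagged non-coding and are excluded from NMD
#' classification.
#'
#' @param path GTF file.
#' @param cds_fasta optional FASTA of coding sequences named by transcript id;
#'   used by the NMD alternative-AUG rule.
#' @return named list of `transcript_model` objects (see
#'   [transcript_model()]), keyed by transcript id.
#' @export
read_gene_models <- function(path, cds_fasta = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  df <- as.data.frame(gr)
  if (!"transcript_id" %in% names(df))
    ase_stop("GTF has no transcript_id attribute")
  seqs <- NULL
  if (!is.null(cds_fasta)) {
    ss <- Biostrings::readDNAStringSet(cds_fasta)
    seqs <- stats::setNames(as.character(ss), names(ss))
  }
  models <- list()
  for (tid in unique(df$transcript_id[!is.na(df$transcript_id)])) {
    sub <- df[df$transcript_id == tid & !is.na(df$transcript_id), ]
    ex <- sub[sub$type == "exon", ]
    cds <- sub[sub$type == "CDS", ]
    if (nrow(ex) == 0) {
      if (nrow(cds) > 0)
        ase_stop(paste0("transcript ", tid, " has CDS but no exons"))
      next
    }
    strand <- as.character(ex$strand[1])
    gene <- if ("gene_id" %in% names(ex)) as.character(ex$gene_id[1]) else tid
    coding <- nrow(cds) > 0
    cds_left <- if (coding) min(cds$start) else NA_integer_
    cds_right <- if (coding) max(cds$end) else NA_integer_
    models[[tid]] <- transcript_model(
      transcript_id = tid, gene = gene,
      chrom = as.character(ex$seqnames[1]), strand = strand,
      exon_starts = ex$start, exon_ends = ex$end,
      cds_start = if (!coding) NA_integer_
                  else if (strand == "+") cds_left else cds_right,
      cds_end = if (!coding) NA_integer_
                else if (strand == "+") cds_right else cds_left,
      cds_seq = if (!is.null(seqs) && tid %in% names(seqs)) seqs[[tid]]
                else NULL
    )
  }
  models
}

#' Construct a transcript model
#'
#' @param transcript_id,gene,chrom,strand identifiers; strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends 1-based inclusive genomic exon intervals (any
#'   order; they are sorted into transcription order).
#' @param cds_start genomic coordinate of the first base of the start codon
#'   (`NA` for non-coding transcripts).
#' @param cds_end genomic coordinate of the last base of the coding region.
#' @param cds_seq optional coding sequence (character), used by the NMD
#'   alternative-AUG rule.
#' @param half_life_hours optional transcript half-life.
#' @param nmd_insensitive logical flag.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene, chrom, strand,
                             exon_starts, exon_ends,
                             cds_start = NA_integer_, cds_end = NA_integer_,
                             cds_seq = NULL, half_life_hours = NA_real_,
                             nmd_insensitive = FALSE) {
  stopifnot(length(exon_starts) == length(exon_ends),
            all(exon_starts <= exon_ends), strand %in% c("+", "-"))
  ord <- order(exon_starts)
  if (strand == "-") ord <- rev(ord)
  exons <- data.frame(start = exon_starts[ord], end = exon_ends[ord])
  # exons must not overlap
  left <- sort(exon_starts); right <- sort(exon_ends)
  if (length(left) > 1 && any(left[-1] <= right[-length(right)]))
    ase_stop(paste0("overlapping exons in transcript ", transcript_id))
  coding <- !is.na(cds_start)
  if (coding) {
    inside <- function(p) any(exons$start <= p & p <= exons$end)
    if (!inside(cds_start) || !inside(cds_end))
      ase_stop(paste0("CDS boundaries outside exons for ", transcript_id))
  }
  structure(list(
    transcript_id = transcript_id, gene = gene, chrom = chrom,
    strand = strand, exons = exons, cds_start = cds_start, cds_end = cds_end,
    coding = coding, single_exon = nrow(exons) == 1L,
    cds_seq = cds_seq, half_life_hours = half_life_hours,
    nmd_insensitive = nmd_insensitive
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$transcript_id, " (", x$gene, ") ",
      x$chrom, x$strand, " ", nrow(x$exons), " exon(s), ",
      if (x$coding) paste0("CDS ", x$cds_start, "..", x$cds_end)
      else "non-coding", "\n", sep = "")
  invisible(x)
}

#' Count reference and variant reads across the four datasets by pileup
#'
#' Optional helper computing a quad-count record directly from four
#' coordinate-sorted, indexed alignment files (normal exome, normal
#' transcriptome, tumor exome, tumor transcriptome). Reads are counted toward
#' `n_ref`/`n_var` when their base at the site matches the reference/variant
#' allele and passes the quality thresholds; any other base is ignored.
#' Duplicate-flagged reads are excluded.
#'
#' @param alignments named list/character vector of BAM paths with names
#'   `Nex`, `Ntr`, `Tex`, `Ttr`.
#' @param site one-row variant data frame (or list) with `chrom`, `pos`,
#'   `ref_allele`, `alt_allele`.
#' @param min_base_quality,min_mapping_quality phred thresholds (default 20).
#' @return one-row tibble with columns `Nex_ref`, `Nex_var`, ..., `Ttr_var`.
#' @export
pileup_quad_counts <- function(alignments, site,
                               min_base_quality = 20L,
                               min_mapping_quality = 20L) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    ase_stop("pileup counting requires the Rsamtools package")
  needed <- c("Nex", "Ntr", "Tex", "Ttr")
  if (!all(needed %in% names(alignments)))
    ase_stop("alignments must be named Nex, Ntr, Tex, Ttr")
  out <- list()
  for (ds in needed) {
    bf <- Rsamtools::BamFile(alignments[[ds]])
    contigs <- names(Rsamtools::scanBamHeader(bf)$targets)
    if (!site$chrom %in% contigs)
      ase_stop(paste0("contig ", site$chrom, " absent from dataset ", ds))
    which <- GenomicRanges::GRanges(site$chrom,
                                    IRanges::IRanges(site$pos, site$pos))
    pp <- Rsamtools::PileupParam(
      max_depth = 1e6L,
      min_base_quality = as.integer(min_base_quality),
      min_mapq = as.integer(min_mapping_quality),
      distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
      include_deletions = FALSE, include_insertions = FALSE)
    sp <- Rsamtools::ScanBamParam(
      which = which,
      flag = Rsamtools::scanBamFlag(isDuplicate = FALSE))
    pu <- Rsamtools::pileup(bf, scanBamParam = sp, pileupParam = pp)
    n_of <- function(base) {
      hit <- pu$nucleotide == base & pu$pos == site$pos
      if (any(hit)) sum(pu$count[hit]) else 0L
    }
    out[[paste0(ds, "_ref")]] <- n_of(site$ref_allele)
    out[[paste0(ds, "_var")]] <- n_of(site$alt_allele)
  }
  tibble::as_tibble(out)
}

#' Read one of the pipeline's tabular inputs
#'
#' Tab-separated inputs with documented headers. `kind = "bed"` reads a
#' standard 0-based half-open BED and returns a `GRanges` in the package's
#' internal 1-based inclusive convention; `kind = "gene_list"` reads one
#' symbol per line.
#'
#' @param path file path.
#' @param kind one of `"counts"`, `"purity"`, `"segments"`, `"expression"`,
#'   `"gene_list"`, `"half_life"`, `"bed"`, `"samples"`.
#' @return a tibble (or `GRanges` for `"bed"`, character vector for
#'   `"gene_list"`).
#' @export
read_input_table <- function(path, kind = c("counts", "purity", "segments",
                                            "expression", "gene_list",
                                            "half_life", "bed", "samples")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) ase_stop(paste0("input file not found: ", path))
  if (kind == "gene_list") {
    x <- readLines(path)
    return(x[nzchar(x)])
  }
  if (kind == "bed") {
    return(rtracklayer::import(path, format = "bed"))
  }
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  required <- switch(kind,
    counts = c("sample_id", "chrom", "pos", "ref_allele", "alt_allele",
               "Nex_ref", "Nex_var", "Ntr_ref", "Ntr_var",
               "Tex_ref", "Tex_var", "Ttr_ref", "Ttr_var"),
    purity = c("sample_id", "ESTIMATE", "ABSOLUTE", "LUMP", "IHC", "CPE"),
    segments = c("sample_id", "chrom", "start", "end", "segment_mean"),
    expression = c("gene", "sample_id", "tumor_expr", "normal_expr"),
    half_life = c("transcript_id", "half_life_hours"),
    samples = c("sample_id", "cancer_type"))
  missing <- setdiff(required, names(tb))
  if (length(missing) > 0)
    ase_stop(paste0(kind, " table is missing column(s): ",
                    paste(missing, collapse = ", ")))
  if (kind == "counts") {
    cnt <- tb[, grep("_(ref|var)$", names(tb))]
    if (any(as.matrix(cnt) < 0, na.rm = TRUE))
      ase_stop("negative read counts in counts table")
  }
  if (kind == "purity") {
    vals <- as.matrix(tb[, c("ESTIMATE", "ABSOLUTE", "LUMP", "IHC", "CPE")])
    if (any(vals < 0 | vals > 1, na.rm = TRUE))
      ase_stop("purity estimates must lie in [0, 1]")
  }
  if (kind == "segments" && any(tb$start > tb$end))
    ase_stop("segment with start > end")
  if (kind == "expression" &&
      any(tb$tumor_expr < 0 | tb$normal_expr < 0, na.rm = TRUE))
    ase_stop("negative expression values")
  if (kind == "half_life" && any(tb$half_life_hours <= 0, na.rm = TRUE))
    ase_stop("half-lives must be positive")
  tb
}
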