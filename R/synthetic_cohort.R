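#' Synthetic-cohort configuration
#'
#' Default study conditions for the synthetic cohort: a matched-quad design
#' (normal exome/transcriptome, tumor exome/transcriptome) of clonal
#' heterozygous SNVs in diploid tumors admixed with normal tissue. Under
#' this model the expected tumor-DNA variant fraction is
#' `f_dna * purity` (= purity/2 at the default `f_dna = 0.5`), and the
#' expected tumor-RNA variant fraction is the odds-multiplier form
#' `s*v / (s*v + 1 - v)` for allelic selection `s`, further scaled by
#' `(1 - d)` (renormalized) for NMD-elicit PTVs with degradation
#' efficiency `d`.
#'
#' @param n_samples samples in the cohort (spread round-robin over
#'   `cancer_types`).
#' @param variants_per_sample somatic SNVs simulated per sample.
#' @param cancer_types synthetic cancer-type codes.
#' @param n_genes size of the synthetic gene universe.
#' @param frac_ptv,frac_missense,frac_silent consequence mix (sums to 1).
#' @param cgc_fraction fraction of genes labelled as CGC members.
#' @param purity `list(shape1, shape2, fixed)`: Beta parameters of the
#'   per-sample purity, or a fixed value.
#' @param f_dna true variant fraction of tumor-cell DNA (0.5 = clonal
#'   heterozygous diploid).
#' @param depth `list(mean, fixed)`: Poisson mean of per-dataset read
#'   depth (truncated below at 10), or fixed depth.
#' @param p_err per-read sequencing error probability used when mixing
#'   counts.
#' @param selection `list(sdlog, ptv_meanlog, frac_strong, strong_meanlog,
#'   strong_sdlog)`: log-normal allelic-selection model; PTVs receive a
#'   mild negative shift, and a small fraction of variants a strong
#'   positive multiplier emulating allelic amplification / LOH-driven
#'   skew.
#' @param nmd_degradation degradation efficiency `d` applied to NMD-elicit
#'   PTVs.
#' @param rho_selection_expression induced (Pearson, bivariate-normal)
#'   correlation between log selection and the expression effect beta
#'   (log2 fold change).
#' @param expression `list(meanlog, sdlog, beta_sd, noise_sd_log2)`:
#'   baseline normal-tissue abundance, spread of the true log2 fold beta,
#'   and measurement noise.
#' @param frac_chrx,frac_imprinted,frac_germline fractions of genes placed
#'   on chrX / in an imprinted region, and of variants contaminated with
#'   germline signal, exercising the filter cascade.
#' @param tfbs `list(frac_gain, frac_loss, halfwidth)`: fractions of
#'   variants with a planted TFBS gain/loss and the window half-width.
#' @return named list of class `cohort_config`.
#' @export
cohort_config <- function(
    n_samples = 40L,
    variants_per_sample = 25L,
    cancer_types = c("SYNA", "SYNB", "SYNC", "SYND"),
    n_genes = 300L,
    frac_ptv = 0.20, frac_missense = 0.50, frac_silent = 0.30,
    cgc_fraction = 0.10,
    purity = list(shape1 = 6.5, shape2 = 3.5, fixed = NULL),
    f_dna = 0.5,
    depth = list(mean = 80, fixed = NULL),
    p_err = 0.001,
    selection = list(sdlog = 0.5, ptv_meanlog = log(0.8),
                     frac_strong = 0.05, strong_meanlog = log(50),
                     strong_sdlog = 0.3),
    nmd_degradation = 0.8,
    rho_selection_expression = 0.3,
    expression = list(meanlog = log(20), sdlog = 1, beta_sd = 1,
                      noise_sd_log2 = 0.1),
    frac_chrx = 0.02, frac_imprinted = 0.02, frac_germline = 0.02,
    tfbs = list(frac_gain = 0.05, frac_loss = 0.05, halfwidth = 20L)) {
  cfg <- as.list(environment())
  if (abs(cfg$frac_ptv + cfg$frac_missense + cfg$frac_silent - 1) > 1e-8)
    ase_stop("consequence fractions must sum to 1")
  if (cfg$nmd_degradation < 0 || cfg$nmd_degradation > 1)
    ase_stop("nmd_degradation must lie in [0, 1]")
  if (abs(cfg$rho_selection_expression) >= 1)
    ase_stop("rho_selection_expression must lie in (-1, 1)")
  structure(cfg, class = "cohort_config")
}

# Archetype geometries for synthetic genes (local 1-based coordinates).
# Every NMD rule is represented so each escape flag fires in truth.
gene_archetypes <- function() {
  three_exon <- data.frame(start = c(1L, 401L, 801L),
                           end = c(300L, 700L, 1100L))
  list(
    elicit = list(exons = three_exon, cds = c(51L, 1050L),
                  ptv_site = 550L, alt_sites = c(470L, 530L, 590L, 650L),
                  half_life = 10, insensitive = FALSE, span = 1100L),
    last_exon = list(exons = three_exon, cds = c(51L, 1050L),
                     ptv_site = 900L, alt_sites = c(470L, 530L, 590L, 650L),
                     half_life = 10, insensitive = FALSE, span = 1100L),
    single_exon = list(exons = data.frame(start = 1L, end = 1200L),
                       cds = c(101L, 1100L),
                       ptv_site = 550L, alt_sites = c(450L, 500L, 600L, 650L),
                       half_life = 10, insensitive = FALSE, span = 1200L),
    start_aug = list(exons = three_exon, cds = c(51L, 1050L),
                     ptv_site = 150L, alt_sites = c(470L, 530L, 590L, 650L),
                     half_life = 10, insensitive = FALSE, span = 1100L,
                     plant_aug = TRUE),
    long_exon = list(exons = data.frame(start = c(1L, 401L, 1601L),
                                        end = c(300L, 1500L, 1900L)),
                     cds = c(51L, 1850L),
                     ptv_site = 501L, alt_sites = c(700L, 760L, 820L, 880L),
                     half_life = 10, insensitive = FALSE, span = 1900L),
    short_halflife = list(exons = three_exon, cds = c(51L, 1050L),
                          ptv_site = 550L,
                          alt_sites = c(470L, 530L, 590L, 650L),
                          half_life = 0.5, insensitive = FALSE, span = 1100L),
    insensitive = list(exons = three_exon, cds = c(51L, 1050L),
                       ptv_site = 550L, alt_sites = c(470L, 530L, 590L, 650L),
                       half_life = 10, insensitive = TRUE, span = 1100L)
  )
}

# Random CDS made of sense codons, avoiding in-frame ATG (and stop codons)
# unless plant_aug: then one ATG codon is placed mid-CDS.
random_cds <- function(n_codons, plant_aug = FALSE) {
  codons <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                              c("A","C","G","T")), 1, paste0, collapse = "")
  codons <- setdiff(codons, c("ATG", "TAA", "TAG", "TGA"))
  out <- sample(codons, n_codons, replace = TRUE)
  if (plant_aug) out[max(2L, n_codons %/% 2L)] <- "ATG"
  paste0(out, collapse = "")
}

random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Sharp 6-nt PWMs used for the planted TFBS truth: with uniformly sharp
# columns the relative score of a k-mismatch word is (w-k)/w, so at the
# default 0.85 threshold only the exact consensus of a width-6 motif hits.
synthetic_motifs <- function() {
  make <- function(id, consensus) {
    w <- nchar(consensus)
    m <- matrix(0, 4, w, dimnames = list(c("A", "C", "G", "T"), NULL))
    for (j in seq_len(w)) m[substr(consensus, j, j), j] <- 1
    list(id = id, name = id, matrix = m, consensus = consensus)
  }
  list(SYN1 = make("SYN1", "TGACTC"), SYN2 = make("SYN2", "GGGCGG"))
}

#' Generate a synthetic study cohort with recorded truth
#'
#' Produces every input the pipeline consumes — variants, quad read
#' counts, gene models with coding sequences, imprinted regions, gene
#' lists, half-lives, purity estimates, copy-number segments, matched
#' tumor/normal expression, PWM motifs and reference windows — together
#' with a per-variant truth table enabling parameter-recovery tests. Fully
#' deterministic given `seed`.
#'
#' @param config see [cohort_config()].
#' @param seed integer RNG seed.
#' @return named list (class `synthetic_cohort`) with elements `variants`,
#'   `counts`, `samples`, `purity`, `segments`, `expression`, `models`,
#'   `half_life`, `insensitive_genes`, `cgc_genes`, `imprinted`, `motifs`,
#'   `windows`, `truth`, `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(as.integer(seed))
  arch <- gene_archetypes()
  arch_names <- names(arch)
  arch_probs <- c(elicit = 0.60, last_exon = 0.08, single_exon = 0.08,
                  start_aug = 0.08, long_exon = 0.08,
                  short_halflife = 0.04, insensitive = 0.04)

  ## ---- gene universe -------------------------------------------------
  n_genes <- config$n_genes
  genes <- sprintf("SGENE%03d", seq_len(n_genes))
  gene_arch <- sample(arch_names, n_genes, replace = TRUE,
                      prob = arch_probs[arch_names])
  n_x <- max(0L, round(config$frac_chrx * n_genes))
  n_imp <- max(0L, round(config$frac_imprinted * n_genes))
  special <- sample(n_genes, n_x + n_imp)
  x_genes <- special[seq_len(n_x)]
  imp_genes <- special[setdiff(seq_len(n_x + n_imp), seq_len(n_x))]
  autosomes <- paste0("chr", 1:5)
  gene_chrom <- autosomes[(seq_len(n_genes) - 1L) %% 5L + 1L]
  gene_chrom[x_genes] <- "chrX"
  gene_strand <- ifelse(seq_len(n_genes) %% 2L == 0L, "-", "+")
  gene_base <- 10000L + ((seq_len(n_genes) - 1L) %/% 5L) * 20000L
  cgc_genes <- genes[sample(n_genes, max(1L, round(config$cgc_fraction *
                                                     n_genes)))]
  models <- list()
  half_life <- tibble::tibble(transcript_id = character(),
                              half_life_hours = numeric())
  insensitive_genes <- character(0)
  imprinted_rows <- list()
  for (i in seq_len(n_genes)) {
    a <- arch[[gene_arch[i]]]
    tid <- paste0("STX", substring(genes[i], 6))
    n_codons <- (a$cds[2] - a$cds[1] + 1L) %/% 3L  # genomic span, ample
    cds_seq <- random_cds(max(70L, min(n_codons, 350L)),
                          plant_aug = isTRUE(a$plant_aug))
    models[[tid]] <- transcript_model(
      transcript_id = tid, gene = genes[i], chrom = gene_chrom[i],
      strand = gene_strand[i],
      exon_starts = gene_base[i] + a$exons$start - 1L,
      exon_ends = gene_base[i] + a$exons$end - 1L,
      cds_start = gene_base[i] +
        (if (gene_strand[i] == "+") a$cds[1] else a$cds[2]) - 1L,
      cds_end = gene_base[i] +
        (if (gene_strand[i] == "+") a$cds[2] else a$cds[1]) - 1L,
      cds_seq = cds_seq, half_life_hours = a$half_life,
      nmd_insensitive = a$insensitive)
    half_life <- dplyr::bind_rows(half_life, tibble::tibble(
      transcript_id = tid, half_life_hours = a$half_life))
    if (a$insensitive) insensitive_genes <- c(insensitive_genes, genes[i])
    if (i %in% imp_genes)
      imprinted_rows[[length(imprinted_rows) + 1L]] <- tibble::tibble(
        chrom = gene_chrom[i], start = gene_base[i],
        end = gene_base[i] + a$span - 1L)
  }
  imprinted <- if (length(imprinted_rows) > 0) {
    df <- dplyr::bind_rows(imprinted_rows)
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
  } else GenomicRanges::GRanges()

  ## ---- samples -------------------------------------------------------
  n_s <- config$n_samples
  sample_ids <- sprintf("SAMP%03d", seq_len(n_s))
  samples <- tibble::tibble(
    sample_id = sample_ids,
    cancer_type = config$cancer_types[(seq_len(n_s) - 1L) %%
                                        length(config$cancer_types) + 1L])
  pur_fixed <- config$purity$fixed
  purity_true <- if (!is.null(pur_fixed)) rep(pur_fixed, n_s)
    else stats::rbeta(n_s, config$purity$shape1, config$purity$shape2)
  purity <- tibble::tibble(sample_id = sample_ids)
  for (m in c("ESTIMATE", "ABSOLUTE", "LUMP", "IHC", "CPE")) {
    vals <- pmin(1, pmax(0, purity_true + stats::rnorm(n_s, 0, 0.03)))
    vals[stats::runif(n_s) < 0.1] <- NA_real_
    purity[[m]] <- vals
  }

  ## ---- variants ------------------------------------------------------
  n_v <- n_s * config$variants_per_sample
  v_sample <- rep(sample_ids, each = config$variants_per_sample)
  v_gene_idx <- sample(n_genes, n_v, replace = TRUE)
  v_cons <- sample(c("PTV", "missense", "silent"), n_v, replace = TRUE,
                   prob = c(config$frac_ptv, config$frac_missense,
                            config$frac_silent))
  # archetype site coordinates are written for the plus strand; on minus-
  # strand genes they are mirrored (the exon/CDS layouts are palindromic,
  # so the transcription-relative geometry is identical on both strands)
  pos <- integer(n_v)
  for (k in seq_len(n_v)) {
    gi <- v_gene_idx[k]
    a <- arch[[gene_arch[gi]]]
    local <- if (v_cons[k] == "PTV") a$ptv_site
             else sample(a$alt_sites, 1L)
    if (gene_strand[gi] == "-") local <- a$span + 1L - local
    pos[k] <- gene_base[gi] + local - 1L
  }

  ## ---- truth: selection, expression beta, NMD ------------------------
  sel <- config$selection
  rho <- config$rho_selection_expression
  z1 <- stats::rnorm(n_v)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_v)
  log_s <- sel$sdlog * z1 + ifelse(v_cons == "PTV", sel$ptv_meanlog, 0)
  strong <- stats::runif(n_v) < sel$frac_strong
  log_s[strong] <- log_s[strong] +
    stats::rnorm(sum(strong), sel$strong_meanlog, sel$strong_sdlog)
  s <- exp(log_s)
  beta <- config$expression$beta_sd * z2

  v_arch <- gene_arch[v_gene_idx]
  nmd_truth <- ifelse(v_cons != "PTV", NA_character_,
                      ifelse(v_arch == "elicit", "elicit", "escape"))
  d_applied <- ifelse(!is.na(nmd_truth) & nmd_truth == "elicit",
                      config$nmd_degradation, 0)

  pur_v <- purity_true[match(v_sample, sample_ids)]
  v_dna <- config$f_dna * pur_v
  mu_rna <- (1 - d_applied) * s * v_dna /
    ((1 - d_applied) * s * v_dna + (1 - v_dna))

  ## ---- read counts ---------------------------------------------------
  draw_depth <- function(n) {
    if (!is.null(config$depth$fixed)) rep(as.integer(config$depth$fixed), n)
    else pmax(10L, stats::rpois(n, config$depth$mean))
  }
  p_err <- config$p_err
  mix <- function(p) p * (1 - p_err) + (1 - p) * p_err
  germline <- stats::runif(n_v) < config$frac_germline
  dep_nex <- draw_depth(n_v); dep_ntr <- draw_depth(n_v)
  dep_tex <- draw_depth(n_v); dep_ttr <- draw_depth(n_v)
  nex_var <- stats::rbinom(n_v, dep_nex, ifelse(germline, mix(v_dna), p_err))
  ntr_var <- stats::rbinom(n_v, dep_ntr, ifelse(germline, mix(mu_rna), p_err))
  tex_var <- stats::rbinom(n_v, dep_tex, mix(v_dna))
  ttr_var <- stats::rbinom(n_v, dep_ttr, mix(mu_rna))

  ## ---- TFBS windows and alleles --------------------------------------
  motifs <- synthetic_motifs()
  hw <- config$tfbs$halfwidth
  wlen <- 2L * hw + 1L
  tfbs_truth <- sample(c("gain", "loss", "none"), n_v, replace = TRUE,
                       prob = c(config$tfbs$frac_gain, config$tfbs$frac_loss,
                                1 - config$tfbs$frac_gain -
                                  config$tfbs$frac_loss))
  windows <- character(n_v)
  ref_allele <- character(n_v)
  alt_allele <- character(n_v)
  bases <- c("A", "C", "G", "T")
  for (k in seq_len(n_v)) {
    win <- random_seq(wlen)
    if (tfbs_truth[k] == "none") {
      ref <- substr(win, hw + 1L, hw + 1L)
      alt <- sample(setdiff(bases, ref), 1L)
    } else {
      m <- motifs[[sample(names(motifs), 1L)]]
      w <- nchar(m$consensus)
      j <- sample(seq_len(w), 1L)             # motif column under the variant
      start <- hw + 1L - (j - 1L)             # motif start so column j = center
      substr(win, start, start + w - 1L) <- m$consensus
      cons_base <- substr(m$consensus, j, j)
      if (tfbs_truth[k] == "gain") {
        ref <- sample(setdiff(bases, cons_base), 1L)
        alt <- cons_base
        substr(win, hw + 1L, hw + 1L) <- ref   # reference lacks the motif
      } else {
        ref <- cons_base                       # reference carries the motif
        alt <- sample(setdiff(bases, cons_base), 1L)
      }
    }
    windows[k] <- win
    ref_allele[k] <- ref
    alt_allele[k] <- alt
  }

  variants <- tibble::tibble(
    sample_id = v_sample,
    cancer_type = samples$cancer_type[match(v_sample, samples$sample_id)],
    chrom = gene_chrom[v_gene_idx],
    pos = pos,
    ref_allele = ref_allele,
    alt_allele = alt_allele,
    gene = genes[v_gene_idx],
    transcript_id = paste0("STX", substring(genes[v_gene_idx], 6)),
    consequence = v_cons,
    is_cgc = genes[v_gene_idx] %in% cgc_genes)
  key <- variant_key(variants$sample_id, variants$chrom, variants$pos,
                     variants$ref_allele, variants$alt_allele)
  dup <- duplicated(key)
  if (any(dup)) {
    variants <- variants[!dup, , drop = FALSE]
    key <- key[!dup]
  }
  keep <- !dup

  counts <- tibble::tibble(
    sample_id = variants$sample_id, chrom = variants$chrom,
    pos = variants$pos, ref_allele = variants$ref_allele,
    alt_allele = variants$alt_allele,
    Nex_ref = (dep_nex - nex_var)[keep], Nex_var = nex_var[keep],
    Ntr_ref = (dep_ntr - ntr_var)[keep], Ntr_var = ntr_var[keep],
    Tex_ref = (dep_tex - tex_var)[keep], Tex_var = tex_var[keep],
    Ttr_ref = (dep_ttr - ttr_var)[keep], Ttr_var = ttr_var[keep])

  ## ---- expression ----------------------------------------------------
  ex <- config$expression
  gs <- tibble::tibble(gene = variants$gene, sample_id = variants$sample_id,
                       beta = beta[keep])
  gs <- gs[!duplicated(paste(gs$gene, gs$sample_id)), , drop = FALSE]
  normal <- stats::rlnorm(nrow(gs), ex$meanlog, ex$sdlog)
  noise <- stats::rnorm(nrow(gs), 0, ex$noise_sd_log2)
  expression <- tibble::tibble(
    gene = gs$gene, sample_id = gs$sample_id,
    tumor_expr = normal * 2^(gs$beta + noise),
    normal_expr = normal)

  ## ---- segments ------------------------------------------------------
  chrom_span <- max(gene_base) + 20000L
  seg_rows <- list()
  for (sid in sample_ids) {
    for (ch in c(autosomes, if (n_x > 0) "chrX")) {
      seg_rows[[length(seg_rows) + 1L]] <- tibble::tibble(
        sample_id = sid, chrom = ch, start = 1L, end = chrom_span,
        segment_mean = stats::rnorm(1, 0, 0.2))
    }
  }
  segments <- dplyr::bind_rows(seg_rows)

  truth <- tibble::tibble(
    variant_key = key,
    sample_id = variants$sample_id, gene = variants$gene,
    consequence = variants$consequence, archetype = v_arch[keep],
    purity = pur_v[keep], f_dna = config$f_dna,
    selection_s = s[keep], beta_log2fc = beta[keep],
    nmd_truth = nmd_truth[keep], degradation = d_applied[keep],
    expected_vaf_tdna = v_dna[keep], expected_vaf_trna = mu_rna[keep],
    germline_contaminated = germline[keep],
    tfbs_truth = tfbs_truth[keep],
    on_chrx = variants$chrom == "chrX",
    in_imprinted = variants$gene %in% genes[imp_genes])

  structure(list(
    variants = variants, counts = counts, samples = samples,
    purity = purity, segments = segments, expression = expression,
    models = models, half_life = half_life,
    insensitive_genes = insensitive_genes, cgc_genes = cgc_genes,
    imprinted = imprinted, motifs = motifs,
    windows = tibble::tibble(variant_key = key, window = windows[keep]),
    truth = truth, config = config, seed = as.integer(seed)
  ), class = "synthetic_cohort")
}

#' Write a synthetic cohort to disk in the dialects the readers consume
#'
#' Emits: `variants.maf`, `counts.tsv`, `samples.tsv`, `purity.tsv`,
#' `segments.tsv`, `expression.tsv`, `models.gtf`, `cds.fa`,
#' `imprinted.bed`, `cgc_genes.txt`, `nmd_insensitive.txt`,
#' `half_life.tsv`, `motifs.jaspar`, `windows.fa`, `truth.tsv` and a
#' `config.yaml` naming them all, suitable for [run_pipeline()].
#' Re-reading the bundle reproduces the in-memory cohort; two writes of
#' the same cohort are byte-identical.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)

  v <- cohort$variants
  maf <- tibble::tibble(
    Hugo_Symbol = v$gene, Chromosome = v$chrom, Start_Position = v$pos,
    End_Position = v$pos, Reference_Allele = v$ref_allele,
    Tumor_Seq_Allele2 = v$alt_allele,
    Variant_Classification = dplyr::case_when(
      v$consequence == "PTV" ~ "Nonsense_Mutation",
      v$consequence == "missense" ~ "Missense_Mutation",
      v$consequence == "silent" ~ "Silent",
      v$consequence == "splice" ~ "Splice_Site",
      TRUE ~ "RNA"),
    Variant_Type = "SNP",
    Tumor_Sample_Barcode = v$sample_id,
    Transcript_ID = v$transcript_id)
  write_result_tsv(maf, p("variants.maf"), "synthetic MAF")
  write_result_tsv(cohort$counts, p("counts.tsv"), "quad counts")
  write_result_tsv(cohort$samples, p("samples.tsv"), "samples")
  write_result_tsv(cohort$purity, p("purity.tsv"), "purity")
  write_result_tsv(cohort$segments, p("segments.tsv"), "segments")
  write_result_tsv(cohort$expression, p("expression.tsv"), "expression")
  write_result_tsv(cohort$half_life, p("half_life.tsv"), "half-life")
  write_result_tsv(cohort$truth, p("truth.tsv"), "generator truth")

  gtf <- character(0)
  for (m in cohort$models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', m$gene,
                     m$transcript_id)
    ex <- m$exons[order(m$exons$start), , drop = FALSE]
    for (i in seq_len(nrow(ex)))
      gtf <- c(gtf, paste(m$chrom, "somaticASE", "exon", ex$start[i],
                          ex$end[i], ".", m$strand, ".", attrs, sep = "\t"))
    if (m$coding) {
      cl <- min(m$cds_start, m$cds_end); cr <- max(m$cds_start, m$cds_end)
      for (i in seq_len(nrow(ex))) {
        s0 <- max(ex$start[i], cl); e0 <- min(ex$end[i], cr)
        if (s0 <= e0)
          gtf <- c(gtf, paste(m$chrom, "somaticASE", "CDS", s0, e0, ".",
                              m$strand, "0", attrs, sep = "\t"))
      }
    }
  }
  writeLines(gtf, p("models.gtf"))

  cds <- unlist(lapply(cohort$models, function(m)
    if (!is.null(m$cds_seq)) c(paste0(">", m$transcript_id), m$cds_seq)))
  writeLines(cds, p("cds.fa"))

  if (length(cohort$imprinted) > 0) {
    df <- as.data.frame(cohort$imprinted)
    writeLines(paste(df$seqnames, df$start - 1L, df$end, sep = "\t"),
               p("imprinted.bed"))
  } else writeLines(character(0), p("imprinted.bed"))

  writeLines(cohort$cgc_genes, p("cgc_genes.txt"))
  writeLines(cohort$insensitive_genes, p("nmd_insensitive.txt"))

  jaspar <- character(0)
  for (m in cohort$motifs) {
    counts <- round(m$matrix * 100)
    jaspar <- c(jaspar, paste0(">", m$id, " ", m$name),
                vapply(c("A", "C", "G", "T"), function(b)
                  paste0(b, "  [ ", paste(counts[b, ], collapse = " "),
                         " ]"), ""))
  }
  writeLines(jaspar, p("motifs.jaspar"))

  writeLines(as.vector(rbind(paste0(">", cohort$windows$variant_key),
                             cohort$windows$window)), p("windows.fa"))

  cfg <- list(
    inputs = list(
      variants = "variants.maf", variant_dialect = "maf",
      counts = "counts.tsv", samples = "samples.tsv",
      purity = "purity.tsv", segments = "segments.tsv",
      expression = "expression.tsv", gtf = "models.gtf",
      cds_fasta = "cds.fa", imprinted_bed = "imprinted.bed",
      cgc_genes = "cgc_genes.txt",
      nmd_insensitive_genes = "nmd_insensitive.txt",
      half_life = "half_life.tsv", motifs = "motifs.jaspar",
      windows_fasta = "windows.fa"),
    params = list(p_err = 0.05, alpha = 0.05, min_depth = 10,
                  min_dna_minor_reads = 2, max_normal_var_reads = 1,
                  min_group_size = 10, expression_floor = 0.01,
                  tfbs_rel_score_threshold = 0.85, min_mutations = 3,
                  nmd_rule1 = "canonical"))
  yaml::write_yaml(cfg, p("config.yaml"))
  invisible(dir)
}

#' Read a written bundle back into memory
#'
#' Convenience loader for bundles produced by [write_bundle()], returning
#' the tables in the shapes [run_pipeline()] uses.
#'
#' @param dir bundle directory.
#' @return named list of inputs.
#' @export
read_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  variants <- read_variants(p("variants.maf"), "maf")
  samples <- read_input_table(p("samples.tsv"), "samples")
  variants$cancer_type <- samples$cancer_type[
    match(variants$sample_id, samples$sample_id)]
  cgc <- read_input_table(p("cgc_genes.txt"), "gene_list")
  variants$is_cgc <- variants$gene %in% cgc
  list(
    variants = variants,
    counts = read_input_table(p("counts.tsv"), "counts"),
    samples = samples,
    purity = read_input_table(p("purity.tsv"), "purity"),
    segments = read_input_table(p("segments.tsv"), "segments"),
    expression = read_input_table(p("expression.tsv"), "expression"),
    models = read_gene_models(p("models.gtf"), cds_fasta = p("cds.fa")),
    half_life = read_input_table(p("half_life.tsv"), "half_life"),
    insensitive_genes = read_input_table(p("nmd_insensitive.txt"),
                                         "gene_list"),
    cgc_genes = cgc,
    imprinted = read_input_table(p("imprinted.bed"), "bed"),
    motifs = read_jaspar(p("motifs.jaspar")),
    windows = {
      ss <- Biostrings::readDNAStringSet(p("windows.fa"))
      tibble::tibble(variant_key = names(ss), window = as.character(ss))
    },
    truth = read_result_tsv(p("truth.tsv")))
}
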