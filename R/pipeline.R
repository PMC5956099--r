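#' Run the full allele-frequency pipeline on a configured input bundle
#'
#' Stage order: sample filters (purity availability, hypermutator rule,
#' minimum group size) -> variant filter cascade -> allele metrics and
#' expression-status calls -> NMD annotation of PTVs -> TFBS gain/loss ->
#' association analyses (expression fold change, stratified correlations,
#' extreme subsets, gene ranking, CGC enrichment, segment-mean
#' comparisons). A missing expression table skips the association stage
#' with a logged warning; the allele table is still produced. Identical
#' config and inputs give byte-identical outputs.
#'
#' @param config path to a YAML config (as written by [write_bundle()]) or
#'   an equivalent named list with elements `inputs` and `params`;
#'   relative input paths resolve against the config file's directory.
#' @param outdir optional output directory: result TSVs plus
#'   `manifest.json` are written there.
#' @param seed integer recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return named list (invisibly when `outdir` given): `allele_table`,
#'   `status_summary`, `status_by_cancer`, `nmd`, `tfbs`, `correlations`,
#'   `extremes`, `ranking`, `enrichment`, `segment_comparison`,
#'   `filter_tally`, `exclusions`, `samples_retained`, `manifest`.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = 1L) {
  if (is.character(config)) {
    cfg_path <- config
    if (!file.exists(cfg_path))
      ase_stop(paste0("config file not found: ", cfg_path))
    cfg <- yaml::read_yaml(cfg_path)
    base <- dirname(cfg_path)
  } else {
    cfg <- config
    cfg_path <- NULL
    base <- cfg$base_dir %||% "."
  }
  inp <- cfg$inputs
  par <- cfg$params %||% list()
  resolve <- function(key, required = TRUE) {
    f <- inp[[key]]
    if (is.null(f)) {
      if (required) ase_stop(paste0("config is missing input key: ", key))
      return(NULL)
    }
    path <- if (file.exists(f)) f else file.path(base, f)
    if (!file.exists(path))
      ase_stop(paste0("input file for config key '", key,
                      "' not found: ", path))
    path
  }
  sc <- status_config(
    p_err = par$p_err %||% 0.05, alpha = par$alpha %||% 0.05,
    min_depth = par$min_depth %||% 10L,
    min_dna_minor_reads = par$min_dna_minor_reads %||% 2L,
    max_normal_var_reads = par$max_normal_var_reads %||% 1L)

  ## ---- inputs --------------------------------------------------------
  variants <- read_variants(resolve("variants"),
                            inp$variant_dialect %||% "maf")
  counts <- read_input_table(resolve("counts"), "counts")
  samples <- read_input_table(resolve("samples"), "samples")
  variants$cancer_type <- samples$cancer_type[
    match(variants$sample_id, samples$sample_id)]
  purity_path <- resolve("purity", required = FALSE)
  purity <- if (!is.null(purity_path))
    read_input_table(purity_path, "purity") else NULL
  cgc_path <- resolve("cgc_genes", required = FALSE)
  cgc <- if (!is.null(cgc_path)) read_input_table(cgc_path, "gene_list")
    else character(0)
  variants$is_cgc <- variants$gene %in% cgc
  imprinted_path <- resolve("imprinted_bed", required = FALSE)
  imprinted <- if (!is.null(imprinted_path))
    read_input_table(imprinted_path, "bed") else NULL

  ## ---- sample-level filters -------------------------------------------
  log <- list()
  if (!is.null(purity)) {
    ok <- vapply(seq_len(nrow(purity)),
                 function(i) purity_sufficient(purity[i, ]), logical(1))
    bad <- purity$sample_id[!ok]
    log$purity_insufficient <- length(bad)
    samples <- samples[!samples$sample_id %in% bad, , drop = FALSE]
  }
  mut_counts <- table(variants$sample_id)
  hc <- if (length(mut_counts) >= 4)
    hypermutator_cutoff(stats::setNames(as.numeric(mut_counts),
                                        names(mut_counts)))
    else list(threshold = Inf, excluded = character(0))
  log$hypermutators <- length(hc$excluded)
  samples <- samples[!samples$sample_id %in% hc$excluded, , drop = FALSE]
  samples <- min_group_size(samples, par$min_group_size %||% 10L)
  variants <- variants[variants$sample_id %in% samples$sample_id, ,
                       drop = FALSE]
  variants$cancer_type <- samples$cancer_type[
    match(variants$sample_id, samples$sample_id)]

  ## ---- variant filters & allele metrics -------------------------------
  filt <- apply_variant_filters(variants, counts, imprinted, sc)
  allele <- compute_allele_table(
    filt$retained[, setdiff(names(filt$retained),
                            grep("_(ref|var)$", names(filt$retained),
                                 value = TRUE))],
    counts, purity, sc)
  allele$variant_key <- variant_key(allele$sample_id, allele$chrom,
                                    allele$pos, allele$ref_allele,
                                    allele$alt_allele)

  ## ---- NMD ------------------------------------------------------------
  nmd <- NULL
  gtf_path <- resolve("gtf", required = FALSE)
  if (!is.null(gtf_path)) {
    models <- read_gene_models(gtf_path,
                               cds_fasta = resolve("cds_fasta", FALSE))
    hl_path <- resolve("half_life", required = FALSE)
    hl <- if (!is.null(hl_path)) read_input_table(hl_path, "half_life")
      else NULL
    ins_path <- resolve("nmd_insensitive_genes", required = FALSE)
    ins <- if (!is.null(ins_path)) read_input_table(ins_path, "gene_list")
      else character(0)
    nmd <- classify_nmd_table(allele, models, hl, ins,
                              rules = nmd_rules(
                                rule1 = par$nmd_rule1 %||% "canonical"))
    if (!is.null(nmd) && nrow(nmd) > 0)
      allele$nmd_verdict <- nmd$verdict[
        match(allele$variant_key, nmd$variant_key)]
    else allele$nmd_verdict <- NA_character_
  } else {
    allele$nmd_verdict <- NA_character_
  }

  ## ---- TFBS -----------------------------------------------------------
  tfbs <- NULL
  motifs_path <- resolve("motifs", required = FALSE)
  windows_path <- resolve("windows_fasta", required = FALSE)
  if (!is.null(motifs_path) && !is.null(windows_path)) {
    motifs <- read_jaspar(motifs_path)
    ss <- Biostrings::readDNAStringSet(windows_path)
    windows <- tibble::tibble(variant_key = names(ss),
                              window = as.character(ss))
    tfbs <- classify_tfbs_table(
      allele, windows, motifs,
      rel_score_threshold = par$tfbs_rel_score_threshold %||% 0.85)
    allele$tfbs_category <- tfbs$tfbs_category[
      match(allele$variant_key, tfbs$variant_key)]
  }

  ## ---- associations ---------------------------------------------------
  correlations <- extremes <- ranking <- enrichment <- seg_cmp <- NULL
  expr_path <- resolve("expression", required = FALSE)
  if (is.null(expr_path)) {
    warning("no expression table configured; association stage skipped")
    ase_log("association stage skipped: no expression table")
  } else {
    expr <- read_input_table(expr_path, "expression")
    expr$log2fc <- log2_fold_change(expr$tumor_expr, expr$normal_expr,
                                    par$expression_floor %||% 0.01)
    allele <- dplyr::left_join(
      allele, expr[, c("gene", "sample_id", "log2fc")],
      by = c("gene", "sample_id"))
    correlations <- correlation_table(allele)
    extremes <- select_extremes(allele)
    ranking <- rank_genes_by_mean_vrd(allele,
                                      par$min_mutations %||% 3L)
    if (nrow(ranking) > 0 && length(cgc) > 0) {
      top <- utils::head(ranking$gene, 50L)
      background <- unique(allele$gene[!is.na(allele$v_rd)])
      enrichment <- tryCatch(
        cgc_enrichment(top, background, cgc),
        error = function(e) NULL)
    }
    seg_path <- resolve("segments", required = FALSE)
    if (!is.null(seg_path)) {
      segs <- read_input_table(seg_path, "segments")
      seg_cmp <- compare_absolute_segment_means(allele, segs, "is_cgc")
    }
  }

  summary_all <- status_summary(allele$status)
  by_cancer <- allele %>%
    dplyr::filter(!is.na(.data$status)) %>%
    dplyr::group_by(.data$cancer_type, .data$status) %>%
    dplyr::summarise(n = dplyr::n(), .groups = "drop_last") %>%
    dplyr::mutate(percent = round(100 * .data$n / sum(.data$n), 1)) %>%
    dplyr::ungroup()

  manifest <- list(
    seed = as.integer(seed),
    config_md5 = config_md5(cfg),
    n_samples_retained = nrow(samples),
    hypermutator_threshold = unname(hc$threshold),
    n_variants_in = nrow(variants),
    n_variants_retained = nrow(filt$retained),
    filter_tally = as.list(filt$tally),
    status_counts = as.list(stats::setNames(summary_all$n,
                                            summary_all$status)),
    package_version = as.character(utils::packageVersion("somaticASE")))

  res <- list(allele_table = allele, status_summary = summary_all,
              status_by_cancer = by_cancer, nmd = nmd, tfbs = tfbs,
              correlations = correlations, extremes = extremes,
              ranking = ranking, enrichment = enrichment,
              segment_comparison = seg_cmp, filter_tally = filt$tally,
              exclusions = filt$exclusions, samples_retained = samples,
              manifest = manifest)
  if (!is.null(outdir)) {
    write_pipeline_outputs(res, outdir)
    return(invisible(res))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable md5 of a config list (serialized to canonical YAML text).
config_md5 <- function(cfg) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(cfg, tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  write_result_tsv(res$allele_table, p("allele_table.tsv"), "allele table")
  write_result_tsv(res$status_summary, p("status_summary.tsv"),
                   "status summary")
  write_result_tsv(res$status_by_cancer, p("status_by_cancer.tsv"),
                   "status by cancer type")
  write_result_tsv(res$exclusions, p("exclusions.tsv"), "filter audit")
  if (!is.null(res$nmd) && nrow(res$nmd) > 0)
    write_result_tsv(res$nmd, p("nmd_annotations.tsv"), "NMD annotations")
  if (!is.null(res$tfbs) && nrow(res$tfbs) > 0)
    write_result_tsv(res$tfbs, p("tfbs.tsv"), "TFBS classification")
  if (!is.null(res$correlations))
    write_result_tsv(res$correlations, p("correlations.tsv"),
                     "stratified correlations")
  if (!is.null(res$extremes)) {
    write_result_tsv(res$extremes$high_af_up, p("extreme_high_af_up.tsv"),
                     "high-AF/up variants")
    write_result_tsv(res$extremes$high_af_down,
                     p("extreme_high_af_down.tsv"), "high-AF/down variants")
  }
  if (!is.null(res$ranking))
    write_result_tsv(res$ranking, p("gene_ranking.tsv"), "gene ranking")
  jsonlite::write_json(res$manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(outdir)
}
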