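#' NMD rule thresholds
#'
#' Thresholds for the six escape rules. `rule1` selects the polarity of the
#' last exon-exon junction rule: `"canonical"` (default) flags escape when
#' the premature termination codon lies in the last exon or within
#' `last_eej_nt` nucleotides upstream of the final exon-exon junction — the
#' boundary rule established by the NMD literature; `"literal"` flags escape
#' when it lies *more* than `last_eej_nt` upstream, for users wishing to
#' reproduce the alternative wording of the rule.
#'
#' @param last_eej_nt distance window to the last exon-exon junction (nt).
#' @param start_window_nt start-proximal window (coding nt from the start
#'   codon).
#' @param long_exon_nt minimum length for a "long" exon (nt).
#' @param boundary_nt maximal distance to the closest exon boundary for the
#'   long-exon rule (nt).
#' @param half_life_h half-life below which a transcript is short-lived (h).
#' @param rule1 `"canonical"` or `"literal"`.
#' @return named list.
#' @export
nmd_rules <- function(last_eej_nt = 50L, start_window_nt = 200L,
                      long_exon_nt = 400L, boundary_nt = 250L,
                      half_life_h = 1, rule1 = c("canonical", "literal")) {
  list(last_eej_nt = last_eej_nt, start_window_nt = start_window_nt,
       long_exon_nt = long_exon_nt, boundary_nt = boundary_nt,
       half_life_h = half_life_h, rule1 = match.arg(rule1))
}

#' Locate a premature termination codon within a transcript model
#'
#' Maps a genomic variant position into spliced mRNA/CDS coordinates,
#' strand-aware. All distances are in nucleotides of the mature transcript.
#'
#' @param pos genomic position of the variant (1-based).
#' @param model a [transcript_model()].
#' @return list with `ptc_cds_offset` (0-based nt from the first base of
#'   the start codon), `exon_index` (in transcription order), `exon_length`,
#'   `dist_last_eej` (nt from the variant to the last exon-exon junction;
#'   negative when the variant lies downstream, i.e. in the last exon; `NA`
#'   for single-exon transcripts), and `dist_nearest_exon_boundary`.
#' @export
locate_ptc <- function(pos, model) {
  if (!model$coding)
    ase_stop(paste0("transcript ", model$transcript_id, " is non-coding"))
  ex <- model$exons
  n_ex <- nrow(ex)
  lens <- ex$end - ex$start + 1L
  cum_before <- c(0L, cumsum(lens))[seq_len(n_ex)]
  mrna_of <- function(p) {
    for (i in seq_len(n_ex)) {
      if (p >= ex$start[i] && p <= ex$end[i]) {
        off <- if (model$strand == "+") p - ex$start[i] + 1L
               else ex$end[i] - p + 1L
        return(list(idx = cum_before[i] + off, exon = i, within = off))
      }
    }
    NULL
  }
  at <- mrna_of(pos)
  if (is.null(at))
    ase_stop(paste0("position ", pos, " is not exonic in ",
                    model$transcript_id))
  start_at <- mrna_of(model$cds_start)
  end_at <- mrna_of(model$cds_end)
  offset <- at$idx - start_at$idx
  if (offset < 0 || at$idx > end_at$idx)
    ase_stop(paste0("position ", pos, " is outside the CDS of ",
                    model$transcript_id))
  eej <- if (n_ex > 1) sum(lens[-n_ex]) else NA_integer_
  list(
    ptc_cds_offset = offset,
    exon_index = at$exon,
    exon_length = lens[at$exon],
    dist_last_eej = if (n_ex > 1) eej - at$idx else NA_integer_,
    dist_nearest_exon_boundary = min(at$within - 1L, lens[at$exon] - at$within)
  )
}

# Is there an in-frame AUG in the CDS downstream of the PTC?
has_downstream_inframe_aug <- function(cds_seq, ptc_cds_offset) {
  if (is.null(cds_seq) || is.na(cds_seq)) return(NA)
  first_codon_after <- (ptc_cds_offset %/% 3L) + 1L  # 0-based codon index
  starts <- seq(from = first_codon_after * 3L + 1L,
                to = nchar(cds_seq) - 2L, by = 3L)
  if (length(starts) == 0) return(FALSE)
  codons <- substring(cds_seq, starts, starts + 2L)
  any(codons == "ATG")
}

#' Classify a premature terminating variant as NMD-elicit or NMD-escape
#'
#' Evaluates the six escape rules: (1) the PTC lies in the last exon or
#' within 50 nt upstream of the last exon-exon junction (canonical
#' polarity; see [nmd_rules()]); (2) the PTC lies within the first 200
#' coding nucleotides and an alternative in-frame AUG is present downstream
#' in the CDS; (3) the PTC lies in a long exon (> 400 nt) fewer than 250 nt
#' from the closest exon boundary; (4) the transcript is short-lived
#' (half-life < 1 h); (5) the transcript is single-exon; (6) the gene is
#' NMD-insensitive. The verdict is `"escape"` if any rule fires, else
#' `"elicit"`.
#'
#' A missing half-life leaves rule 4 unset (false) with a logged
#' assumption; a missing coding sequence does the same for the
#' alternative-AUG part of rule 2.
#'
#' @param pos genomic variant position.
#' @param model a [transcript_model()]; its `half_life_hours`,
#'   `nmd_insensitive` and `cds_seq` fields feed rules 4, 6 and 2 unless
#'   overridden.
#' @param half_life_hours,nmd_insensitive,cds_seq optional overrides.
#' @param rules see [nmd_rules()].
#' @return one-row tibble: `transcript_id`, the coordinate fields of
#'   [locate_ptc()], the six logical rule flags (`last_eej_proximal`,
#'   `start_proximal_with_alt_aug`, `long_exon_boundary`,
#'   `short_half_life`, `single_exon`, `nmd_insensitive`) and `verdict`.
#' @export
classify_nmd <- function(pos, model,
                         half_life_hours = model$half_life_hours,
                         nmd_insensitive = model$nmd_insensitive,
                         cds_seq = model$cds_seq,
                         rules = nmd_rules()) {
  loc <- locate_ptc(pos, model)
  n_ex <- nrow(model$exons)
  in_last_exon <- loc$exon_index == n_ex

  f1 <- if (rules$rule1 == "canonical") {
    in_last_exon ||
      (!is.na(loc$dist_last_eej) && loc$dist_last_eej <= rules$last_eej_nt)
  } else {
    !is.na(loc$dist_last_eej) && loc$dist_last_eej > rules$last_eej_nt
  }

  aug <- has_downstream_inframe_aug(cds_seq, loc$ptc_cds_offset)
  if (is.na(aug)) {
    if (loc$ptc_cds_offset < rules$start_window_nt)
      ase_log("no CDS sequence for ", model$transcript_id,
              "; alternative-AUG rule assumed not to fire")
    aug <- FALSE
  }
  f2 <- loc$ptc_cds_offset < rules$start_window_nt && aug

  f3 <- loc$exon_length > rules$long_exon_nt &&
    loc$dist_nearest_exon_boundary < rules$boundary_nt

  if (is.na(half_life_hours)) {
    f4 <- FALSE
  } else {
    f4 <- half_life_hours < rules$half_life_h
  }

  f5 <- n_ex == 1L
  f6 <- isTRUE(nmd_insensitive)

  tibble::tibble(
    transcript_id = model$transcript_id,
    ptc_cds_offset = loc$ptc_cds_offset,
    exon_index = loc$exon_index,
    exon_length = loc$exon_length,
    dist_last_eej = loc$dist_last_eej,
    dist_nearest_exon_boundary = loc$dist_nearest_exon_boundary,
    last_eej_proximal = f1,
    start_proximal_with_alt_aug = f2,
    long_exon_boundary = f3,
    short_half_life = f4,
    single_exon = f5,
    nmd_insensitive = f6,
    verdict = if (f1 || f2 || f3 || f4 || f5 || f6) "escape" else "elicit"
  )
}

#' Annotate all PTVs in a variant table with NMD classifications
#'
#' For each PTV the transcript named on the variant record is used; when it
#' is not among the models, the model with the longest CDS among the gene's
#' transcripts is used as fallback. Variants whose position cannot be
#' placed in a coding transcript are skipped with a log entry.
#'
#' @param variants variant tibble (only rows with `consequence == "PTV"`
#'   are annotated).
#' @param models named list of [transcript_model()] objects.
#' @param half_life optional tibble (`transcript_id`, `half_life_hours`).
#' @param insensitive_genes optional character vector of NMD-insensitive
#'   gene symbols.
#' @param rules see [nmd_rules()].
#' @return tibble with `variant_key`, `gene` and the [classify_nmd()]
#'   columns.
#' @export
classify_nmd_table <- function(variants, models, half_life = NULL,
                               insensitive_genes = character(0),
                               rules = nmd_rules()) {
  ptv <- variants[variants$consequence == "PTV", , drop = FALSE]
  hl <- function(tid) {
    if (is.null(half_life)) return(NA_real_)
    i <- match(tid, half_life$transcript_id)
    if (is.na(i)) NA_real_ else half_life$half_life_hours[i]
  }
  by_gene <- split(models, vapply(models, `[[`, "", "gene"))
  pick_model <- function(tid, gene) {
    if (!is.na(tid) && tid %in% names(models)) return(models[[tid]])
    cands <- by_gene[[gene]]
    cands <- Filter(function(m) m$coding, cands)
    if (is.null(cands) || length(cands) == 0) return(NULL)
    lens <- vapply(cands, function(m) abs(m$cds_end - m$cds_start), 0)
    cands[[which.max(lens)]]
  }
  rows <- vector("list", nrow(ptv))
  for (i in seq_len(nrow(ptv))) {
    m <- pick_model(ptv$transcript_id[i], ptv$gene[i])
    if (is.null(m) || !m$coding) {
      ase_log("no coding model for PTV in gene ", ptv$gene[i], "; skipped")
      next
    }
    ann <- tryCatch(
      classify_nmd(ptv$pos[i], m, half_life_hours = hl(m$transcript_id),
                   nmd_insensitive = m$nmd_insensitive ||
                     ptv$gene[i] %in% insensitive_genes,
                   rules = rules),
      error = function(e) NULL)
    if (is.null(ann)) {
      ase_log("PTV at ", ptv$chrom[i], ":", ptv$pos[i],
              " not placeable in CDS of ", m$transcript_id, "; skipped")
      next
    }
    ann$variant_key <- variant_key(ptv$sample_id[i], ptv$chrom[i],
                                   ptv$pos[i], ptv$ref_allele[i],
                                   ptv$alt_allele[i])
    ann$gene <- ptv$gene[i]
    rows[[i]] <- ann
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0)
    out <- dplyr::select(out, "variant_key", "gene", dplyr::everything())
  out
}
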