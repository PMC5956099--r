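#' Read a JASPAR-format PWM set
#'
#' Parses the standard JASPAR text format (`>ID NAME` header followed by
#' four `A/C/G/T [ counts ]` rows). Count matrices are normalized to
#' per-column probabilities.
#'
#' @param path JASPAR text file.
#' @return named list of motifs, each a list with `id`, `name` and `matrix`
#'   (4 x width probability matrix, rows A, C, G, T).
#' @export
read_jaspar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) ase_stop("no motif headers ('>') found")
  motifs <- list()
  for (h in seq_along(heads)) {
    i <- heads[h]
    hdr <- strsplit(sub("^>", "", lines[i]), "\\s+")[[1]]
    id <- hdr[1]
    name <- if (length(hdr) > 1) hdr[2] else id
    rows <- lines[(i + 1):(i + 4)]
    parse_row <- function(r) {
      s <- sub("^\\s*[ACGT]", "", r)
      s <- gsub("[][]", " ", s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])
    }
    bases <- substr(trimws(rows), 1, 1)
    if (!identical(sort(bases), c("A", "C", "G", "T")))
      ase_stop(paste0("motif ", id, ": expected A/C/G/T rows"))
    m <- do.call(rbind, lapply(rows, parse_row))
    rownames(m) <- bases
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    colsum <- colSums(m)
    if (any(colsum <= 0)) ase_stop(paste0("motif ", id, ": empty column"))
    m <- sweep(m, 2, colsum, "/")
    motifs[[id]] <- list(id = id, name = name, matrix = m)
  }
  motifs
}

# log2 odds against a uniform background, with a floor avoiding -Inf
pwm_log_odds <- function(prob_matrix, floor = 1e-4) {
  log2(pmax(prob_matrix, floor) / 0.25)
}

#' Scan a sequence with one position weight matrix
#'
#' Scores every offset with the log2-odds of the motif against a uniform
#' background and reports hits whose *relative* score,
#' `(score - min) / (max - min)` with min/max the lowest-/highest-scoring
#' sequences under the PWM, reaches the threshold. With
#' `scan_both_strands` the reverse complement is scanned too; minus-strand
#' hit offsets refer to the forward sequence.
#'
#' @param seq character, A/C/G/T only.
#' @param motif a motif as returned by [read_jaspar()] (or a bare 4 x w
#'   probability matrix with rows A, C, G, T).
#' @param rel_score_threshold fraction in \[0, 1\] (default 0.85).
#' @param scan_both_strands logical (default TRUE).
#' @return tibble with columns `offset` (1-based start on the forward
#'   sequence), `strand` and `rel_score`.
#' @export
scan_pwm <- function(seq, motif, rel_score_threshold = 0.85,
                     scan_both_strands = TRUE) {
  m <- if (is.list(motif)) motif$matrix else motif
  if (grepl("[^ACGT]", seq))
    ase_stop("sequence contains non-ACGT characters")
  w <- ncol(m)
  L <- nchar(seq)
  if (L < w) ase_stop("sequence shorter than the motif")
  lo <- pwm_log_odds(m)
  smin <- sum(apply(lo, 2, min))
  smax <- sum(apply(lo, 2, max))
  rel <- function(s) if (smax > smin) (s - smin) / (smax - smin) else 0

  score_strand <- function(s) {
    chars <- strsplit(s, "")[[1]]
    idx <- match(chars, c("A", "C", "G", "T"))
    n_off <- L - w + 1L
    scores <- numeric(n_off)
    for (j in seq_len(w)) scores <- scores + lo[cbind(idx[seq_len(n_off) + j - 1L], j)]
    scores
  }

  fw <- vapply(score_strand(seq), rel, 0)
  hits <- tibble::tibble(offset = which(fw >= rel_score_threshold),
                         strand = "+",
                         rel_score = fw[fw >= rel_score_threshold])
  if (scan_both_strands) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    rv <- vapply(score_strand(rc), rel, 0)
    keep <- which(rv >= rel_score_threshold)
    if (length(keep) > 0) {
      hits <- dplyr::bind_rows(hits, tibble::tibble(
        offset = L - keep - w + 2L, strand = "-", rel_score = rv[keep]))
    }
  }
  dplyr::arrange(hits, .data$offset)
}

#' Classify a variant's effect on transcription factor binding sites
#'
#' The reference window (centered on the variant position, center base
#' equal to the reference allele) and the alternate window (center base
#' substituted) are both scanned with every motif. A motif is *gained* when
#' it has a hit overlapping the variant position in the alternate window
#' but none in the reference window, and *lost* in the converse case. The
#' category is `"gain"`, `"loss"`, `"both"` (different motifs gained and
#' lost) or `"none"`.
#'
#' @param ref_allele,alt_allele single bases.
#' @param ref_window odd-length window centered on the variant; must extend
#'   at least (longest motif - 1) bases on each side.
#' @param motifs list of motifs from [read_jaspar()].
#' @param rel_score_threshold,scan_both_strands passed to [scan_pwm()].
#' @return list with `category`, `gained` and `lost` (character vectors of
#'   motif ids).
#' @export
classify_tfbs_change <- function(ref_allele, alt_allele, ref_window, motifs,
                                 rel_score_threshold = 0.85,
                                 scan_both_strands = TRUE) {
  L <- nchar(ref_window)
  if (L %% 2 == 0) ase_stop("reference window must have odd length")
  center <- (L + 1L) %/% 2L
  if (substr(ref_window, center, center) != ref_allele)
    ase_stop("window center does not match the reference allele")
  if (length(motifs) > 0) {
    maxw <- max(vapply(motifs, function(m) ncol(m$matrix), 0L))
    if (center - 1L < maxw - 1L)
      ase_stop("window too short for the longest motif")
  }
  alt_window <- ref_window
  substr(alt_window, center, center) <- alt_allele

  overlaps_center <- function(hits, w) {
    if (nrow(hits) == 0) return(FALSE)
    any(hits$offset <= center & hits$offset + w - 1L >= center)
  }
  gained <- character(0); lost <- character(0)
  for (m in motifs) {
    w <- ncol(m$matrix)
    in_ref <- overlaps_center(
      scan_pwm(ref_window, m, rel_score_threshold, scan_both_strands), w)
    in_alt <- overlaps_center(
      scan_pwm(alt_window, m, rel_score_threshold, scan_both_strands), w)
    if (in_alt && !in_ref) gained <- c(gained, m$id)
    if (in_ref && !in_alt) lost <- c(lost, m$id)
  }
  category <- if (length(gained) > 0 && length(lost) > 0) "both"
    else if (length(gained) > 0) "gain"
    else if (length(lost) > 0) "loss"
    else "none"
  list(category = category, gained = gained, lost = lost)
}

#' Classify TFBS changes for a table of variants
#'
#' @param variants variant tibble.
#' @param windows tibble with `variant_key` and `window` (reference-window
#'   sequence centered on the variant), or a named character vector.
#' @param motifs list of motifs from [read_jaspar()].
#' @param rel_score_threshold,scan_both_strands passed to
#'   [classify_tfbs_change()].
#' @return tibble: `variant_key`, `tfbs_category`, `gained_motifs`,
#'   `lost_motifs` (comma-separated ids).
#' @export
classify_tfbs_table <- function(variants, windows, motifs,
                                rel_score_threshold = 0.85,
                                scan_both_strands = TRUE) {
  if (is.character(windows))
    windows <- tibble::tibble(variant_key = names(windows), window = windows)
  keys <- variant_key(variants$sample_id, variants$chrom, variants$pos,
                      variants$ref_allele, variants$alt_allele)
  idx <- match(keys, windows$variant_key)
  rows <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    if (is.na(idx[i])) next
    res <- classify_tfbs_change(variants$ref_allele[i],
                                variants$alt_allele[i],
                                windows$window[idx[i]], motifs,
                                rel_score_threshold, scan_both_strands)
    rows[[i]] <- tibble::tibble(
      variant_key = keys[i], tfbs_category = res$category,
      gained_motifs = paste(res$gained, collapse = ","),
      lost_motifs = paste(res$lost, collapse = ","))
  }
  dplyr::bind_rows(rows)
}
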