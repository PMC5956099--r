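# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

options(somaticASE.quiet = TRUE)

# Binomial upper tail by explicit term-by-term enumeration (log-scale
# binomial coefficients; no pbinom).
enum_upper_tail <- function(k, n, p) {
  if (k > n) return(0)
  if (k <= 0) return(1)
  i <- k:n
  if (p == 0) return(as.numeric(k <= 0))
  if (p == 1) return(1)
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log(1 - p)))
}

# Exhaustive per-base spliced-coordinate mapper: lists every exonic genomic
# position in transcription order and locates by lookup.
mapper_oracle <- function(model, pos) {
  ex <- model$exons
  gpos <- unlist(lapply(seq_len(nrow(ex)), function(i) {
    p <- ex$start[i]:ex$end[i]
    if (model$strand == "-") rev(p) else p
  }))
  exon_of <- unlist(lapply(seq_len(nrow(ex)), function(i)
    rep(i, ex$end[i] - ex$start[i] + 1L)))
  idx <- match(pos, gpos)
  start_idx <- match(model$cds_start, gpos)
  lens <- ex$end - ex$start + 1L
  n_ex <- nrow(ex)
  within <- idx - c(0L, cumsum(lens))[exon_of[idx]]
  list(
    ptc_cds_offset = idx - start_idx,
    exon_index = exon_of[idx],
    exon_length = lens[exon_of[idx]],
    dist_last_eej = if (n_ex > 1) sum(lens[-n_ex]) - idx else NA_integer_,
    dist_nearest_exon_boundary = min(within - 1L,
                                     lens[exon_of[idx]] - within)
  )
}

# Mirror a transcript-model fixture onto the minus strand: genomic
# coordinates are reflected so the transcription-relative geometry is
# unchanged.
mirror_case <- function(model, pos, span = NULL) {
  ex <- model$exons
  if (is.null(span)) span <- max(ex$end) + min(ex$start)
  flip <- function(p) span - p
  list(model = transcript_model(
    transcript_id = paste0(model$transcript_id, "_mirror"),
    gene = model$gene, chrom = model$chrom, strand = "-",
    exon_starts = flip(ex$end), exon_ends = flip(ex$start),
    cds_start = flip(model$cds_start), cds_end = flip(model$cds_end),
    cds_seq = model$cds_seq, half_life_hours = model$half_life_hours,
    nmd_insensitive = model$nmd_insensitive),
    pos = flip(pos))
}

# Coding sequence of GGC codons with an optional in-frame ATG at a given
# codon (1-based), used to toggle the alternative-AUG rule.
codon_seq <- function(n_codons, aug_at = NULL) {
  codons <- rep("GGC", n_codons)
  if (!is.null(aug_at)) codons[aug_at] <- "ATG"
  paste0(codons, collapse = "")
}
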