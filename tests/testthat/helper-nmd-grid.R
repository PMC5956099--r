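# Fixture constructor for the exhaustive NMD flag grid.
#
# Geometry templates are indexed by the positional flags (rule 1: PTC in
# the last exon or <= 50 nt upstream of the last exon-exon junction;
# rule 3: long exon, < 250 nt from the closest boundary; rule 5: single
# exon). Every template places the PTC within the first 200 coding nt so
# that rule 2 can be toggled purely by planting (or not) a downstream
# in-frame AUG; rules 4 and 6 are toggled by half-life and the
# insensitivity flag. A single-exon transcript geometrically forces rule 1
# (the PTC is always in the last exon), so combinations with f5 and not f1
# are unrealizable and return NULL.
make_nmd_case <- function(f1, f2, f3, f4, f5, f6) {
  if (f5 && !f1) return(NULL)
  geom <- if (f5) {
    if (f3) list(starts = 1L, ends = 1000L, cds = c(51L, 950L), ptc = 150L)
    else    list(starts = 1L, ends = 350L, cds = c(51L, 330L), ptc = 150L)
  } else if (!f1 && !f3) {
    list(starts = c(1L, 401L, 801L), ends = c(300L, 700L, 1100L),
         cds = c(51L, 1050L), ptc = 150L)
  } else if (!f1 && f3) {
    list(starts = c(1L, 201L, 1401L), ends = c(100L, 1300L, 1700L),
         cds = c(51L, 1650L), ptc = 221L)
  } else if (f1 && !f3) {
    list(starts = c(1L, 201L), ends = c(120L, 500L),
         cds = c(51L, 450L), ptc = 100L)
  } else {
    list(starts = c(1L, 201L), ends = c(120L, 1300L),
         cds = c(51L, 1250L), ptc = 221L)
  }
  model <- transcript_model(
    transcript_id = paste0("TX_", paste(as.integer(c(f1, f2, f3, f4, f5,
                                                     f6)), collapse = "")),
    gene = "GENE", chrom = "chr1", strand = "+",
    exon_starts = geom$starts, exon_ends = geom$ends,
    cds_start = geom$cds[1], cds_end = geom$cds[2],
    cds_seq = codon_seq(60L, aug_at = if (f2) 45L else NULL),
    half_life_hours = if (f4) 0.5 else 10,
    nmd_insensitive = f6)
  list(model = model, pos = geom$ptc,
       flags = c(last_eej_proximal = f1, start_proximal_with_alt_aug = f2,
                 long_exon_boundary = f3, short_half_life = f4,
                 single_exon = f5, nmd_insensitive = f6))
}

nmd_flag_grid <- function() {
  g <- expand.grid(f1 = c(FALSE, TRUE), f2 = c(FALSE, TRUE),
                   f3 = c(FALSE, TRUE), f4 = c(FALSE, TRUE),
                   f5 = c(FALSE, TRUE), f6 = c(FALSE, TRUE))
  g[!(g$f5 & !g$f1), , drop = FALSE]
}
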