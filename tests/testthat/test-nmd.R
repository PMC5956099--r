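two_exon_model <- function(strand = "+") {
  transcript_model("TXA", "GENEA", "chr1", strand,
                   exon_starts = c(100L, 300L), exon_ends = c(200L, 400L),
                   cds_start = if (strand == "+") 150L else 350L,
                   cds_end = if (strand == "+") 350L else 150L)
}

test_that("PTC location matches manual coordinate arithmetic", {
  m <- two_exon_model("+")
  loc <- locate_ptc(180L, m)
  expect_equal(loc$ptc_cds_offset, 30L)
  expect_equal(loc$exon_index, 1L)
  expect_equal(loc$dist_last_eej, 20L)
  expect_equal(loc$dist_nearest_exon_boundary, 20L)

  loc2 <- locate_ptc(320L, m)
  expect_equal(loc2$exon_index, 2L)   # last exon
  expect_lt(loc2$dist_last_eej, 0)

  expect_error(locate_ptc(120L, m), "outside the CDS")
  expect_error(locate_ptc(250L, m), "not exonic")
  nc <- transcript_model("TNC", "G", "chr1", "+", 100L, 200L)
  expect_error(locate_ptc(150L, nc), "non-coding")
})

test_that("minus-strand mirrors give identical spliced coordinates", {
  m <- two_exon_model("+")
  for (pos in c(155L, 180L, 200L, 300L, 320L, 349L)) {
    mir <- mirror_case(m, pos)
    expect_equal(locate_ptc(mir$pos, mir$model), locate_ptc(pos, m),
                 info = paste("pos", pos))
  }
})

test_that("locate_ptc agrees with the per-base enumeration oracle", {
  set.seed(402)
  for (rep in 1:25) {
    n_ex <- sample(1:4, 1)
    lens <- sample(80:600, n_ex, replace = TRUE)
    gaps <- sample(50:200, n_ex, replace = TRUE)
    starts <- cumsum(c(1L, head(lens + gaps, -1)))
    ends <- starts + lens - 1L
    strand <- sample(c("+", "-"), 1)
    # CDS spanning from inside the first to inside the last exon
    left <- starts[1] + sample(0:30, 1)
    right <- ends[n_ex] - sample(0:30, 1)
    m <- transcript_model("T", "G", "chr1", strand, starts, ends,
                          cds_start = if (strand == "+") left else right,
                          cds_end = if (strand == "+") right else left)
    exonic <- unlist(mapply(seq, starts, ends, SIMPLIFY = FALSE))
    cds_pos <- exonic[exonic >= left & exonic <= right]
    for (pos in sample(cds_pos, 8)) {
      expect_equal(locate_ptc(pos, m), mapper_oracle(m, pos),
                   info = paste("strand", strand, "pos", pos))
    }
  }
})

test_that("single rules fire as documented", {
  # single-exon transcript: escape regardless of position
  se <- transcript_model("TSE", "G", "chr1", "+", 1L, 900L,
                         cds_start = 51L, cds_end = 850L,
                         half_life_hours = 10)
  ann <- classify_nmd(450L, se)
  expect_true(ann$single_exon)
  expect_equal(ann$verdict, "escape")

  # PTC 20 nt upstream of the last junction: canonical rule-1 escape
  m <- two_exon_model("+")
  ann2 <- classify_nmd(180L, m, half_life_hours = 10)
  expect_true(ann2$last_eej_proximal)
  expect_equal(ann2$verdict, "escape")

  # far upstream, short exons, stable, sensitive, no AUG: elicit
  big <- transcript_model("TB", "G", "chr1", "+",
                          exon_starts = c(1L, 401L, 801L),
                          exon_ends = c(300L, 700L, 1100L),
                          cds_start = 51L, cds_end = 1050L,
                          cds_seq = codon_seq(200L), half_life_hours = 10)
  ann3 <- classify_nmd(620L, big)
  expect_equal(sum(unlist(ann3[c("last_eej_proximal",
                                 "start_proximal_with_alt_aug",
                                 "long_exon_boundary", "short_half_life",
                                 "single_exon", "nmd_insensitive")])), 0)
  expect_equal(ann3$verdict, "elicit")

  # the literal rule-1 polarity flips far-upstream PTCs to escape
  ann4 <- classify_nmd(620L, big, rules = nmd_rules(rule1 = "literal"))
  expect_true(ann4$last_eej_proximal)
  expect_equal(ann4$verdict, "escape")

  # short half-life alone
  ann5 <- classify_nmd(620L, big, half_life_hours = 0.5)
  expect_true(ann5$short_half_life)
  expect_equal(ann5$verdict, "escape")

  # start-proximal PTC with a downstream in-frame AUG
  aug <- transcript_model("TA", "G", "chr1", "+",
                          exon_starts = c(1L, 401L, 801L),
                          exon_ends = c(300L, 700L, 1100L),
                          cds_start = 51L, cds_end = 1050L,
                          cds_seq = codon_seq(200L, aug_at = 60L),
                          half_life_hours = 10)
  ann6 <- classify_nmd(150L, aug)
  expect_true(ann6$start_proximal_with_alt_aug)
  # same position without the AUG: rule 2 does not fire
  ann7 <- classify_nmd(150L, big)
  expect_false(ann7$start_proximal_with_alt_aug)
  expect_equal(ann7$verdict, "elicit")
})

test_that("the verdict is the OR of the six flags over every realizable
          flag combination, and is strand invariant", {
  grid <- nmd_flag_grid()
  expect_equal(nrow(grid), 48L)  # 64 minus single-exon forcing rule 1
  flag_cols <- c("last_eej_proximal", "start_proximal_with_alt_aug",
                 "long_exon_boundary", "short_half_life", "single_exon",
                 "nmd_insensitive")
  for (i in seq_len(nrow(grid))) {
    tgt <- unlist(grid[i, ])
    case <- make_nmd_case(tgt[1], tgt[2], tgt[3], tgt[4], tgt[5], tgt[6])
    ann <- classify_nmd(case$pos, case$model)
    got <- unlist(ann[flag_cols])
    expect_equal(unname(got), unname(tgt),
                 info = paste("combo", paste(as.integer(tgt),
                                             collapse = "")))
    expect_equal(ann$verdict, if (any(tgt)) "escape" else "elicit")
    # minus-strand mirror: identical flags and verdict
    mir <- mirror_case(case$model, case$pos)
    ann_m <- classify_nmd(mir$pos, mir$model)
    expect_equal(unlist(ann_m[flag_cols]), got)
    expect_equal(ann_m$verdict, ann$verdict)
  }
})

test_that("the table annotator picks the named or longest-CDS transcript", {
  models <- list(
    TXSHORT = transcript_model("TXSHORT", "G1", "chr1", "+", 100L, 400L,
                               cds_start = 150L, cds_end = 350L),
    TXLONG = transcript_model("TXLONG", "G1", "chr1", "+",
                              c(100L, 500L), c(400L, 900L),
                              cds_start = 150L, cds_end = 850L))
  variants <- tibble::tibble(
    sample_id = "S1", cancer_type = "SYNA", chrom = "chr1",
    pos = c(200L, 200L), ref_allele = "C", alt_allele = "T",
    gene = "G1", transcript_id = c("TXSHORT", NA),
    consequence = "PTV", is_cgc = FALSE)
  ann <- classify_nmd_table(variants, models,
                            half_life = tibble::tibble(
                              transcript_id = c("TXSHORT", "TXLONG"),
                              half_life_hours = c(10, 10)))
  expect_equal(ann$transcript_id, c("TXSHORT", "TXLONG"))
  # insensitive-gene list forces rule 6
  ann2 <- classify_nmd_table(variants, models,
                             insensitive_genes = "G1")
  expect_true(all(ann2$nmd_insensitive))
  expect_true(all(ann2$verdict == "escape"))
})
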