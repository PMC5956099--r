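test_that("cohort generation is deterministic per seed", {
  cfg <- cohort_config(n_samples = 8L, variants_per_sample = 10L)
  a <- generate_cohort(cfg, seed = 3)
  b <- generate_cohort(cfg, seed = 3)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(a$windows, b$windows)
  c <- generate_cohort(cfg, seed = 4)
  expect_false(identical(a$counts, c$counts))
})

test_that("no selection, no degradation, pure tumor: mean V_R:D is 1", {
  cfg <- cohort_config(
    n_samples = 40L, variants_per_sample = 25L,
    purity = list(shape1 = 1, shape2 = 1, fixed = 1),
    depth = list(mean = 1000, fixed = 1000L),
    selection = list(sdlog = 0, ptv_meanlog = 0, frac_strong = 0,
                     strong_meanlog = 0, strong_sdlog = 0),
    nmd_degradation = 0, frac_germline = 0)
  co <- generate_cohort(cfg, seed = 21)
  tab <- compute_allele_table(co$variants, co$counts)
  expect_gt(mean(tab$v_rd, na.rm = TRUE), 0.97)
  expect_lt(mean(tab$v_rd, na.rm = TRUE), 1.03)
})

test_that("admixture halves the DNA allele fraction at purity 0.5", {
  cfg <- cohort_config(
    n_samples = 30L, variants_per_sample = 30L,
    purity = list(shape1 = 1, shape2 = 1, fixed = 0.5),
    depth = list(mean = 200, fixed = 200L))
  co <- generate_cohort(cfg, seed = 22)
  tab <- compute_allele_table(co$variants, co$counts)
  # expected VAF_tDNA = f_dna * purity = 0.25 under the admixture model
  expect_equal(mean(tab$vaf_tdna, na.rm = TRUE), 0.25, tolerance = 0.01)
})

test_that("complete NMD degradation drives elicit PTVs to SOM-L", {
  cfg <- cohort_config(n_samples = 40L, variants_per_sample = 25L,
                       nmd_degradation = 1,
                       depth = list(mean = 100, fixed = 100L),
                       frac_germline = 0)
  co <- generate_cohort(cfg, seed = 23)
  tab <- compute_allele_table(co$variants, co$counts)
  key <- paste(tab$sample_id, tab$chrom, tab$pos, tab$ref_allele,
               tab$alt_allele, sep = ":")
  truth <- co$truth[match(key, co$truth$variant_key), ]
  elicit <- !is.na(truth$nmd_truth) & truth$nmd_truth == "elicit"
  rate <- mean(tab$status[elicit] == "SOM_L", na.rm = TRUE)
  expect_gte(rate, 0.9)
})

test_that("the written bundle round-trips and is byte-stable", {
  cfg <- cohort_config(n_samples = 8L, variants_per_sample = 10L)
  co <- generate_cohort(cfg, seed = 31)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_bundle(co, d1)
  write_bundle(co, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     info = f)
  }
  back <- read_bundle(d1)
  expect_equal(nrow(back$variants), nrow(co$variants))
  expect_equal(nrow(back$counts), nrow(co$counts))
  expect_equal(back$counts$Ttr_var, co$counts$Ttr_var)
  expect_equal(length(back$models), length(co$models))
  expect_equal(sort(back$cgc_genes), sort(co$cgc_genes))
  expect_equal(nrow(back$windows), nrow(co$windows))
  # truth selection values survive the round trip numerically
  expect_equal(back$truth$selection_s, co$truth$selection_s)
})

test_that("generated gene models agree with the recorded NMD truth", {
  cfg <- cohort_config(n_samples = 20L, variants_per_sample = 25L)
  co <- generate_cohort(cfg, seed = 32)
  ann <- classify_nmd_table(co$variants, co$models, co$half_life,
                            co$insensitive_genes)
  truth <- co$truth[match(ann$variant_key, co$truth$variant_key), ]
  expect_gt(nrow(ann), 50)
  expect_equal(ann$verdict, truth$nmd_truth)
})

test_that("planted TFBS gains and losses are recovered by the scanner", {
  cfg <- cohort_config(n_samples = 20L, variants_per_sample = 25L,
                       tfbs = list(frac_gain = 0.2, frac_loss = 0.2,
                                   halfwidth = 20L))
  co <- generate_cohort(cfg, seed = 33)
  tab <- classify_tfbs_table(co$variants, co$windows, co$motifs)
  truth <- co$truth[match(tab$variant_key, co$truth$variant_key), ]
  planted <- truth$tfbs_truth %in% c("gain", "loss")
  agree <- tab$tfbs_category[planted] == truth$tfbs_truth[planted]
  expect_gt(sum(planted), 100)
  # sporadic chance motif matches in the random flanks may add a second
  # category; exact agreement is still expected for nearly all sites
  expect_gt(mean(agree), 0.95)
})
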