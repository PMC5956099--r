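test_that("log2 fold change handles floors, zeros and sign symmetry", {
  expect_equal(log2_fold_change(4, 1, floor = 0), 2)
  expect_equal(log2_fold_change(1, 4, floor = 0), -2)
  expect_true(is.na(log2_fold_change(0, 0)))
  expect_equal(log2_fold_change(2, 8), -log2_fold_change(8, 2))
  expect_error(log2_fold_change(-1, 2), "non-negative")
})

test_that("spearman reproduces hand-ranked values", {
  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman(1:10, -(1:10)^3)$rho, -1)
  # d = (1,1,1,1), sum d^2 = 4: rho = 1 - 6*4/(4*15) = 0.6
  expect_equal(spearman(c(1, 2, 3, 4), c(2, 1, 4, 3))$rho, 0.6)
  expect_error(spearman(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman(1:2, 2:1), "at least 3")
})

test_that("kruskal-wallis reproduces hand rank-sum arithmetic", {
  expect_equal(kruskal_wallis(list(c(1, 5, 9), c(1, 5, 9)))$H, 0,
               tolerance = 1e-12)
  # ranks 1..6, R1 = 6, R2 = 15: H = 12/42 * (12 + 75) - 21 = 27/7
  kw <- kruskal_wallis(list(c(1, 2, 3), c(10, 11, 12)))
  expect_equal(kw$H, 27 / 7, tolerance = 1e-6)
  # exchangeable groups: no signal
  set.seed(5)
  vals <- rnorm(8)
  expect_gt(kruskal_wallis(list(vals, vals, vals))$p, 0.9)
  expect_error(kruskal_wallis(list(1:3)), ">= 2 groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
  # all observations tied: H defined as 0
  expect_equal(kruskal_wallis(list(c(0, 0), c(0, 0, 0)))$H, 0)
})

test_that("extreme subsets are thresholded and disjoint", {
  tab <- tibble::tibble(
    id = 1:6,
    v_rd = c(2.5, 2.5, 1.5, 2.1, 3.0, NA),
    log2fc = c(1.5, -1.2, 3, 0.5, 1.0, 2))
  ex <- select_extremes(tab)
  expect_equal(ex$high_af_up$id, c(1L, 5L))
  expect_equal(ex$high_af_down$id, 2L)
  expect_length(intersect(ex$high_af_up$id, ex$high_af_down$id), 0)
  expect_true(all(c(ex$high_af_up$v_rd, ex$high_af_down$v_rd) > 2))
})

test_that("gene ranking averages V_R:D with an alphabetical tie-break", {
  calls <- tibble::tibble(
    gene = c(rep("BGENE", 3), rep("AGENE", 3), rep("CGENE", 2)),
    v_rd = c(1, 2, 3, 2, 2, 2, 9, 9))
  rk <- rank_genes_by_mean_vrd(calls, min_mutations = 3)
  expect_equal(rk$gene, c("AGENE", "BGENE"))  # tie at mean 2: A before B
  expect_equal(rk$mean_v_rd, c(2, 2))
  expect_false("CGENE" %in% rk$gene)          # only 2 mutations
  rk5 <- rank_genes_by_mean_vrd(calls, min_mutations = 5)
  expect_equal(nrow(rk5), 0)
})

test_that("CGC enrichment flags an all-CGC selection and not a
          proportional one", {
  background <- c(paste0("C", 1:20), paste0("N", 1:20))
  cgc <- paste0("C", 1:20)
  res <- cgc_enrichment(paste0("C", 1:10), background, cgc)
  expect_lt(res$p, 0.01)
  expect_equal(res$table["selected", "cgc"], 10)
  # selection with the background CGC proportion: no signal
  prop <- c(paste0("C", 1:5), paste0("N", 1:5))
  expect_gt(cgc_enrichment(prop, background, cgc)$p, 0.9)
  expect_error(cgc_enrichment(character(0), background, cgc), "empty")
  expect_error(cgc_enrichment("X1", background, cgc), "subset")
})

test_that("segment-mean comparison joins by overlap and tallies
          unmatched variants", {
  calls <- tibble::tibble(
    sample_id = c("S1", "S1", "S2", "S2"), chrom = "chr1",
    pos = c(100L, 200L, 100L, 5000L),
    is_cgc = c(TRUE, FALSE, FALSE, TRUE))
  segments <- tibble::tibble(
    sample_id = c("S1", "S2"), chrom = "chr1",
    start = 1L, end = 1000L, segment_mean = c(1.5, 0.1))
  res <- compare_absolute_segment_means(calls, segments, "is_cgc")
  expect_equal(res$n_unmatched, 1L)   # S2:5000 overlaps no segment
  med <- res$summary$median_abs_segment_mean
  expect_equal(med[res$summary$group == TRUE], 1.5)
  # identical distributions: H = 0
  seg0 <- dplyr::mutate(segments, segment_mean = 0)
  res0 <- compare_absolute_segment_means(calls, seg0, "is_cgc")
  expect_equal(res0$H, 0)
})

test_that("stratified correlation tables cover pooled and CGC strata", {
  set.seed(9)
  n <- 120
  tab <- tibble::tibble(
    v_rd = runif(n, 0, 3),
    is_cgc = rep(c(TRUE, FALSE), n / 2),
    consequence = rep(c("PTV", "missense", "silent"), n / 3),
    cancer_type = rep(c("SYNA", "SYNB"), each = n / 2))
  tab$log2fc <- 0.5 * tab$v_rd + rnorm(n, 0, 0.5)
  ct <- correlation_table(tab)
  expect_true(all(c("all", "CGC", "non-CGC") %in% ct$stratum))
  expect_gt(ct$rho[ct$stratum == "all"], 0.4)
  expect_true(all(ct$n[ct$stratum == "all"] == n))
})
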