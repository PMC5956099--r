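#' log2 tumor/normal expression fold change
#'
#' `log2((tumor + floor) / (normal + floor))`; missing when both abundances
#' are zero. The floor guards against division by zero for genes detected
#' in only one tissue.
#'
#' @param tumor_expr,normal_expr non-negative abundances (FPKM-like).
#' @param floor small positive abundance added to both (default 0.01).
#' @return numeric (NA where both abundances are zero).
#' @export
log2_fold_change <- function(tumor_expr, normal_expr, floor = 0.01) {
  if (any(tumor_expr < 0, na.rm = TRUE) || any(normal_expr < 0, na.rm = TRUE))
    ase_stop("expression abundances must be non-negative")
  out <- log2((tumor_expr + floor) / (normal_expr + floor))
  out[tumor_expr == 0 & normal_expr == 0] <- NA_real_
  out
}

#' Spearman rank correlation
#'
#' Average ranks for ties; two-sided p-value. Thin wrapper around
#' `stats::cor.test(method = "spearman")` so every result table reports
#' correlations through one code path.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with `rho`, `p` and `n`.
#' @export
spearman <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) ase_stop("spearman requires at least 3 paired values")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    ase_stop("correlation undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected H statistic with a chi-square p-value.
#'
#' @param groups list of (>= 2) numeric vectors.
#' @return list with `H`, `p`, `df` and `n`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) ase_stop("kruskal_wallis requires >= 2 groups")
  if (any(vapply(groups, length, 0L) == 0))
    ase_stop("kruskal_wallis requires nonempty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  if (length(unique(x)) == 1L)  # all tied: H is 0, not 0/0
    return(list(H = 0, p = 1, df = length(groups) - 1L, n = length(x)))
  kt <- stats::kruskal.test(x, g)
  list(H = unname(kt$statistic), p = kt$p.value,
       df = unname(kt$parameter), n = length(x))
}

#' Select extreme variants: high expressed allele frequency with
#' up- or down-regulated total expression
#'
#' High-AF/up: `v_rd > 2` and `log2fc >= 1` (at least two-fold increase);
#' high-AF/down: `v_rd > 2` and `log2fc <= -1`. The two sets are disjoint.
#'
#' @param tab tibble with columns `v_rd` and `log2fc`.
#' @param v_rd_min V_R:D threshold (default 2).
#' @param log2fc_min absolute log2 fold-change threshold (default 1).
#' @return list with tibbles `high_af_up` and `high_af_down`.
#' @export
select_extremes <- function(tab, v_rd_min = 2, log2fc_min = 1) {
  ok <- !is.na(tab$v_rd) & !is.na(tab$log2fc) & tab$v_rd > v_rd_min
  list(high_af_up = tab[ok & tab$log2fc >= log2fc_min, , drop = FALSE],
       high_af_down = tab[ok & tab$log2fc <= -log2fc_min, , drop = FALSE])
}

#' Rank genes by mean V_R:D
#'
#' Genes with at least `min_mutations` somatic variants carrying a defined
#' V_R:D are ranked in descending order of mean V_R:D; ties break
#' alphabetically by gene symbol.
#'
#' @param calls allele table with `gene` and `v_rd`.
#' @param min_mutations minimum number of qualifying variants per gene
#'   (default 3).
#' @return tibble `gene`, `n_mutations`, `mean_v_rd`, ordered.
#' @export
rank_genes_by_mean_vrd <- function(calls, min_mutations = 3L) {
  calls %>%
    dplyr::filter(!is.na(.data$v_rd)) %>%
    dplyr::group_by(.data$gene) %>%
    dplyr::summarise(n_mutations = dplyr::n(),
                     mean_v_rd = mean(.data$v_rd), .groups = "drop") %>%
    dplyr::filter(.data$n_mutations >= min_mutations) %>%
    dplyr::arrange(dplyr::desc(.data$mean_v_rd), .data$gene)
}

#' Chi-square enrichment of CGC genes in a selected gene set
#'
#' 2x2 chi-square test of CGC membership in the selected set versus the
#' rest of the background (continuity correction off by default).
#'
#' @param selected character vector of selected genes (subset of
#'   `background`).
#' @param background character vector of all analyzed genes.
#' @param cgc_list character vector of CGC gene symbols.
#' @param correct logical, Yates continuity correction (default FALSE).
#' @return list with `chi2`, `p` and `table` (2x2 matrix).
#' @export
cgc_enrichment <- function(selected, background, cgc_list,
                           correct = FALSE) {
  if (length(selected) == 0) ase_stop("empty gene selection")
  if (!all(selected %in% background))
    ase_stop("selected genes must be a subset of the background")
  rest <- setdiff(background, selected)
  tab <- matrix(c(sum(selected %in% cgc_list),
                  sum(!selected %in% cgc_list),
                  sum(rest %in% cgc_list),
                  sum(!rest %in% cgc_list)),
                nrow = 2, byrow = TRUE,
                dimnames = list(set = c("selected", "rest"),
                                cgc = c("cgc", "non_cgc")))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    ase_stop("degenerate 2x2 table (zero margin)")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi2 = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Compare absolute copy-number segment means between variant groups
#'
#' Joins each variant to the copy-number segment overlapping its position
#' in the same sample and compares the distributions of |segment mean|
#' between groups with a Kruskal-Wallis test. Variants overlapping no
#' segment are counted and excluded.
#'
#' @param calls allele table with `sample_id`, `chrom`, `pos` and the
#'   grouping column.
#' @param segments tibble (`sample_id`, `chrom`, `start`, `end`,
#'   `segment_mean`).
#' @param group_col name of the grouping column in `calls` (e.g.
#'   `"is_cgc"` or `"status"`).
#' @return list with `summary` (per-group n and median |segment mean|),
#'   `H`, `p` and `n_unmatched`.
#' @export
compare_absolute_segment_means <- function(calls, segments,
                                           group_col = "is_cgc") {
  seg_gr <- GenomicRanges::GRanges(
    paste(segments$sample_id, segments$chrom, sep = "|"),
    IRanges::IRanges(segments$start, segments$end))
  var_gr <- GenomicRanges::GRanges(
    paste(calls$sample_id, calls$chrom, sep = "|"),
    IRanges::IRanges(calls$pos, calls$pos))
  hit <- GenomicRanges::findOverlaps(var_gr, seg_gr, select = "first")
  matched <- !is.na(hit)
  df <- tibble::tibble(
    group = calls[[group_col]][matched],
    abs_segment_mean = abs(segments$segment_mean[hit[matched]]))
  df <- df[!is.na(df$group), , drop = FALSE]
  groups <- split(df$abs_segment_mean, df$group)
  kw <- if (length(groups) >= 2 && all(lengths(groups) > 0))
    kruskal_wallis(groups) else list(H = NA_real_, p = NA_real_)
  summary <- df %>%
    dplyr::group_by(.data$group) %>%
    dplyr::summarise(n = dplyr::n(),
                     median_abs_segment_mean = stats::median(.data$abs_segment_mean),
                     .groups = "drop")
  list(summary = summary, H = kw$H, p = kw$p,
       n_unmatched = sum(!matched))
}

#' Correlations of V_R:D with log2 expression fold change, stratified
#'
#' Computes Spearman correlations between V_R:D and log2\[T/N\] in the
#' pooled data and within strata (CGC membership x consequence class x
#' cancer type), skipping strata with fewer than `min_n` complete pairs.
#'
#' @param tab allele table joined to expression (`v_rd`, `log2fc`,
#'   `is_cgc`, `consequence`, `cancer_type`).
#' @param min_n minimum pairs per stratum (default 10).
#' @return tibble: `stratum`, `rho`, `p`, `n`.
#' @export
correlation_table <- function(tab, min_n = 10L) {
  run <- function(sub, label) {
    sub <- sub[!is.na(sub$v_rd) & !is.na(sub$log2fc), , drop = FALSE]
    if (nrow(sub) < min_n) return(NULL)
    res <- tryCatch(spearman(sub$v_rd, sub$log2fc), error = function(e) NULL)
    if (is.null(res)) return(NULL)
    tibble::tibble(stratum = label, rho = res$rho, p = res$p, n = res$n)
  }
  out <- list(run(tab, "all"))
  for (cg in c(TRUE, FALSE)) {
    lab <- if (cg) "CGC" else "non-CGC"
    sub <- tab[!is.na(tab$is_cgc) & tab$is_cgc == cg, , drop = FALSE]
    out <- c(out, list(run(sub, lab)))
    for (cons in unique(tab$consequence))
      out <- c(out, list(run(sub[sub$consequence == cons, , drop = FALSE],
                             paste(lab, cons, sep = "/"))))
  }
  for (cons in unique(tab$consequence))
    out <- c(out, list(run(tab[tab$consequence == cons, , drop = FALSE],
                           cons)))
  for (ct in unique(tab$cancer_type[!is.na(tab$cancer_type)]))
    out <- c(out, list(run(tab[tab$cancer_type %in% ct, , drop = FALSE],
                           paste0("cancer/", ct))))
  dplyr::bind_rows(out)
}
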