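#' Hypermutator cutoff and excluded samples
#'
#' Samples whose somatic mutation count lies more than 1.5 interquartile
#' ranges above the third quartile are flagged as hypermutators. Quartiles
#' use linear interpolation between order statistics
#' (`stats::quantile` type 7).
#'
#' @param mutation_counts named numeric vector of per-sample mutation
#'   counts (names are sample ids).
#' @return list with `threshold` (Q3 + 1.5 IQR) and `excluded` (character
#'   vector of sample ids strictly above the threshold).
#' @export
hypermutator_cutoff <- function(mutation_counts) {
  if (length(mutation_counts) < 4)
    ase_stop("hypermutator cutoff requires at least 4 samples")
  q <- stats::quantile(mutation_counts, c(0.25, 0.75), names = FALSE,
                       type = 7)
  iqr <- q[2] - q[1]
  threshold <- q[2] + 1.5 * iqr
  excluded <- names(mutation_counts)[mutation_counts > threshold]
  if (is.null(excluded)) excluded <- character(0)
  list(threshold = threshold, excluded = excluded)
}

#' Drop cancer-type groups below the minimum size
#'
#' Cancer types retaining fewer than `minimum` samples suitable for
#' assessment are removed (a group of exactly `minimum` is retained).
#'
#' @param samples tibble with `sample_id` and `cancer_type`.
#' @param minimum smallest retained group size (default 10).
#' @return tibble of retained samples; dropped groups are logged.
#' @export
min_group_size <- function(samples, minimum = 10L) {
  if (nrow(samples) == 0) return(samples)
  sizes <- table(samples$cancer_type)
  drop <- names(sizes)[sizes < minimum]
  if (length(drop) > 0)
    ase_log("dropping cancer type(s) below ", minimum, " samples: ",
            paste(drop, collapse = ", "))
  samples[!samples$cancer_type %in% drop, , drop = FALSE]
}

#' Variant filter cascade
#'
#' Applies the variant-level exclusion rules in a fixed order, attributing
#' each excluded variant to the first failing rule:
#' `missing_counts` (no quad-count record), `min_depth` (fewer than
#' `min_depth` reads in tumor DNA or tumor RNA), `chrX` (X-chromosome
#' position), `imprinted` (overlap with a known imprinted region),
#' `germline` (variant reads in the normal DNA or RNA above the noise
#' tolerance), `splice` (splice-annotated consequence), and `non_exonic`
#' (consequence `"other"`). The retained set does not depend on rule order;
#' only the reason attribution does.
#'
#' @param variants variant tibble.
#' @param counts quad-count tibble keyed by sample/chrom/pos/ref/alt.
#' @param imprinted optional `GRanges` of imprinted regions (1-based).
#' @param config see [status_config()] (uses `min_depth` and
#'   `max_normal_var_reads`).
#' @return list with `retained` (variant tibble joined to counts),
#'   `exclusions` (tibble `variant_key`, `reason`) and `tally` (named
#'   vector of per-rule exclusion counts).
#' @export
apply_variant_filters <- function(variants, counts, imprinted = NULL,
                                  config = status_config()) {
  key <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele")
  tab <- dplyr::left_join(variants, counts, by = key)
  n <- nrow(tab)
  reason <- rep(NA_character_, n)

  has_counts <- !is.na(tab$Tex_ref) & !is.na(tab$Tex_var) &
    !is.na(tab$Ttr_ref) & !is.na(tab$Ttr_var)
  reason[!has_counts] <- "missing_counts"

  dna_depth <- tab$Tex_ref + tab$Tex_var
  rna_depth <- tab$Ttr_ref + tab$Ttr_var
  low <- has_counts & (dna_depth < config$min_depth |
                         rna_depth < config$min_depth)
  reason[is.na(reason) & low] <- "min_depth"

  on_x <- tab$chrom %in% c("chrX", "X")
  reason[is.na(reason) & on_x] <- "chrX"

  if (!is.null(imprinted) && length(imprinted) > 0) {
    gr <- GenomicRanges::GRanges(tab$chrom,
                                 IRanges::IRanges(tab$pos, tab$pos))
    hit <- GenomicRanges::countOverlaps(gr, imprinted) > 0
    reason[is.na(reason) & hit] <- "imprinted"
  }

  germ <- has_germline_evidence(tab, config$max_normal_var_reads)
  reason[is.na(reason) & has_counts & germ] <- "germline"

  reason[is.na(reason) & tab$consequence == "splice"] <- "splice"
  reason[is.na(reason) & tab$consequence == "other"] <- "non_exonic"

  keep <- is.na(reason)
  exclusions <- tibble::tibble(
    variant_key = variant_key(tab$sample_id, tab$chrom, tab$pos,
                              tab$ref_allele, tab$alt_allele)[!keep],
    reason = reason[!keep])
  rules <- c("missing_counts", "min_depth", "chrX", "imprinted", "germline",
             "splice", "non_exonic")
  tally <- vapply(rules, function(r) sum(exclusions$reason == r), integer(1))
  stopifnot(sum(keep) + sum(tally) == n)
  list(retained = tab[keep, , drop = FALSE],
       exclusions = exclusions, tally = tally)
}
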