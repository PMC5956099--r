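#' Upper tail of the binomial distribution
#'
#' P(X >= k) for X ~ Binomial(n, p). Exact (no normal approximation).
#'
#' @param k,n counts with 0 <= k <= n.
#' @param p success probability.
#' @return probability.
#' @export
binomial_upper_tail <- function(k, n, p) {
  if (any(k < 0) || any(n < 0) || any(k > n) || any(p < 0) || any(p > 1))
    ase_stop("binomial_upper_tail requires 0 <= k <= n and 0 <= p <= 1")
  stats::pbinom(k - 1, size = n, prob = p, lower.tail = FALSE)
}

#' Status-call configuration
#'
#' Defaults for the binomial expression-status calls: `p_err` is the
#' per-read noise probability of observing the minority base, `alpha` the
#' significance level at which the noise-only model is rejected,
#' `min_depth` the minimum tumor DNA and RNA depth, `min_dna_minor_reads`
#' the bi-allelic DNA gate (both tumor-DNA alleles must carry at least this
#' many reads for SOM-E/SOM-L to be callable), and `max_normal_var_reads`
#' the number of variant reads tolerated as noise in each normal dataset
#' before a variant is flagged as germline.
#'
#' @param p_err,alpha,min_depth,min_dna_minor_reads,max_normal_var_reads
#'   see above.
#' @return named list.
#' @export
status_config <- function(p_err = 0.05, alpha = 0.05, min_depth = 10L,
                          min_dna_minor_reads = 2L,
                          max_normal_var_reads = 1L) {
  stopifnot(p_err >= 0, p_err <= 1, alpha > 0, alpha < 1)
  list(p_err = p_err, alpha = alpha, min_depth = as.integer(min_depth),
       min_dna_minor_reads = as.integer(min_dna_minor_reads),
       max_normal_var_reads = as.integer(max_normal_var_reads))
}

#' Call SOM / SOM-E / SOM-L expression status for one variant
#'
#' SOM-L (loss of the variant allele in the transcriptome, VAF_tRNA ~ 0) is
#' called when the tumor-RNA variant reads are consistent with sequencing
#' noise alone, i.e. the noise-only model X ~ Binomial(n, p_err) is *not*
#' rejected at level `alpha`: P(X >= n_var) >= alpha. SOM-E (VAF_tRNA ~ 1)
#' is the mirrored condition on the reference reads. Both require a
#' bi-allelic DNA signal (0 < VAF_tDNA < 1, operationalized as both tumor
#' DNA alleles carrying at least `min_dna_minor_reads` reads). Everything
#' else is SOM. In the degenerate small-depth case where both one-sided
#' conditions hold simultaneously the call falls back to SOM, keeping SOM-E
#' and SOM-L mutually exclusive.
#'
#' @param q named list/one-row data frame of quad counts (`Tex_ref`,
#'   `Tex_var`, `Ttr_ref`, `Ttr_var`; normal counts are not used here).
#' @param config see [status_config()].
#' @return list with `status` (`"SOM"`, `"SOM_E"`, `"SOM_L"` or `NA` when
#'   depth is insufficient), `p_noise_var`, `p_noise_ref`.
#' @export
call_status <- function(q, config = status_config()) {
  tab <- tibble::tibble(Tex_ref = q$Tex_ref, Tex_var = q$Tex_var,
                        Ttr_ref = q$Ttr_ref, Ttr_var = q$Ttr_var)
  res <- call_status_table(tab, config)
  list(status = res$status[1], p_noise_var = res$p_noise_var[1],
       p_noise_ref = res$p_noise_ref[1])
}

# Vectorized status calling over an allele table.
call_status_table <- function(tab, config = status_config()) {
  dna_depth <- tab$Tex_ref + tab$Tex_var
  rna_depth <- tab$Ttr_ref + tab$Ttr_var
  ok <- !is.na(dna_depth) & !is.na(rna_depth) &
    dna_depth >= config$min_depth & rna_depth >= config$min_depth
  p_var <- rep(NA_real_, nrow(tab))
  p_ref <- rep(NA_real_, nrow(tab))
  p_var[ok] <- binomial_upper_tail(tab$Ttr_var[ok], rna_depth[ok],
                                   config$p_err)
  p_ref[ok] <- binomial_upper_tail(tab$Ttr_ref[ok], rna_depth[ok],
                                   config$p_err)
  biallelic <- ok & tab$Tex_ref >= config$min_dna_minor_reads &
    tab$Tex_var >= config$min_dna_minor_reads
  is_l <- biallelic & p_var >= config$alpha
  is_e <- biallelic & p_ref >= config$alpha
  status <- rep(NA_character_, nrow(tab))
  status[ok] <- "SOM"
  status[which(is_l & !is_e)] <- "SOM_L"
  status[which(is_e & !is_l)] <- "SOM_E"
  # both conditions holding is only possible at tiny depth; fall back to SOM
  list(status = status, p_noise_var = p_var, p_noise_ref = p_ref)
}

#' Is there read-level evidence of germline origin?
#'
#' A variant is considered germline-suspect when its variant-read count in
#' the normal exome or the normal transcriptome exceeds
#' `max_normal_var_reads` (counts up to the threshold are tolerated as
#' sequencing noise).
#'
#' @param q named list/one-row data frame with `Nex_var` and `Ntr_var`.
#' @param max_normal_var_reads tolerance (default 1).
#' @return logical.
#' @export
has_germline_evidence <- function(q, max_normal_var_reads = 1L) {
  nex <- q$Nex_var
  ntr <- q$Ntr_var
  nex[is.na(nex)] <- 0L
  ntr[is.na(ntr)] <- 0L
  nex > max_normal_var_reads | ntr > max_normal_var_reads
}

#' Summarize expression-status calls as counts and percentages
#'
#' The report formatter used for cohort summaries: given per-status call
#' counts it computes each status's percentage of all called variants,
#' rounded to one decimal (the convention used in cohort reports).
#'
#' @param status character vector of per-variant calls, or a named vector of
#'   counts (e.g. `c(SOM = 4129, SOM_E = 350, SOM_L = 1044)`).
#' @return tibble with columns `status`, `n`, `percent`.
#' @export
status_summary <- function(status) {
  if (is.numeric(status)) {
    counts <- status
    if (is.null(names(counts))) ase_stop("count vector must be named")
  } else {
    counts <- table(status[!is.na(status)])
  }
  total <- sum(counts)
  tibble::tibble(
    status = names(counts),
    n = as.integer(counts),
    percent = round(100 * as.integer(counts) / total, 1)
  )
}
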