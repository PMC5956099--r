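#' Variant allele fraction
#'
#' \deqn{VAF = n_{var} / (n_{ref} + n_{var})}
#'
#' @param n_ref,n_var non-negative read counts.
#' @return fraction in \[0, 1\].
#' @export
vaf <- function(n_ref, n_var) {
  if (any(n_ref < 0) || any(n_var < 0)) ase_stop("read counts must be >= 0")
  depth <- n_ref + n_var
  if (any(depth == 0))
    ase_stop("VAF undefined at zero depth")
  n_var / depth
}

#' Expressed-to-DNA allele fraction ratio
#'
#' \deqn{V_{R:D} = VAF_{tRNA} / VAF_{tDNA}}
#'
#' A value of 1 means the transcriptome mirrors the DNA allele balance;
#' values above 1 indicate preferential expression of the variant allele.
#' The ratio is undefined (error for the scalar form; `NA` in table
#' pipelines) when `vaf_tdna` is 0; it is not capped above.
#'
#' @param vaf_trna,vaf_tdna allele fractions in \[0, 1\].
#' @return non-negative real.
#' @export
v_ratio <- function(vaf_trna, vaf_tdna) {
  if (any(vaf_tdna == 0))
    ase_stop("V_R:D undefined when VAF_tDNA = 0")
  vaf_trna / vaf_tdna
}

#' Purity-weighted V_R:D
#'
#' Multiplies V_R:D by each available tumor-purity estimate:
#' aV_R:D = V_R:D x ABSOLUTE, iV_R:D = V_R:D x IHC, eV_R:D = V_R:D x
#' ESTIMATE, lV_R:D = V_R:D x LUMP, cV_R:D = V_R:D x CPE. A missing purity
#' method yields a missing weighted value.
#'
#' @param v_rd V_R:D value (scalar or vector).
#' @param purity named list/one-row data frame with (possibly `NA`) entries
#'   `ESTIMATE`, `ABSOLUTE`, `LUMP`, `IHC`, `CPE`.
#' @return named list with entries `aV_RD`, `iV_RD`, `eV_RD`, `lV_RD`,
#'   `cV_RD`.
#' @export
weight_by_purity <- function(v_rd, purity) {
  get <- function(m) {
    p <- purity[[m]]
    if (is.null(p)) NA_real_ else as.numeric(p)
  }
  list(aV_RD = v_rd * get("ABSOLUTE"),
       iV_RD = v_rd * get("IHC"),
       eV_RD = v_rd * get("ESTIMATE"),
       lV_RD = v_rd * get("LUMP"),
       cV_RD = v_rd * get("CPE"))
}

#' Does a sample have sufficiently many purity estimates?
#'
#' A sample qualifies when at least three of the five purity estimates
#' (ESTIMATE, ABSOLUTE, LUMP, IHC, CPE) are available.
#'
#' @param purity named list/one-row data frame of purity estimates, `NA`
#'   when unavailable.
#' @param minimum required number of non-missing methods (default 3).
#' @return logical.
#' @export
purity_sufficient <- function(purity, minimum = 3L) {
  methods <- c("ESTIMATE", "ABSOLUTE", "LUMP", "IHC", "CPE")
  present <- vapply(methods, function(m) {
    p <- purity[[m]]
    !is.null(p) && length(p) == 1L && !is.na(p)
  }, logical(1))
  sum(present) >= minimum
}

#' Compute the per-variant allele table
#'
#' Joins variants to quad counts and purity, computes VAF_tDNA, VAF_tRNA,
#' V_R:D, the five purity-weighted V_R:D columns, and the SOM/SOM-E/SOM-L
#' expression status. VAFs are `NA` at zero depth; V_R:D is `NA` whenever
#' VAF_tDNA is 0 or undefined.
#'
#' @param variants variant tibble from [read_variants()] (already filtered).
#' @param counts quad-count tibble (`read_input_table(kind = "counts")`).
#' @param purity optional purity tibble keyed by `sample_id`.
#' @param config status-call configuration, see [status_config()].
#' @return tibble: variant columns plus the eight counts, `vaf_tdna`,
#'   `vaf_trna`, `v_rd`, `aV_RD` ... `cV_RD`, `status` and the two
#'   noise-model p-values.
#' @export
compute_allele_table <- function(variants, counts, purity = NULL,
                                 config = status_config()) {
  key <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele")
  tab <- dplyr::left_join(variants, counts, by = key)
  dna_depth <- tab$Tex_ref + tab$Tex_var
  rna_depth <- tab$Ttr_ref + tab$Ttr_var
  tab$vaf_tdna <- ifelse(dna_depth > 0, tab$Tex_var / dna_depth, NA_real_)
  tab$vaf_trna <- ifelse(rna_depth > 0, tab$Ttr_var / rna_depth, NA_real_)
  tab$v_rd <- ifelse(!is.na(tab$vaf_tdna) & tab$vaf_tdna > 0 &
                       !is.na(tab$vaf_trna),
                     tab$vaf_trna / tab$vaf_tdna, NA_real_)
  if (!is.null(purity)) {
    tab <- dplyr::left_join(
      tab, purity[, c("sample_id", "ESTIMATE", "ABSOLUTE", "LUMP", "IHC",
                      "CPE")], by = "sample_id")
  } else {
    tab$ESTIMATE <- tab$ABSOLUTE <- tab$LUMP <- tab$IHC <- tab$CPE <- NA_real_
  }
  tab$aV_RD <- tab$v_rd * tab$ABSOLUTE
  tab$iV_RD <- tab$v_rd * tab$IHC
  tab$eV_RD <- tab$v_rd * tab$ESTIMATE
  tab$lV_RD <- tab$v_rd * tab$LUMP
  tab$cV_RD <- tab$v_rd * tab$CPE
  st <- call_status_table(tab, config)
  tab$status <- st$status
  tab$p_noise_var <- st$p_noise_var
  tab$p_noise_ref <- st$p_noise_ref
  tab
}
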