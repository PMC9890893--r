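## Targeted-proteomics absolute quantitation of TREM2 species and the small
## assay normalizations (2^-dCT, C/N Ct ratios, fold-of-reference).

#' Absolute molar amount from a PRM measurement
#'
#' With a known spike of stable-isotope-labeled internal standard (SIL-IS)
#' peptide, the native amount is the native-to-standard peak-area ratio times
#' the spike: \code{fmol = native_area / sil_area * spike_fmol}.
#'
#' @param native_area native peptide chromatographic peak area.
#' @param sil_area internal-standard peak area (> 0).
#' @param spike_fmol spiked internal-standard amount, fmol (default 5).
#' @return amount in fmol (vectorized).
#' @export
prm_amount <- function(native_area, sil_area, spike_fmol = 5) {
  if (any(sil_area <= 0)) stop("unquantifiable: internal-standard peak area must be > 0", call. = FALSE)
  if (any(native_area < 0)) stop("negative native peak area", call. = FALSE)
  if (any(spike_fmol <= 0)) stop("spike_fmol must be > 0", call. = FALSE)
  native_area / sil_area * spike_fmol
}

#' Per-sample TREM2 species summary from PRM measurements
#'
#' Sums soluble (sTREM2) and full-length (flTREM2) amounts across alleles,
#' forms the global soluble/full-length (s/fl) ratio, and in heterozygotes
#' the allele-specific ratios.
#'
#' @param measurements data.frame with columns \code{sample_id, species,
#'   native_area, sil_area, spike_fmol}; species follow the
#'   \code{"sTREM2-<allele>"} / \code{"flTREM2-<allele>"} convention.
#' @return data.frame of class \code{trem_quant}, one row per sample:
#'   \code{s_total_fmol, fl_total_fmol, s_fl_ratio} and, where both alleles
#'   are measured, \code{s_fl_ratio_WT, s_fl_ratio_H157Y}. Ratios with a
#'   zero full-length denominator are NA with a warning.
#' @export
trem2_summary <- function(measurements) {
  req <- c("sample_id", "species", "native_area", "sil_area", "spike_fmol")
  stopifnot(all(req %in% names(measurements)))
  measurements$fmol <- prm_amount(measurements$native_area,
                                  measurements$sil_area,
                                  measurements$spike_fmol)
  form <- sub("-.*$", "", measurements$species)    # sTREM2 / flTREM2
  allele <- sub("^[^-]*-", "", measurements$species)
  measurements$form <- form; measurements$allele <- allele
  ratio_or_na <- function(s, fl, what) {
    if (fl == 0) {
      ## an absent species pair (both zero, e.g. the other allele in a
      ## homozygote) is silently undefined; a measured soluble amount with
      ## no full-length signal deserves a warning
      if (s > 0) warning(sprintf("zero full-length amount: %s ratio undefined", what))
      return(NA_real_)
    }
    s / fl
  }
  rows <- lapply(split(measurements, measurements$sample_id), function(m) {
    s_tot <- sum(m$fmol[m$form == "sTREM2"])
    fl_tot <- sum(m$fmol[m$form == "flTREM2"])
    out <- data.frame(sample_id = m$sample_id[1],
                      s_total_fmol = s_tot, fl_total_fmol = fl_tot,
                      s_fl_ratio = ratio_or_na(s_tot, fl_tot, "global s/fl"),
                      s_fl_ratio_WT = NA_real_, s_fl_ratio_H157Y = NA_real_)
    for (al in c("WT", "H157Y")) {
      s <- m$fmol[m$form == "sTREM2" & m$allele == al]
      fl <- m$fmol[m$form == "flTREM2" & m$allele == al]
      if (length(s) == 1 && length(fl) == 1) {
        out[[paste0("s_fl_ratio_", al)]] <-
          ratio_or_na(s, fl, paste0("allele ", al, " s/fl"))
      }
    }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trem_quant", "data.frame")
  out
}

#' Relative expression by the 2^-dCT method
#'
#' @param ct_target,ct_reference cycle-threshold values of the target and the
#'   housekeeping reference (vectorized).
#' @return \code{2^-(ct_target - ct_reference)}.
#' @export
rel_expr_2dct <- function(ct_target, ct_reference) {
  stopifnot(all(is.finite(ct_target)), all(is.finite(ct_reference)))
  2^(-(ct_target - ct_reference))
}

#' C-terminal / N-terminal Ct ratio normalized to a reference group
#'
#' Per-sample ratio of C-terminal to N-terminal cycle thresholds, divided by
#' the mean ratio of the reference group. A C/N ratio above the reference
#' indicates relative loss of the C-terminal amplicon (e.g., aberrant
#' splicing downstream of the targeted exon).
#'
#' @param ct_cterm,ct_nterm Ct vectors (N-terminal must be > 0).
#' @param group_labels group of each sample.
#' @param reference_group label of the reference group.
#' @export
ct_ratio_cn <- function(ct_cterm, ct_nterm, group_labels, reference_group = "WT") {
  if (any(ct_nterm <= 0)) stop("N-terminal Ct must be > 0", call. = FALSE)
  ratio <- ct_cterm / ct_nterm
  fold_of_reference(ratio, group_labels, reference_group)
}

#' Normalize values to the mean of a reference group
#'
#' Each value divided by the arithmetic mean of the reference group's values
#' (optionally after a per-sample division by total protein); the reference
#' group then has mean exactly 1.
#'
#' @param values numeric vector.
#' @param group_labels group of each value.
#' @param reference_group label of the reference group.
#' @param total_protein optional per-sample total protein for a prior
#'   per-sample normalization.
#' @export
fold_of_reference <- function(values, group_labels, reference_group = "WT",
                              total_protein = NULL) {
  if (!is.null(total_protein)) {
    if (any(total_protein <= 0)) stop("total_protein must be > 0", call. = FALSE)
    values <- values / total_protein
  }
  ref <- values[group_labels == reference_group]
  if (length(ref) == 0) stop("reference group is empty", call. = FALSE)
  m <- mean(ref)
  if (m == 0) stop("reference group mean is zero", call. = FALSE)
  values / m
}
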