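#' Apparent ploidy from a FACS G1 peak
#'
#' DNA content of a sample expressed relative to a haploid control run
#' in parallel: the ratio of the modes of the two G1 peaks.
#'
#' @param g1_peak G1 peak position of the sample (arbitrary
#'   fluorescence units, > 0).
#' @param control_g1_peak G1 peak position of the haploid control
#'   (same units, > 0).
#' @return Apparent ploidy (1.0 for the haploid control itself).
#' @export
apparent_ploidy_from_facs <- function(g1_peak, control_g1_peak) {
  if (any(!is.finite(g1_peak)) || any(g1_peak <= 0) ||
      !is.finite(control_g1_peak) || control_g1_peak <= 0) {
    stop("G1 peak positions must be positive")
  }
  g1_peak / control_g1_peak
}

#' Relative quantity from qPCR Ct values
#'
#' Single-normalization relative quantification:
#' `efficiency^(calibrator_ct - sample_ct)`. With a perfectly doubling
#' reaction (efficiency 2) a sample one cycle later than the calibrator
#' has half the template. Double normalization (delta-delta-Ct against
#' an endogenous control probe) composes multiplicatively, see
#' [ddct_ratio()].
#'
#' @param sample_ct,calibrator_ct Ct values (cycle numbers, replicate
#'   means).
#' @param efficiency Amplification efficiency in fold per cycle, in
#'   (1, 2]; default 2 (perfect doubling).
#' @return Relative quantity of the sample vs the calibrator.
#' @export
#' @examples
#' relative_ratio_from_ct(21, 20)        # 0.5
#' relative_ratio_from_ct(19, 20)        # 2
relative_ratio_from_ct <- function(sample_ct, calibrator_ct,
                                   efficiency = 2) {
  if (!is.finite(efficiency) || efficiency <= 1 || efficiency > 2) {
    stop("amplification efficiency must be in (1, 2]")
  }
  efficiency^(calibrator_ct - sample_ct)
}

#' Delta-delta-Ct relative copy ratio
#'
#' Normalized relative quantity of a target probe versus an endogenous
#' control probe, each scaled to a calibrator sample:
#' `E_t^(dCt_target) / E_r^(dCt_reference)` with
#' `dCt = calibrator_ct - sample_ct`. Per-probe efficiencies are
#' accepted; both default to 2.
#'
#' @param sample_target_ct,calibrator_target_ct Target-probe Ct in the
#'   sample and calibrator.
#' @param sample_ref_ct,calibrator_ref_ct Endogenous-control-probe Ct
#'   in the sample and calibrator.
#' @param efficiency_target,efficiency_ref Amplification efficiencies.
#' @return Normalized relative copy ratio.
#' @export
ddct_ratio <- function(sample_target_ct, calibrator_target_ct,
                       sample_ref_ct, calibrator_ref_ct,
                       efficiency_target = 2, efficiency_ref = 2) {
  relative_ratio_from_ct(sample_target_ct, calibrator_target_ct,
                         efficiency_target) /
    relative_ratio_from_ct(sample_ref_ct, calibrator_ref_ct,
                           efficiency_ref)
}

#' Per-chromosome stoichiometry from a Ct table
#'
#' Averages technical replicates and converts Ct values into relative
#' copy ratios scaled to a calibrator sample (e.g. a wild-type
#' haploid). With `reference_probe` set, the delta-delta-Ct chain is
#' used (each chromosome normalized to the reference probe within
#' sample, then to the calibrator); otherwise single normalization to
#' the calibrator only, which leaves an arbitrary global scale that
#' downstream integer calling absorbs.
#'
#' @param ct_table Data frame with columns `sample_id`, `probe_id`,
#'   `ct` (one row per technical replicate).
#' @param calibrator `sample_id` of the calibrator sample.
#' @param reference_probe Optional `probe_id` used as endogenous
#'   control.
#' @param efficiency Amplification efficiency (fold/cycle).
#' @return Data frame `sample_id`, `probe_id`, `ratio` for all
#'   non-calibrator samples.
#' @export
stoichiometry_from_ct <- function(ct_table, calibrator,
                                  reference_probe = NULL,
                                  efficiency = 2) {
  need <- c("sample_id", "probe_id", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("ct_table must have columns ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(ct_table$ct)) || any(ct_table$ct <= 0)) {
    stop("Ct values must be positive")
  }
  means <- stats::aggregate(ct ~ sample_id + probe_id, data = ct_table,
                            FUN = mean)
  cal <- means[means$sample_id == calibrator, ]
  if (nrow(cal) == 0) stop("calibrator sample '", calibrator, "' not found")
  samp <- means[means$sample_id != calibrator, ]
  cal_ct <- cal$ct[match(samp$probe_id, cal$probe_id)]
  if (any(is.na(cal_ct))) stop("calibrator lacks some probes")
  ratio <- relative_ratio_from_ct(samp$ct, cal_ct, efficiency)
  if (!is.null(reference_probe)) {
    ref <- samp$probe_id == reference_probe
    if (!any(ref)) stop("reference probe '", reference_probe, "' not found")
    ref_ratio <- ratio[ref][match(samp$sample_id, samp$sample_id[ref])]
    ratio <- ratio / ref_ratio
  }
  data.frame(sample_id = samp$sample_id, probe_id = samp$probe_id,
             ratio = ratio, stringsAsFactors = FALSE)
}

#' Call an integer karyotype from stoichiometry and apparent ploidy
#'
#' Finds the integer copy-number vector `c` and positive scale `s`
#' minimizing `sum_i w_i (s * r_i - c_i)^2` over the allowed copy-number
#' range, subject to the called karyotype's apparent ploidy agreeing
#' with the FACS estimate within `ploidy_tol`. Because qPCR
#' stoichiometry is relative, the profile `r` carries an arbitrary
#' global scale which `s` absorbs; the FACS ploidy anchors the absolute
#' level. Given `s` the objective separates per chromosome, so the
#' optimal `c` is per-chromosome rounding of `s * r`; `s` is searched
#' on a grid and refined by the closed-form optimum for each candidate
#' rounding.
#'
#' Chromosomes whose scaled ratio lies farther than
#' `residual_threshold` from the called integer are flagged
#' heterogeneous (a non-integer population copy number). If no integer
#' vector satisfies the ploidy constraint the strain is declared too
#' heterogeneous and no karyotype is returned.
#'
#' @param ratios Numeric vector of 16 positive per-chromosome relative
#'   copy ratios (named by chromosome or in canonical order).
#' @param facs_ploidy Apparent ploidy from FACS (plausible range
#'   roughly 0.5-4).
#' @param table Chromosome length table.
#' @param copy_range Allowed integer copy numbers (default `1:3`).
#' @param ploidy_tol Maximum allowed |called - FACS| apparent-ploidy
#'   discrepancy (default 0.15).
#' @param residual_threshold Scaled-ratio residual above which a
#'   chromosome is flagged heterogeneous (default 0.25).
#' @param weights Per-chromosome weights in the objective (default
#'   uniform).
#' @return Object of class `karyotype_call`: list with `karyotype`
#'   (or `NULL`), `scale`, `residuals`, `flags` (logical, heterogeneous
#'   chromosomes), `called_ploidy`, `facs_ploidy`, `verdict`
#'   (`"ok"` or `"too_heterogeneous"`).
#' @export
#' @examples
#' k <- rep(1, 16); k[c(4, 7)] <- 2
#' call_karyotype(k / 3.7, apparent_ploidy(k))$karyotype # recovers k
call_karyotype <- function(ratios, facs_ploidy,
                           table = yeast_chromosomes(),
                           copy_range = 1:3,
                           ploidy_tol = 0.15,
                           residual_threshold = 0.25,
                           weights = rep(1, 16)) {
  if (length(ratios) != 16L) stop("need 16 chromosome ratios")
  if (any(!is.finite(ratios)) || any(ratios <= 0)) {
    stop("all stoichiometry ratios must be positive")
  }
  if (!is.finite(facs_ploidy) || facs_ploidy < 0.5 || facs_ploidy > 4) {
    stop("apparent ploidy outside plausible range [0.5, 4]")
  }
  r <- as.numeric(ratios)
  if (!is.null(names(ratios)) && !all(names(ratios) == "")) {
    nm <- normalize_chromosome(names(ratios))
    r <- r[match(chromosome_ids(), nm)]
  }
  table <- validate_chromosome_table(table)
  cmin <- min(copy_range)
  cmax <- max(copy_range)
  w <- weights / sum(weights)

  # s grid centered on the scale that matches mean ratio to FACS ploidy
  s0 <- facs_ploidy / mean(r)
  grid <- s0 * exp(seq(log(0.4), log(2.5), length.out = 600))
  best <- NULL
  seen <- character(0)
  for (s in grid) {
    cc <- pmin(pmax(round(s * r), cmin), cmax)
    key <- paste(cc, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    # closed-form optimal scale for this integer assignment
    s_opt <- sum(w * r * cc) / sum(w * r^2)
    resid <- s_opt * r - cc
    obj <- sum(w * resid^2)
    called_ploidy <- apparent_ploidy(cc, table)
    ok <- abs(called_ploidy - facs_ploidy) <= ploidy_tol
    if (ok && (is.null(best) || obj < best$obj)) {
      best <- list(c = cc, s = s_opt, resid = resid, obj = obj,
                   ploidy = called_ploidy)
    }
  }
  if (is.null(best)) {
    return(structure(list(karyotype = NULL, scale = NA_real_,
                          residuals = NULL, flags = NULL,
                          called_ploidy = NA_real_,
                          facs_ploidy = facs_ploidy,
                          verdict = "too_heterogeneous"),
                     class = "karyotype_call"))
  }
  flags <- abs(best$resid) > residual_threshold
  names(flags) <- chromosome_ids()
  resid <- best$resid
  names(resid) <- chromosome_ids()
  structure(list(karyotype = as_karyotype(best$c), scale = best$s,
                 residuals = resid, flags = flags,
                 called_ploidy = best$ploidy,
                 facs_ploidy = facs_ploidy, verdict = "ok"),
            class = "karyotype_call")
}

#' @export
print.karyotype_call <- function(x, ...) {
  if (x$verdict != "ok") {
    cat("Karyotype call: too heterogeneous (no integer karyotype within",
        "ploidy tolerance)\n")
    return(invisible(x))
  }
  cat("Karyotype call (apparent ploidy", sprintf("%.2f", x$called_ploidy),
      "vs FACS", sprintf("%.2f", x$facs_ploidy), ")\n")
  print(x$karyotype)
  if (any(x$flags)) {
    cat("heterogeneous chromosomes:",
        paste(names(x$flags)[x$flags], collapse = ", "), "\n")
  }
  invisible(x)
}

#' Classify ploidy stability from G1-peak variation
#'
#' The coefficient of variation (CV) of the 12 G1 peak positions (the
#' original spore sample plus its 11 colonies) is compared with the CV
#' of 12 haploid control colonies processed in parallel. A strain is
#' ploidy stable only if its CV is no larger than the control CV times
#' `cv_factor`. Strains with obviously heterogeneous, noisy DNA
#' profiles can be pre-classified unstable via `force_unstable`.
#'
#' @param peaks Numeric vector of exactly 12 G1 peak positions (spore +
#'   11 colonies).
#' @param control_peaks G1 peak positions of haploid control colonies
#'   (>= 2 values, conventionally 12).
#' @param cv_factor Tolerance multiplier on the control CV (default 1).
#' @param force_unstable If `TRUE`, classify unstable regardless of CV
#'   (heterogeneous/noisy profile override).
#' @return Object of class `ploidy_stability`: list with `cv_g1`,
#'   `control_cv` and `verdict` (`"stable"`/`"unstable"`).
#' @export
#' @examples
#' classify_ploidy_stability(rep(100, 12), c(99, 100, 101, 100))
classify_ploidy_stability <- function(peaks, control_peaks,
                                      cv_factor = 1,
                                      force_unstable = FALSE) {
  if (length(peaks) != 12L) {
    stop("need exactly 12 G1 peaks (spore + 11 colonies), got ",
         length(peaks))
  }
  if (length(control_peaks) < 2L) stop("need >= 2 control peaks")
  if (any(peaks <= 0) || any(control_peaks <= 0)) {
    stop("peak positions must be positive")
  }
  cv <- stats::sd(peaks) / mean(peaks)
  ccv <- stats::sd(control_peaks) / mean(control_peaks)
  verdict <- if (force_unstable || cv > ccv * cv_factor) {
    "unstable"
  } else {
    "stable"
  }
  structure(list(cv_g1 = cv, control_cv = ccv, verdict = verdict,
                 cv_factor = cv_factor),
            class = "ploidy_stability")
}

#' @export
print.ploidy_stability <- function(x, ...) {
  cat(sprintf("Ploidy stability: %s (CV %.4f vs control %.4f)\n",
              x$verdict, x$cv_g1, x$control_cv))
  invisible(x)
}

#' Assign a MAD2:MAD1 ratio class
#'
#' Maps a measured copy ratio to the nearest admissible rational class.
#' With copy numbers 1-3 the admissible ratios are 0.5, 1, 1.5 and 2
#' (the default class set). The binary split used in stability
#' association analyses - ratio equal vs not equal to 0.5 - is exposed
#' via the `is_half` element.
#'
#' @param ratio Positive measured MAD2:MAD1 copy ratio.
#' @param classes Admissible ratio classes (default
#'   `c(0.5, 1, 1.5, 2)`).
#' @return List with `class` (nearest admissible ratio) and `is_half`
#'   (`TRUE` if that class is 0.5).
#' @export
#' @examples
#' mad_ratio_class(0.52)$class # 0.5
mad_ratio_class <- function(ratio, classes = c(0.5, 1, 1.5, 2)) {
  if (length(ratio) != 1L || !is.finite(ratio) || ratio <= 0) {
    stop("ratio must be a single positive number")
  }
  cls <- classes[which.min(abs(classes - ratio))]
  list(class = cls, is_half = cls == 0.5)
}
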