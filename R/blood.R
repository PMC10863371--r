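#' Blood tryptophan / large-neutral-amino-acid ratio
#'
#' Tryptophan competes with the other large neutral amino acids (LNAAs) for
#' transport across the blood-brain barrier, so the tryptophan/sum(LNAA)
#' ratio indexes central serotonin availability. Threonine, lysine and
#' methionine appear in the intervention mixture for tolerability reasons but
#' are not transport competitors and are excluded from the LNAA sum.
#'
#' @param profile Named numeric vector of amino-acid concentrations (any
#'   consistent units); must contain a `tryptophan` entry.
#' @param excluded Amino acids excluded from the LNAA sum.
#' @return Positive scalar ratio.
#' @examples
#' trp_lnaa_ratio(c(tryptophan = 1, valine = 1, leucine = 1,
#'                  isoleucine = 1, phenylalanine = 0.5, tyrosine = 0.5))
#' @export
trp_lnaa_ratio <- function(profile,
                           excluded = c("threonine", "lysine", "methionine")) {
  stopifnot(is.numeric(profile), !is.null(names(profile)))
  if (!"tryptophan" %in% names(profile)) stop("profile must contain tryptophan")
  lnaa <- profile[setdiff(names(profile), c("tryptophan", excluded))]
  denom <- sum(lnaa)
  if (!is.finite(denom) || denom <= 0)
    stop("LNAA sum must be positive")
  unname(profile[["tryptophan"]] / denom)
}

#' Baseline-normalized area under the ratio curve
#'
#' Divides the four-timepoint tryptophan/LNAA-ratio series by its T0 value
#' and integrates by the trapezoidal rule over the sampling hours
#' (0, 1, 3, 6.5). A constant series therefore integrates to 6.5.
#' `mode = "subtract"` instead subtracts the T0 value before integrating (the
#' baseline-normalization wording is ambiguous; division is the default
#' reading).
#'
#' @param ratio Numeric vector of four ratios, T0 first, `ratio[1] > 0`.
#' @param timepoints_h Sampling times in hours, strictly increasing.
#' @param mode `"divide"` (default) or `"subtract"`.
#' @return Scalar AUC (hours, for the divide mode's unitless integrand).
#' @examples
#' auc_normalized(c(1, 2, 2, 1))   # 10.75
#' @export
auc_normalized <- function(ratio, timepoints_h = blood_timepoints,
                           mode = c("divide", "subtract")) {
  mode <- match.arg(mode)
  stopifnot(length(ratio) == length(timepoints_h),
            length(ratio) == 4L, all(diff(timepoints_h) > 0))
  if (!is.finite(ratio[1]) || ratio[1] <= 0)
    stop("T0 value must be positive for baseline normalization")
  y <- if (mode == "divide") ratio / ratio[1] else ratio - ratio[1]
  sum(diff(timepoints_h) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Intervention ANOVA on normalized blood AUC values
#'
#' Computes the baseline-normalized AUC per subject-session and runs the
#' one-way within-subject ANOVA with intervention as the factor — the
#' manipulation check that the dietary interventions actually moved blood
#' tryptophan availability.
#'
#' @param blood Blood table (subject_id, intervention, t0, t1, t2, t3), one
#'   row per subject-session, all interventions present per subject.
#' @param mode Normalization mode, see [auc_normalized()].
#' @return List with `anova` (an [rm_anova_oneway()] result) and `auc`
#'   (subject_id, intervention, auc).
#' @export
intervention_auc_anova <- function(blood, mode = "divide") {
  stopifnot(all(c("subject_id", "intervention", "t0", "t1", "t2", "t3") %in%
                  names(blood)))
  auc <- vapply(seq_len(nrow(blood)), function(i)
    auc_normalized(as.numeric(blood[i, c("t0", "t1", "t2", "t3")]),
                   mode = mode), numeric(1))
  tab <- data.frame(subject_id = blood$subject_id,
                    intervention = blood$intervention, auc = auc,
                    stringsAsFactors = FALSE)
  wide <- stats::reshape(tab, idvar = "subject_id", timevar = "intervention",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  if (anyNA(mat)) stop("every subject needs all interventions' blood series")
  colnames(mat) <- sub("^auc\\.", "", colnames(mat))
  list(anova = rm_anova_oneway(mat), auc = tab)
}
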