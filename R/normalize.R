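#' Control reference statistics for z-scoring
#'
#' Per-feature mean and standard deviation of the control (HC) group, the
#' reference against which patient maps are standardised. The sample
#' (n - 1) SD is the default estimator; the population variant is available
#' because the convention is not universal.
#'
#' @param hc_matrix numeric matrix, control subjects x features.
#' @param sd_type `"sample"` (n - 1, default) or `"population"` (n).
#' @param degenerate_tol features with SD below this are flagged degenerate
#'   and excluded by [vertex_zscores()].
#' @return list of class `"reference_stats"`: `mean`, `sd`, `n_hc`,
#'   `degenerate` (logical per feature), `sd_type`.
#' @export
fit_reference <- function(hc_matrix, sd_type = c("sample", "population"),
                          degenerate_tol = 1e-8) {
  sd_type <- match.arg(sd_type)
  hc_matrix <- as.matrix(hc_matrix)
  n <- nrow(hc_matrix)
  if (n < 2L) stop("insufficient reference: need >= 2 control subjects")
  mu <- colMeans(hc_matrix)
  ss <- colSums(sweep(hc_matrix, 2L, mu)^2)
  sdv <- sqrt(ss / (if (sd_type == "sample") n - 1L else n))
  degenerate <- sdv < degenerate_tol
  if (any(degenerate))
    message(sum(degenerate), " degenerate feature(s) flagged (SD < ",
            degenerate_tol, ")")
  structure(list(mean = mu, sd = sdv, n_hc = n, degenerate = degenerate,
                 sd_type = sd_type),
            class = "reference_stats")
}

#' Vertex-wise z-scores against the control reference
#'
#' \eqn{z = (x - \bar{x}_{HC}) / \sigma_{HC}} per feature. Degenerate
#' features (control SD below tolerance) are dropped from the output so the
#' result is finite everywhere.
#'
#' @param ads_matrix numeric matrix, subjects x features, feature dimension
#'   matching the reference.
#' @param ref a [fit_reference()] result.
#' @param modality optional tag (`"tau"` or `"thickness"`) carried along as
#'   an attribute.
#' @return subjects x kept-features z-score matrix of class
#'   `"zscore_matrix"`; attribute `dropped` lists excluded feature indices.
#' @export
vertex_zscores <- function(ads_matrix, ref, modality = NULL) {
  stopifnot(inherits(ref, "reference_stats"))
  ads_matrix <- as.matrix(ads_matrix)
  if (ncol(ads_matrix) != length(ref$mean))
    stop("shape error: ", ncol(ads_matrix), " features vs reference ",
         length(ref$mean))
  keep <- !ref$degenerate
  z <- sweep(ads_matrix[, keep, drop = FALSE], 2L, ref$mean[keep])
  z <- sweep(z, 2L, ref$sd[keep], "/")
  structure(z, class = c("zscore_matrix", "matrix", "array"),
            modality = modality, dropped = which(!keep))
}

#' Parcel-wise means of vertex values
#'
#' Unweighted mean of member vertices per parcel, for every subject.
#'
#' @param values numeric matrix, subjects x vertices.
#' @param parcel factor or character vector of length `ncol(values)` mapping
#'   each vertex to a parcel; `"unassigned"` vertices are ignored. A
#'   `data.frame` with a `parcel` column (as produced by the synthetic
#'   generator) is also accepted.
#' @return subjects x parcels matrix, columns in parcel-level order. Parcels
#'   with zero vertices yield `NA` with a warning.
#' @export
parcel_means <- function(values, parcel) {
  values <- as.matrix(values)
  if (is.data.frame(parcel)) parcel <- parcel$parcel
  if (!is.factor(parcel)) parcel <- factor(parcel, levels = unique(parcel))
  if (length(parcel) != ncol(values))
    stop("parcel lookup length must equal number of vertices")
  keep <- !is.na(parcel) & parcel != "unassigned"
  counts <- table(parcel[keep])
  sums <- t(rowsum(t(values[, keep, drop = FALSE]),
                   droplevels(parcel[keep]), reorder = FALSE))
  out <- matrix(NA_real_, nrow(values), nlevels(parcel),
                dimnames = list(rownames(values), levels(parcel)))
  present <- colnames(sums)
  out[, present] <- sweep(sums, 2L, as.numeric(counts[present]), "/")
  empty <- setdiff(levels(parcel), c(present, "unassigned"))
  if (length(empty))
    warning("parcel(s) with zero vertices: ", paste(empty, collapse = ", "))
  out[, setdiff(levels(parcel), "unassigned"), drop = FALSE]
}

# Composite regions defining tau-PET positivity.
meta_roi_regions <- c("entorhinal", "amygdala", "fusiform",
                      "inferiortemporal", "middletemporal")

#' Temporal meta-ROI SUVr
#'
#' Unweighted mean of the five-region composite (entorhinal, amygdala,
#' fusiform, inferior and middle temporal) used for tau positivity.
#' Laterality handling is the caller's: pass bilateral averages for the
#' conventional reading.
#'
#' @param roi_values named numeric vector containing at least the five
#'   meta-ROI regions.
#' @return scalar SUVr.
#' @export
meta_roi_suvr <- function(roi_values) {
  missing_r <- setdiff(meta_roi_regions, names(roi_values))
  if (length(missing_r))
    stop("missing meta-ROI region(s): ", paste(missing_r, collapse = ", "))
  mean(roi_values[meta_roi_regions])
}

# Positivity cut-offs and centiloid calibrations (fixed constants).
biomarker_thresholds <- list(csf_ratio_cut = 0.075, av45_cut = 1.11,
                             fbb_cut = 1.08, tau_metaroi_cut = 1.37)
tracer_calibration <- list(AV45 = c(slope = 196.9, intercept = -196.03),
                           FBB = c(slope = 159.08, intercept = -151.65))

#' Amyloid positivity from CSF and/or amyloid-PET
#'
#' CSF takes precedence when available: a CSF A-beta 42/40 ratio strictly
#' below 0.075 is positive (lower ratio = more amyloid, the standard
#' convention; the direction of the published cut-off is not stated).
#' Otherwise tracer-specific SUVr strictly above the cut (AV45 1.11,
#' FBB 1.08) is positive. Boundary values are negative.
#'
#' @param csf_ratio CSF A-beta 42/40 ratio, or `NA`.
#' @param suvr global amyloid-PET SUVr, or `NA`.
#' @param tracer `"AV45"` or `"FBB"` (required with `suvr`).
#' @return `"positive"` or `"negative"` (vectorised).
#' @export
classify_amyloid <- function(csf_ratio = NA, suvr = NA, tracer = NA) {
  n <- max(length(csf_ratio), length(suvr), length(tracer))
  csf_ratio <- rep_len(csf_ratio, n)
  suvr <- rep_len(suvr, n)
  tracer <- rep_len(tracer, n)
  vapply(seq_len(n), function(i) {
    if (!is.na(csf_ratio[i]))
      return(if (csf_ratio[i] < biomarker_thresholds$csf_ratio_cut)
        "positive" else "negative")
    if (is.na(suvr[i]))
      stop("missing biomarker: need csf_ratio or suvr")
    cut <- switch(as.character(tracer[i]),
                  AV45 = biomarker_thresholds$av45_cut,
                  FBB = biomarker_thresholds$fbb_cut,
                  stop("unknown tracer: ", tracer[i]))
    if (suvr[i] > cut) "positive" else "negative"
  }, character(1L))
}

#' Tau positivity from the temporal meta-ROI
#'
#' Strictly above 1.37 SUVr is positive; the boundary is negative.
#'
#' @param meta_suvr meta-ROI SUVr value(s).
#' @return `"positive"` or `"negative"` (vectorised).
#' @export
classify_tau <- function(meta_suvr) {
  if (any(!is.finite(meta_suvr))) stop("meta_suvr must be finite")
  ifelse(meta_suvr > biomarker_thresholds$tau_metaroi_cut,
         "positive", "negative")
}

#' Cohort inclusion filter
#'
#' Applies the two stated exclusion rules — amyloid-positive cognitively
#' unimpaired subjects, and amyloid-negative tau-positive subjects
#' (suspected non-AD pathology) — plus the implicit third: amyloid-negative
#' impaired subjects belong to neither the control nor the patient group.
#' Retained subjects are assigned `group` HC (unimpaired) or ADS
#' (amyloid-positive MCI/ADD).
#'
#' @param metadata data.frame with columns `subject_id`, `diagnosis`
#'   (`"CN"`/`"HC"`/`"CU"` = unimpaired, `"MCI"`, `"ADD"`),
#'   `amyloid_status` and `tau_status` (`"positive"`/`"negative"`).
#' @return list: `included` (metadata rows retained, with `group`),
#'   `excluded` (data.frame `subject_id`, `rule`).
#' @export
filter_cohort <- function(metadata) {
  need <- c("subject_id", "diagnosis", "amyloid_status", "tau_status")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(metadata) == 0L)
    return(list(included = cbind(metadata, group = character(0)),
                excluded = data.frame(subject_id = character(0),
                                      rule = character(0))))
  unimpaired <- metadata$diagnosis %in% c("CN", "HC", "CU")
  abeta_pos <- metadata$amyloid_status == "positive"
  tau_pos <- metadata$tau_status == "positive"
  rule <- rep(NA_character_, nrow(metadata))
  rule[abeta_pos & unimpaired] <- "abeta_positive_unimpaired"
  rule[!abeta_pos & tau_pos] <- "suspected_non_ad_pathology"
  rule[!abeta_pos & !tau_pos & !unimpaired] <- "abeta_negative_impaired"
  keep <- is.na(rule)
  included <- metadata[keep, , drop = FALSE]
  included$group <- ifelse(unimpaired[keep], "HC", "ADS")
  list(included = included,
       excluded = data.frame(subject_id = metadata$subject_id[!keep],
                             rule = rule[!keep], stringsAsFactors = FALSE))
}

#' Centiloid transform of amyloid-PET SUVr
#'
#' Linear tracer-specific rescaling onto the common centiloid scale:
#' AV45 196.9 x SUVr - 196.03; FBB 159.08 x SUVr - 151.65.
#'
#' @param suvr SUVr value(s).
#' @param tracer `"AV45"` or `"FBB"`.
#' @return centiloid value(s).
#' @export
centiloid <- function(suvr, tracer) {
  cal <- tracer_calibration[[as.character(tracer[1L])]]
  if (is.null(cal)) stop("unknown tracer: ", tracer)
  cal[["slope"]] * suvr + cal[["intercept"]]
}

#' Cortex-to-hippocampus volume ratio
#'
#' Distinguishes hippocampal-sparing (high ratio) from limbic-predominant
#' (low ratio) atrophy. Default is cortical / hippocampal, consistent with
#' the "CTV:HV" label and the direction of the published group differences;
#' `invert = TRUE` returns hippocampal / cortical.
#'
#' @param cortical_volume total cortical volume (> 0).
#' @param hippocampal_volume bilateral hippocampal volume (> 0).
#' @param invert return the reciprocal orientation.
#' @return ratio value(s).
#' @export
ctv_hv <- function(cortical_volume, hippocampal_volume, invert = FALSE) {
  if (any(cortical_volume <= 0) || any(hippocampal_volume <= 0))
    stop("volumes must be positive")
  if (invert) hippocampal_volume / cortical_volume
  else cortical_volume / hippocampal_volume
}
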