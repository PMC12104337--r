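#' Skewness-reducing clinical score transforms
#'
#' `log10` for MMSE and square root for CDR-SoB, the transforms used before
#' modelling longitudinal clinical trajectories. MMSE of 0 is undefined
#' under the log transform and raises an error rather than silently
#' offsetting.
#'
#' @param score numeric value(s).
#' @param kind `"mmse"` or `"cdr_sob"`.
#' @return transformed value(s).
#' @export
transform_scores <- function(score, kind = c("mmse", "cdr_sob")) {
  kind <- match.arg(kind)
  if (kind == "mmse") {
    if (any(score <= 0)) stop("MMSE must be > 0 for the log10 transform")
    log10(score)
  } else {
    if (any(score < 0)) stop("CDR-SoB must be >= 0")
    sqrt(score)
  }
}

#' Per-subject annual change rates for regional measures
#'
#' Estimates each subject's annual slope for every ROI column of a visit
#' table, either by a linear mixed model per ROI (random intercept and slope
#' per subject, optional fixed covariates; subject slopes are BLUPs, fixed +
#' random) or by transparent per-subject ordinary least squares. Subjects
#' with fewer than 2 visits are excluded and reported.
#'
#' @param visits data.frame with `subject_id`, `time_years` and one column
#'   per ROI measure.
#' @param roi_cols character vector of ROI column names (default: every
#'   column except `subject_id`, `visit`, `time_years`).
#' @param covariates optional data.frame (one row per subject, with
#'   `subject_id`) of fixed-effect adjusters for the mixed model, e.g. age,
#'   sex, APOE.
#' @param model `"per_subject_ols"` (default) or `"mixed"` (lme4).
#' @return list of class `"slope_table"`: `slopes` (subjects x ROI matrix,
#'   units/yr), `model`, `excluded` (single-visit subject ids).
#' @export
subject_slopes <- function(visits, roi_cols = NULL, covariates = NULL,
                           model = c("per_subject_ols", "mixed")) {
  model <- match.arg(model)
  if (is.null(roi_cols))
    roi_cols <- setdiff(names(visits), c("subject_id", "visit", "time_years"))
  if (!all(c("subject_id", "time_years") %in% names(visits)))
    stop("visits needs subject_id and time_years columns")
  nv <- table(visits$subject_id)
  excluded <- names(nv)[nv < 2L]
  if (length(excluded) == length(nv))
    stop("no subject has >= 2 visits")
  keep <- !(visits$subject_id %in% excluded)
  v <- visits[keep, , drop = FALSE]
  subjects <- unique(v$subject_id)
  slopes <- matrix(NA_real_, length(subjects), length(roi_cols),
                   dimnames = list(subjects, roi_cols))
  if (model == "per_subject_ols") {
    sid <- factor(v$subject_id, levels = subjects)
    tbar <- tapply(v$time_years, sid, mean)
    tc <- v$time_years - tbar[sid]
    denom <- tapply(tc^2, sid, sum)
    for (rc in roi_cols) {
      num <- tapply(tc * v[[rc]], sid, sum)
      slopes[, rc] <- num / denom
    }
  } else {
    dat <- v
    cov_terms <- ""
    if (!is.null(covariates)) {
      dat <- merge(dat, covariates, by = "subject_id", sort = FALSE)
      cov_terms <- paste0(" + ",
                          paste(setdiff(names(covariates), "subject_id"),
                                collapse = " + "))
    }
    for (rc in roi_cols) {
      fml <- stats::as.formula(paste0(
        "`", rc, "` ~ time_years", cov_terms,
        " + (1 + time_years | subject_id)"))
      fit <- suppressWarnings(suppressMessages(
        lme4::lmer(fml, data = dat,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular =
                                                 lme4::.makeCC("ignore", 1e-4)))))
      fx <- lme4::fixef(fit)[["time_years"]]
      re <- lme4::ranef(fit)$subject_id
      slopes[rownames(re), rc] <- fx + re[["time_years"]]
    }
  }
  structure(list(slopes = slopes, model = model, excluded = excluded),
            class = "slope_table")
}

#' Standardise patient slopes against control slopes
#'
#' Per ROI, z = (slope - mean of HC slopes) / SD of HC slopes. ROIs whose
#' control slope SD is (near) zero are flagged and excluded.
#'
#' @param ads_slopes,hc_slopes `slope_table`s over the same ROI set.
#' @param degenerate_tol SD tolerance below which an ROI is dropped.
#' @return list of class `"change_z_table"`: `z` (patients x kept ROIs),
#'   `dropped` (excluded ROI names).
#' @export
slope_zscores <- function(ads_slopes, hc_slopes, degenerate_tol = 1e-10) {
  A <- ads_slopes$slopes; H <- hc_slopes$slopes
  shared <- intersect(colnames(A), colnames(H))
  if (length(shared) == 0L) stop("slope tables share no ROI")
  A <- A[, shared, drop = FALSE]; H <- H[, shared, drop = FALSE]
  mu <- colMeans(H); sdv <- apply(H, 2L, stats::sd)
  drop_roi <- sdv < degenerate_tol
  if (any(drop_roi))
    warning("ROI(s) with degenerate HC slope SD dropped: ",
            paste(shared[drop_roi], collapse = ", "))
  keep <- !drop_roi
  z <- sweep(sweep(A[, keep, drop = FALSE], 2L, mu[keep]), 2L,
             sdv[keep], "/")
  structure(list(z = z, dropped = shared[drop_roi]),
            class = "change_z_table")
}

# Kruskal-Wallis H with tie correction; returns statistic, df, p.
kruskal_stat <- function(x, g) {
  g <- factor(g)
  n <- length(x)
  r <- rank(x)
  rs <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  H <- 12 / (n * (n + 1)) * sum(rs^2 / ns) - 3 * (n + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) H <- H / corr
  df <- nlevels(g) - 1L
  list(statistic = H, df = df,
       p_value = stats::pchisq(H, df, lower.tail = FALSE))
}

# Wilcoxon rank-sum p via normal approximation with tie correction
# (two-sided); used for pairwise post-hoc tests.
ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(c(x, y))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  zstat <- (W - mu) / sqrt(sigma2)
  2 * stats::pnorm(-abs(zstat))
}

#' Compare annual change-rate z-scores among clusters
#'
#' Per ROI, a non-parametric Kruskal-Wallis test across clusters; overall
#' p-values are Benjamini-Hochberg adjusted over the ROI family (34
#' cortical regions in the hemisphere-collapsed atlas). Within ROIs passing
#' the FDR threshold, pairwise rank-sum tests are Bonferroni-corrected over
#' the pairs within that ROI.
#'
#' @param change_z a [slope_zscores()] result, or a patients x ROI matrix.
#' @param partition cluster labels over the patients (>= 2 clusters with
#'   >= 2 subjects each).
#' @param alpha FDR threshold selecting ROIs for post-hoc tests.
#' @return list of class `"slope_comparison"`: `table` (data.frame roi,
#'   statistic, df, p, p_fdr), `pairwise` (named list per significant ROI of
#'   Bonferroni-adjusted pairwise p matrices), `alpha`.
#' @export
compare_slopes <- function(change_z, partition, alpha = 0.05) {
  Z <- if (inherits(change_z, "change_z_table")) change_z$z else
    as.matrix(change_z)
  f <- factor(partition)
  if (nlevels(f) < 2L) stop("need >= 2 clusters")
  if (any(table(f) < 2L)) stop("every cluster needs >= 2 subjects")
  if (length(partition) != nrow(Z))
    stop("partition must cover all patients")
  res <- lapply(colnames(Z), function(rc) {
    kw <- kruskal_stat(Z[, rc], f)
    data.frame(roi = rc, statistic = kw$statistic, df = kw$df,
               p = kw$p_value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  tab$p_fdr <- stats::p.adjust(tab$p, method = "BH")
  sig <- tab$roi[tab$p_fdr < alpha]
  pairwise <- list()
  labs <- levels(f)
  npair <- choose(length(labs), 2)
  for (rc in sig) {
    M <- matrix(NA_real_, length(labs), length(labs),
                dimnames = list(labs, labs))
    for (i in seq_along(labs)) for (j in seq_along(labs)) if (i < j) {
      p <- ranksum_p(Z[f == labs[i], rc], Z[f == labs[j], rc])
      M[i, j] <- M[j, i] <- min(1, p * npair)
    }
    pairwise[[rc]] <- M
  }
  structure(list(table = tab, pairwise = pairwise, alpha = alpha),
            class = "slope_comparison")
}
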