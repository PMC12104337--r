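# Desikan-Killiany cortical region names (34 per hemisphere).
dk_regions <- c(
  "bankssts", "caudalanteriorcingulate", "caudalmiddlefrontal", "cuneus",
  "entorhinal", "fusiform", "inferiorparietal", "inferiortemporal",
  "isthmuscingulate", "lateraloccipital", "lateralorbitofrontal", "lingual",
  "medialorbitofrontal", "middletemporal", "parahippocampal", "paracentral",
  "parsopercularis", "parsorbitalis", "parstriangularis", "pericalcarine",
  "postcentral", "posteriorcingulate", "precentral", "precuneus",
  "rostralanteriorcingulate", "rostralmiddlefrontal", "superiorfrontal",
  "superiorparietal", "superiortemporal", "supramarginal", "frontalpole",
  "temporalpole", "transversetemporal", "insula")

#' Specification of a synthetic two-modality cohort
#'
#' Describes the world the analysis assumes: a control group and a patient
#' group measured on a shared vertex grid in two modalities (tau-PET-like
#' SUVr and cortical-thickness-like values), with four planted spatial
#' abnormality patterns per modality, optional cross-modal label
#' discordance, covariates without effect (so adjustment code is testable
#' against a known null), and longitudinal visits with cluster-specific
#' annual slopes.
#'
#' Defaults mirror the reference cohort: 154 controls, 166 patients split
#' 57/53/36/20 across clusters, ~2,000 vertices total (1,000 per
#' hemisphere), 34 parcels per hemisphere, a 3-SD mean abnormality shift at
#' pattern vertices with unit vertex noise, and 3 visits spaced so the
#' median within-subject follow-up is ~1.85 years.
#'
#' @param n_hc number of control subjects.
#' @param n_ads number of patient subjects.
#' @param cluster_sizes integer vector of 4 cluster sizes summing to
#'   `n_ads`.
#' @param n_vertices vertices per hemisphere.
#' @param n_parcels parcels per hemisphere (at most 34).
#' @param pattern_overlap target pairwise Jaccard overlap between pattern
#'   core masks, in \[0, 1\].
#' @param effect_size mean abnormality shift, in control-SD units, at a
#'   pattern's core vertices (added for tau, subtracted for thickness).
#' @param noise_sd vertex noise standard deviation.
#' @param crossmodal_discordance probability that a subject's atrophy
#'   cluster label differs from its tau label.
#' @param independent_patterns if `TRUE` the thickness modality gets its own
#'   independently drawn pattern geometry instead of sharing the tau one.
#' @param n_visits visits per subject (including baseline).
#' @param visit_spacing_years nominal spacing between visits; each subject's
#'   actual spacing is this times a Uniform(0.5, 1.5) draw.
#' @param slope_by_cluster per-cluster annual change applied to a pattern's
#'   core parcels (raw units/yr; with `noise_sd = 1` this is the z/yr
#'   scale). Thickness-modality volumes decline at the same rate.
#' @param visit_noise_sd measurement noise added to each visit's ROI values.
#' @param seed integer; same spec + seed gives an identical dataset.
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_hc = 154L, n_ads = 166L,
                        cluster_sizes = c(57L, 53L, 36L, 20L),
                        n_vertices = 1000L, n_parcels = 34L,
                        pattern_overlap = 0, effect_size = 3,
                        noise_sd = 1, crossmodal_discordance = 0,
                        independent_patterns = FALSE,
                        n_visits = 3L, visit_spacing_years = 0.925,
                        slope_by_cluster = c(0.30, 0.25, 0.20, 0.15),
                        visit_noise_sd = 0.05, seed = 1L) {
  spec <- list(n_hc = as.integer(n_hc), n_ads = as.integer(n_ads),
               cluster_sizes = as.integer(cluster_sizes),
               n_vertices = as.integer(n_vertices),
               n_parcels = as.integer(n_parcels),
               pattern_overlap = pattern_overlap,
               effect_size = effect_size, noise_sd = noise_sd,
               crossmodal_discordance = crossmodal_discordance,
               independent_patterns = isTRUE(independent_patterns),
               n_visits = as.integer(n_visits),
               visit_spacing_years = visit_spacing_years,
               slope_by_cluster = as.numeric(slope_by_cluster),
               visit_noise_sd = visit_noise_sd, seed = as.integer(seed))
  validate_cohort_spec(spec)
  structure(spec, class = "cohort_spec")
}

validate_cohort_spec <- function(spec) {
  with(spec, {
    if (n_hc < 1L || n_ads < 1L || n_vertices < 1L || n_parcels < 1L ||
        n_visits < 1L)
      stop("invalid spec: all counts must be > 0")
    if (length(cluster_sizes) != 4L || any(cluster_sizes < 1L))
      stop("invalid spec: cluster_sizes must be 4 positive counts")
    if (sum(cluster_sizes) != n_ads)
      stop("invalid spec: cluster_sizes must sum to n_ads")
    if (pattern_overlap < 0 || pattern_overlap > 1 ||
        crossmodal_discordance < 0 || crossmodal_discordance > 1)
      stop("invalid spec: probabilities must be in [0, 1]")
    if (n_parcels > 34L)
      stop("invalid spec: at most 34 parcels per hemisphere")
    if (visit_spacing_years <= 0)
      stop("invalid spec: visit_spacing_years must be positive")
    if (noise_sd < 0 || visit_noise_sd < 0)
      stop("invalid spec: noise SDs must be non-negative")
    if (length(slope_by_cluster) != 4L)
      stop("invalid spec: slope_by_cluster must have 4 entries")
  })
  invisible(spec)
}

#' Planted spatial abnormality patterns
#'
#' Builds `k` binary vertex masks as random contiguous index blocks: the
#' vertex ring is split into `k` equal blocks at a random rotation, and each
#' mask is extended into its neighbour until the requested pairwise Jaccard
#' overlap is reached. Geometry is deliberately schematic — nothing
#' downstream uses spatial layout beyond the parcel lookup.
#'
#' @param k number of patterns (>= 1).
#' @param n_vertices total vertex count (>= k).
#' @param pattern_overlap target pairwise Jaccard overlap in \[0, 1\].
#' @param seed integer seed for the rotation.
#' @return k x n_vertices 0/1 matrix; each row covers >= 5% of vertices and
#'   pairwise Jaccard overlaps are at most `pattern_overlap + 0.05`.
#' @export
build_patterns <- function(k, n_vertices, pattern_overlap = 0, seed = 1L) {
  k <- as.integer(k); n_vertices <- as.integer(n_vertices)
  if (k < 1L) stop("invalid spec: k must be >= 1")
  if (k > n_vertices) stop("invalid spec: k exceeds n_vertices")
  if (k > 20L) stop("invalid spec: k > 20 cannot guarantee 5% coverage")
  if (pattern_overlap < 0 || pattern_overlap > 1)
    stop("invalid spec: pattern_overlap must be in [0, 1]")
  masks <- matrix(0L, k, n_vertices)
  if (k == 1L) {
    masks[1L, ] <- 1L
    return(masks)
  }
  withr_seed(seed, {
    rot <- sample.int(n_vertices, 1L) - 1L
  })
  bounds <- floor(seq(0L, n_vertices, length.out = k + 1L))
  sizes <- diff(bounds)
  # extension into the next block sized so Jaccard e / (2s - e) hits target
  for (i in seq_len(k)) {
    s <- sizes[i]
    e <- round(pattern_overlap * 2 * s / (1 + pattern_overlap))
    idx <- (bounds[i] + seq_len(s + e) - 1L) %% n_vertices + 1L
    idx <- ((idx + rot - 1L) %% n_vertices) + 1L
    masks[i, idx] <- 1L
  }
  masks
}

# Evaluate expr with a private RNG state seeded from `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Amplitude field for one pattern: linear taper with mean exactly 1 over the
# core mask, plus a small pattern-specific per-parcel background off the
# core. The background is what couples the two modalities' cluster profiles
# beyond the core when patterns are shared (see the methods vignette).
pattern_field <- function(mask, parcel_id, seed) {
  v <- which(mask == 1L)
  w <- numeric(length(mask))
  m <- length(v)
  w[v] <- if (m == 1L) 1 else 0.5 + (seq_len(m) - 1L) / (m - 1L)  # mean 1
  withr_seed(seed, {
    bg <- runif(max(parcel_id), 0, 0.3)
  })
  off <- which(mask == 0L)
  w[off] <- bg[parcel_id[off]]
  w
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Control subjects get pure-noise maps around modality baselines (tau 1.2
#' SUVr-like, thickness 2.5 mm-like). Patient subjects additionally receive
#' their cluster's amplitude field times `effect_size` — added for tau,
#' subtracted for thickness. Atrophy labels equal tau labels except with
#' probability `crossmodal_discordance`, in which case a different label is
#' drawn uniformly.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `"synthetic_cohort"` with elements `metadata`
#'   (one row per subject), `tau` and `thickness` (subjects x vertices
#'   matrices, rows aligned to metadata), `parcels` (vertex -> parcel
#'   lookup), `truth` (per-patient tau and atrophy cluster labels),
#'   `patterns` (list of 0/1 mask matrices per modality) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  V <- 2L * spec$n_vertices
  n <- spec$n_hc + spec$n_ads
  parcels <- parcel_lookup(spec$n_vertices, spec$n_parcels)
  pid <- parcels$parcel_id

  masks_tau <- build_patterns(4L, V, spec$pattern_overlap, seed = spec$seed)
  masks_thk <- if (spec$independent_patterns)
    build_patterns(4L, V, spec$pattern_overlap, seed = spec$seed + 7919L)
  else masks_tau
  fields_tau <- t(vapply(1:4, function(j)
    pattern_field(masks_tau[j, ], pid, seed = spec$seed * 17L + j), numeric(V)))
  fields_thk <- if (spec$independent_patterns)
    t(vapply(1:4, function(j)
      pattern_field(masks_thk[j, ], pid, seed = spec$seed * 29L + 100L + j),
      numeric(V)))
  else fields_tau

  withr_seed(spec$seed + 1L, {
    ids <- sprintf("sub%04d", seq_len(n))
    group <- rep(c("HC", "ADS"), c(spec$n_hc, spec$n_ads))
    tau_lab <- rep(1:4, spec$cluster_sizes)
    tau_lab <- sample(tau_lab)                       # shuffle row order
    atr_lab <- tau_lab
    flip <- runif(spec$n_ads) < spec$crossmodal_discordance
    atr_lab[flip] <- vapply(tau_lab[flip], function(l)
      sample(setdiff(1:4, l), 1L), integer(1L))

    age <- round(ifelse(group == "HC", rnorm(n, 74, 6), rnorm(n, 75, 8)))
    sex <- ifelse(runif(n) < ifelse(group == "HC", 0.55, 0.46), "F", "M")
    apoe4 <- as.integer(runif(n) < ifelse(group == "HC", 0.20, 0.65))
    education <- pmax(8L, round(rnorm(n, ifelse(group == "HC", 17, 16), 2)))
    site <- sample(paste0("site", 1:3), n, replace = TRUE)
    diagnosis <- ifelse(group == "HC", "CN",
                        ifelse(runif(n) < 0.67, "MCI", "ADD"))
    csf <- ifelse(group == "HC",
                  0.075 + abs(rnorm(n, 0.02, 0.010)),
                  pmax(0.01, 0.0745 - abs(rnorm(n, 0.02, 0.008))))
    tracer <- sample(c("AV45", "FBB"), n, replace = TRUE, prob = c(0.7, 0.3))
    cut <- ifelse(tracer == "AV45", 1.11, 1.08)
    amyloid_suvr <- ifelse(group == "HC",
                           cut - abs(rnorm(n, 0.08, 0.04)),
                           cut + abs(rnorm(n, 0.25, 0.10)))

    tau <- matrix(rnorm(n * V, 0, spec$noise_sd), n, V) + 1.2
    thk <- matrix(rnorm(n * V, 0, spec$noise_sd), n, V) + 2.5
    is_ads <- group == "ADS"
    tau[is_ads, ] <- tau[is_ads, ] +
      spec$effect_size * fields_tau[tau_lab, , drop = FALSE]
    thk[is_ads, ] <- thk[is_ads, ] -
      spec$effect_size * fields_thk[atr_lab, , drop = FALSE]
  })
  rownames(tau) <- rownames(thk) <- ids
  colnames(tau) <- colnames(thk) <- parcels$vertex_name

  metadata <- data.frame(
    subject_id = ids, group = group, diagnosis = diagnosis, age = age,
    sex = sex, apoe4 = apoe4, education = education, site = site,
    csf_ab42_40 = round(csf, 4), tracer = tracer,
    amyloid_suvr = round(amyloid_suvr, 4), stringsAsFactors = FALSE)
  truth <- data.frame(subject_id = ids[group == "ADS"],
                      tau_cluster = tau_lab, atrophy_cluster = atr_lab,
                      stringsAsFactors = FALSE)
  structure(list(metadata = metadata, tau = tau, thickness = thk,
                 parcels = parcels, truth = truth,
                 patterns = list(tau = masks_tau, thickness = masks_thk),
                 spec = spec),
            class = "synthetic_cohort")
}

# Vertex -> parcel lookup over two hemispheres of contiguous equal chunks.
parcel_lookup <- function(n_vertices, n_parcels) {
  hemi <- rep(c("lh", "rh"), each = n_vertices)
  within <- rep(seq_len(n_vertices), 2L)
  pc <- pmin(ceiling(within / (n_vertices / n_parcels)), n_parcels)
  region <- dk_regions[pc]
  data.frame(vertex = seq_len(2L * n_vertices),
             vertex_name = paste0(hemi, "_v", within),
             hemi = hemi,
             parcel = paste0(hemi, "_", region),
             region = region,
             parcel_id = pc + (hemi == "rh") * n_parcels,
             stringsAsFactors = FALSE)
}

#' Longitudinal visit table for a synthetic cohort
#'
#' Expands each subject's baseline regional values into `n_visits` visits.
#' ROI trajectories are baseline + slope x time + noise; the slope is the
#' subject's cluster entry of `slope_by_cluster` on that cluster's core
#' parcels (positive for tau SUVr, negative for cortical volume) and zero
#' elsewhere and for controls. Per-subject visit spacing is jittered by a
#' Uniform(0.5, 1.5) factor so the follow-up duration varies around the
#' target median.
#'
#' @param cohort a `"synthetic_cohort"` from [generate_cohort()].
#' @param spec the [cohort_spec()] used to generate it (defaults to the one
#'   stored in the cohort).
#' @return data.frame with `subject_id`, `visit`, `time_years`, then one
#'   `tau_<parcel>` and one `vol_<parcel>` column per parcel.
#' @export
generate_visits <- function(cohort, spec = cohort$spec) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  validate_cohort_spec(spec)
  fac <- factor(cohort$parcels$parcel, levels = unique(cohort$parcels$parcel))
  tau0 <- parcel_means(cohort$tau, fac)
  # thickness maps stand in for regional cortical volume at baseline
  vol0 <- parcel_means(cohort$thickness, fac)
  parc <- levels(fac)
  n <- nrow(cohort$metadata)

  # core parcels per pattern: >= 50% of the parcel's vertices in the mask
  core <- function(masks) {
    t(vapply(1:4, function(j) {
      frac <- tapply(masks[j, ], fac, mean)
      as.numeric(frac >= 0.5)
    }, numeric(length(parc))))
  }
  core_tau <- core(cohort$patterns$tau)
  core_vol <- core(cohort$patterns$thickness)

  lab_tau <- lab_atr <- rep(NA_integer_, n)
  idx <- match(cohort$truth$subject_id, cohort$metadata$subject_id)
  lab_tau[idx] <- cohort$truth$tau_cluster
  lab_atr[idx] <- cohort$truth$atrophy_cluster

  withr_seed(spec$seed + 2L, {
    jitter <- runif(n, 0.5, 1.5)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      times <- (seq_len(spec$n_visits) - 1L) * spec$visit_spacing_years *
        jitter[i]
      s_tau <- if (is.na(lab_tau[i])) numeric(length(parc)) else
        spec$slope_by_cluster[lab_tau[i]] * core_tau[lab_tau[i], ]
      s_vol <- if (is.na(lab_atr[i])) numeric(length(parc)) else
        -spec$slope_by_cluster[lab_atr[i]] * core_vol[lab_atr[i], ]
      tau_v <- outer(times, s_tau) + rep(tau0[i, ], each = length(times)) +
        matrix(rnorm(length(times) * length(parc), 0, spec$visit_noise_sd),
               length(times))
      vol_v <- outer(times, s_vol) + rep(vol0[i, ], each = length(times)) +
        matrix(rnorm(length(times) * length(parc), 0, spec$visit_noise_sd),
               length(times))
      colnames(tau_v) <- paste0("tau_", parc)
      colnames(vol_v) <- paste0("vol_", parc)
      out[[i]] <- data.frame(subject_id = cohort$metadata$subject_id[i],
                             visit = seq_len(spec$n_visits),
                             time_years = times, tau_v, vol_v,
                             stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' @exportS3Method base::print
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort: ", x$spec$n_hc, " HC + ", x$spec$n_ads, " ADS, ",
      ncol(x$tau), " vertices, clusters ",
      paste(x$spec$cluster_sizes, collapse = "/"), "\n", sep = "")
  invisible(x)
}
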