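test_that("reference statistics match the declared estimator", {
  expect_error(fit_reference(matrix(1, 1, 3)), "insufficient reference")

  m <- rbind(c(2, 1), c(2, 3))
  expect_message(ref <- fit_reference(m), "degenerate")
  expect_equal(unname(ref$mean), c(2, 2))
  expect_equal(unname(ref$sd), c(0, sd(c(1, 3))))
  expect_identical(unname(ref$degenerate), c(TRUE, FALSE))

  set.seed(1)
  big <- matrix(rnorm(10000), ncol = 1)
  r <- fit_reference(big)
  expect_lt(abs(r$mean), 0.03)
  expect_gt(r$sd, 0.97); expect_lt(r$sd, 1.03)

  rp <- fit_reference(m, sd_type = "population")
  expect_equal(unname(rp$sd[2]), 1)
})

test_that("z-scoring is exact and idempotent on the reference itself", {
  ref <- fit_reference(rbind(c(2, 5), c(2, 3), c(2, 4)))
  z <- vertex_zscores(matrix(c(9, 3.0), 1), ref)
  # degenerate first column dropped; z = (3 - 4)/1
  expect_identical(attr(z, "dropped"), 1L)
  expect_equal(as.vector(z), -1)

  expect_error(vertex_zscores(matrix(1, 2, 5), ref), "shape error")

  set.seed(2)
  hc <- matrix(rnorm(40 * 30), 40, 30)
  zz <- vertex_zscores(hc, fit_reference(hc))
  expect_lt(max(abs(colMeans(zz))), 1e-10)
  expect_equal(unname(apply(zz, 2, sd)), rep(1, 30), tolerance = 1e-12)

  sub <- matrix(c(3.0), 1, 1)
  r1 <- fit_reference(rbind(1.5, 2.5))  # mean 2, sd ~0.707
  expect_equal(as.vector(vertex_zscores(matrix(3), r1)),
               (3 - 2) / sd(c(1.5, 2.5)))
})

test_that("parcel means equal brute-force per-parcel summation", {
  expect_equal(unname(parcel_means(matrix(1:4, 1), rep("a", 4))[1, 1]), 2.5)
  # single-vertex parcels: identity
  v <- matrix(rnorm(6), 2, 3)
  expect_equal(unname(parcel_means(v, c("p1", "p2", "p3"))), unname(v))

  set.seed(3)
  X <- matrix(rnorm(5 * 100), 5, 100)
  pc <- sample(paste0("r", 1:7), 100, replace = TRUE)
  got <- parcel_means(X, pc)
  for (p in unique(pc))
    expect_equal(unname(got[, p]), unname(rowMeans(X[, pc == p, drop = FALSE])),
                 tolerance = 1e-12)
  # unassigned vertices ignored; empty parcels warned and NA
  pc2 <- factor(c("a", "unassigned", "a"), levels = c("a", "b", "unassigned"))
  expect_warning(out <- parcel_means(matrix(c(1, 5, 3), 1), pc2),
                 "zero vertices")
  expect_equal(unname(out[1, "a"]), 2)
  expect_true(is.na(out[1, "b"]))
})

test_that("meta-ROI SUVr is the unweighted five-region mean", {
  v <- c(entorhinal = 1.37, amygdala = 1.37, fusiform = 1.37,
         inferiortemporal = 1.37, middletemporal = 1.37)
  expect_equal(meta_roi_suvr(v), 1.37)
  expect_equal(meta_roi_suvr(setNames(rep(1, 5), names(v))), 1)
  expect_equal(meta_roi_suvr(setNames(c(1.2, 1.3, 1.4, 1.5, 1.6), names(v))),
               1.4)
  expect_error(meta_roi_suvr(v[-2]), "amygdala")
})

test_that("positivity classifiers apply the published strict cut-offs", {
  expect_identical(classify_amyloid(csf_ratio = 0.05), "positive")
  expect_identical(classify_amyloid(csf_ratio = 0.075), "negative")
  expect_identical(classify_amyloid(suvr = 1.20, tracer = "AV45"), "positive")
  expect_identical(classify_amyloid(suvr = 1.11, tracer = "AV45"), "negative")
  expect_identical(classify_amyloid(suvr = 1.08, tracer = "FBB"), "negative")
  expect_identical(classify_amyloid(suvr = 1.081, tracer = "FBB"), "positive")
  # CSF precedence over a discordant PET value
  expect_identical(classify_amyloid(csf_ratio = 0.09, suvr = 2, tracer = "AV45"),
                   "negative")
  expect_error(classify_amyloid(), "missing biomarker")
  expect_error(classify_amyloid(suvr = 1.2, tracer = "PIB"), "unknown tracer")

  expect_identical(classify_tau(c(1.40, 1.37, 1.00)),
                   c("positive", "negative", "negative"))
  expect_error(classify_tau(NaN), "finite")

  # monotone step behaviour
  grid <- seq(1.0, 1.8, by = 0.01)
  status <- classify_tau(grid) == "positive"
  expect_true(all(diff(status) >= 0))
})

test_that("cohort filter applies the stated exclusion rules", {
  toy <- data.frame(
    subject_id = paste0("s", 1:5),
    diagnosis = c("CN", "CN", "MCI", "MCI", "ADD"),
    amyloid_status = c("negative", "positive", "positive", "negative",
                       "positive"),
    tau_status = c("negative", "negative", "positive", "positive",
                   "positive"),
    stringsAsFactors = FALSE)
  res <- filter_cohort(toy)
  expect_identical(res$included$subject_id, c("s1", "s3", "s5"))
  expect_identical(res$included$group, c("HC", "ADS", "ADS"))
  expect_identical(res$excluded$rule,
                   c("abeta_positive_unimpaired", "suspected_non_ad_pathology"))

  empty <- filter_cohort(toy[0, ])
  expect_identical(nrow(empty$included), 0L)
  expect_identical(nrow(empty$excluded), 0L)

  expect_error(filter_cohort(toy[, -3]), "schema error")
})

test_that("centiloid transform matches the tracer calibrations exactly", {
  expect_equal(centiloid(1.0, "AV45"), 0.87, tolerance = 1e-9)
  expect_equal(centiloid(1.0, "FBB"), 7.43, tolerance = 1e-9)
  expect_lt(abs(centiloid(1.11, "AV45") - 22.53), 0.01)
  expect_error(centiloid(1, "PIB"), "unknown tracer")
  # affine: differences scale with the slope
  a <- runif(10, 0.8, 2); b <- runif(10, 0.8, 2)
  expect_equal(centiloid(a, "AV45") - centiloid(b, "AV45"), 196.9 * (a - b),
               tolerance = 1e-12)
  expect_equal(centiloid(a, "FBB") - centiloid(b, "FBB"), 159.08 * (a - b),
               tolerance = 1e-12)
})

test_that("cortex-to-hippocampus ratio handles both orientations", {
  expect_equal(ctv_hv(400, 8), 50)
  expect_equal(ctv_hv(10, 10), 1)
  expect_equal(ctv_hv(400, 8, invert = TRUE), 0.02)
  expect_error(ctv_hv(400, 0), "positive")
  expect_error(ctv_hv(-1, 8), "positive")
})
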