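test_that("clinical score transforms match their definitions", {
  expect_equal(transform_scores(10, "mmse"), 1)
  expect_equal(transform_scores(9, "cdr_sob"), 3)
  expect_equal(transform_scores(0, "cdr_sob"), 0)
  expect_error(transform_scores(0, "mmse"), "> 0")
  expect_error(transform_scores(-1, "cdr_sob"), ">= 0")
})

test_that("subject slopes recover noiseless trajectories exactly", {
  visits <- do.call(rbind, lapply(1:6, function(i)
    data.frame(subject_id = paste0("s", i), visit = 1:3,
               time_years = c(0, 1, 2),
               roi_a = 1 + 0.5 * c(0, 1, 2),
               roi_b = 2 - 0.25 * c(0, 1, 2))))
  ols <- subject_slopes(visits, model = "per_subject_ols")
  expect_equal(unname(ols$slopes[, "roi_a"]), rep(0.5, 6), tolerance = 1e-9)
  expect_equal(unname(ols$slopes[, "roi_b"]), rep(-0.25, 6), tolerance = 1e-9)

  mix <- subject_slopes(visits, model = "mixed")
  expect_equal(unname(mix$slopes[, "roi_a"]), rep(0.5, 6), tolerance = 1e-6)

  # single-visit subjects are excluded and reported
  v2 <- rbind(visits, data.frame(subject_id = "solo", visit = 1,
                                 time_years = 0, roi_a = 1, roi_b = 2))
  out <- subject_slopes(v2)
  expect_identical(out$excluded, "solo")
  expect_false("solo" %in% rownames(out$slopes))
  expect_error(subject_slopes(v2[v2$subject_id == "solo", ]), ">= 2 visits")
})

test_that("per-subject OLS equals the closed-form slope oracle", {
  set.seed(13)
  rows <- lapply(1:15, function(i) {
    t <- sort(runif(4, 0, 3))
    data.frame(subject_id = sprintf("s%02d", i), visit = 1:4,
               time_years = t, roi_x = rnorm(1) + rnorm(1) * t + rnorm(4, 0, 0.3))
  })
  visits <- do.call(rbind, rows)
  got <- subject_slopes(visits)$slopes[, "roi_x"]
  for (i in 1:15) {
    d <- rows[[i]]
    beta <- unname(coef(lm(roi_x ~ time_years, data = d))[2])
    expect_equal(unname(got[sprintf("s%02d", i)]), beta, tolerance = 1e-9)
  }
})

test_that("mixed-model slopes recover simulated population parameters", {
  set.seed(14)
  est <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    n <- 100
    slopes <- rnorm(n, 0.4, 0.2)
    visits <- do.call(rbind, lapply(1:n, function(i)
      data.frame(subject_id = sprintf("s%03d", i), visit = 1:3,
                 time_years = c(0, 1, 2),
                 roi = 1 + slopes[i] * c(0, 1, 2) + rnorm(3, 0, 0.3))))
    mean(subject_slopes(visits, model = "mixed")$slopes[, "roi"])
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.4) / 0.4, 0.05)
})

test_that("slope z-scores standardise against the control distribution", {
  hc <- structure(list(slopes = matrix(c(0, 0.2), 2, 1,
                                       dimnames = list(c("h1", "h2"), "roi")),
                       model = "per_subject_ols", excluded = character(0)),
                  class = "slope_table")
  ads <- structure(list(slopes = matrix(0.3, 1, 1,
                                        dimnames = list("a1", "roi")),
                        model = "per_subject_ols", excluded = character(0)),
                   class = "slope_table")
  cz <- slope_zscores(ads, hc)
  expect_equal(unname(cz$z[1, 1]), (0.3 - 0.1) / sd(c(0, 0.2)))

  # ADS slope equal to the HC mean maps to zero
  ads0 <- ads; ads0$slopes[1, 1] <- 0.1
  expect_equal(unname(slope_zscores(ads0, hc)$z[1, 1]), 0)

  # HC standardised against itself: mean ~0, sd ~1 per ROI
  set.seed(15)
  H <- structure(list(slopes = matrix(rnorm(40 * 3), 40, 3,
                                      dimnames = list(paste0("h", 1:40),
                                                      paste0("r", 1:3)))),
                 class = "slope_table")
  self <- slope_zscores(H, H)
  expect_lt(max(abs(colMeans(self$z))), 1e-10)
  expect_equal(unname(apply(self$z, 2, sd)), rep(1, 3), tolerance = 1e-12)

  # degenerate HC SD: ROI dropped with a warning
  hc2 <- hc; hc2$slopes <- cbind(hc2$slopes, flat = c(1, 1))
  ads2 <- ads; ads2$slopes <- cbind(ads2$slopes, flat = 1.5)
  expect_warning(cz2 <- slope_zscores(ads2, hc2), "degenerate")
  expect_identical(cz2$dropped, "flat")
})

test_that("kruskal-wallis machinery matches stats::kruskal.test", {
  set.seed(16)
  for (rep_i in 1:10) {
    x <- round(rnorm(45), 2)  # rounding forces ties
    g <- sample(3, 45, replace = TRUE)
    ours <- corticlust:::kruskal_stat(x, g)
    ref <- kruskal.test(x, factor(g))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("cluster slope comparison flags shifted ROIs with direction", {
  set.seed(17)
  n_per <- 25
  part <- rep(1:3, each = n_per)
  Z <- matrix(rnorm(3 * n_per * 10), ncol = 10,
              dimnames = list(NULL, paste0("roi", 1:10)))
  Z[part == 2, 1:2] <- Z[part == 2, 1:2] + 2
  res <- compare_slopes(Z, part)
  expect_true(all(res$table$p_fdr[1:2] < 0.05))
  # BH is monotone in the raw p ordering
  ord <- order(res$table$p)
  expect_true(all(diff(res$table$p_fdr[ord]) >= -1e-12))
  # shifted cluster significantly differs from both others in roi1
  pw <- res$pairwise[["roi1"]]
  expect_lt(pw["2", "1"], 0.05)
  expect_lt(pw["2", "3"], 0.05)
  expect_gt(median(Z[part == 2, 1]), median(Z[part == 1, 1]))

  expect_error(compare_slopes(Z, rep(1, nrow(Z))), ">= 2 clusters")
  expect_error(compare_slopes(Z, c(1, rep(2, nrow(Z) - 1))), ">= 2 subjects")
})
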