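test_that("the median split assigns the median subject to the below group", {
  res <- medianSplit(data.frame(iq = c(90, 102, 102, 110)))
  expect_equal(res$median, 102)
  expect_equal(as.character(res$labels), c("below", "below", "below", "above"))
  # boundary rule: 102 goes below, 103 above
  res2 <- medianSplit(data.frame(iq = c(75, 102, 103, 138)))
  expect_equal(as.character(res2$labels)[2:3], c("below", "above"))
  expect_error(medianSplit(data.frame(iq = rep(100, 4))), "degenerate")
  expect_error(medianSplit(data.frame(iq = c(90, NA))), "present")
})

test_that("odd-sized samples split around the single median subject", {
  set.seed(41)
  iq <- sample(71:140, 31)
  res <- medianSplit(data.frame(iq = iq))
  expect_equal(sum(res$labels == "below"), sum(iq <= median(iq)))
  expect_equal(sum(res$labels == "above"), sum(iq > median(iq)))
})

test_that("only upper-tail IQ outliers are excluded by the 1.5 IQR rule", {
  ph <- data.frame(id = 1:42, iq = c(80:120, 200))
  out <- excludeIqOutliers(ph)
  expect_equal(out$excluded, 42)
  expect_equal(nrow(out$phenotypes), 41)
  # a low outlier is kept: the rule is one-sided
  ph2 <- data.frame(id = 1:42, iq = c(80:120, 30))
  expect_length(excludeIqOutliers(ph2)$excluded, 0)
  # no outliers: identity
  ph3 <- data.frame(id = 1:10, iq = 95:104)
  expect_identical(excludeIqOutliers(ph3)$phenotypes, ph3)
})

test_that("outlier exclusion on a generated cohort matches a direct recount", {
  ph <- generateCohort(simConfig(nPerCell = 100, seed = 42))
  out <- excludeIqOutliers(ph)
  qs <- quantile(ph$iq, c(0.25, 0.75), names = FALSE)
  thr <- qs[2] + 1.5 * (qs[2] - qs[1])
  expect_setequal(out$excluded, ph$id[ph$iq > thr])
  expect_equal(out$threshold, thr)
})

test_that("noise-free coefficients are recovered exactly by the GLM", {
  set.seed(43)
  ph <- generateCohort(simConfig(nPerCell = 25, seed = 43))
  ph$y <- 2 * ph$age + 5 * (ph$diagnosis == "adhd") + 1
  fit <- fitVolumetricGlm(ph, "y", terms = c("group", "age"))
  expect_equal(unname(fit$coefficients), c(1, 5, 2), tolerance = 1e-10)
  expect_equal(unname(diff(fit$adjustedMeans)), 5, tolerance = 1e-10)
})

test_that("the log transform requires a strictly positive outcome", {
  ph <- generateCohort(simConfig(nPerCell = 5, seed = 44))
  ph$y <- c(0, seq_len(nrow(ph) - 1))
  expect_error(fitVolumetricGlm(ph, "y", terms = c("group", "age"),
                                transform = "log"), "positive")
})

test_that("aliased designs raise a collinearity error", {
  ph <- generateCohort(simConfig(nPerCell = 10, seed = 45))
  ph$slice_dummy <- as.integer(ph$diagnosis == "adhd")  # aliases the group
  ph$y <- rnorm(nrow(ph))
  expect_error(fitVolumetricGlm(ph, "y", terms = c("group", "slice_dummy")),
               "rank-deficient")
})

test_that("interactions require their main effects", {
  ph <- generateCohort(simConfig(nPerCell = 5, seed = 46))
  ph$y <- rnorm(nrow(ph))
  expect_error(fitVolumetricGlm(ph, "y", terms = c("group", "group:age")),
               "main effects")
})

test_that("adding group-by-age never increases the fitted RSS", {
  cfg <- simConfig(nPerCell = 40, seed = 47)
  ph <- generateCohort(cfg)
  vol <- generateVolumetrics(ph, cfg)
  d <- merge(ph, vol, by = "id", sort = FALSE)
  base <- fitVolumetricGlm(d, "total_brain")
  inter <- fitVolumetricGlm(d, "total_brain",
                            terms = c("group", "age", "sex", "hand",
                                      "slice_dummy", "group:age"))
  expect_lte(sum(resid(inter$model)^2), sum(resid(base$model)^2) + 1e-8)
})

test_that("group-by-age p-values are uniform when slopes match", {
  set.seed(48)
  ps <- replicate(300, {
    n <- 60
    d <- data.frame(diagnosis = factor(rep(c("control", "adhd"), each = n / 2),
                                       levels = c("control", "adhd")),
                    age = runif(n, 6, 15))
    d$y <- 3 * d$age + rnorm(n)
    fitVolumetricGlm(d, "y",
                     terms = c("group", "age", "group:age"))$pValues[["diagnosis:age"]]
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("the dimensional IQ model reports main and interaction p-values", {
  cfg <- simConfig(nPerCell = 300, seed = 49)
  ph <- generateCohort(cfg)
  vol <- generateVolumetrics(ph, cfg)
  d <- excludeIqOutliers(merge(ph, vol, by = "id", sort = FALSE))$phenotypes
  res <- dimensionalIqModel(d, "cerebral_gray_matter")
  # control slope present, case slope absent: the interaction shows
  expect_lt(res$pIqGroup, 0.05)
  expect_lt(res$pIq, 0.05)
  d$iq <- 100
  expect_error(dimensionalIqModel(d, "cerebral_gray_matter"), "constant")
})

test_that("the IQ interaction p-value is uniform when slopes coincide", {
  set.seed(50)
  ps <- replicate(300, {
    n <- 80
    d <- data.frame(diagnosis = factor(rep(c("control", "adhd"), each = n / 2),
                                       levels = c("control", "adhd")),
                    age = runif(n, 6, 15),
                    sex = factor(sample(c("male", "female"), n, TRUE)),
                    hand = factor(sample(c("R", "L"), n, TRUE)),
                    slice_dummy = rbinom(n, 1, 0.3),
                    iq = rnorm(n, 103, 13))
    d$y <- 700 + 0.5 * d$iq + rnorm(n, 0, 10)
    dimensionalIqModel(d, "y")$pIqGroup
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("within-group correlations recover their generating values", {
  cfg <- simConfig(nPerCell = 2500, seed = 51)
  ph <- generateCohort(cfg)
  vol <- generateVolumetrics(ph, cfg)
  d <- merge(ph, vol, by = "id", sort = FALSE)
  res <- groupCorrelation(d, "cerebral_gray_matter")
  rC <- res$r[res$group == "control"]
  expect_lt(abs(rC - 0.31), 0.04)
  expect_lt(res$p[res$group == "control"], 0.001)
  # exact collinearity
  d2 <- data.frame(diagnosis = factor(rep("control", 10)), iq = 1:10,
                   m = 2 * (1:10))
  resc <- groupCorrelation(d2, "m")
  expect_equal(resc$r, 1)
  expect_lt(resc$p, 1e-10)
  d2$m <- 5
  expect_error(groupCorrelation(d2, "m"), "constant")
})

test_that("percent reduction does its arithmetic and is scale invariant", {
  expect_equal(percentReduction(100, 100), 0)
  expect_equal(percentReduction(748.6, 704.3), 5.9177, tolerance = 1e-4)
  expect_equal(percentReduction(100, 97), 3)
  expect_equal(percentReduction(7.486, 7.043),
               percentReduction(748.6, 704.3), tolerance = 1e-12)
  expect_error(percentReduction(0, 1), "positive")
})

test_that("the gray matter proxy has correct units and magnitude", {
  expect_equal(corticalGmProxy(1, 10), 1)       # 1 mm x 10 cm^2 = 1 ml
  proxy <- corticalGmProxy(3.344, 1906.5)
  expect_equal(proxy, 637.5, tolerance = 1e-3)
  expect_gte(proxy / 735.2, 0.80)
  expect_error(corticalGmProxy(-1, 10), "positive")
})

test_that("corrected medication duration follows its defining formula", {
  expect_equal(correctedMedicationDuration(24, 120), 0.40)
  expect_equal(correctedMedicationDuration(0, 100), 0)
  expect_true(is.na(correctedMedicationDuration(NA, 100)))
  expect_error(correctedMedicationDuration(10, 60), "60")
})

test_that("log-scale adjusted means back-transform near the generator median", {
  cfg <- simConfig(nPerCell = 1500, seed = 52)
  ph <- generateCohort(cfg)
  vol <- generateVolumetrics(ph, cfg)
  d <- merge(ph, vol, by = "id", sort = FALSE)
  fit <- fitVolumetricGlm(d, "lateral_ventricles", transform = "log")
  # moment-matched log-normal with m = 9.5, s ~ 5.5 has median ~ 8.2
  backCtrl <- fit$adjustedMeansResponse[["control"]]
  expect_lt(abs(backCtrl - 9.5 / sqrt(1 + (5.4 / 9.5)^2)), 0.6)
})

test_that("the summary table covers all measures with the expected pattern", {
  cfg <- simConfig(nPerCell = 150, seed = 53)
  ph <- generateCohort(cfg)
  vol <- generateVolumetrics(ph, cfg)
  d <- merge(ph, vol, by = "id", sort = FALSE)
  tab <- volumetricSummaryTable(d)
  expect_equal(nrow(tab), 13)
  expect_true(all(c("p_group_all", "p_group_below", "p_group_above",
                    "p_group_age", "p_iq", "p_iq_group") %in% names(tab)))
  expect_true(all(tab$p_group_all >= 0 & tab$p_group_all <= 1, na.rm = TRUE))
  gm <- tab[tab$measure == "cerebral_gray_matter", ]
  # the case deficit concentrates in the above-median cell: stronger raw
  # reduction there (directional pattern, not numeric equality)
  redAbove <- percentReduction(gm$control_above.mean, gm$adhd_above.mean)
  redBelow <- percentReduction(gm$control_below.mean, gm$adhd_below.mean)
  expect_gt(redAbove, redBelow)
  expect_lt(gm$p_group_all, 0.05)
})
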