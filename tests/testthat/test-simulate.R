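test_that("the cohort has four balanced diagnosis-by-IQ cells", {
  ph <- generateCohort(simConfig(nPerCell = 25, seed = 1))
  expect_equal(nrow(ph), 100)
  expect_equal(unname(c(table(ph$diagnosis, ph$sim_cell))), rep(25, 4))
  expect_false(anyDuplicated(ph$id) > 0)
  expect_true(all(ph$age >= 6 & ph$age < 15))
})

test_that("generation is bit-reproducible from the configuration seed", {
  cfg <- simConfig(nPerCell = 20, nVertices = 40, seed = 77)
  ce1 <- simulateCohort(cfg)
  ce2 <- simulateCohort(cfg)
  expect_identical(thickness(ce1), thickness(ce2))
  expect_identical(phenotypes(ce1), phenotypes(ce2))
  ce3 <- simulateCohort(simConfig(nPerCell = 20, nVertices = 40, seed = 78))
  expect_false(identical(thickness(ce1), thickness(ce3)))
})

test_that("IQ respects the floor and the median-split cell boundaries", {
  ph <- generateCohort(simConfig(nPerCell = 200, seed = 2))
  expect_true(all(ph$iq >= 70))
  expect_true(all(ph$iq[ph$sim_cell == "below"] <= 102))
  expect_true(all(ph$iq[ph$sim_cell == "above"] >= 103))
})

test_that("a zero-SD IQ cell collapses to its mean", {
  cells <- data.frame(cell = c("control_below", "control_above",
                               "adhd_below", "adhd_above"),
                      mean = 100, sd = 0, lower = 70, upper = Inf)
  ph <- generateCohort(simConfig(nPerCell = 5, iqCells = cells, seed = 3))
  expect_true(all(ph$iq == 100))
})

test_that("control IQ reproduces the target mean at moderate n", {
  ph <- generateCohort(simConfig(nPerCell = 50, seed = 11))
  expect_lt(abs(mean(ph$iq[ph$diagnosis == "control"]) - 106), 3)
})

test_that("unknown volumetric measure names are rejected", {
  tg <- defaultVolumetricTargets()
  tg$measure[1] <- "no_such_measure"
  expect_error(simConfig(volumetricTargets = tg), "unknown measure")
})

test_that("zero-SD volumetric targets are reproduced exactly", {
  tg <- defaultVolumetricTargets()
  tg$sd <- 0
  cfg <- simConfig(nPerCell = 5, volumetricTargets = tg, seed = 4)
  ph <- generateCohort(cfg)
  vol <- generateVolumetrics(ph, cfg)
  cb <- ph$diagnosis == "control" & ph$sim_cell == "below"
  target <- tg$mean[tg$measure == "total_brain" & tg$cell == "control_below"]
  expect_equal(vol$total_brain[cb], rep(target, sum(cb)))
})

test_that("targeted IQ correlations are recovered at large n", {
  cfg <- simConfig(nPerCell = 2500, seed = 5)
  ph <- generateCohort(cfg)
  vol <- generateVolumetrics(ph, cfg)
  d <- merge(ph, vol, by = "id", sort = FALSE)
  ctrl <- d[d$diagnosis == "control", ]
  adhd <- d[d$diagnosis == "adhd", ]
  expect_gt(cor(ctrl$iq, ctrl$cerebral_gray_matter), 0.27)
  expect_lt(cor(ctrl$iq, ctrl$cerebral_gray_matter), 0.35)
  expect_gt(cor(ctrl$iq, ctrl$cerebral_fa), 0.34)
  expect_lt(cor(ctrl$iq, ctrl$cerebral_fa), 0.42)
  expect_gt(cor(adhd$iq, adhd$mean_cortical_thickness), -0.29)
  expect_lt(cor(adhd$iq, adhd$mean_cortical_thickness), -0.21)
  # the case group carries no gray-matter or FA correlation with IQ
  expect_lt(abs(cor(adhd$iq, adhd$cerebral_gray_matter)), 0.1)
  expect_lt(abs(cor(adhd$iq, adhd$cerebral_fa)), 0.1)
})

test_that("zeroed correlation targets give a null everywhere", {
  cfg <- simConfig(nPerCell = 1500, seed = 6,
                   targetCorrelations = c(gm_iq_control = 0,
                                          fa_iq_control = 0,
                                          thickness_iq_adhd = 0))
  ph <- generateCohort(cfg)
  vol <- generateVolumetrics(ph, cfg)
  d <- merge(ph, vol, by = "id", sort = FALSE)
  for (g in c("control", "adhd")) {
    dg <- d[d$diagnosis == g, ]
    expect_lt(abs(cor(dg$iq, dg$cerebral_gray_matter)), 0.1)
    expect_lt(abs(cor(dg$iq, dg$cerebral_fa)), 0.1)
    expect_lt(abs(cor(dg$iq, dg$mean_cortical_thickness)), 0.1)
  }
})

test_that("cell means calibrate to their targets at n = 1000 per cell", {
  cfg <- simConfig(nPerCell = 1000, seed = 7)
  ph <- generateCohort(cfg)
  vol <- generateVolumetrics(ph, cfg)
  targets <- defaultVolumetricTargets()
  correlated <- c("cerebral_gray_matter", "cerebral_fa",
                  "mean_cortical_thickness")
  z <- c()
  for (ms in setdiff(unique(targets$measure), correlated)) {
    for (g in c("control", "adhd")) {
      for (cl in c("below", "above")) {
        tg <- targets[targets$measure == ms &
                      targets$cell == paste0(g, "_", cl), ]
        if (is.na(tg$mean))
          tg <- targets[targets$measure == ms &
                        targets$cell == paste0(g, "_all"), ]
        inCell <- ph$diagnosis == g & ph$sim_cell == cl
        z <- c(z, (mean(vol[[ms]][inCell]) - tg$mean) /
                   (tg$sd / sqrt(sum(inCell))))
      }
    }
  }
  # ~40 independent 2-SE checks: expect ~95% inside, allow binomial slack
  expect_gte(mean(abs(z) <= 2), 0.85)
  expect_true(all(abs(z) <= 4))
})

test_that("ventricle volumes are right-skewed", {
  cfg <- simConfig(nPerCell = 1000, seed = 8)
  ph <- generateCohort(cfg)
  vol <- generateVolumetrics(ph, cfg)
  x <- vol$lateral_ventricles
  expect_gt(mean(x), median(x))
  skew <- mean((x - mean(x))^3) / sd(x)^3
  expect_gt(skew, 0.5)
  expect_true(all(x > 0))
})

test_that("noise-free null maps coincide across cells at equal ages", {
  ages <- rep(seq(6.5, 13.5, length.out = 5), 4)
  ph <- data.frame(
    id = sprintf("S%02d", 1:20),
    diagnosis = factor(rep(c("control", "control", "adhd", "adhd"), each = 5),
                       levels = c("control", "adhd")),
    sim_cell = factor(rep(c("below", "above"), times = 2, each = 5),
                      levels = c("below", "above")),
    age = ages, iq = 100)
  mesh <- buildToyMesh(30, seed = 1)
  cfg <- simConfig(nPerCell = 5, nVertices = 30, seed = 9)
  mod <- trajectoryModel(noiseSd = 0, peakShift = 0, interceptOffset = 0)
  Y <- generateThicknessMaps(ph, mesh, mod, cfg)
  for (i in 1:5)
    expect_equal(unname(Y[i, ]), unname(Y[i + 5, ]))
  expect_equal(unname(Y[1:5, ]), unname(Y[11:15, ]))
})

test_that("the intercept offset lowers case-above maps by exactly its value", {
  ph <- data.frame(
    id = c("a", "b"),
    diagnosis = factor(c("control", "adhd"), levels = c("control", "adhd")),
    sim_cell = factor(c("above", "above"), levels = c("below", "above")),
    age = c(9, 9), iq = 110)
  mesh <- buildToyMesh(30, seed = 1)
  cfg <- simConfig(nPerCell = 5, nVertices = 30, seed = 10)
  mod <- trajectoryModel(noiseSd = 0, interceptOffset = 0.05)
  Y <- generateThicknessMaps(ph, mesh, mod, cfg)
  expect_equal(unname(Y[1, ] - Y[2, ]), rep(0.05, ncol(Y)))
})

test_that("the peak shift acts only at affected vertices for case-below", {
  ph <- data.frame(
    id = c("a", "b"),
    diagnosis = factor(c("control", "adhd"), levels = c("control", "adhd")),
    sim_cell = factor(c("below", "below"), levels = c("below", "above")),
    age = c(12, 12), iq = 90)
  mesh <- buildToyMesh(30, seed = 1)
  cfg <- simConfig(nPerCell = 5, nVertices = 30, seed = 10)
  aff <- clusterAroundVertex(mesh, 2, 6)
  mod <- trajectoryModel(noiseSd = 0, peakShift = 1.5,
                         affectedVertices = aff)
  Y <- generateThicknessMaps(ph, mesh, mod, cfg)
  delta <- Y[2, ] - Y[1, ]
  expect_true(all(abs(delta[-aff]) < 1e-12))
  expect_true(all(abs(delta[aff]) > 1e-6))
})

test_that("a nonzero peak shift with no affected vertices warns", {
  ph <- generateCohort(simConfig(nPerCell = 3, seed = 1))
  mesh <- buildToyMesh(12, seed = 1)
  cfg <- simConfig(nPerCell = 3, nVertices = 12, seed = 1)
  expect_warning(
    generateThicknessMaps(ph, mesh, trajectoryModel(peakShift = 1),
                          cfg),
    "no vertices")
})

test_that("default maps have a grand mean thickness near the printed value", {
  ce <- simulateCohort(simConfig(nPerCell = 50, nVertices = 60, seed = 12))
  gm <- mean(thickness(ce))
  expect_gt(gm, 3.24)
  expect_lt(gm, 3.44)
})

test_that("the experiment container aligns mesh, maps and phenotypes", {
  ce <- simulateCohort(simConfig(nPerCell = 5, nVertices = 30, seed = 13))
  expect_s4_class(ce, "CorticalExperiment")
  expect_equal(dim(thickness(ce)), c(60, 20))
  expect_equal(nVertices(surfaceMesh(ce)), 60)
  expect_identical(colnames(ce), phenotypes(ce)$id)
  expect_true(validObject(ce))
  expect_error(
    CorticalExperiment(thickness(ce)[1:10, ], phenotypes(ce),
                       surfaceMesh(ce)))
})

test_that("configuration invariants are enforced", {
  expect_error(simConfig(nPerCell = 2), "nPerCell")
  expect_error(simConfig(ageRange = c(15, 6)), "ageRange")
  expect_error(simConfig(nVertices = 4), "nVertices")
  expect_error(simConfig(targetCorrelations = c(gm_iq_control = 1.2,
                                                fa_iq_control = 0.38,
                                                thickness_iq_adhd = -0.25)),
               "correlations")
})
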