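#' Volumetric generator targets
#'
#' Per-measure, per-cell mean/SD targets of the volumetric generator:
#' diagnostic-group values overall and within the below/above-median-IQ
#' subgroups. Measures are in ml except mean cortical thickness (mm),
#' cortical surface area (cm^2) and cerebral FA (dimensionless); FA has no
#' IQ-subgroup targets (it was measured in a smaller subsample not split by
#' IQ) and falls back to the group value.
#'
#' @return data.frame with columns `measure`, `cell`, `mean`, `sd`. Cells
#'   are `control_all`, `control_below`, `control_above`, `adhd_all`,
#'   `adhd_below`, `adhd_above`.
#' @export
defaultVolumetricTargets <- function() {
  m <- function(measure, ...) {
    v <- c(...)
    data.frame(measure = measure,
               cell = c("control_all", "control_below", "control_above",
                        "adhd_all", "adhd_below", "adhd_above"),
               mean = v[c(1, 3, 5, 7, 9, 11)],
               sd = v[c(2, 4, 6, 8, 10, 12)])
  }
  rbind(
    m("intracranial_volume", 1545.7, 133.5, 1508.6, 127.1, 1570.2, 133.0,
      1491.6, 122.6, 1478.1, 123.1, 1508.4, 121.4),
    m("total_brain", 1393.4, 117.2, 1366.4, 111.6, 1411.1, 118.3,
      1345.9, 113.5, 1335.4, 114.8, 1360.7, 111.3),
    m("total_cerebrum", 1242.5, 108.8, 1217.1, 99.7, 1259.2, 112.0,
      1198.1, 106.1, 1189.1, 108.3, 1210.8, 102.8),
    m("total_cerebellum", 157.1, 15.7, 152.0, 14.0, 160.5, 15.8,
      151.0, 12.5, 148.4, 12.7, 154.7, 11.3),
    m("lateral_ventricles", 9.5, 5.4, 9.9, 5.9, 9.2, 5.2,
      9.2, 5.7, 9.2, 5.5, 9.0, 6.0),
    m("third_ventricle", 0.56, 0.26, 0.55, 0.30, 0.56, 0.24,
      0.54, 0.29, 0.53, 0.26, 0.56, 0.35),
    m("cerebral_gray_matter", 735.2, 66.0, 714.8, 59.7, 748.6, 67.0,
      700.5, 62.7, 697.7, 62.5, 704.3, 63.5),
    m("cerebral_white_matter", 488.8, 57.0, 484.2, 55.8, 491.8, 58.0,
      480.4, 58.2, 474.9, 59.8, 487.8, 55.9),
    m("cerebellar_gray_matter", 109.5, 10.9, 106.3, 11.0, 111.5, 10.4,
      104.6, 9.5, 102.7, 9.4, 107.2, 9.2),
    m("cerebellar_white_matter", 46.9, 8.2, 45.3, 7.8, 47.9, 8.4,
      45.3, 7.4, 44.2, 6.6, 46.6, 8.3),
    m("mean_cortical_thickness", 3.344, 0.100, 3.338, 0.106, 3.348, 0.097,
      3.343, 0.109, 3.372, 0.102, 3.306, 0.109),
    m("cortical_surface_area", 1906.5, 155.5, 1876.3, 145.6, 1926.2, 159.9,
      1841.0, 158.7, 1823.3, 151.8, 1864.2, 166.5),
    m("cerebral_fa", 0.379, 0.023, NA, NA, NA, NA,
      0.374, 0.020, NA, NA, NA, NA)
  )
}

# measures drawn from a right-skewed (log-normal) law, moment-matched to
# the target mean/SD
.skewedMeasures <- c("lateral_ventricles", "third_ventricle")

# (measure, group) pairs generated with a targeted IQ correlation; these use
# the group-level ("all") target so the IQ-cell structure induces the
# printed subgroup means
.correlatedMeasures <- function(config) {
  r <- config@targetCorrelations
  data.frame(
    measure = c("cerebral_gray_matter", "cerebral_fa",
                "mean_cortical_thickness"),
    group = c("control", "control", "adhd"),
    r = c(r[["gm_iq_control"]], r[["fa_iq_control"]],
          r[["thickness_iq_adhd"]])
  )
}

.defaultIqCells <- function() {
  data.frame(
    cell = c("control_below", "control_above", "adhd_below", "adhd_above"),
    mean = c(93.3, 114.3, 90.7, 116.9),
    sd = c(7.0, 8.3, 7.7, 11.7),
    lower = c(70, 103, 70, 103),
    upper = c(102, Inf, 102, Inf)
  )
}

.defaultIqGroups <- function() {
  data.frame(group = c("control", "adhd"),
             mean = c(106.0, 101.6),
             sd = c(12.9, 16.0))
}

#' Construct a simulation configuration
#'
#' Builds a [SimConfig-class] with defaults calibrated to the demographic
#' and volumetric structure the analyses assume: four diagnosis-by-IQ cells
#' with ages uniform on `ageRange`; per-cell IQ normals truncated to the
#' median-split ranges (below: 70--102, above: 103 and up); volumetric
#' targets from [defaultVolumetricTargets()]; targeted IQ correlations of
#' .31 (control gray matter), .38 (control FA) and -.25 (case mean
#' thickness); demographic marginals shared across cells (14% female,
#' right/left/ambidextrous handedness .84/.13/.03, thin-slice dummy rate
#' .315); and a corrected medication-duration law with mean .39, SD .25 for
#' cases with a recorded history (83%).
#'
#' @param nPerCell subjects per cell (>= 3).
#' @param ageRange c(lower, upper) in years; ages drawn uniformly.
#' @param seed master integer seed.
#' @param nVertices vertices per hemisphere of the toy mesh (>= 12).
#' @param fwhm surface smoothing FWHM in mesh distance units; `NA` picks
#'   twice the mean edge length of the built mesh (the scale at which
#'   smoothing spans roughly two graph edges).
#' @param targetCorrelations named numeric overriding the defaults.
#' @param iqCells,iqGroups,volumetricTargets data.frames overriding the
#'   defaults (same columns).
#' @param sexFemaleProb,handProbs,sliceThinProb,medAvailability,medDuration
#'   demographic marginals.
#' @return A validated [SimConfig-class].
#' @examples
#' cfg <- simConfig(nPerCell = 25, seed = 7)
#' @export
simConfig <- function(nPerCell = 25L,
                      ageRange = c(6, 15),
                      seed = 1L,
                      nVertices = 150L,
                      fwhm = NA_real_,
                      targetCorrelations = c(gm_iq_control = 0.31,
                                             fa_iq_control = 0.38,
                                             thickness_iq_adhd = -0.25),
                      iqCells = .defaultIqCells(),
                      iqGroups = .defaultIqGroups(),
                      volumetricTargets = defaultVolumetricTargets(),
                      sexFemaleProb = 0.14,
                      handProbs = c(R = 0.84, L = 0.13, A = 0.03),
                      sliceThinProb = 0.315,
                      medAvailability = 0.83,
                      medDuration = c(mean = 0.39, sd = 0.25)) {
  known <- defaultVolumetricTargets()$measure
  if (!all(volumetricTargets$measure %in% known))
    stop("unknown measure in volumetric targets: ",
         paste(setdiff(volumetricTargets$measure, known), collapse = ", "))
  new("SimConfig",
      nPerCell = as.integer(nPerCell),
      ageRange = as.numeric(ageRange),
      iqCells = iqCells,
      iqGroups = iqGroups,
      volumetricTargets = volumetricTargets,
      targetCorrelations = targetCorrelations,
      sexFemaleProb = sexFemaleProb,
      handProbs = handProbs,
      sliceThinProb = sliceThinProb,
      medAvailability = medAvailability,
      medDuration = medDuration,
      nVertices = as.integer(nVertices),
      fwhm = as.numeric(fwhm),
      seed = as.integer(seed))
}

#' Construct a trajectory generative model
#'
#' Defaults describe a thickness-by-age curve peaking at 8.5 years with a
#' gentle post-peak decline -- the typical-development pattern in which
#' cortical thickness crests in middle childhood and thins through
#' adolescence -- calibrated so the grand mean thickness over ages 6--15 is
#' about 3.34 mm and so the age trajectory plus vertexwise residual noise
#' (SD 0.05 mm) jointly reproduce a between-subject SD of mean thickness
#' near 0.10 mm. The two
#' distortions default to zero (the global null); set `peakShift` and
#' `affectedVertices` for delayed maturation in cases below median IQ, and
#' `interceptOffset` for the uniform thinning in cases above median IQ.
#'
#' @param baseline,amplitude,peakAge,width,declineSlope curve parameters
#'   (mm, mm, years, years, mm/year).
#' @param peakShift years of delay at affected vertices (cases below median
#'   IQ only).
#' @param interceptOffset mm of uniform thinning (cases above median IQ).
#' @param noiseSd vertexwise residual SD (mm).
#' @param affectedVertices integer vertex ids carrying the peak shift.
#' @return A validated [TrajectoryModel-class].
#' @export
trajectoryModel <- function(baseline = 3.375, amplitude = 0.15,
                            peakAge = 8.5, width = 2,
                            declineSlope = 0.045,
                            peakShift = 0, interceptOffset = 0,
                            noiseSd = 0.05,
                            affectedVertices = integer(0)) {
  new("TrajectoryModel", baseline = baseline, amplitude = amplitude,
      peakAge = peakAge, width = width, declineSlope = declineSlope,
      peakShift = peakShift, interceptOffset = interceptOffset,
      noiseSd = noiseSd, affectedVertices = as.integer(affectedVertices))
}

#' Evaluate a trajectory curve
#'
#' The noise-free thickness-by-age curve of a [TrajectoryModel-class]:
#' `baseline + amplitude * exp(-(age - peak)^2 / (2 * width^2))
#'  - declineSlope * max(0, age - peak)`,
#' a single interior peak with a linear post-peak decline. `peakShift`
#' displaces the peak age; `interceptOffset` lowers the whole curve.
#'
#' @param model a [TrajectoryModel-class].
#' @param age numeric vector of ages (years).
#' @param peakShift,interceptOffset optional overrides applied on top of
#'   zero (the model's own slots are applied per cell by the generator, not
#'   here).
#' @return Numeric thickness values (mm).
#' @export
thicknessTrajectory <- function(model, age, peakShift = 0,
                                interceptOffset = 0) {
  peak <- model@peakAge + peakShift
  model@baseline +
    model@amplitude * exp(-(age - peak)^2 / (2 * model@width^2)) -
    model@declineSlope * pmax(0, age - peak) -
    interceptOffset
}

.truncNorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean < lower || mean > upper)
      stop("degenerate truncated normal: mean outside bounds")
    return(rep(mean, n))
  }
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2L * n, mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

#' Generate a synthetic phenotype table
#'
#' Draws four cells of `nPerCell` subjects (control/case crossed with
#' below/above median IQ). Ages are uniform on the configured range with
#' the same law in every cell; IQ comes from the cell's truncated normal
#' (never below 70, and respecting the median-split boundary); sex,
#' handedness and the slice-thickness dummy share one marginal law across
#' cells; corrected medication duration is drawn for cases with a recorded
#' history and converted to months of use.
#'
#' @param config a [SimConfig-class].
#' @return data.frame with columns `id`, `diagnosis` (factor
#'   control/adhd), `age`, `sex`, `hand`, `iq`, `slice_dummy`,
#'   `med_months`, plus the generation cell in `sim_cell`.
#' @examples
#' ph <- generateCohort(simConfig(nPerCell = 10, seed = 3))
#' table(ph$diagnosis, ph$sim_cell)
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  cells <- config@iqCells
  n <- config@nPerCell
  .withSeed(.stageSeed(config@seed, "cohort"), {
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      cell <- cells$cell[i]
      group <- sub("_(below|above)$", "", cell)
      data.frame(
        diagnosis = group,
        sim_cell = sub("^(control|adhd)_", "", cell),
        age = runif(n, config@ageRange[1L], config@ageRange[2L]),
        iq = .truncNorm(n, cells$mean[i], cells$sd[i],
                        lower = max(70, cells$lower[i]),
                        upper = cells$upper[i])
      )
    })
    ph <- do.call(rbind, rows)
    N <- nrow(ph)
    ph$id <- sprintf("S%04d", seq_len(N))
    ph$sex <- factor(ifelse(runif(N) < config@sexFemaleProb,
                            "female", "male"),
                     levels = c("male", "female"))
    ph$hand <- factor(sample(names(config@handProbs), N, replace = TRUE,
                             prob = config@handProbs),
                      levels = c("R", "L", "A"))
    ph$slice_dummy <- as.integer(runif(N) < config@sliceThinProb)
    ph$diagnosis <- factor(ph$diagnosis, levels = c("control", "adhd"))
    ph$sim_cell <- factor(ph$sim_cell, levels = c("below", "above"))
    ph$med_months <- NA_real_
    adhd <- which(ph$diagnosis == "adhd")
    hasMed <- adhd[runif(length(adhd)) < config@medAvailability]
    corrDur <- .truncNorm(length(hasMed), config@medDuration[["mean"]],
                          config@medDuration[["sd"]], lower = 0)
    ph$med_months[hasMed] <- corrDur * (ph$age[hasMed] * 12 - 60)
    ph[, c("id", "diagnosis", "age", "sex", "hand", "iq", "slice_dummy",
           "med_months", "sim_cell")]
  })
}

#' Generate a synthetic volumetric table
#'
#' One row per subject, one column per measure. Each measure is drawn so
#' that its cell mean/SD matches the configured targets in expectation.
#' Measures with a targeted IQ correlation (control gray matter and FA,
#' case mean thickness) are generated from the group-level target around a
#' regression on the subject's standardized IQ, so both the correlation and
#' the implied subgroup means are honoured; everything else uses the
#' per-cell target with independent noise. Ventricle volumes come from a
#' log-normal law moment-matched to the target mean/SD (they are
#' right-skewed, which is why the analysis log-transforms them).
#'
#' @param phenotypes a phenotype table from [generateCohort()].
#' @param config a [SimConfig-class].
#' @return data.frame with `id` plus one numeric column per measure.
#' @export
generateVolumetrics <- function(phenotypes, config) {
  stopifnot(is(config, "SimConfig"))
  if (!nrow(phenotypes)) stop("phenotype table is empty")
  if (!all(c("id", "diagnosis", "iq") %in% names(phenotypes)))
    stop("phenotypes must carry id, diagnosis and iq")
  targets <- config@volumetricTargets
  known <- defaultVolumetricTargets()$measure
  if (!all(targets$measure %in% known))
    stop("unknown measure in volumetric targets: ",
         paste(setdiff(targets$measure, known), collapse = ", "))

  cellOf <- .simCellLabels(phenotypes)
  group <- as.character(phenotypes$diagnosis)
  corr <- .correlatedMeasures(config)
  N <- nrow(phenotypes)

  .withSeed(.stageSeed(config@seed, "volumetrics"), {
    out <- data.frame(id = phenotypes$id)
    for (measure in unique(targets$measure)) {
      vals <- numeric(N)
      for (g in c("control", "adhd")) {
        inG <- which(group == g)
        if (!length(inG)) next
        ci <- which(corr$measure == measure & corr$group == g)
        if (length(ci)) {
          tg <- targets[targets$measure == measure &
                        targets$cell == paste0(g, "_all"), ]
          ig <- config@iqGroups[config@iqGroups$group == g, ]
          z <- (phenotypes$iq[inG] - ig$mean) / ig$sd
          r <- corr$r[ci]
          vals[inG] <- tg$mean +
            tg$sd * (r * z + sqrt(1 - r^2) * rnorm(length(inG)))
        } else {
          for (cl in c("below", "above")) {
            inCell <- inG[cellOf[inG] == cl]
            if (!length(inCell)) next
            tg <- targets[targets$measure == measure &
                          targets$cell == paste0(g, "_", cl), ]
            if (!nrow(tg) || is.na(tg$mean))
              tg <- targets[targets$measure == measure &
                            targets$cell == paste0(g, "_all"), ]
            vals[inCell] <- .drawMeasure(measure, length(inCell),
                                         tg$mean, tg$sd)
          }
        }
      }
      out[[measure]] <- vals
    }
    out
  })
}

# below/above labels: generation cell if present, otherwise a median split
.simCellLabels <- function(phenotypes) {
  if ("sim_cell" %in% names(phenotypes))
    as.character(phenotypes$sim_cell)
  else
    as.character(medianSplit(phenotypes)$labels)
}

.drawMeasure <- function(measure, n, mean, sd) {
  if (measure %in% .skewedMeasures && sd > 0) {
    sdlog2 <- log(1 + sd^2 / mean^2)
    rlnorm(n, meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
  } else {
    rnorm(n, mean, sd)
  }
}

#' Generate vertexwise thickness maps
#'
#' Each subject's map is the cell-specific trajectory curve evaluated at
#' their age -- peak-shifted at the model's affected vertices for cases
#' below median IQ, intercept-lowered everywhere for cases above median IQ
#' -- plus spatially smoothed Gaussian noise. The noise field is smoothed
#' on the mesh with the configured FWHM kernel and rescaled so the marginal
#' per-vertex SD stays at `noiseSd` (smoothing redistributes variance into
#' spatial correlation without shrinking it).
#'
#' @param phenotypes a phenotype table from [generateCohort()].
#' @param mesh a [SurfaceMesh-class].
#' @param model a [TrajectoryModel-class]; its `affectedVertices` must lie
#'   within the mesh.
#' @param config a [SimConfig-class] (supplies the FWHM and seed).
#' @param smoothOp optional precomputed [smoothingOperator()] for the mesh,
#'   useful when generating many replicate cohorts on one mesh.
#' @return numeric matrix, subjects x vertices, rownames from subject ids.
#' @export
generateThicknessMaps <- function(phenotypes, mesh, model, config,
                                  smoothOp = NULL) {
  stopifnot(is(mesh, "SurfaceMesh"), is(model, "TrajectoryModel"),
            is(config, "SimConfig"))
  nv <- nVertices(mesh)
  aff <- model@affectedVertices
  if (length(aff) && (min(aff) < 1L || max(aff) > nv))
    stop("affectedVertices outside the mesh")
  if (!length(aff) && model@peakShift != 0)
    warning("peakShift is nonzero but no vertices are affected")

  N <- nrow(phenotypes)
  cellOf <- .simCellLabels(phenotypes)
  group <- as.character(phenotypes$diagnosis)

  base <- thicknessTrajectory(model, phenotypes$age)
  shifted <- thicknessTrajectory(model, phenotypes$age,
                                 peakShift = model@peakShift)

  Y <- matrix(base, nrow = N, ncol = nv)
  delayed <- which(group == "adhd" & cellOf == "below")
  if (length(aff) && length(delayed))
    Y[delayed, aff] <- shifted[delayed]
  thinned <- which(group == "adhd" & cellOf == "above")
  if (length(thinned))
    Y[thinned, ] <- Y[thinned, , drop = FALSE] - model@interceptOffset

  if (model@noiseSd > 0) {
    K <- if (!is.null(smoothOp)) smoothOp
         else smoothingOperator(mesh, .resolveFwhm(config, mesh))
    stopifnot(nrow(K) == nv)
    scale <- 1 / sqrt(rowSums(K^2))   # restore per-vertex marginal SD
    E <- .withSeed(.stageSeed(config@seed, "thickness"),
                   matrix(rnorm(N * nv), nrow = N, ncol = nv))
    Y <- Y + model@noiseSd * (E %*% t(K)) *
      matrix(scale, nrow = N, ncol = nv, byrow = TRUE)
  }
  dimnames(Y) <- list(phenotypes$id, paste0("v", seq_len(nv)))
  Y
}

.resolveFwhm <- function(config, mesh) config@fwhm

#' Simulate a complete cortical thickness experiment
#'
#' Runs the full generator -- toy mesh, phenotype table, volumetric table,
#' thickness maps -- and assembles a [CorticalExperiment-class]. All stages
#' derive their randomness from the configuration seed by fixed offsets, so
#' the result is bit-reproducible.
#'
#' @param config a [SimConfig-class].
#' @param model a [TrajectoryModel-class] (default: the null model with no
#'   group effect on trajectories).
#' @return A [CorticalExperiment-class].
#' @examples
#' ce <- simulateCohort(simConfig(nPerCell = 5, nVertices = 30, seed = 2))
#' ce
#' @export
simulateCohort <- function(config, model = trajectoryModel()) {
  mesh <- buildToyMesh(config@nVertices, seed = .stageSeed(config@seed, "mesh"))
  ph <- generateCohort(config)
  vol <- generateVolumetrics(ph, config)
  Y <- generateThicknessMaps(ph, mesh, model, config)
  CorticalExperiment(thickness = t(Y), phenotypes = ph, mesh = mesh,
                     volumetrics = vol, config = config, model = model)
}

#' Construct a CorticalExperiment
#'
#' @param thickness vertices x subjects matrix.
#' @param phenotypes per-subject data.frame (one row per column of
#'   `thickness`, matched by position; `id` becomes the column name).
#' @param mesh the [SurfaceMesh-class] of the rows.
#' @param volumetrics optional per-subject volumetric data.frame joined
#'   into `colData` by `id`.
#' @param config,model optional generator settings stored in `metadata()`.
#' @return A [CorticalExperiment-class].
#' @export
CorticalExperiment <- function(thickness, phenotypes, mesh,
                               volumetrics = NULL, config = NULL,
                               model = NULL) {
  stopifnot(is(mesh, "SurfaceMesh"),
            nrow(thickness) == nVertices(mesh),
            ncol(thickness) == nrow(phenotypes))
  cd <- S4Vectors::DataFrame(phenotypes)
  if (!is.null(volumetrics)) {
    stopifnot(identical(as.character(volumetrics$id),
                        as.character(phenotypes$id)))
    cd <- cbind(cd, S4Vectors::DataFrame(volumetrics[,
                  setdiff(names(volumetrics), "id"), drop = FALSE]))
  }
  rownames(cd) <- phenotypes$id
  colnames(thickness) <- phenotypes$id
  rd <- S4Vectors::DataFrame(hemisphere = hemisphere(mesh))
  rownames(rd) <- rownames(thickness) <-
    paste0("v", seq_len(nVertices(mesh)))
  se <- SummarizedExperiment(assays = list(thickness = thickness),
                             colData = cd, rowData = rd)
  md <- list()
  if (!is.null(config)) md$config <- config
  if (!is.null(model)) md$model <- model
  S4Vectors::metadata(se) <- md
  new("CorticalExperiment", se, mesh = mesh)
}

#' @rdname cortdev-accessors
#' @export
setMethod("surfaceMesh", "CorticalExperiment", function(x) x@mesh)

#' @rdname cortdev-accessors
#' @export
setMethod("thickness", "CorticalExperiment",
          function(x) SummarizedExperiment::assay(x, "thickness"))

#' @rdname cortdev-accessors
#' @export
setMethod("phenotypes", "CorticalExperiment", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @rdname cortdev-accessors
#' @export
setMethod("nVertices", "CorticalExperiment", function(x) nrow(x))

#' @rdname cortdev-accessors
#' @export
setMethod("hemisphere", "CorticalExperiment",
          function(x) hemisphere(x@mesh))

setMethod("show", "CorticalExperiment", function(object) {
  callNextMethod()
  cat("mesh:", nVertices(object@mesh), "vertices over",
      nlevels(hemisphere(object@mesh)), "hemispheres\n")
})
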