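#' @import methods
#' @importFrom stats approx coef cor cor.test lm lm.fit median na.omit
#'   p.adjust pf predict quantile rbinom rlnorm rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv read.table write.table packageVersion
NULL

#' Toy triangulated cortical surface
#'
#' A closed sphere-like triangulation per hemisphere, standing in for a
#' cortical surface mesh. Vertices carry 3-D coordinates and a hemisphere
#' label; faces are triangles over vertex indices. The neighbour graph used
#' for surface smoothing is derived from the faces.
#'
#' @slot coordinates numeric matrix, one row per vertex, columns x/y/z.
#' @slot faces integer matrix, one row per triangle, 1-based vertex indices.
#' @slot hemisphere factor of length \code{nrow(coordinates)} with levels
#'   \code{"left"}, \code{"right"}.
#'
#' @seealso [buildToyMesh()], [smoothOnMesh()]
#' @export
setClass("SurfaceMesh",
  representation(
    coordinates = "matrix",
    faces = "matrix",
    hemisphere = "factor"
  )
)

setValidity("SurfaceMesh", function(object) {
  msg <- character(0)
  nv <- nrow(object@coordinates)
  if (ncol(object@coordinates) != 3L)
    msg <- c(msg, "coordinates must have 3 columns")
  if (ncol(object@faces) != 3L)
    msg <- c(msg, "faces must have 3 columns")
  f <- object@faces
  if (nrow(f) && (min(f) < 1L || max(f) > nv))
    msg <- c(msg, "faces reference vertices outside the mesh")
  if (length(object@hemisphere) != nv)
    msg <- c(msg, "hemisphere labels must match vertex count")
  if (nrow(f)) {
    hf <- matrix(as.integer(object@hemisphere)[f], ncol = 3L)
    if (any(hf[, 1L] != hf[, 2L] | hf[, 1L] != hf[, 3L]))
      msg <- c(msg, "faces must not straddle hemispheres")
  }
  if (length(msg)) msg else TRUE
})

#' Generative model for thickness-by-age trajectories
#'
#' Parameterizes the hypothesized developmental trajectory of cortical
#' thickness: a baseline with a single interior peak (Gaussian bump) and a
#' linear post-peak decline, plus the two group-specific distortions under
#' study -- a rightward shift of the peak age (delayed maturation) applied at
#' a set of affected vertices for the case-below-median-IQ cell, and a
#' uniform downward intercept offset for the case-above-median-IQ cell.
#'
#' @slot baseline asymptotic thickness (mm).
#' @slot amplitude peak height above baseline (mm).
#' @slot peakAge age at maximal thickness (years).
#' @slot width Gaussian width of the peak (years).
#' @slot declineSlope post-peak linear decline (mm per year).
#' @slot peakShift years added to \code{peakAge} at affected vertices for
#'   cases below median IQ.
#' @slot interceptOffset mm subtracted everywhere for cases above median IQ.
#' @slot noiseSd vertexwise residual SD (mm).
#' @slot affectedVertices integer vertex ids where the peak shift applies.
#' @seealso [trajectoryModel()], [generateThicknessMaps()]
#' @export
setClass("TrajectoryModel",
  representation(
    baseline = "numeric",
    amplitude = "numeric",
    peakAge = "numeric",
    width = "numeric",
    declineSlope = "numeric",
    peakShift = "numeric",
    interceptOffset = "numeric",
    noiseSd = "numeric",
    affectedVertices = "integer"
  )
)

setValidity("TrajectoryModel", function(object) {
  msg <- character(0)
  if (object@width <= 0) msg <- c(msg, "width must be > 0")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (object@baseline <= 0) msg <- c(msg, "baseline must be > 0")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration for the synthetic cohort generator
#'
#' Holds every knob of the synthetic-cohort generator: cell sizes for the
#' four diagnosis-by-IQ-subgroup cells, the age range, per-cell IQ
#' distributions, per-measure volumetric targets, the three targeted
#' IQ correlations (control gray matter, control FA, case thickness),
#' demographic marginals, mesh size, surface smoothing extent, and the seed.
#'
#' @slot nPerCell subjects per diagnosis x IQ-subgroup cell.
#' @slot ageRange years, lower/upper (ages drawn uniformly).
#' @slot iqCells data.frame with columns cell, mean, sd, lower, upper.
#' @slot iqGroups data.frame with columns group, mean, sd (group-level IQ
#'   law used to standardize IQ when imposing correlations).
#' @slot volumetricTargets data.frame with columns measure, cell, mean, sd.
#' @slot targetCorrelations named numeric: gm_iq_control, fa_iq_control,
#'   thickness_iq_adhd.
#' @slot sexFemaleProb,handProbs,sliceThinProb demographic marginals shared
#'   by all cells.
#' @slot medAvailability probability a case has a recorded medication
#'   history.
#' @slot medDuration mean/sd of the corrected medication-duration fraction.
#' @slot nVertices vertices per hemisphere of the toy mesh.
#' @slot fwhm smoothing kernel FWHM in mesh distance units (NA = twice the
#'   mean edge length of the built mesh).
#' @slot seed integer master seed; sub-stages use fixed offsets from it.
#' @seealso [simConfig()]
#' @export
setClass("SimConfig",
  representation(
    nPerCell = "integer",
    ageRange = "numeric",
    iqCells = "data.frame",
    iqGroups = "data.frame",
    volumetricTargets = "data.frame",
    targetCorrelations = "numeric",
    sexFemaleProb = "numeric",
    handProbs = "numeric",
    sliceThinProb = "numeric",
    medAvailability = "numeric",
    medDuration = "numeric",
    nVertices = "integer",
    fwhm = "numeric",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character(0)
  if (object@nPerCell < 3L) msg <- c(msg, "nPerCell must be >= 3")
  if (length(object@ageRange) != 2L || diff(object@ageRange) <= 0)
    msg <- c(msg, "ageRange must be increasing (lower, upper)")
  if (any(object@iqCells$sd < 0)) msg <- c(msg, "IQ cell SDs must be >= 0")
  if (any(object@volumetricTargets$sd < 0, na.rm = TRUE))
    msg <- c(msg, "volumetric SDs must be >= 0")
  if (any(abs(object@targetCorrelations) >= 1))
    msg <- c(msg, "target correlations must satisfy |r| < 1")
  need <- c("gm_iq_control", "fa_iq_control", "thickness_iq_adhd")
  if (!all(need %in% names(object@targetCorrelations)))
    msg <- c(msg, paste("targetCorrelations must name:",
                        paste(need, collapse = ", ")))
  if (object@nVertices < 12L) msg <- c(msg, "nVertices must be >= 12")
  if (!is.na(object@fwhm) && object@fwhm < 0)
    msg <- c(msg, "fwhm must be >= 0")
  if (abs(sum(object@handProbs) - 1) > 1e-8)
    msg <- c(msg, "handProbs must sum to 1")
  if (length(msg)) msg else TRUE
})

#' A single semiparametric age fit
#'
#' The result of fitting one of the ladder's models to (age, y) data: the
#' sample mean (\code{kind = "constant"}, 1 df), the ordinary least-squares
#' line (\code{kind = "line"}, 2 df), or the locally-weighted running-line
#' smoother at the span achieving a requested effective df
#' (\code{kind = "smooth"}).
#'
#' @slot kind one of \code{"constant"}, \code{"line"}, \code{"smooth"}.
#' @slot span neighbourhood span of the smoother (NA for parametric fits).
#' @slot effectiveDf trace of the smoother operator (1 and 2 exactly for the
#'   parametric fits).
#' @slot fitted per-observation fitted values.
#' @slot rss residual sum of squares.
#' @slot n observation count.
#' @slot ages,y the data, kept for prediction on new age grids.
#' @seealso [fitTrajectory()], [selectDf()]
#' @export
setClass("SmootherFit",
  representation(
    kind = "character",
    span = "numeric",
    effectiveDf = "numeric",
    fitted = "numeric",
    rss = "numeric",
    n = "integer",
    ages = "numeric",
    y = "numeric"
  )
)

setValidity("SmootherFit", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("constant", "line", "smooth"))
    msg <- c(msg, "kind must be constant, line or smooth")
  if (object@rss < 0) msg <- c(msg, "rss must be >= 0")
  if (object@effectiveDf < 1 - 1e-8 || object@effectiveDf > object@n + 1e-8)
    msg <- c(msg, "effectiveDf must lie in [1, n]")
  if (object@kind == "constant" && abs(object@effectiveDf - 1) > 1e-8)
    msg <- c(msg, "constant fit must have effectiveDf == 1")
  if (object@kind == "line" && abs(object@effectiveDf - 2) > 1e-8)
    msg <- c(msg, "line fit must have effectiveDf == 2")
  if (length(msg)) msg else TRUE
})

#' Outcome of the parsimony walk along the df ladder
#'
#' Records the forward-stepwise selection of effective degrees of freedom:
#' each candidate df was tested against its immediate predecessor with the
#' approximate nested F test; the walk stops at the first non-rejection and
#' keeps the last candidate that was a significant improvement.
#'
#' @slot ladder candidate df values, ascending, starting at 1.
#' @slot chosenDf the selected (achieved) effective df.
#' @slot chosenFit the [SmootherFit-class] at the selected df.
#' @slot stepTests data.frame: one row per ladder step with the candidate
#'   and predecessor dfs, the F statistic and p-value.
#' @slot alpha test level of each step (default 0.05).
#' @seealso [selectDf()]
#' @export
setClass("DfSelection",
  representation(
    ladder = "numeric",
    chosenDf = "numeric",
    chosenFit = "SmootherFit",
    stepTests = "data.frame",
    alpha = "numeric"
  )
)

#' Vertexwise trajectory-difference statistics
#'
#' Per-vertex results of comparing the two diagnostic groups' thickness
#' trajectories against the pooled whole-group fit, with BH FDR control
#' across vertices and a per-hemisphere critical statistic (the smallest
#' absolute signed statistic among rejected vertices, the analogue of a
#' reported critical t).
#'
#' @slot stats data.frame with columns vertex, hemisphere, statistic (F),
#'   signed, p, q, rejected, dfGroup1, dfGroup2, dfPooled, degenerate.
#' @slot critical named numeric, one critical statistic per hemisphere
#'   (NA where nothing was rejected).
#' @slot params list echoing the analysis configuration (group sizes,
#'   ladder, alpha, FDR level, age window, group labels).
#' @seealso [vertexwiseAnalysis()]
#' @export
setClass("VertexStatMap",
  representation(
    stats = "data.frame",
    critical = "numeric",
    params = "list"
  )
)

#' Container for a cortical thickness experiment
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with vertices as rows and subjects as columns, holding the thickness
#' assay, per-subject phenotypes (and optionally volumetric measures) as
#' \code{colData}, per-vertex annotation as \code{rowData}, and the toy
#' surface mesh.
#'
#' @slot mesh the [SurfaceMesh-class] the rows are measured on.
#' @seealso [CorticalExperiment()], [simulateCohort()]
#' @export
setClass("CorticalExperiment",
  contains = "SummarizedExperiment",
  representation(mesh = "SurfaceMesh")
)

setValidity("CorticalExperiment", function(object) {
  if (nrow(object) != nrow(object@mesh@coordinates))
    "number of rows must equal the number of mesh vertices"
  else TRUE
})
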