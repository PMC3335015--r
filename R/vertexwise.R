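#' Restrict a cohort to the trajectory analysis window
#'
#' Keeps subjects strictly younger than `maxAge` (the smoother is
#' sensitive to sparse data at the top of the age range) and errors if any
#' diagnostic group drops below `minGroupN`.
#'
#' @param phenotypes data.frame with `age` and the grouping column.
#' @param maxAge exclusive upper age bound in years (default 14).
#' @param minGroupN minimum subjects per group after filtering.
#' @param groupVar name of the grouping column (default `diagnosis`).
#' @return The filtered data.frame.
#' @examples
#' ph <- data.frame(age = c(13.9, 14, 14.1),
#'                  diagnosis = factor("control"))
#' nrow(ageFilter(ph, minGroupN = 1))  # 1
#' @export
ageFilter <- function(phenotypes, maxAge = 14, minGroupN = 5,
                      groupVar = "diagnosis") {
  out <- phenotypes[phenotypes$age < maxAge, , drop = FALSE]
  counts <- table(out[[groupVar]])
  low <- names(counts)[counts < minGroupN]
  if (length(low))
    stop("insufficient data after age filter for group(s): ",
         paste(low, collapse = ", "))
  out
}

#' Benjamini-Hochberg false discovery rate control
#'
#' The step-up procedure: with p-values sorted ascending, find the largest
#' rank i with `p_(i) <= i * level / m` and reject all hypotheses at or
#' below it. Reported q-values are the usual step-up adjusted values
#' `q_(i) = min_{j >= i} m * p_(j) / j`, capped at 1; a hypothesis is
#' rejected exactly when its q-value is at most `level`.
#'
#' @param p numeric p-values in \[0, 1\].
#' @param level target FDR (default 0.05).
#' @return list with `q` (adjusted values, input order) and `rejected`
#'   (logical).
#' @examples
#' bhFdr(c(0.01, 0.02, 0.03, 0.04), level = 0.05)$rejected  # all TRUE
#' @export
bhFdr <- function(p, level = 0.05) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  q <- p.adjust(p, method = "BH")
  list(q = q, rejected = q <= level)
}

# ---- shared machinery for trajectory difference testing -------------------

# lazily-built per-design cache of ladder operators: for each smooth df the
# smoother matrix, its trace, and the mean-over-grid prediction weights
.designContext <- function(ages, grid, kernel = "tricube") {
  ctx <- new.env(parent = emptyenv())
  ctx$ages <- ages
  ctx$grid <- grid
  ctx$kernel <- kernel
  ctx$ops <- list()
  ctx
}

.designOp <- function(ctx, df) {
  key <- sprintf("df%.4f", df)
  if (!is.null(ctx$ops[[key]])) return(ctx$ops[[key]])
  sp <- spanForDf(ctx$ages, df, kernel = ctx$kernel)
  S <- smootherMatrix(ctx$ages, sp$span, kernel = ctx$kernel)
  G <- .runlineOperator(ctx$ages, sp$span, evalAt = ctx$grid,
                        kernel = ctx$kernel)
  op <- list(S = S, trace = sp$df, gw = colMeans(G))
  ctx$ops[[key]] <- op
  op
}

# forward-stepwise df selection for every column of Y at once (all columns
# share the design, so ladder operators are built once). Returns per-column
# chosen df, rss at the chosen fit, and the mean fitted value over the
# reference age grid.
.selectDfMatrix <- function(ctx, Y, ladder, alpha) {
  ages <- ctx$ages
  n <- length(ages)
  V <- ncol(Y)
  m <- colMeans(Y)
  Yc <- Y - matrix(m, n, V, byrow = TRUE)
  rss1 <- colSums(Yc^2)

  chosen <- rep(1, V)
  rssCh <- rss1
  meanPred <- m                     # grand mean predicts the grid mean

  if (length(ladder) < 2L || var(ages) == 0)
    return(list(df = chosen, rss = rssCh, meanPred = meanPred))

  # rung 2: global least-squares line, closed form
  cx <- ages - mean(ages)
  b <- as.vector(crossprod(cx, Yc)) / sum(cx^2)
  rss2 <- colSums((Yc - outer(cx, b))^2)
  Fst <- pmax(rss1 - rss2, 0) / (rss2 / (n - 2))
  pv <- pf(Fst, 1, n - 2, lower.tail = FALSE)
  active <- which(pv < alpha & rss1 > rss2)
  chosen[active] <- 2
  rssCh[active] <- rss2[active]
  gridDev <- mean(ctx$grid) - mean(ages)
  meanPred[active] <- m[active] + b[active] * gridDev

  prevTrace <- 2
  prevRss <- rss2
  for (df in ladder[ladder > 2]) {
    if (!length(active)) break
    op <- .designOp(ctx, df)
    if (op$trace <= prevTrace + 1e-8) break        # df plateau
    if (n - op$trace <= 0) break
    Ya <- Y[, active, drop = FALSE]
    R <- Ya - op$S %*% Ya
    rssNew <- colSums(R^2)
    num <- (prevRss[active] - rssNew) / (op$trace - prevTrace)
    Fst <- ifelse(num > 0, num / (rssNew / (n - op$trace)), 0)
    pv <- pf(Fst, op$trace - prevTrace, n - op$trace, lower.tail = FALSE)
    pv[Fst == 0] <- 1
    rej <- pv < alpha
    if (any(rej)) {
      adv <- active[rej]
      chosen[adv] <- op$trace
      rssCh[adv] <- rssNew[rej]
      meanPred[adv] <- as.vector(op$gw %*% Ya[, rej, drop = FALSE])
    }
    prevRss[active] <- rssNew
    active <- active[rej]
    prevTrace <- op$trace
  }
  list(df = chosen, rss = rssCh, meanPred = meanPred)
}

# pooled-versus-separate F statistics from per-column selections
.trajectoryF <- function(n, poolSel, sel1, sel2) {
  ddf <- sel1$df + sel2$df - poolSel$df
  dfDen <- n - sel1$df - sel2$df
  rssSep <- sel1$rss + sel2$rss
  degenerate <- ddf <= 1e-9 | dfDen <= 0
  num <- (poolSel$rss - rssSep) / ifelse(degenerate, 1, ddf)
  Fst <- ifelse(!degenerate & num > 0,
                num / (rssSep / ifelse(dfDen > 0, dfDen, 1)), 0)
  pv <- ifelse(!degenerate & Fst > 0,
               pf(Fst, pmax(ddf, 1e-9), pmax(dfDen, 1e-9),
                  lower.tail = FALSE), 1)
  pv[Fst == 0] <- 1
  list(statistic = Fst, p.value = pv, ddf = ddf, dfDen = dfDen,
       degenerate = degenerate)
}

#' Test whether two groups share one developmental trajectory
#'
#' Fits the pooled sample and each group separately, each with its own
#' parsimony df selection ([selectDf()]); the pooled single-curve model is
#' the null, the two-curve model the alternative. The statistic is
#' `F = [(rss_pooled - rss_g1 - rss_g2) / ddf] / [(rss_g1 + rss_g2) / (n - df_g1 - df_g2)]`
#' with `ddf = df_g1 + df_g2 - df_pooled`, referred to the corresponding F
#' law. The companion signed statistic is `sign(mean fitted difference
#' across a reference age grid) * sqrt(F)`, with the difference taken as
#' the second factor level minus the first (case minus control for the
#' default diagnosis coding).
#'
#' @param ages,y numeric vectors of equal length.
#' @param group a two-level factor (or coercible) aligned with `ages`.
#' @param ladder,alpha df ladder and step level for [selectDf()].
#' @param gridN size of the reference age grid for the sign (default 50).
#' @param kernel smoother kernel.
#' @return list with `statistic` (F), `signed`, `p.value`, `dfGroup1`,
#'   `dfGroup2`, `dfPooled`, `degenerate` (TRUE when the pooled df is at
#'   least the sum of the group dfs, in which case `p = 1`).
#' @export
trajectoryDifferenceTest <- function(ages, y, group, ladder = dfLadder(),
                                     alpha = 0.05, gridN = 50,
                                     kernel = c("tricube", "uniform")) {
  kernel <- match.arg(kernel)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("exactly two groups are required")
  stopifnot(length(ages) == length(y), length(ages) == length(group))

  selP <- selectDf(ages, y, ladder, alpha, kernel = kernel)
  i1 <- which(group == levels(group)[1L])
  i2 <- which(group == levels(group)[2L])
  sel1 <- selectDf(ages[i1], y[i1], ladder, alpha, kernel = kernel)
  sel2 <- selectDf(ages[i2], y[i2], ladder, alpha, kernel = kernel)

  res <- .trajectoryF(length(ages),
                      list(df = chosenDf(selP), rss = rss(chosenFit(selP))),
                      list(df = chosenDf(sel1), rss = rss(chosenFit(sel1))),
                      list(df = chosenDf(sel2), rss = rss(chosenFit(sel2))))
  grid <- seq(min(ages), max(ages), length.out = gridN)
  diffMean <- mean(predict(chosenFit(sel2), grid) -
                   predict(chosenFit(sel1), grid))
  list(statistic = res$statistic, p.value = res$p.value,
       signed = sign(diffMean) * sqrt(res$statistic),
       dfGroup1 = chosenDf(sel1), dfGroup2 = chosenDf(sel2),
       dfPooled = chosenDf(selP), degenerate = res$degenerate)
}

#' Vertexwise trajectory-difference analysis
#'
#' The full surface analysis: restrict to the age window, optionally
#' residualize thickness on nuisance covariates, run the pooled-versus-
#' separate trajectory F test at every vertex (each of the three designs
#' gets its own parsimony df selection per vertex, with ladder operators
#' shared across vertices), control the FDR across all vertices jointly
#' with [bhFdr()], and report a per-hemisphere critical statistic -- the
#' smallest absolute signed statistic among that hemisphere's rejected
#' vertices.
#'
#' @param x a [CorticalExperiment-class], or a subjects x vertices matrix.
#' @param phenotypes data.frame aligned with the rows of the matrix
#'   (ignored for a CorticalExperiment).
#' @param hemisphereLabels optional per-vertex factor for the matrix
#'   method.
#' @param maxAge,minGroupN age window (see [ageFilter()]).
#' @param ladder,alpha df ladder and step level.
#' @param fdrLevel FDR level across vertices (default 0.05).
#' @param residualize residualize thickness on `covariates` before fitting
#'   (default TRUE).
#' @param covariates nuisance columns used when residualizing.
#' @param groupVar grouping column (default `diagnosis`; must have two
#'   levels after filtering).
#' @param gridN reference age grid size for the signed statistic.
#' @param kernel smoother kernel.
#' @param ... passed down from the CorticalExperiment method.
#' @return A [VertexStatMap-class].
#' @export
setGeneric("vertexwiseAnalysis",
           function(x, ...) standardGeneric("vertexwiseAnalysis"))

#' @rdname vertexwiseAnalysis
#' @export
setMethod("vertexwiseAnalysis", "CorticalExperiment",
  function(x, ...) {
    .vertexwiseCore(t(thickness(x)), phenotypes(x),
                    hemisphereLabels = hemisphere(x), ...)
  })

#' @rdname vertexwiseAnalysis
#' @export
setMethod("vertexwiseAnalysis", "matrix",
  function(x, phenotypes, hemisphereLabels = NULL, ...) {
    .vertexwiseCore(x, phenotypes, hemisphereLabels = hemisphereLabels, ...)
  })

.vertexwiseCore <- function(Y, phenotypes, hemisphereLabels = NULL,
                            maxAge = 14, minGroupN = 5,
                            ladder = dfLadder(), alpha = 0.05,
                            fdrLevel = 0.05, residualize = TRUE,
                            covariates = c("sex", "hand", "slice_dummy"),
                            groupVar = "diagnosis", gridN = 50,
                            kernel = c("tricube", "uniform")) {
  kernel <- match.arg(kernel)
  if (nrow(Y) != nrow(phenotypes))
    stop("thickness rows do not align with phenotype rows")
  V <- ncol(Y)
  if (is.null(hemisphereLabels))
    hemisphereLabels <- factor(rep("all", V))
  if (length(hemisphereLabels) != V)
    stop("hemisphere labels do not align with vertices")

  ph <- ageFilter(phenotypes, maxAge = maxAge, minGroupN = minGroupN,
                  groupVar = groupVar)
  keep <- phenotypes$age < maxAge
  Y <- Y[keep, , drop = FALSE]
  group <- droplevels(as.factor(ph[[groupVar]]))
  if (nlevels(group) != 2L) stop("exactly two groups are required")

  if (residualize) {
    use <- intersect(covariates, names(ph))
    use <- use[vapply(use, function(v) length(unique(ph[[v]])) > 1L,
                      logical(1))]
    if (length(use)) {
      X <- stats::model.matrix(stats::reformulate(use), data = ph)
      mu <- colMeans(Y)
      Y <- qr.resid(qr(X), Y) + matrix(mu, nrow(Y), V, byrow = TRUE)
    }
  }

  ages <- ph$age
  grid <- seq(min(ages), max(ages), length.out = gridN)
  i1 <- which(group == levels(group)[1L])
  i2 <- which(group == levels(group)[2L])

  ctxP <- .designContext(ages, grid, kernel)
  ctx1 <- .designContext(ages[i1], grid, kernel)
  ctx2 <- .designContext(ages[i2], grid, kernel)
  selP <- .selectDfMatrix(ctxP, Y, ladder, alpha)
  sel1 <- .selectDfMatrix(ctx1, Y[i1, , drop = FALSE], ladder, alpha)
  sel2 <- .selectDfMatrix(ctx2, Y[i2, , drop = FALSE], ladder, alpha)

  res <- .trajectoryF(length(ages), selP, sel1, sel2)
  signed <- sign(sel2$meanPred - sel1$meanPred) * sqrt(res$statistic)
  fdr <- bhFdr(res$p.value, level = fdrLevel)

  stats <- data.frame(vertex = seq_len(V),
                      hemisphere = hemisphereLabels,
                      statistic = res$statistic,
                      signed = signed,
                      p = res$p.value,
                      q = fdr$q,
                      rejected = fdr$rejected,
                      dfGroup1 = sel1$df,
                      dfGroup2 = sel2$df,
                      dfPooled = selP$df,
                      degenerate = res$degenerate)

  critical <- vapply(levels(hemisphereLabels), function(h) {
    sel <- stats$rejected & stats$hemisphere == h
    if (any(sel)) min(abs(stats$signed[sel])) else NA_real_
  }, numeric(1))

  new("VertexStatMap", stats = stats, critical = critical,
      params = list(nPerGroup = setNames(c(length(i1), length(i2)),
                                         levels(group)),
                    groups = levels(group), maxAge = maxAge,
                    ladder = ladder, alpha = alpha, fdrLevel = fdrLevel,
                    residualized = residualize, kernel = kernel))
}

#' @rdname cortdev-accessors
#' @export
setMethod("vertexStats", "VertexStatMap", function(x) x@stats)

#' @rdname cortdev-accessors
#' @export
setMethod("criticalStatistic", "VertexStatMap", function(x) x@critical)

setMethod("show", "VertexStatMap", function(object) {
  st <- object@stats
  cat(sprintf("VertexStatMap: %d vertices, %d rejected at FDR %.3g\n",
              nrow(st), sum(st$rejected), object@params$fdrLevel))
  crit <- object@critical
  cat("critical |statistic| per hemisphere:",
      paste(sprintf("%s = %.3g", names(crit), crit), collapse = ", "),
      "\n")
})

#' Age of maximal fitted thickness
#'
#' Evaluates a fitted trajectory on a fine age grid and returns the age of
#' its maximum -- the estimated peak age of cortical thickness.
#'
#' @param fit a [SmootherFit-class] (or a [DfSelection-class], whose chosen
#'   fit is used).
#' @param gridN grid resolution (default 201).
#' @return The grid age with the largest fitted value.
#' @export
estimatePeakAge <- function(fit, gridN = 201) {
  if (is(fit, "DfSelection")) fit <- chosenFit(fit)
  grid <- seq(min(fit@ages), max(fit@ages), length.out = gridN)
  grid[which.max(predict(fit, grid))]
}
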