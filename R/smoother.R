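#' The default ladder of candidate degrees of freedom
#'
#' Candidate effective dfs for the parsimony walk: 1 (constant),
#' 2 (straight line), then 2.2, 2.4, ... up to `dfMax` (curved lines).
#'
#' @param dfMax upper end of the ladder (default 5).
#' @return Ascending numeric vector starting at 1.
#' @export
dfLadder <- function(dfMax = 5) {
  stopifnot(dfMax > 2)
  c(1, 2, seq(2.2, dfMax, by = 0.2))
}

# weights of a locally-weighted running-line smoother, evaluated at evalAt.
# Row i holds the linear weights over the observations whose weighted
# least-squares line, evaluated at evalAt[i], gives the fitted value.
# For span <= 1 the neighbourhood is the ceiling(span * n) nearest
# observations with tricube weights on distance to the k-th neighbour; for
# span > 1 all observations are used with the distance scale inflated by
# span (the usual loess continuation), which lets the trace approach 2.
.runlineOperator <- function(ages, span, evalAt = ages,
                             kernel = c("tricube", "uniform")) {
  kernel <- match.arg(kernel)
  n <- length(ages)
  if (n < 3L) stop("need at least 3 observations")
  if (!all(is.finite(ages))) stop("ages must be finite")
  if (!is.numeric(span) || length(span) != 1L || is.na(span) || span <= 0)
    stop("span must be a single positive number")
  if (span * n < 2) stop("span too small: span * n must be >= 2")

  D <- abs(outer(evalAt, ages, "-"))
  if (span <= 1) {
    k <- max(2L, ceiling(span * n))
    dmax <- apply(D, 1L, function(r) sort.int(r, partial = k)[k])
  } else {
    dmax <- apply(D, 1L, max) * span
  }

  if (kernel == "tricube") {
    U <- D / ifelse(dmax > 0, dmax, 1)
    W <- (1 - pmin(U, 1)^3)^3
  } else {
    W <- (D <= dmax + 1e-12) * 1
  }
  # degenerate rows (>= k ties at the evaluation age): uniform over the ties
  zero <- dmax <= 0
  if (any(zero)) W[zero, ] <- (D[zero, , drop = FALSE] == 0) * 1

  Wsum <- rowSums(W)
  xbar <- as.vector(W %*% ages) / Wsum
  Cdev <- matrix(ages, nrow = nrow(D), ncol = n, byrow = TRUE) - xbar
  V <- rowSums(W * Cdev^2)
  a <- evalAt - xbar
  scale2 <- max(abs(ages), 1)^2
  # slope term drops out where the local design is degenerate (V ~ 0):
  # the row then falls back to a locally-weighted mean
  ratio <- ifelse(V > scale2 * 1e-12, a / pmax(V, scale2 * 1e-12), 0)
  W / Wsum + (W * Cdev) * ratio
}

#' Running-line smoother operator
#'
#' Builds the n x n linear operator of a locally-weighted running-line
#' smoother: row i contains the weights of a weighted least-squares line fit
#' over the `ceiling(span * n)` nearest neighbours of `ages[i]` (tricube
#' distance weights by default), evaluated at `ages[i]`. Rows reproduce
#' affine functions exactly: the operator maps a constant vector to itself
#' and the age vector to itself. With `span = 1` and uniform weights it
#' degenerates to the ordinary global-line hat matrix (trace 2). Spans above
#' 1 keep all observations and inflate the tricube distance scale, so the
#' operator tends continuously to the global line as the span grows.
#'
#' @param ages numeric ages (any order, ties allowed).
#' @param span fraction of observations per local neighbourhood; values in
#'   (0, 1] select nearest neighbours, values above 1 flatten the weights.
#' @param kernel local weight kernel, `"tricube"` (default) or `"uniform"`.
#' @return An `n x n` numeric matrix.
#' @examples
#' ages <- seq(6, 14, length.out = 20)
#' S <- smootherMatrix(ages, span = 0.5)
#' range(S %*% rep(1, 20))     # reproduces constants
#' @export
smootherMatrix <- function(ages, span, kernel = c("tricube", "uniform")) {
  .runlineOperator(ages, span, evalAt = ages, kernel = match.arg(kernel))
}

#' @rdname effectiveDf
#' @export
setMethod("effectiveDf", "matrix", function(x) {
  if (nrow(x) != ncol(x)) stop("operator must be square")
  sum(diag(x))
})

#' @rdname effectiveDf
#' @export
setMethod("effectiveDf", "SmootherFit", function(x) x@effectiveDf)

#' Span achieving a target effective df
#'
#' Inverts the span-to-df map of the running-line smoother by bisection,
#' exploiting that the operator trace decreases as the span grows. Because
#' the nearest-neighbour count is discrete for spans at or below 1, the
#' trace is a step function there; targets below the df at span 1 are
#' reached exactly on the continuous span > 1 branch, while larger targets
#' snap to the nearest achievable neighbour count and are flagged via
#' `exact = FALSE` when the achieved df misses the target by more than
#' `tol`.
#'
#' @param ages numeric ages.
#' @param targetDf requested effective df, strictly between 2 and
#'   `length(ages)`. (Dfs 1 and 2 are parametric fits, not smoother spans.)
#' @param tol acceptable |achieved - target| (default 0.01).
#' @param kernel passed to [smootherMatrix()].
#' @return A list with elements `span`, `df` (achieved), and `exact`.
#' @examples
#' ages <- seq(6, 14, length.out = 100)
#' spanForDf(ages, 2.2)$df
#' @export
spanForDf <- function(ages, targetDf, tol = 0.01,
                      kernel = c("tricube", "uniform")) {
  kernel <- match.arg(kernel)
  n <- length(ages)
  if (!is.numeric(targetDf) || length(targetDf) != 1L ||
      targetDf <= 2 || targetDf >= n)
    stop("targetDf must lie strictly between 2 and n")

  dfAt <- function(s) effectiveDf(smootherMatrix(ages, s, kernel = kernel))
  dfOne <- dfAt(1)

  if (targetDf <= dfOne) {
    # continuous branch: df decreases monotonically to 2 as span grows
    lo <- 1; hi <- 2
    while (dfAt(hi) > targetDf && hi < 2^26) hi <- hi * 2
    span <- hi
    achieved <- dfAt(hi)
    for (i in seq_len(60L)) {
      if (abs(achieved - targetDf) <= 0.3 * tol) break
      mid <- sqrt(lo * hi)
      dm <- dfAt(mid)
      if (abs(dm - targetDf) < abs(achieved - targetDf)) {
        span <- mid; achieved <- dm
      }
      if (dm > targetDf) lo <- mid else hi <- mid
    }
    return(list(span = span, df = achieved,
                exact = abs(achieved - targetDf) <= tol))
  }

  # discrete branch: bisect the neighbour count k (df decreasing in k)
  klo <- 2L; khi <- n
  while (khi - klo > 1L) {
    km <- (klo + khi) %/% 2L
    if (dfAt(km / n) > targetDf) klo <- km else khi <- km
  }
  cand <- unique(pmin(pmax(c(klo, khi), 2L), n))
  dfs <- vapply(cand, function(k) dfAt(k / n), numeric(1))
  best <- which.min(abs(dfs - targetDf))
  list(span = cand[best] / n, df = dfs[best],
       exact = abs(dfs[best] - targetDf) <= tol)
}

#' Fit one rung of the df ladder
#'
#' Fits the age trajectory at a requested effective df: `df = 1` is the
#' sample mean, `df = 2` the ordinary least-squares line, and `df > 2` the
#' running-line smoother at the span achieving that df (see [spanForDf()]).
#'
#' @param ages,y numeric vectors of equal length (at least 3).
#' @param df requested effective df (1, 2, or a value in (2, n)).
#' @param kernel passed to [smootherMatrix()] for `df > 2`.
#' @return A [SmootherFit-class].
#' @examples
#' fit <- fitTrajectory(c(1, 2, 3), c(1, 2, 3), df = 1)
#' rss(fit)  # 2
#' @export
fitTrajectory <- function(ages, y, df, kernel = c("tricube", "uniform")) {
  kernel <- match.arg(kernel)
  n <- length(ages)
  if (length(y) != n) stop("ages and y must have equal length")
  if (n < 3L) stop("need at least 3 observations")
  if (!all(is.finite(ages)) || !all(is.finite(y)))
    stop("ages and y must be finite")

  if (df == 1) {
    fv <- rep(mean(y), n)
    return(new("SmootherFit", kind = "constant", span = NA_real_,
               effectiveDf = 1, fitted = fv, rss = sum((y - fv)^2),
               n = n, ages = as.numeric(ages), y = as.numeric(y)))
  }
  if (var(ages) == 0)
    stop("degenerate design: all ages identical, cannot fit df >= 2")
  if (df == 2) {
    cx <- ages - mean(ages)
    b <- sum(cx * y) / sum(cx^2)
    fv <- mean(y) + b * cx
    return(new("SmootherFit", kind = "line", span = NA_real_,
               effectiveDf = 2, fitted = fv, rss = sum((y - fv)^2),
               n = n, ages = as.numeric(ages), y = as.numeric(y)))
  }
  sp <- spanForDf(ages, df, kernel = kernel)
  S <- smootherMatrix(ages, sp$span, kernel = kernel)
  fv <- as.vector(S %*% y)
  new("SmootherFit", kind = "smooth", span = sp$span,
      effectiveDf = sp$df, fitted = fv, rss = sum((y - fv)^2),
      n = n, ages = as.numeric(ages), y = as.numeric(y))
}

#' @rdname cortdev-accessors
#' @export
setMethod("rss", "SmootherFit", function(x) x@rss)

#' @export
setMethod("fitted", "SmootherFit", function(object) object@fitted)

#' Predict a fitted trajectory on new ages
#'
#' Evaluates the fitted curve at arbitrary ages: the mean for constant
#' fits, the least-squares line for linear fits, and the local running-line
#' evaluated at each new age for smooth fits.
#'
#' @param object a [SmootherFit-class].
#' @param newAges numeric vector of evaluation ages.
#' @export
setMethod("predict", "SmootherFit", function(object, newAges) {
  if (missing(newAges)) return(object@fitted)
  switch(object@kind,
    constant = rep(mean(object@y), length(newAges)),
    line = {
      cx <- object@ages - mean(object@ages)
      b <- sum(cx * object@y) / sum(cx^2)
      mean(object@y) + b * (newAges - mean(object@ages))
    },
    smooth = {
      G <- .runlineOperator(object@ages, object@span, evalAt = newAges)
      as.vector(G %*% object@y)
    })
})

setMethod("show", "SmootherFit", function(object) {
  cat(sprintf("SmootherFit (%s): n = %d, effective df = %.3f, rss = %.4g\n",
              object@kind, object@n, object@effectiveDf, object@rss))
})

#' Approximate nested F test between two smoother fits
#'
#' Compares a richer fit to a nested simpler fit on the same data using the
#' approximate F statistic for linear smoothers:
#' `F = [(rss_small - rss_big) / (df_big - df_small)] / [rss_big / (n - df_big)]`,
#' referred to the F distribution with `(df_big - df_small, n - df_big)`
#' degrees of freedom. For the df 1-versus-2 step this reduces exactly to
#' the classical regression slope F test. A negative numerator (possible
#' with smoothers) is clamped to `F = 0`, `p = 1` -- the conservative
#' non-rejection.
#'
#' @param fitSmall,fitBig [SmootherFit-class] objects on the same data, with
#'   `effectiveDf(fitBig) > effectiveDf(fitSmall)`.
#' @return A list with `statistic`, `p.value`, `dfNum`, `dfDen`.
#' @examples
#' ages <- seq(6, 14, length.out = 20)
#' y <- 2 * ages + rnorm(20)
#' nestedFTest(fitTrajectory(ages, y, 1), fitTrajectory(ages, y, 2))
#' @export
nestedFTest <- function(fitSmall, fitBig) {
  if (fitSmall@n != fitBig@n) stop("fits are not on the same data length")
  dfS <- fitSmall@effectiveDf
  dfB <- fitBig@effectiveDf
  if (dfB <= dfS) stop("fitBig must have larger effective df than fitSmall")
  n <- fitBig@n
  dfDen <- n - dfB
  if (dfDen <= 0) stop("n - df of the larger fit must be positive")
  dfNum <- dfB - dfS
  num <- (fitSmall@rss - fitBig@rss) / dfNum
  if (num <= 0 || fitBig@rss < 0)
    return(list(statistic = 0, p.value = 1, dfNum = dfNum, dfDen = dfDen))
  Fstat <- num / (fitBig@rss / dfDen)
  list(statistic = Fstat,
       p.value = pf(Fstat, dfNum, dfDen, lower.tail = FALSE),
       dfNum = dfNum, dfDen = dfDen)
}

#' Parsimony-based selection of effective df
#'
#' Walks the df ladder from the bottom, testing each candidate against its
#' immediate predecessor with [nestedFTest()]. The walk stops at the first
#' step that fails to reject at `alpha`; the chosen fit is the last
#' candidate that was a significant improvement (the constant fit if even
#' the straight line is not). This keeps the least complex trajectory that
#' the data still demand.
#'
#' @param ages,y numeric vectors of equal length.
#' @param ladder ascending candidate dfs starting at 1 (see [dfLadder()]).
#' @param alpha step test level (default 0.05).
#' @param kernel passed to [fitTrajectory()].
#' @return A [DfSelection-class].
#' @examples
#' ages <- seq(6, 14, length.out = 40)
#' sel <- selectDf(ages, 2 * ages + rnorm(40, sd = 0.01))
#' chosenDf(sel)  # 2: a straight line suffices
#' @export
selectDf <- function(ages, y, ladder = dfLadder(), alpha = 0.05,
                     kernel = c("tricube", "uniform")) {
  kernel <- match.arg(kernel)
  if (is.unsorted(ladder, strictly = TRUE))
    stop("ladder must be strictly ascending")
  if (ladder[1L] != 1) stop("ladder must start at df = 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")

  prev <- fitTrajectory(ages, y, ladder[1L], kernel = kernel)
  chosen <- prev
  steps <- data.frame(dfSmall = numeric(0), dfBig = numeric(0),
                      statistic = numeric(0), p.value = numeric(0))
  for (df in ladder[-1L]) {
    cand <- fitTrajectory(ages, y, df, kernel = kernel)
    if (cand@effectiveDf <= prev@effectiveDf + 1e-8) break  # df plateau
    tst <- nestedFTest(prev, cand)
    steps <- rbind(steps, data.frame(dfSmall = prev@effectiveDf,
                                     dfBig = cand@effectiveDf,
                                     statistic = tst$statistic,
                                     p.value = tst$p.value))
    if (tst$p.value >= alpha) break
    chosen <- cand
    prev <- cand
  }
  new("DfSelection", ladder = as.numeric(ladder),
      chosenDf = chosen@effectiveDf, chosenFit = chosen,
      stepTests = steps, alpha = alpha)
}

#' @rdname cortdev-accessors
#' @export
setMethod("chosenDf", "DfSelection", function(x) x@chosenDf)

#' @rdname cortdev-accessors
#' @export
setMethod("chosenFit", "DfSelection", function(x) x@chosenFit)

#' @rdname cortdev-accessors
#' @export
setMethod("stepTests", "DfSelection", function(x) x@stepTests)

setMethod("show", "DfSelection", function(object) {
  cat(sprintf("DfSelection: chose df = %.3f (alpha = %.3g) after %d step(s)\n",
              object@chosenDf, object@alpha, nrow(object@stepTests)))
})
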