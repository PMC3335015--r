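#' Median split of the sample by IQ
#'
#' Computes the whole-sample median IQ across both diagnostic groups and
#' labels every subject: IQ at or below the median is `below`, strictly
#' above is `above`. The subject sitting exactly at the median therefore
#' joins the below-median subgroup, matching subgroup ranges of the form
#' 75--102 / 103--138 around a median of 102.
#'
#' @param phenotypes data.frame with an `iq` column (no missing values).
#' @return list with `labels` (factor below/above, in input order) and
#'   `median` (the split value).
#' @examples
#' medianSplit(data.frame(iq = c(90, 102, 102, 110)))
#' @export
medianSplit <- function(phenotypes) {
  iq <- phenotypes$iq
  if (is.null(iq) || anyNA(iq)) stop("iq must be present for all subjects")
  med <- median(iq)
  labels <- factor(ifelse(iq <= med, "below", "above"),
                   levels = c("below", "above"))
  if (any(table(labels) == 0))
    stop("degenerate split: one IQ subgroup is empty")
  list(labels = labels, median = med)
}

#' Exclude upper-tail IQ outliers
#'
#' Removes subjects whose IQ exceeds Q3 + 1.5 IQR of the whole-sample IQ
#' distribution (the upper tail only -- the sparsely populated very-high-IQ
#' region). Applied before any analysis that treats IQ as a continuous
#' variable; median splits and group contrasts keep the full sample.
#'
#' @param phenotypes data.frame with `iq` (and usually `id`).
#' @return list with `phenotypes` (filtered), `excluded` (ids, or row
#'   indices when there is no id column), and `threshold`.
#' @export
excludeIqOutliers <- function(phenotypes) {
  iq <- phenotypes$iq
  if (is.null(iq)) stop("phenotypes must carry iq")
  qs <- quantile(iq, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
  threshold <- qs[2L] + 1.5 * (qs[2L] - qs[1L])
  drop <- which(!is.na(iq) & iq > threshold)
  ids <- if ("id" %in% names(phenotypes)) phenotypes$id[drop] else drop
  list(phenotypes = if (length(drop)) phenotypes[-drop, , drop = FALSE]
                    else phenotypes,
       excluded = ids, threshold = threshold)
}

.baseCovariates <- c("age", "sex", "hand", "slice_dummy")

.termToFormula <- function(terms) {
  stats::reformulate(sub("x", ":", terms, fixed = TRUE))
}

#' Covariate-adjusted volumetric GLM
#'
#' Ordinary least-squares fit of one volumetric outcome on diagnostic group
#' and the standard covariate set (age, sex, handedness, slice-thickness
#' dummy), optionally with a group-by-age interaction and/or dimensional IQ
#' terms. Rows with missing values in any used column are dropped
#' (listwise deletion). Per-term p-values are Type II F tests; adjusted
#' group means are fitted values at the covariate means (numeric
#' covariates at their sample mean, factor covariates at their observed
#' proportions). Outcomes with `transform = "log"` are modelled on the
#' natural log scale and their adjusted means reported on both scales.
#'
#' @param data joined phenotype + volumetric data.frame.
#' @param outcome name of the outcome column.
#' @param terms character vector of model terms; interactions are written
#'   `"group:age"` or `"iq:group"`. `"group"` refers to the `diagnosis`
#'   column.
#' @param transform `"none"` or `"log"` (natural log; outcome must be
#'   strictly positive).
#' @return list with elements `model` (the `lm`), `n`, `coefficients`,
#'   `pValues` (named, Type II), `adjustedMeans` (per diagnostic group; for
#'   log outcomes also `adjustedMeansResponse`), `outcome`, `transform`.
#' @examples
#' ph <- generateCohort(simConfig(nPerCell = 30, seed = 1))
#' vol <- generateVolumetrics(ph, simConfig(nPerCell = 30, seed = 1))
#' fit <- fitVolumetricGlm(merge(ph, vol, by = "id"), "cerebral_gray_matter")
#' fit$pValues[["diagnosis"]]
#' @export
fitVolumetricGlm <- function(data, outcome,
                             terms = c("group", .baseCovariates),
                             transform = c("none", "log")) {
  transform <- match.arg(transform)
  terms <- sub("^group$", "diagnosis", terms)
  terms <- gsub("\\bgroup\\b", "diagnosis", terms)
  mains <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  inter <- terms[grepl(":", terms, fixed = TRUE)]
  for (tm in inter) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1L]]
    if (!all(parts %in% terms))
      stop("interaction ", tm, " requires its main effects in terms")
  }
  if (!all(mains %in% names(data)))
    stop("missing columns: ",
         paste(setdiff(mains, names(data)), collapse = ", "))
  if (!outcome %in% names(data)) stop("unknown outcome: ", outcome)

  used <- data[, c(outcome, mains), drop = FALSE]
  keep <- stats::complete.cases(used)
  used <- used[keep, , drop = FALSE]
  if (transform == "log") {
    if (any(used[[outcome]] <= 0))
      stop("log transform requires a strictly positive outcome")
    used[[outcome]] <- log(used[[outcome]])
  }
  used <- droplevels(used)

  # nuisance covariates that are constant in the estimation sample carry no
  # information and would break the contrasts; drop them (never the group
  # or IQ terms, whose degeneracy is a real error)
  constant <- vapply(mains, function(v) length(unique(used[[v]])) < 2L,
                     logical(1))
  if (constant[match("diagnosis", mains)] %in% TRUE)
    stop("degenerate design: only one diagnostic group present")
  if ("iq" %in% mains && constant[match("iq", mains)])
    stop("degenerate design: iq is constant")
  dropMains <- mains[constant]
  if (length(dropMains)) {
    keepTerm <- !vapply(terms, function(tm) {
      any(strsplit(tm, ":", fixed = TRUE)[[1L]] %in% dropMains)
    }, logical(1))
    terms <- terms[keepTerm]
  }

  fml <- stats::reformulate(terms, response = outcome)
  fit <- lm(fml, data = used)
  if (any(is.na(coef(fit)))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }

  if (sum(resid(fit)^2) > 1e-10 * max(1, sum(fit$fitted.values^2))) {
    an <- car::Anova(fit, type = 2)
    pv <- setNames(an[["Pr(>F)"]], rownames(an))
    pv <- pv[!is.na(pv)]
  } else {
    # perfect fit: F tests are undefined
    pv <- setNames(rep(NA_real_, length(terms)), terms)
  }

  adj <- .adjustedGroupMeans(fit, used)
  out <- list(model = fit, n = nrow(used),
              coefficients = coef(fit), pValues = pv,
              adjustedMeans = adj, outcome = outcome,
              transform = transform)
  if (transform == "log") out$adjustedMeansResponse <- exp(adj)
  out
}

# fitted values per diagnostic group with every other model-matrix column
# averaged over the estimation sample
.adjustedGroupMeans <- function(fit, data) {
  if (!"diagnosis" %in% names(data)) return(NULL)
  X <- stats::model.matrix(fit)
  asgn <- attr(X, "assign")
  labs <- attr(stats::terms(fit), "term.labels")
  groupCols <- which(asgn %in% which(labs == "diagnosis"))
  xbar <- colMeans(X)
  lv <- levels(data$diagnosis)
  vapply(lv, function(g) {
    row <- xbar
    # set the group dummy columns to this level, leave covariates at means
    gx <- stats::model.matrix(~diagnosis,
            data = data.frame(diagnosis = factor(g, levels = lv)))
    row[groupCols] <- gx[1L, -1L][seq_along(groupCols)]
    sum(row * coef(fit))
  }, numeric(1))
}

#' Dimensional IQ moderation model
#'
#' The base covariate-adjusted group model with a main effect of IQ and an
#' IQ-by-group interaction added, giving the two dimensional p-values per
#' outcome: `pIq` (does the measure track IQ overall?) and `pIqGroup`
#' (does that relationship differ between diagnostic groups?). Upper-tail
#' IQ outliers are expected to have been removed first (see
#' [excludeIqOutliers()]); the function fits whatever it is given.
#'
#' @inheritParams fitVolumetricGlm
#' @return As [fitVolumetricGlm()], with `pIq` and `pIqGroup` added.
#' @export
dimensionalIqModel <- function(data, outcome,
                               transform = c("none", "log")) {
  if (!"iq" %in% names(data)) stop("data must carry iq")
  keep <- !is.na(data$iq)
  if (length(unique(data$iq[keep])) < 2L)
    stop("degenerate design: iq is constant")
  res <- fitVolumetricGlm(data, outcome,
                          terms = c("group", .baseCovariates,
                                    "iq", "iq:group"),
                          transform = match.arg(transform))
  res$pIq <- res$pValues[["iq"]]
  res$pIqGroup <- res$pValues[["diagnosis:iq"]]
  res
}

#' Within-group IQ correlations
#'
#' Pearson correlation between IQ and a measure, separately within each
#' diagnostic group, with two-sided p-values. Optionally partials out the
#' standard covariates first (the default reports plain zero-order r).
#'
#' @param data joined phenotype + volumetric data.frame.
#' @param measure column to correlate with IQ.
#' @param partial if TRUE, residualize both IQ and the measure on the base
#'   covariates within group before correlating.
#' @return data.frame with columns `group`, `n`, `r`, `p`.
#' @export
groupCorrelation <- function(data, measure, partial = FALSE) {
  stopifnot(measure %in% names(data), "iq" %in% names(data))
  groups <- levels(factor(data$diagnosis))
  rows <- lapply(groups, function(g) {
    d <- data[data$diagnosis == g, , drop = FALSE]
    d <- d[stats::complete.cases(d[, c("iq", measure)]), , drop = FALSE]
    if (nrow(d) < 3L) stop("need at least 3 subjects per group")
    x <- d$iq
    y <- d[[measure]]
    if (sd(x) == 0 || sd(y) == 0)
      stop("undefined correlation: constant column in group ", g)
    if (partial) {
      covars <- intersect(.baseCovariates, names(d))
      fml <- stats::reformulate(covars)
      x <- stats::resid(lm(update(fml, x ~ .), data = cbind(d, x = x)))
      y <- stats::resid(lm(update(fml, y ~ .), data = cbind(d, y = y)))
    }
    ct <- cor.test(x, y)
    data.frame(group = g, n = nrow(d), r = unname(ct$estimate),
               p = ct$p.value)
  })
  do.call(rbind, rows)
}

#' Percent volumetric reduction relative to controls
#'
#' `100 * (meanControl - meanCase) / meanControl`; callable on raw or
#' covariate-adjusted means. Scale-invariant.
#'
#' @param meanControl,meanCase group means (control mean must be positive).
#' @return Percentage reduction (negative if cases are larger).
#' @examples
#' percentReduction(748.6, 704.3)  # 5.92
#' @export
percentReduction <- function(meanControl, meanCase) {
  if (any(meanControl <= 0)) stop("control mean must be positive")
  100 * (meanControl - meanCase) / meanControl
}

#' Cortical gray matter proxy volume
#'
#' Approximates cortical gray matter volume as mean cortical thickness
#' times total cortical surface area. With thickness in mm and area in
#' cm^2, the product mm x cm^2 equals 0.1 ml, hence the factor.
#'
#' @param thicknessMm mean cortical thickness in mm.
#' @param areaCm2 total cortical surface area in cm^2.
#' @return Proxy volume in ml.
#' @examples
#' corticalGmProxy(3.344, 1906.5)  # about 637.5 ml
#' @export
corticalGmProxy <- function(thicknessMm, areaCm2) {
  if (any(thicknessMm <= 0) || any(areaCm2 <= 0))
    stop("thickness and area must be positive")
  thicknessMm * areaCm2 * 0.1
}

#' Age-corrected medication duration
#'
#' Months of stimulant use divided by the months elapsed since age 60
#' months (the youngest age at which stimulants were prescribed):
#' `monthsUsed / (ageMonths - 60)`. Missing usage propagates as missing.
#'
#' @param monthsUsed months of medication use (may be NA).
#' @param ageMonths age in months, strictly greater than 60.
#' @return Dimensionless fraction of the eligible window spent medicated.
#' @examples
#' correctedMedicationDuration(24, 120)  # 0.4
#' @export
correctedMedicationDuration <- function(monthsUsed, ageMonths) {
  if (any(ageMonths <= 60))
    stop("ageMonths must exceed 60 (earliest prescription age)")
  monthsUsed / (ageMonths - 60)
}

#' Volumetric summary table
#'
#' The full volumetric analysis for a set of measures, shaped like a
#' cohort-description table: per-cell raw means and SDs, the
#' covariate-adjusted diagnostic group p-value (overall and within each
#' IQ subgroup), the group-by-age interaction p, and the dimensional IQ
#' p-values (IQ main effect and IQ-by-group interaction, computed after
#' upper-tail IQ outlier exclusion). Ventricle measures are log-transformed
#' for modelling; tabulated means stay on the raw scale.
#'
#' @param data joined phenotype + volumetric data.frame.
#' @param measures character vector of measure columns (default: all known
#'   measures present in `data`).
#' @return data.frame, one row per measure.
#' @export
volumetricSummaryTable <- function(data, measures = NULL) {
  if (is.null(measures))
    measures <- intersect(defaultVolumetricTargets()$measure, names(data))
  split <- medianSplit(data)
  data$iq_cell <- split$labels
  noOut <- excludeIqOutliers(data)$phenotypes

  rows <- lapply(measures, function(ms) {
    tr <- if (ms %in% .skewedMeasures) "log" else "none"
    cellStat <- function(d) c(mean = mean(d[[ms]], na.rm = TRUE),
                              sd = sd(d[[ms]], na.rm = TRUE))
    cells <- list(
      control_all = data[data$diagnosis == "control", ],
      control_below = data[data$diagnosis == "control" &
                             data$iq_cell == "below", ],
      control_above = data[data$diagnosis == "control" &
                             data$iq_cell == "above", ],
      adhd_all = data[data$diagnosis == "adhd", ],
      adhd_below = data[data$diagnosis == "adhd" &
                          data$iq_cell == "below", ],
      adhd_above = data[data$diagnosis == "adhd" &
                          data$iq_cell == "above", ])
    st <- unlist(lapply(cells, cellStat))

    pGroup <- function(d) {
      fitVolumetricGlm(d, ms, transform = tr)$pValues[["diagnosis"]]
    }
    fitAge <- fitVolumetricGlm(data, ms,
                               terms = c("group", .baseCovariates,
                                         "group:age"),
                               transform = tr)
    dim <- dimensionalIqModel(noOut, ms, transform = tr)

    data.frame(measure = ms, t(st),
               p_group_all = pGroup(data),
               p_group_below = pGroup(data[data$iq_cell == "below", ]),
               p_group_above = pGroup(data[data$iq_cell == "above", ]),
               p_group_age = fitAge$pValues[["diagnosis:age"]],
               p_iq = dim$pIq,
               p_iq_group = dim$pIqGroup,
               row.names = NULL, check.names = FALSE)
  })
  do.call(rbind, rows)
}
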