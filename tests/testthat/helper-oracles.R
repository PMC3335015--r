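# Independent brute-force constructions used as oracles. These deliberately
# take a different computational route from the package (normal equations
# and explicit sorting rather than the closed-form weighted-moments rows).

bruteSmootherMatrix <- function(ages, span, kernel = "tricube") {
  n <- length(ages)
  S <- matrix(0, n, n)
  X <- cbind(1, ages)
  for (i in seq_len(n)) {
    d <- abs(ages - ages[i])
    if (span <= 1) {
      k <- max(2L, ceiling(span * n))
      dmax <- sort(d)[k]
    } else {
      dmax <- max(d) * span
    }
    if (dmax == 0) {
      w <- as.numeric(d == 0)
    } else if (kernel == "tricube") {
      u <- d / dmax
      w <- ifelse(u < 1, (1 - u^3)^3, 0)
    } else {
      w <- as.numeric(d <= dmax + 1e-12)
    }
    XtWX <- t(X) %*% (w * X)
    if (abs(det(XtWX)) > 1e-10 * max(abs(ages), 1)^2 * sum(w)^2) {
      S[i, ] <- c(1, ages[i]) %*% solve(XtWX, t(w * X))
    } else {
      S[i, ] <- w / sum(w)
    }
  }
  S
}

bruteBH <- function(p, level) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  ok <- which(ps <= seq_len(m) * level / m)
  rejected <- logical(m)
  if (length(ok)) rejected[o[seq_len(max(ok))]] <- TRUE
  q <- numeric(m)
  q[o] <- pmin(rev(cummin(rev(m * ps / seq_len(m)))), 1)
  list(q = q, rejected = rejected)
}

# two-group phenotype table with matched uniform ages, for null cohorts
makeTwoGroupPheno <- function(nPerGroup, ageRange = c(6, 14)) {
  data.frame(
    id = sprintf("S%04d", seq_len(2 * nPerGroup)),
    diagnosis = factor(rep(c("control", "adhd"), each = nPerGroup),
                       levels = c("control", "adhd")),
    age = runif(2 * nPerGroup, ageRange[1], ageRange[2]),
    sex = factor(sample(c("male", "female"), 2 * nPerGroup, TRUE,
                        prob = c(0.86, 0.14)),
                 levels = c("male", "female")),
    hand = factor(sample(c("R", "L"), 2 * nPerGroup, TRUE,
                         prob = c(0.85, 0.15)),
                  levels = c("R", "L", "A")),
    iq = round(rnorm(2 * nPerGroup, 103, 12)),
    slice_dummy = rbinom(2 * nPerGroup, 1, 0.3),
    med_months = NA_real_,
    sim_cell = factor("below", levels = c("below", "above")))
}
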