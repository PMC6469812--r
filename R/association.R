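# Statistics stage: normality gating, paired side comparisons, Pearson
# correlations with Fisher 95% CIs, partial correlations controlling for a
# covariate (aBMD_neck in the intended use), and multivariate linear models
# with standardized coefficients and adjusted R2. Alpha = 0.05 two-sided
# throughout; no multiple-testing correction is applied (flagged in the
# association-table metadata).

#' Shapiro-Wilk normality gate
#'
#' Classifies a sample as normal or non-normal at alpha from the
#' Shapiro-Wilk test, the gate that selects paired t-test versus Wilcoxon
#' signed-rank downstream.
#'
#' @param x numeric vector, 3 <= n <= 5000, non-constant.
#' @param alpha significance level.
#' @return list with `classification` (`"normal"`/`"non-normal"`), `W`, `p`.
#' @export
normalityGate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3 || n > 5000)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(x) == 0)
    stop("constant vector: Shapiro-Wilk W undefined")
  sw <- stats::shapiro.test(x)
  list(classification = if (sw$p.value >= alpha) "normal" else "non-normal",
       W = unname(sw$statistic), p = sw$p.value)
}

#' Paired comparison of left and right sides
#'
#' Paired t-test when the differences pass the normality gate, Wilcoxon
#' signed-rank otherwise. Identical sides (all differences zero) are a
#' degenerate case reported with p = 1.
#'
#' @param left,right numeric vectors of equal length, paired by subject.
#' @param alpha gate level for the Shapiro-Wilk test on the differences.
#' @return list with `test` (`"paired-t"`, `"wilcoxon-signed-rank"` or
#'   `"degenerate"`), `statistic`, `p`, `meanDifference`, `degenerate` flag.
#' @export
pairedSideTest <- function(left, right, alpha = 0.05) {
  if (length(left) != length(right))
    stop("left and right must have equal length (paired by subject)")
  ok <- !(is.na(left) | is.na(right))
  d <- left[ok] - right[ok]
  if (length(d) < 3) stop("need at least 3 complete pairs")
  if (all(d == 0))
    return(list(test = "degenerate", statistic = NA_real_, p = 1,
                meanDifference = 0, degenerate = TRUE))
  normal <- if (stats::sd(d) == 0) FALSE else
    normalityGate(d, alpha)$classification == "normal"
  if (normal) {
    tt <- stats::t.test(left[ok], right[ok], paired = TRUE)
    list(test = "paired-t", statistic = unname(tt$statistic),
         p = tt$p.value, meanDifference = mean(d), degenerate = FALSE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(left[ok], right[ok],
                                              paired = TRUE))
    list(test = "wilcoxon-signed-rank", statistic = unname(wt$statistic),
         p = wt$p.value, meanDifference = mean(d), degenerate = FALSE)
  }
}

#' Pearson correlation with Fisher confidence interval
#'
#' Product-moment correlation, two-sided p from
#' t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom, and the CI from the
#' Fisher z-transform, atanh(r) +/- z_{1-alpha/2} / sqrt(n-3),
#' back-transformed and clamped to \[-1, 1\].
#'
#' @param x,y numeric vectors; pairwise-complete observations are used.
#' @param alpha two-sided level (default 0.05 for a 95% CI).
#' @return list with `n`, `r`, `p`, `ci` (`c(lo, hi)`).
#' @export
pearsonWithCI <- function(x, y, alpha = 0.05) {
  ok <- !(is.na(x) | is.na(y))
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
    ci <- c(sign(r), sign(r))
    if (n > 3) {
      # CI still defined through the clamp at the boundary
      ci <- sort(pmin(1, pmax(-1, c(sign(r), sign(r)))))
    }
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    ci <- c(NA_real_, NA_real_)
    if (n > 3) {
      z <- atanh(r)
      hw <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
      ci <- pmin(1, pmax(-1, tanh(c(z - hw, z + hw))))
    }
  }
  list(n = n, r = r, p = p, ci = ci)
}

#' Partial correlation controlling for one covariate
#'
#' Pearson correlation between the residuals of `x ~ z` and `y ~ z`
#' (`method = "residual"`, the default) or the closed form
#' (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))
#' (`method = "formula"`); both agree to numerical precision. The p-value
#' uses n - 3 degrees of freedom.
#'
#' @param x,y,z numeric vectors; complete cases are used.
#' @param method `"residual"` or `"formula"`.
#' @return list with `n`, `r`, `p`.
#' @export
partialCorrelation <- function(x, y, z, method = c("residual", "formula")) {
  method <- match.arg(method)
  ok <- !(is.na(x) | is.na(y) | is.na(z))
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations")
  if (stats::sd(z) == 0) stop("constant covariate: residualization undefined")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  rx <- stats::residuals(stats::lm(x ~ z))
  ry <- stats::residuals(stats::lm(y ~ z))
  if (stats::sd(rx) < 1e-12 * stats::sd(x) ||
      stats::sd(ry) < 1e-12 * stats::sd(y))
    stop("covariate collinear with input: zero residual variance")
  r <- if (method == "residual") {
    stats::cor(rx, ry)
  } else {
    rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
    (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  }
  df <- n - 3
  p <- if (abs(r) >= 1 - 1e-15) 0 else {
    tstat <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = df)
  }
  list(n = n, r = r, p = p)
}

#' Multivariate linear model with standardized coefficients
#'
#' Ordinary least squares of a response on one or more predictors. With
#' `standardize = TRUE` (default) all variables are z-scored with the
#' sample SD (n - 1) first, so with a single predictor the standardized
#' coefficient equals the Pearson correlation. Reports per-coefficient
#' two-sided p-values and the adjusted R2
#' = 1 - (1 - R2)(n - 1)/(n - p - 1).
#'
#' @param response numeric vector.
#' @param predictors data.frame or matrix of predictors (named columns).
#' @param standardize z-score all variables before fitting.
#' @return list with `beta` (named, intercept excluded), `se`, `p`, `r2`,
#'   `adjR2`, `n`, `fit` (the underlying `lm`).
#' @export
fitLinearModel <- function(response, predictors, standardize = TRUE) {
  X <- as.data.frame(predictors)
  if (is.null(names(X)) || any(!nzchar(names(X))))
    stop("predictors must have names")
  ok <- stats::complete.cases(X) & !is.na(response)
  X <- X[ok, , drop = FALSE]
  y <- response[ok]
  n <- length(y)
  p <- ncol(X)
  if (n <= p + 1) stop("need n > p + 1 observations")
  if (standardize) {
    y <- as.numeric(scale(y))
    X[] <- lapply(X, function(v) as.numeric(scale(v)))
  }
  qrX <- qr(cbind(1, as.matrix(X)))
  if (qrX$rank < p + 1) {
    bad <- names(X)[qrX$pivot[seq(qrX$rank + 1, p + 1)] - 1L]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  dat <- cbind(.response = y, X)
  fit <- stats::lm(.response ~ ., data = dat)
  sm <- summary(fit)
  cf <- sm$coefficients[-1, , drop = FALSE]
  list(beta = stats::setNames(cf[, 1], rownames(cf)),
       se = stats::setNames(cf[, 2], rownames(cf)),
       p = stats::setNames(cf[, 4], rownames(cf)),
       r2 = sm$r.squared, adjR2 = sm$adj.r.squared,
       n = n, fit = fit)
}

#' Association table between morphometry and outcome columns
#'
#' For every morphometry x outcome pair: the marginal Pearson correlation
#' with 95% CI, and the partial correlation controlling for the covariate.
#' Following the reporting convention of the intended analysis,
#' coefficients are additionally given in masked form (`NA` when the
#' corresponding p >= alpha). Pairwise-complete observations are used and
#' n is reported per cell; when the partial correlation fails (e.g. a
#' degenerate covariate) its columns are `NA` and the marginal part is
#' still reported.
#'
#' @param cohort data.frame with one row per subject.
#' @param morphColumns,outcomeColumns character vectors of column names.
#' @param covariate name of the covariate column (default `"aBMD_neck"`).
#' @param alpha two-sided significance level for the reporting mask.
#' @return data.frame, one row per pair, with attribute
#'   `multipleTestingCorrection = "none"`.
#' @export
buildAssociationTable <- function(cohort,
                                  morphColumns,
                                  outcomeColumns,
                                  covariate = "aBMD_neck",
                                  alpha = 0.05) {
  need <- c(morphColumns, outcomeColumns, covariate)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  rows <- list()
  for (mc in morphColumns) for (oc in outcomeColumns) {
    x <- cohort[[mc]]; y <- cohort[[oc]]; z <- cohort[[covariate]]
    marg <- tryCatch(pearsonWithCI(x, y, alpha), error = function(e) NULL)
    part <- tryCatch(partialCorrelation(x, y, z), error = function(e) NULL)
    rows[[length(rows) + 1L]] <- data.frame(
      morphometry = mc, outcome = oc,
      n = if (is.null(marg)) sum(!(is.na(x) | is.na(y))) else marg$n,
      r = if (is.null(marg)) NA_real_ else marg$r,
      p = if (is.null(marg)) NA_real_ else marg$p,
      ci_lo = if (is.null(marg)) NA_real_ else marg$ci[1],
      ci_hi = if (is.null(marg)) NA_real_ else marg$ci[2],
      r_masked = if (is.null(marg) || marg$p >= alpha) NA_real_ else marg$r,
      partial_r = if (is.null(part)) NA_real_ else part$r,
      partial_p = if (is.null(part)) NA_real_ else part$p,
      partial_r_masked = if (is.null(part) || part$p >= alpha) NA_real_
                         else part$r)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  attr(out, "covariate") <- covariate
  attr(out, "multipleTestingCorrection") <- "none"
  out
}

#' Average left and right outcome columns
#'
#' Documented transform for the single-leg-to-subject analysis: averages
#' paired left/right outcome columns per subject before correlation, so
#' correlations against the average are always computed at matched n.
#'
#' @param cohort data.frame with one row per subject-side.
#' @param subject name of the subject id column.
#' @param side name of the side column (values `"left"`/`"right"`).
#' @param columns outcome columns to average.
#' @return data.frame with one row per subject and the averaged columns.
#' @export
averageSides <- function(cohort, subject = "subject", side = "side",
                         columns) {
  miss <- setdiff(c(subject, side, columns), names(cohort))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  sp <- split(cohort, cohort[[subject]])
  rows <- lapply(sp, function(d) {
    if (nrow(d) != 2L)
      stop("subject ", d[[subject]][1], " does not have exactly two sides")
    out <- d[1, setdiff(names(d), c(side, columns)), drop = FALSE]
    for (cl in columns) out[[cl]] <- mean(d[[cl]])
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
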