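# Published linear coefficients linking the 12-minute distance (km) to
# physiology: the classical Cooper VO2max equation and the MAS/sVT2
# regressions estimated on a mixed trained/recreational cohort.
COOPER_VO2_SLOPE <- 22.351
COOPER_VO2_INTERCEPT <- -11.288
VO2_PER_MAS <- 3.5
MAS_SLOPE <- 5.0629
MAS_INTERCEPT <- 1.5427
SVT2_SLOPE <- 4.6486
SVT2_INTERCEPT <- 0.7878

#' Cooper-test predictions from the 12-minute distance
#'
#' `cooper_vo2max()` evaluates the classical Cooper equation
#' `VO2max = 22.351 d - 11.288` (ml/kg/min, d in km); `cooper_mas()` divides
#' by 3.5 to express it as a maximal aerobic speed (km/h).
#' `predict_mas()` and `predict_svt2()` evaluate the direct linear equations
#' `MAS = 5.0629 d + 1.5427` and `sVT2 = 4.6486 d + 0.7878` (km/h).
#'
#' @param d_km 12-minute distance in km (positive for the Cooper equation).
#' @return Numeric predictions, vectorised.
#' @export
cooper_vo2max <- function(d_km) {
  if (any(d_km <= 0)) stop("`d_km` must be positive", call. = FALSE)
  COOPER_VO2_SLOPE * d_km + COOPER_VO2_INTERCEPT
}

#' @rdname cooper_vo2max
#' @export
cooper_mas <- function(d_km) cooper_vo2max(d_km) / VO2_PER_MAS

#' @rdname cooper_vo2max
#' @export
predict_mas <- function(d_km) MAS_SLOPE * d_km + MAS_INTERCEPT

#' @rdname cooper_vo2max
#' @export
predict_svt2 <- function(d_km) SVT2_SLOPE * d_km + SVT2_INTERCEPT

#' Fit a distance-to-performance linear model with LOOCV
#'
#' Ordinary least squares of a performance variable on the reference
#' distance (optionally plus additional predictors), with leave-one-out
#' cross-validated determination coefficient (`R^2 = 1 - SSE/SST` over
#' held-out predictions) and RMSE.
#'
#' @param d Predictor vector (e.g. distance in km), or a matrix/data frame
#'   of predictors.
#' @param y Response (km/h).
#' @return A list with `coefficients`, `r2`, `rmse`, `cv_predictions`.
#' @export
fit_distance_model <- function(d, y) {
  X <- as.matrix(d)
  n <- nrow(X)
  if (n != length(y)) stop("lengths differ", call. = FALSE)
  if (any(apply(X, 2, sd) == 0))
    stop("degenerate predictor (zero variance)", call. = FALSE)
  dat <- data.frame(y = y, X)
  fit <- lm(y ~ ., data = dat)
  pred <- vapply(seq_len(n), function(i) {
    f <- lm(y ~ ., data = dat[-i, , drop = FALSE])
    unname(predict(f, newdata = dat[i, , drop = FALSE]))
  }, numeric(1))
  list(coefficients = coef(fit),
       r2 = 1 - sum((pred - y)^2) / sum((y - mean(y))^2),
       rmse = sqrt(mean((pred - y)^2)),
       cv_predictions = pred)
}

#' Bland-Altman agreement statistics
#'
#' Bias (mean difference `a - b`) and 95% limits of agreement
#' `bias +/- 1.96 sd(a - b)`.
#'
#' @param a,b Paired measurements.
#' @return Named numeric `c(bias, loa_lower, loa_upper)`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("lengths differ", call. = FALSE)
  d <- a - b
  s <- if (length(d) > 1) sd(d) else 0
  c(bias = mean(d), loa_lower = mean(d) - 1.96 * s,
    loa_upper = mean(d) + 1.96 * s)
}
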