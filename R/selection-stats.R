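#' Z-score normalization across participants
#'
#' Centres and scales every column to mean 0, sample (n-1) sd 1.
#' Zero-variance columns become all-zero and are listed in the
#' `zero_variance` attribute.
#'
#' @param mat Numeric matrix, participants x metrics.
#' @return The normalized matrix with attributes `center`, `scale`,
#'   `zero_variance`.
#' @export
zscore <- function(mat) {
  mat <- as.matrix(mat)
  mu <- colMeans(mat)
  s <- apply(mat, 2, sd)
  zv <- !is.finite(s) | s == 0
  s_safe <- ifelse(zv, 1, s)
  out <- sweep(sweep(mat, 2, mu), 2, s_safe, "/")
  out[, zv] <- 0
  attr(out, "center") <- mu
  attr(out, "scale") <- s
  attr(out, "zero_variance") <- colnames(mat)[zv]
  out
}

# Duration rank of a segment for the multicollinearity tie-break: longer
# segments first; of the two one-minute segments the earlier (start) wins;
# the derived delta segment ranks last.
segment_rank <- function(segment) {
  match(segment, c("t", "sy", "s", "e", "d"))
}

#' Prune multicollinear metrics
#'
#' Greedy pass over metric pairs with `|r| > r_thresh` (Pearson, across
#' participants): within a pair the metric computed over the longer time
#' segment is retained (duration order t > sy > s > e > d; metrics from the
#' same segment keep the earlier column). Deterministic given column order.
#'
#' @param mat Numeric matrix, participants x metrics, with canonical metric
#'   names as column names.
#' @param r_thresh Absolute-correlation threshold above which a pair is
#'   considered collinear.
#' @return Character vector of retained metric names.
#' @export
prune_multicollinear <- function(mat, r_thresh = 0.95) {
  mat <- as.matrix(mat)
  nms <- colnames(mat)
  seg <- parse_metric_name(nms)$segment
  rank <- segment_rank(seg)
  cm <- suppressWarnings(abs(cor(mat)))
  cm[!is.finite(cm)] <- 0
  dropped <- rep(FALSE, ncol(mat))
  p <- ncol(mat)
  for (i in seq_len(p - 1)) {
    if (dropped[i]) next
    for (j in (i + 1):p) {
      if (dropped[j] || cm[i, j] <= r_thresh) next
      # keep the longer-segment metric; ties keep the earlier column (i)
      if (rank[j] < rank[i]) dropped[i] <- TRUE else dropped[j] <- TRUE
      if (dropped[i]) break
    }
  }
  nms[!dropped]
}

#' Filter metrics by correlation with a performance variable
#'
#' Retains metrics whose absolute Pearson correlation with `y` is at least
#' `r_min`. The absolute value is used so that metrics contributing
#' negatively to performance survive the filter.
#'
#' @param mat Numeric matrix, participants x metrics.
#' @param y Performance variable (km/h), one value per participant.
#' @param r_min Minimum `|r|`.
#' @return Character vector of retained metric names.
#' @export
filter_by_target <- function(mat, y, r_min = 0.3) {
  mat <- as.matrix(mat)
  r <- suppressWarnings(as.numeric(cor(mat, y)))
  r[!is.finite(r)] <- 0
  colnames(mat)[abs(r) >= r_min]
}

#' LASSO metric selection with leave-one-out cross-validation
#'
#' Fits the LASSO path on the (normalized) metric matrix, evaluates each
#' penalty by exhaustive leave-one-out cross-validation, and applies the
#' one-standard-error rule: the largest penalty (fewest nonzero
#' coefficients) whose CV mean-squared error is within one standard error
#' of the minimum. Among the nonzero coefficients, those with an absolute
#' weight below `prune_frac` of the total absolute weight are then removed.
#' Fit quality (cross-validated determination coefficient
#' `R^2 = 1 - SSE/SST` over held-out predictions, and RMSE in the units of
#' `y`) is reported from the unpruned chosen-penalty LOOCV predictions; an
#' uninformative model can therefore report a (slightly) negative `R^2`.
#'
#' @param mat Numeric matrix, participants x metrics (z-scored).
#' @param y Performance variable, one value per participant.
#' @param prune_frac Relative-weight pruning threshold.
#' @return An object of class `lasso_fit`: list with `coefficients` (named,
#'   nonzero, on the normalized scale), `selected` (names surviving the 5%
#'   pruning), `lambda`, `r2`, `rmse`, `cv_predictions`.
#' @export
lasso_select <- function(mat, y, prune_frac = 0.05) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (n < 5) stop("need at least 5 participants", call. = FALSE)
  if (sd(y) == 0) stop("degenerate performance variable (zero variance)",
                       call. = FALSE)
  if (ncol(mat) < 2)
    stop("need at least two candidate metrics", call. = FALSE)
  cv <- glmnet::cv.glmnet(mat, y, family = "gaussian", alpha = 1,
                          foldid = seq_len(n), grouped = FALSE, keep = TRUE,
                          standardize = FALSE)
  ilam <- match(cv$lambda.1se, cv$lambda)
  beta <- coef(cv$glmnet.fit, s = cv$lambda.1se)
  b <- as.numeric(beta)[-1]
  names(b) <- rownames(beta)[-1]
  nz <- b[b != 0]
  tot <- sum(abs(nz))
  selected <- if (tot > 0) names(nz)[abs(nz) >= prune_frac * tot]
              else character(0)
  pred <- cv$fit.preval[, ilam]
  r2 <- 1 - sum((pred - y)^2) / sum((y - mean(y))^2)
  structure(
    list(coefficients = nz, selected = selected, lambda = cv$lambda.1se,
         r2 = r2, rmse = sqrt(mean((pred - y)^2)), cv_predictions = pred,
         n = n),
    class = "lasso_fit"
  )
}

#' Relative contribution of metric categories to a LASSO model
#'
#' Sums the absolute coefficients of the retained metrics within each
#' category and expresses each category as a percentage of the total; the
#' shares sum to 100 whenever any coefficient is nonzero.
#'
#' @param fit A [lasso_select()] result.
#' @param categories Named character vector mapping metric name to category;
#'   by default derived from the canonical metric names.
#' @return Named numeric vector of percentage shares.
#' @export
category_contributions <- function(fit, categories = NULL) {
  stopifnot(inherits(fit, "lasso_fit"))
  b <- fit$coefficients[fit$selected]
  if (!length(b)) return(stats::setNames(numeric(0), character(0)))
  if (is.null(categories)) {
    p <- parse_metric_name(names(b))
    categories <- stats::setNames(categorize(p$feature, p$parameter, p$segment),
                                  names(b))
  }
  shares <- tapply(abs(b), categories[names(b)], sum)
  stats::setNames(as.numeric(100 * shares / sum(shares)), names(shares))
}

#' Welch comparison of top and bottom performers
#'
#' Splits the cohort into the `k` highest and `k` lowest performers by `y`
#' and tests every metric for a group difference with Welch's
#' unequal-variance t-test (two-sided). Effect size is Cohen's d with the
#' pooled standard deviation. P-values are uncorrected for multiple testing
#' (set `adjust = "BH"` for Benjamini-Hochberg).
#'
#' @param mat Numeric matrix, participants x metrics.
#' @param y Performance variable.
#' @param k Group size.
#' @param alpha Significance level.
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return A data frame of class `group_comparison`: `metric`, `t`, `p`,
#'   `cohens_d`, `significant`; group indices attached as attributes
#'   `top`/`bottom`.
#' @export
welch_compare <- function(mat, y, k = 10, alpha = 0.05, adjust = "none") {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (2 * k > n) stop("`k` too large: groups must be disjoint", call. = FALSE)
  ord <- order(y, decreasing = TRUE)
  top <- ord[seq_len(k)]
  bottom <- ord[(n - k + 1):n]
  res <- apply(mat, 2, function(col) {
    a <- col[top]; b <- col[bottom]
    if (sd(a) == 0 && sd(b) == 0) {
      c(t = 0, p = 1, d = 0)
    } else {
      tt <- t.test(a, b, var.equal = FALSE)
      sp <- sqrt(((k - 1) * var(a) + (k - 1) * var(b)) / (2 * k - 2))
      c(t = unname(tt$statistic), p = tt$p.value,
        d = if (sp > 0) (mean(a) - mean(b)) / sp else 0)
    }
  })
  p <- if (adjust == "none") res["p", ] else stats::p.adjust(res["p", ], adjust)
  out <- data.frame(metric = colnames(mat), t = res["t", ], p = p,
                    cohens_d = res["d", ], significant = p < alpha,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "top") <- top
  attr(out, "bottom") <- bottom
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Build the biomechanical profile
#'
#' For each performance variable, the selected set is the union of the
#' LASSO-selected metrics and those with a significant group difference;
#' the profile is the intersection of the three per-variable sets,
#' annotated with categories. An empty intersection raises a warning.
#'
#' @param selections Named list (one element per performance variable),
#'   each a list with components `lasso` (a `lasso_fit`) and `welch`
#'   (a `group_comparison`).
#' @param zmat Optional z-scored cohort matrix; the profile columns are
#'   attached for display.
#' @return An object of class `biomech_profile`: list with `metrics` (data
#'   frame `name`, `category`), `per_variable` (the union sets) and
#'   `values` (participants x profile metrics, or `NULL`).
#' @export
build_profile <- function(selections, zmat = NULL) {
  stopifnot(length(selections) >= 1)
  sets <- lapply(selections, function(s) {
    union(s$lasso$selected, s$welch$metric[s$welch$significant])
  })
  prof <- Reduce(intersect, sets)
  if (!length(prof))
    warning("profile is empty: no metric is selected for every performance variable",
            call. = FALSE)
  p <- if (length(prof)) parse_metric_name(prof) else
    data.frame(feature = character(0), parameter = character(0),
               segment = character(0))
  metrics <- data.frame(
    name = prof,
    category = if (length(prof))
      categorize(p$feature, p$parameter, p$segment) else character(0),
    stringsAsFactors = FALSE)
  values <- if (!is.null(zmat) && length(prof))
    zmat[, prof, drop = FALSE] else NULL
  structure(list(metrics = metrics, per_variable = sets, values = values),
            class = "biomech_profile")
}

#' Run the full metric-selection pipeline for one performance variable
#'
#' Chains z-scoring, multicollinearity pruning (cohort-wide), correlation
#' filtering against the target, LOOCV-LASSO with the one-SE rule and 5%
#' pruning, category contributions and the Welch top/bottom comparison.
#'
#' @param mat Raw cohort metric matrix (participants x metrics).
#' @param y Performance variable.
#' @param r_thresh Multicollinearity threshold.
#' @param r_min Target-correlation threshold.
#' @param k,alpha Welch group size and significance level.
#' @return A list with `retained` (post-collinearity names), `filtered`
#'   (post-correlation names), `lasso`, `welch`, `contributions`, and the
#'   funnel counts in `counts`.
#' @export
select_metrics <- function(mat, y, r_thresh = 0.95, r_min = 0.3,
                           k = 10, alpha = 0.05) {
  z <- zscore(mat)
  retained <- prune_multicollinear(z, r_thresh)
  z_ret <- z[, retained, drop = FALSE]
  filtered <- filter_by_target(z_ret, y, r_min)
  if (length(filtered) < 2)
    stop("fewer than two metrics survive the correlation filter",
         call. = FALSE)
  fit <- lasso_select(z_ret[, filtered, drop = FALSE], y)
  wl <- welch_compare(z_ret, y, k = k, alpha = alpha)
  list(retained = retained, filtered = filtered, lasso = fit, welch = wl,
       contributions = category_contributions(fit),
       counts = c(total = ncol(mat), collinearity = length(retained),
                  correlation = length(filtered),
                  lasso = length(fit$selected)))
}
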