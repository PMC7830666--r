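rr_feature_names <- function() {
  paste0("glle_", c("0.1", "0.5", "1", "2", "3", "4", "5"))
}

#' GLLE feature vector of an R-R interval series
#'
#' Runs [glle_spectrum()] over the 7-point R-R grid
#' \{0.1, 0.5, 1, 2, 3, 4, 5\} and returns the fitted exponents multiplied
#' by 100 — the scale on which the logistic scorers operate (raw exponents
#' for inter-beat series are of order 0.1/beat, so the rescaling keeps the
#' odds ratios interpretable).
#'
#' @param ts an [mc_series] or numeric vector of R-R intervals.
#' @param params an [embedding_params]; `NULL` estimates them (correlation
#'   integral delay, Cao dimension).
#' @param subject optional subject identifier.
#' @param group optional group label (`"hs"`, `"chf"`, `"af"`, ...).
#' @param ... forwarded to [glle_spectrum()].
#'
#' @return Named numeric vector of the 7 features (class `mc_features`)
#'   with attributes `subject`, `group`, `width` (spectrum width, raw
#'   scale) and `spectrum`.
#' @examples
#' s <- simulate_system("logistic", n_samples = 1500, seed = 1)
#' extract_features(s, embedding_params(2, 1))["glle_2"]  # about 69
#' @export
extract_features <- function(ts, params = NULL, subject = NULL,
                             group = NULL, ...) {
  sp <- glle_spectrum(ts, params = params, p_grid = default_p_grid("rr"),
                      delay_method = "ci", ...)
  fv <- 100 * sp$glle
  names(fv) <- rr_feature_names()
  structure(fv, subject = subject, group = group,
            width = attr(sp, "width"), spectrum = sp,
            class = "mc_features")
}

#' Logistic scorer with fixed coefficients
#'
#' A linear logistic decision rule over named GLLE features:
#' \eqn{P = 1 / (1 + e^{-(b_0 + \sum b_k f_k)})}, labelled positive when
#' `P` strictly exceeds the threshold.
#'
#' @param intercept intercept \eqn{b_0}.
#' @param coefficients named numeric vector; names must be a subset of the
#'   feature names returned by [extract_features()].
#' @param threshold decision threshold in (0, 1).
#' @param positive,negative labels attached to the two decisions.
#'
#' @return An object of class `mc_scorer`.
#' @examples
#' sc <- logistic_scorer(0, c(glle_2 = 1), threshold = 0.5)
#' score(sc, c(glle_2 = 0))$probability  # 0.5
#' @export
logistic_scorer <- function(intercept, coefficients, threshold = 0.5,
                            positive = "positive", negative = "negative") {
  if (is.null(names(coefficients)) || any(names(coefficients) == ""))
    stop("'coefficients' must be a fully named vector", call. = FALSE)
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)", call. = FALSE)
  structure(list(intercept = as.numeric(intercept),
                 coefficients = coefficients,
                 threshold = threshold,
                 positive = positive, negative = negative),
            class = "mc_scorer")
}

#' @export
print.mc_scorer <- function(x, ...) {
  cat(sprintf("<mc_scorer> P(%s) = logistic(%.4g %s), threshold > %g\n",
              x$positive, x$intercept,
              paste(sprintf("%+.4g*%s", x$coefficients,
                            names(x$coefficients)), collapse = " "),
              x$threshold))
  invisible(x)
}

#' Score a feature vector with a logistic scorer
#'
#' @param scorer an `mc_scorer`.
#' @param features named numeric vector holding at least the scorer's
#'   features (on the x100 scale of [extract_features()]).
#'
#' @return A list with `probability` and `label` (positive only when the
#'   probability strictly exceeds the threshold).
#' @examples
#' score(model1_scorer(), setNames(numeric(7), rr_feature_names()))
#' @export
score <- function(scorer, features) {
  stopifnot(inherits(scorer, "mc_scorer"))
  need <- names(scorer$coefficients)
  missing <- setdiff(need, names(features))
  if (length(missing))
    stop("missing feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  eta <- scorer$intercept +
    sum(scorer$coefficients * as.numeric(features[need]))
  p <- 1 / (1 + exp(-eta))
  list(probability = p,
       label = if (p > scorer$threshold) scorer$positive else scorer$negative)
}

#' Pre-fitted scorer: healthy versus pathology (model-1)
#'
#' The five-factor logistic rule for the probability that an R-R series
#' belongs to the pathology (chf or af) group rather than the healthy
#' group, with decision threshold 0.46:
#' \deqn{\ln\frac{P}{1-P} = -0.45 + 1.02\,GLLE_{0.1} - 5.18\,GLLE_{0.5}
#'   - 7.09\,GLLE_{1} + 105.39\,GLLE_{4} - 95.23\,GLLE_{5}.}
#'
#' @return An `mc_scorer`.
#' @examples
#' model1_scorer()
#' @export
model1_scorer <- function() {
  logistic_scorer(
    intercept = -0.45,
    coefficients = c(glle_0.1 = 1.02, glle_0.5 = -5.18, glle_1 = -7.09,
                     glle_4 = 105.39, glle_5 = -95.23),
    threshold = 0.46,
    positive = "pathology", negative = "healthy")
}

#' Pre-fitted scorer: atrial fibrillation versus heart failure (model-2)
#'
#' The three-factor logistic rule for the probability that a pathological
#' R-R series belongs to the atrial fibrillation group rather than the
#' congestive heart failure group, with decision threshold 0.48:
#' \deqn{\ln\frac{P}{1-P} = 3.34 - 4.851\,GLLE_{1} + 75.71\,GLLE_{4}
#'   - 70.84\,GLLE_{5}.}
#'
#' @return An `mc_scorer`.
#' @examples
#' model2_scorer()
#' @export
model2_scorer <- function() {
  logistic_scorer(
    intercept = 3.34,
    coefficients = c(glle_1 = -4.851, glle_4 = 75.71, glle_5 = -70.84),
    threshold = 0.48,
    positive = "af", negative = "chf")
}

#' Probability of pathology from GLLE features (model-1)
#'
#' @param fv named feature vector from [extract_features()].
#' @return As [score()]: `probability` and `label` (`"pathology"` /
#'   `"healthy"`).
#' @examples
#' score_model1(setNames(numeric(7), rr_feature_names()))
#' @export
score_model1 <- function(fv) score(model1_scorer(), fv)

#' Probability of atrial fibrillation from GLLE features (model-2)
#'
#' @param fv named feature vector from [extract_features()].
#' @return As [score()]: `probability` and `label` (`"af"` / `"chf"`).
#' @examples
#' score_model2(setNames(numeric(7), rr_feature_names()))
#' @export
score_model2 <- function(fv) score(model2_scorer(), fv)

#' Names of the seven GLLE features
#'
#' @return Character vector `glle_0.1 ... glle_5`, the fixed, name-addressable
#'   feature order used by the scorers.
#' @examples
#' rr_feature_names()
#' @export
rr_feature_names <- rr_feature_names

#' Stepwise logistic regression over GLLE features
#'
#' Forward selection with backward elimination after each step (entry
#' `p < entry_p`, stay `p < stay_p`), the conventional
#' stepwise-variable-selection recipe.  Term p-values come from
#' likelihood-ratio tests rather than Wald statistics, which collapse
#' under near-separation (the Hauck-Donner effect).  Constant features
#' are excluded up front.  If the final maximum-likelihood fit shows
#' complete separation, a ridge-penalised fit (glmnet, small penalty)
#' over the selected features is returned instead, with a warning.
#'
#' @param features data frame or matrix of candidate predictors.
#' @param labels binary outcome: logical, 0/1, or a two-level factor whose
#'   second level is the positive class.
#' @param entry_p,stay_p Wald p-value thresholds (defaults 0.05 / 0.10).
#' @param threshold decision threshold stored in the returned scorer.
#'
#' @return An `mc_scorer` with attributes `selected` (feature names) and
#'   `fit` (the underlying model object).
#' @examples
#' set.seed(1)
#' x <- data.frame(a = rnorm(200), b = rnorm(200))
#' y <- rbinom(200, 1, plogis(2 * x$a))
#' names(fit_stepwise_logistic(x, y)$coefficients)
#' @export
fit_stepwise_logistic <- function(features, labels, entry_p = 0.05,
                                  stay_p = 0.10, threshold = 0.5) {
  features <- as.data.frame(features)
  if (nrow(features) < 10L) stop("need at least 10 cases", call. = FALSE)
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in 'labels'", call. = FALSE)
  keep <- vapply(features, function(col) sd(col) > 0, logical(1))
  features <- features[, keep, drop = FALSE]
  cand <- names(features)
  sel <- character(0)

  fit_set <- function(vars) {
    dat <- if (length(vars))
      cbind(features[, vars, drop = FALSE], .y = y)
    else data.frame(.y = y)
    suppressWarnings(glm(.y ~ ., data = dat, family = binomial()))
  }
  # likelihood-ratio p-value for the terms distinguishing two nested fits
  lr_p <- function(small, big, df = 1L) {
    stats::pchisq(small$deviance - big$deviance, df = df,
                  lower.tail = FALSE)
  }

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > 2L * length(cand) + 2L) break   # guard add/drop cycling
    changed <- FALSE
    # forward: best candidate by likelihood-ratio p
    remaining <- setdiff(cand, sel)
    if (length(remaining)) {
      base_fit <- fit_set(sel)
      pvals <- vapply(remaining, function(v)
        lr_p(base_fit, fit_set(c(sel, v))), numeric(1))
      if (any(is.finite(pvals)) && min(pvals, na.rm = TRUE) < entry_p) {
        sel <- c(sel, remaining[which.min(pvals)])
        changed <- TRUE
      }
    }
    # backward: drop the weakest survivor by likelihood-ratio p
    if (length(sel) > 1L) {
      full_fit <- fit_set(sel)
      pvals <- vapply(sel, function(v)
        lr_p(fit_set(setdiff(sel, v)), full_fit), numeric(1))
      if (max(pvals, na.rm = TRUE) > stay_p) {
        sel <- setdiff(sel, sel[which.max(pvals)])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (!length(sel))
    stop("no feature met the entry criterion p < ", entry_p, call. = FALSE)

  fit <- fit_set(sel)
  separated <- !fit$converged ||
    (any(fit$fitted.values > 1 - 1e-8) && any(fit$fitted.values < 1e-8))
  if (separated && requireNamespace("glmnet", quietly = TRUE)) {
    warning("separation detected; returning a ridge-penalised fit",
            call. = FALSE)
    xm <- as.matrix(features[, sel, drop = FALSE])
    if (ncol(xm) == 1L) xm <- cbind(xm, 0)  # glmnet needs >= 2 columns
    gfit <- glmnet::glmnet(xm, y, family = "binomial", alpha = 0,
                           lambda = 1e-3)
    cf <- as.numeric(coef(gfit))
    names(cf) <- rownames(coef(gfit))
    b <- cf[sel]
    out <- logistic_scorer(cf["(Intercept)"], b, threshold = threshold)
    attr(out, "selected") <- sel
    attr(out, "fit") <- gfit
    return(out)
  }
  cf <- coef(fit)
  b <- cf[-1L]
  names(b) <- sub("^`(.*)`$", "\\1", names(b))
  out <- logistic_scorer(cf[["(Intercept)"]], b, threshold = threshold)
  attr(out, "selected") <- sel
  attr(out, "fit") <- fit
  out
}

#' Confusion counts
#'
#' @param TP,FP,TN,FN non-negative integer counts.
#' @return A `confusion_counts` list.
#' @examples
#' confusion_counts(TP = 19, FP = 4, TN = 40, FN = 6)
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  v <- c(TP = TP, FP = FP, TN = TN, FN = FN)
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(v) == 0) stop("total count must be positive", call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' a balanced summary of a binary confusion matrix in `[-1, 1]`; defined
#' as 0 when any marginal is empty (the all-one-class degenerate case).
#'
#' @param conf a [confusion_counts] object.
#' @return Scalar in `[-1, 1]`.
#' @examples
#' mcc(confusion_counts(TP = 19, FP = 4, TN = 40, FN = 6))  # 0.68
#' @export
mcc <- function(conf) {
  stopifnot(inherits(conf, "confusion_counts"))
  tp <- as.numeric(conf$TP); fp <- as.numeric(conf$FP)
  tn <- as.numeric(conf$TN); fn <- as.numeric(conf$FN)
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom2 == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom2)
}

#' Precision-recall curve and area under it
#'
#' Sweeps every score threshold, records (recall, precision), and
#' integrates precision over recall by the trapezoidal rule.  Preferred
#' over ROC for imbalanced classes, where precision tracks the practically
#' relevant false-alarm burden.  The associated criterion is the threshold
#' maximising F1 (configurable).
#'
#' @param scores numeric scores, higher meaning more positive.
#' @param labels binary labels: logical, 0/1, or a two-level factor whose
#'   second level is positive.
#' @param n_boot if `> 0`, a stratified bootstrap of this many resamples
#'   yields a percentile confidence interval on the AUC.
#' @param conf_level confidence level for the bootstrap interval.
#' @param seed seed for the bootstrap resampling.
#'
#' @return A list of class `mc_prc` with `curve` (data frame of
#'   `threshold`, `recall`, `precision`), `auc`, `criterion` (F1-optimal
#'   threshold) and optionally `auc_ci`.
#' @examples
#' prc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc  # 1
#' @export
prc_auc <- function(scores, labels, n_boot = 0L, conf_level = 0.95,
                    seed = NULL) {
  y <- if (is.factor(labels)) as.integer(labels) - 1L else as.integer(labels)
  if (length(unique(y)) < 2L)
    stop("both classes must be present in 'labels'", call. = FALSE)
  stopifnot(length(scores) == length(y))

  curve_of <- function(s, yy) {
    thr <- sort(unique(s), decreasing = TRUE)
    n_pos <- sum(yy == 1L)
    pts <- vapply(thr, function(t) {
      pred <- s >= t
      tp <- sum(pred & yy == 1L)
      fp <- sum(pred & yy == 0L)
      c(recall = tp / n_pos,
        precision = if (tp + fp > 0) tp / (tp + fp) else 1)
    }, numeric(2))
    data.frame(threshold = thr, recall = pts["recall", ],
               precision = pts["precision", ])
  }
  auc_of <- function(cv) {
    r <- c(0, cv$recall)
    p <- c(cv$precision[1L], cv$precision)
    o <- order(r)
    sum(diff(r[o]) * (head(p[o], -1) + tail(p[o], -1)) / 2)
  }

  cv <- curve_of(scores, y)
  auc <- auc_of(cv)
  f1 <- with(cv, 2 * precision * recall / pmax(precision + recall, 1e-12))
  criterion <- cv$threshold[which.max(f1)]
  out <- list(curve = cv, auc = auc, criterion = criterion)
  if (n_boot > 0L) {
    pos <- which(y == 1L); neg <- which(y == 0L)
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      auc_of(curve_of(scores[idx], y[idx]))
    }, numeric(1)))
    a <- (1 - conf_level) / 2
    out$auc_ci <- quantile(boots, c(a, 1 - a), names = FALSE)
  }
  structure(out, class = "mc_prc")
}

#' @export
print.mc_prc <- function(x, ...) {
  cat(sprintf("<mc_prc> AUC = %.3f, F1-optimal threshold = %.3f\n",
              x$auc, x$criterion))
  if (!is.null(x$auc_ci))
    cat(sprintf("  bootstrap CI: [%.3f, %.3f]\n", x$auc_ci[1], x$auc_ci[2]))
  invisible(x)
}
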