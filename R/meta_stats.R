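#' Pearson correlation with Student-t p-value
#'
#' Product-moment correlation between two rate vectors, with two-sided
#' significance from t = r * sqrt((n-2) / (1-r^2)) on n - 2 degrees of
#' freedom.
#'
#' @param xs,ys numeric vectors of equal length, n >= 3, each with
#'   non-zero variance.
#' @return list with fields \code{r}, \code{t}, \code{df}, \code{p},
#'   \code{n}; class \code{"correlation_result"}.
#' @export
pearson_with_p <- function(xs, ys) {
  if (length(xs) != length(ys)) stop("xs and ys must have the same length")
  n <- length(xs)
  if (n < 3L) stop("correlation needs at least 3 pairs")
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    stop("correlation undefined: a variable has zero variance")
  }
  r <- sum((xs - mean(xs)) * (ys - mean(ys))) /
    sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
  r <- max(-1, min(1, r))
  df <- n - 2L
  if (abs(r) == 1) {
    t <- Inf * sign(r); p <- 0
  } else {
    t <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df)
  }
  structure(list(r = r, t = t, df = df, p = p, n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, t = %.3f on %d df, p = %.4g)\n",
              x$r, x$n, x$t, x$df, x$p))
  invisible(x)
}

#' Perpendicular (orthogonal) trend line
#'
#' Fits the line minimizing the summed squared perpendicular distances to
#' the points (total least squares with equal error variance in both
#' axes), the natural trend line when neither variable is the "response".
#' The closed-form slope on centered second moments is
#' \deqn{b = (s_{yy} - s_{xx} + \sqrt{(s_{yy} - s_{xx})^2 + 4 s_{xy}^2}) /
#'   (2 s_{xy}).}
#' Swapping the axes yields the reciprocal slope. 0.95 confidence and
#' prediction band half-widths are computed by a seeded pairs bootstrap:
#' the confidence band from the bootstrap spread of the fitted line, the
#' prediction band from fitted values plus resampled vertical residuals.
#'
#' @param xs,ys numeric vectors, n >= 3, not all points coincident.
#' @param level band level (default 0.95).
#' @param at abscissae at which band half-widths are evaluated (default
#'   the sorted distinct \code{xs}).
#' @param nboot bootstrap resamples (default 2000).
#' @param seed optional integer seed for the bootstrap.
#' @return list with fields \code{slope}, \code{intercept},
#'   \code{vertical} (a vertical best-fit line is reported explicitly,
#'   with \code{x0} and \code{slope = Inf}), \code{perp_rss} (summed
#'   squared perpendicular residuals), \code{at},
#'   \code{conf_halfwidth}, \code{pred_halfwidth}, \code{n},
#'   \code{level}; class \code{"perp_fit"}.
#' @export
perpendicular_fit <- function(xs, ys, level = 0.95, at = NULL,
                              nboot = 2000L, seed = NULL) {
  if (length(xs) != length(ys)) stop("xs and ys must have the same length")
  n <- length(xs)
  if (n < 3L) stop("perpendicular fit needs at least 3 points")
  if (all(xs == xs[1]) && all(ys == ys[1])) {
    stop("all points coincident: no trend line")
  }
  core <- perp_fit_core(xs, ys)
  if (is.null(at)) at <- sort(unique(xs))
  conf <- pred <- rep(NA_real_, length(at))
  if (!core$vertical && nboot > 0L) {
    alpha <- (1 - level) / 2
    resid <- ys - (core$intercept + core$slope * xs)
    fits <- matrix(NA_real_, nrow = nboot, ncol = length(at))
    preds <- matrix(NA_real_, nrow = nboot, ncol = length(at))
    with_seed(seed, {
      for (b in seq_len(nboot)) {
        idx <- sample.int(n, n, replace = TRUE)
        cb <- perp_fit_core(xs[idx], ys[idx])
        if (cb$vertical) next
        fb <- cb$intercept + cb$slope * at
        fits[b, ] <- fb
        preds[b, ] <- fb + sample(resid, length(at), replace = TRUE)
      }
    })
    qhw <- function(m) {
      apply(m, 2L, function(col) {
        col <- col[!is.na(col)]
        if (length(col) < 2L) return(NA_real_)
        diff(stats::quantile(col, c(alpha, 1 - alpha), names = FALSE)) / 2
      })
    }
    conf <- qhw(fits)
    pred <- qhw(preds)
  }
  structure(c(core, list(at = at, conf_halfwidth = conf,
                         pred_halfwidth = pred, n = n, level = level,
                         nboot = nboot)),
            class = "perp_fit")
}

perp_fit_core <- function(xs, ys) {
  mx <- mean(xs); my <- mean(ys)
  sxx <- sum((xs - mx)^2); syy <- sum((ys - my)^2)
  sxy <- sum((xs - mx) * (ys - my))
  if (sxy == 0) {
    if (syy > sxx) {
      return(list(slope = Inf, intercept = NA_real_, x0 = mx,
                  vertical = TRUE,
                  perp_rss = sum((xs - mx)^2)))
    }
    b <- 0
  } else {
    b <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  }
  a <- my - b * mx
  d <- (ys - a - b * xs) / sqrt(1 + b^2)
  list(slope = b, intercept = a, x0 = NA_real_, vertical = FALSE,
       perp_rss = sum(d^2))
}

#' @export
print.perp_fit <- function(x, ...) {
  if (x$vertical) {
    cat(sprintf("Perpendicular trend line: vertical at x = %.4f (n = %d)\n",
                x$x0, x$n))
  } else {
    cat(sprintf(
      "Perpendicular trend line: y = %.4f + %.4f x (n = %d, perp RSS %.4g)\n",
      x$intercept, x$slope, x$n, x$perp_rss))
  }
  invisible(x)
}

#' "n-1" chi-squared test for two independent proportions
#'
#' The Pearson chi-squared statistic of the 2x2 responder table multiplied
#' by (N-1)/N, N the total count -- the recommended small-sample variant
#' for comparing two proportions. No continuity correction is applied.
#' When a table margin is zero (e.g. both rates are 0) the comparison is
#' vacuous and p = 1 by convention.
#'
#' @param p1,p2 \code{rate_point}s, or length-2 numeric vectors
#'   \code{c(responders, total)}.
#' @return list with fields \code{statistic}, \code{df} (1), \code{p},
#'   \code{N}; class \code{"chi2_nminus1"}.
#' @export
chi2_nminus1 <- function(p1, p2) {
  cnt <- function(p) {
    if (inherits(p, "rate_point")) c(p$numerator, p$denominator)
    else if (is.numeric(p) && length(p) == 2L) c(p[1], p[2])
    else stop("supply a rate_point or c(responders, total)")
  }
  u <- as.double(cnt(p1)); v <- as.double(cnt(p2))
  a <- u[1]; b <- u[2] - u[1]; c_ <- v[1]; d <- v[2] - v[1]
  N <- a + b + c_ + d
  marg <- c(a + b, c_ + d, a + c_, b + d)
  if (any(marg == 0)) {
    out <- list(statistic = 0, df = 1L, p = 1, N = N, degenerate = TRUE)
  } else {
    chi2 <- N * (a * d - b * c_)^2 / prod(marg)
    stat <- chi2 * (N - 1) / N
    out <- list(statistic = stat, df = 1L,
                p = stats::pchisq(stat, 1L, lower.tail = FALSE),
                N = N, degenerate = FALSE)
  }
  structure(out, class = "chi2_nminus1")
}

#' @export
print.chi2_nminus1 <- function(x, ...) {
  cat(sprintf("\"n-1\" chi-squared: statistic = %.4f (1 df, N = %d), p = %.4g\n",
              x$statistic, x$N, x$p))
  invisible(x)
}

validate_pairs <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  need <- c("measured_responders", "measured_total",
            "predicted_numerator", "predicted_denominator")
  miss <- setdiff(need, names(pairs))
  if (length(miss)) stop("data pairs need columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(pairs) == 0L) stop("no data pairs supplied")
  if (any(pairs$measured_total < 1) || any(pairs$predicted_denominator < 1)) {
    stop("totals must be >= 1")
  }
  if (any(pairs$measured_responders > pairs$measured_total) ||
      any(pairs$predicted_numerator > pairs$predicted_denominator)) {
    stop("responders exceed totals in the data pairs")
  }
  pairs$measured_rate <- pairs$measured_responders / pairs$measured_total
  pairs$predicted_rate <- pairs$predicted_numerator / pairs$predicted_denominator
  pairs
}

#' Fraction of measured/predicted pairs that match
#'
#' Pairwise agreement between measured trial rates and predicted in
#' silico rates, in either of two senses: \code{"p_gt_0.05"} -- no
#' significant difference by the "n-1" chi-squared test (p > 0.05) --
#' or \code{"within_10pct"} -- the two rates differ by at most 10
#' absolute percentage points (inclusive boundary).
#'
#' @param pairs data frame with columns \code{measured_responders},
#'   \code{measured_total}, \code{predicted_numerator},
#'   \code{predicted_denominator} (and optionally \code{label}).
#' @param mode \code{"p_gt_0.05"} or \code{"within_10pct"}.
#' @param p_cutoff significance cutoff for the chi-squared mode
#'   (default 0.05).
#' @param rate_margin absolute rate margin for the within mode
#'   (default 0.10).
#' @return the matching fraction in [0, 1].
#' @export
pairwise_match_summary <- function(pairs, mode = c("p_gt_0.05", "within_10pct"),
                                   p_cutoff = 0.05, rate_margin = 0.10) {
  mode <- match.arg(mode)
  pairs <- validate_pairs(pairs)
  if (mode == "p_gt_0.05") {
    ps <- vapply(seq_len(nrow(pairs)), function(i) {
      chi2_nminus1(c(pairs$measured_responders[i], pairs$measured_total[i]),
                   c(pairs$predicted_numerator[i],
                     pairs$predicted_denominator[i]))$p
    }, numeric(1))
    mean(ps > p_cutoff)
  } else {
    mean(abs(pairs$measured_rate - pairs$predicted_rate) <= rate_margin)
  }
}

#' ROC curve of predicted rates against a trial-success threshold
#'
#' Each data pair is labelled a success when its measured rate reaches
#' the success threshold; the predicted in silico rate is the
#' classification score. Sweeping the score cutoff over the distinct
#' predicted values (ties grouped into a single ROC vertex) yields
#' TP/FP/TN/FN counts, sensitivity and specificity at each cutoff, and
#' the trapezoidal AUC of sensitivity against 1 - specificity.
#'
#' @inheritParams pairwise_match_summary
#' @param success_threshold measured-rate cutoff in percent (e.g. 70).
#' @return list with fields \code{success_threshold}, \code{points}
#'   (data frame \code{cutoff}, \code{tp}, \code{fp}, \code{tn},
#'   \code{fn}, \code{sensitivity}, \code{specificity}), \code{auc},
#'   \code{n_pos}, \code{n_neg}, \code{degenerate}; class
#'   \code{"roc_result"}. A single-class labelling is degenerate and has
#'   \code{auc = NA}.
#' @export
roc_for_threshold <- function(pairs, success_threshold) {
  pairs <- validate_pairs(pairs)
  labels <- pairs$measured_rate >= success_threshold / 100
  scores <- pairs$predicted_rate
  n_pos <- sum(labels); n_neg <- sum(!labels)
  cutoffs <- sort(unique(scores), decreasing = TRUE)
  tp <- fp <- integer(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    test_pos <- scores >= cutoffs[i]
    tp[i] <- sum(test_pos & labels)
    fp[i] <- sum(test_pos & !labels)
  }
  pts <- data.frame(cutoff = cutoffs, tp = tp, fp = fp,
                    tn = n_neg - fp, fn = n_pos - tp)
  pts$sensitivity <- if (n_pos) pts$tp / n_pos else NA_real_
  pts$specificity <- if (n_neg) pts$tn / n_neg else NA_real_
  degenerate <- n_pos == 0L || n_neg == 0L
  auc <- NA_real_
  if (!degenerate) {
    fpr <- c(0, pts$fp / n_neg, 1)
    tpr <- c(0, pts$tp / n_pos, 1)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  structure(list(success_threshold = success_threshold, points = pts,
                 auc = auc, n_pos = n_pos, n_neg = n_neg,
                 degenerate = degenerate),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC at success threshold >= %g%%: ", x$success_threshold))
  if (x$degenerate) cat("degenerate (single-class labels), AUC undefined\n")
  else cat(sprintf("AUC = %.4f (%d successes vs %d failures)\n",
                   x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' AUC sweep over trial-success thresholds
#'
#' Applies \code{\link{roc_for_threshold}} at each threshold of a
#' balanced range (default 30..80 percent, the interval avoiding
#' one-sided labellings) and reports the AUC at each, with the min and
#' max over the non-degenerate thresholds as attributes.
#'
#' @inheritParams pairwise_match_summary
#' @param thresholds percent thresholds (default \code{seq(30, 80, 10)}).
#' @return data frame with columns \code{threshold}, \code{auc},
#'   \code{n_pos}, \code{n_neg}, \code{degenerate}; attributes
#'   \code{auc_min} / \code{auc_max}.
#' @export
auc_sweep <- function(pairs, thresholds = seq(30, 80, by = 10)) {
  rows <- lapply(thresholds, function(th) {
    r <- roc_for_threshold(pairs, th)
    data.frame(threshold = th, auc = r$auc, n_pos = r$n_pos,
               n_neg = r$n_neg, degenerate = r$degenerate)
  })
  out <- do.call(rbind, rows)
  ok <- out$auc[!out$degenerate]
  attr(out, "auc_min") <- if (length(ok)) min(ok) else NA_real_
  attr(out, "auc_max") <- if (length(ok)) max(ok) else NA_real_
  out
}

#' Two-group location comparison
#'
#' Compares the response rates of two groups of trials, either by ranks
#' (two-sided Mann-Whitney with normal approximation and tie correction,
#' no continuity correction) or by means (two-sided Welch t). The choice
#' of kind is configuration, not inference.
#'
#' @param a,b numeric vectors (each of length >= 2).
#' @param kind \code{"rank"} or \code{"mean"}.
#' @return two-sided p-value; 1 when every value is identical across both
#'   groups.
#' @export
group_location_test <- function(a, b, kind = c("rank", "mean")) {
  kind <- match.arg(kind)
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations")
  }
  if (all(c(a, b) == c(a, b)[1])) return(1)
  if (kind == "rank") {
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
  } else {
    p <- stats::t.test(a, b)$p.value
  }
  if (is.na(p)) 1 else p
}

#' Per-position binder frequency along an antigen
#'
#' For each 9-mer start position of an antigen, the fraction of cohort
#' subjects predicted to bind the window with at least n distinct
#' autologous HLA alleles. Comparing two cohorts' vectors via
#' \code{\link{pearson_with_p}} measures how similar their
#' epitope-binding capabilities are.
#'
#' @param population an \code{hla_population}.
#' @param antigen amino-acid string (optionally named by its antigen id).
#' @param table a \code{binding_table}.
#' @param n HLA threshold (1..6).
#' @param k window length (default 9).
#' @return numeric vector of length L - k + 1, in position order.
#' @export
per_position_binder_frequency <- function(population, antigen, table, n,
                                          k = 9L) {
  vacc <- antigen_as_vaccine(antigen)
  bc <- binder_count_matrix(population, vacc, table, k = k, dedup = FALSE)
  rowMeans(bc$counts >= n)
}

#' Mean per-subject epitope count of an antigen
#'
#' The average, over cohort subjects, of the number of k-mer windows of
#' the antigen predicted to bind at least n distinct autologous HLA
#' alleles. Identically equal to the sum of the per-position binder
#' frequencies.
#'
#' @inheritParams per_position_binder_frequency
#' @return a single number.
#' @export
mean_epitope_count <- function(population, antigen, table, n, k = 9L) {
  vacc <- antigen_as_vaccine(antigen)
  bc <- binder_count_matrix(population, vacc, table, k = k, dedup = FALSE)
  mean(colSums(bc$counts >= n))
}

antigen_as_vaccine <- function(antigen) {
  id <- if (!is.null(names(antigen)) && nzchar(names(antigen)[1])) {
    names(antigen)[1]
  } else "antigen"
  vaccine(id, stats::setNames(as.character(antigen)[1], id))
}
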