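# Agreement statistics: two-way intraclass correlation with F-based 95%
# confidence intervals, score-range stratification, and binary
# healthy-versus-cancer accuracy.

#' Two-way intraclass correlation with confidence interval
#'
#' Computes a two-way ANOVA decomposition of an n-subjects x k-raters
#' score matrix and returns a single-rater intraclass correlation. The
#' default \code{"agreement"} variant is the two-way random-effects,
#' absolute-agreement form ICC(2,1) (rater effects count as disagreement);
#' \code{"consistency"} selects ICC(3,1), which is invariant to adding a
#' constant per rater. Confidence intervals use the standard F-based
#' formulas (exact for the consistency form; the Satterthwaite
#' approximation for the agreement form).
#'
#' Degenerate inputs follow documented conventions: a matrix in which all
#' raters agree exactly on every subject (and subjects differ) has ICC 1;
#' a matrix with zero between-subject variance has ICC defined as 0 and
#' raises a degenerate-variance warning (the CI is undefined).
#'
#' @param score_matrix Numeric matrix, subjects in rows, raters in
#'   columns; rows containing missing values are dropped (listwise
#'   deletion) and at least 5 complete subjects and 2 raters are required.
#' @param variant \code{"agreement"} (ICC(2,1), default) or
#'   \code{"consistency"} (ICC(3,1)).
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class \code{"icc_result"}: list with
#'   \code{estimate}, \code{ci_lower}, \code{ci_upper}, \code{conf_level},
#'   \code{n} (subjects used), \code{k}, \code{n_dropped}, \code{variant}
#'   and the mean squares \code{ms}.
#' @export
icc_two_way <- function(score_matrix, variant = c("agreement",
                                                  "consistency"),
                        conf_level = 0.95) {
  variant <- match.arg(variant)
  m <- as.matrix(score_matrix)
  stopifnot(is.numeric(m))
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("ICC needs at least 2 raters")
  if (n < 5L) stop("ICC needs at least 5 complete subjects")

  gm <- mean(m)
  rowm <- rowMeans(m); colm <- colMeans(m)
  ssr <- k * sum((rowm - gm)^2)          # between subjects
  ssc <- n * sum((colm - gm)^2)          # between raters
  sst <- sum((m - gm)^2)
  sse <- sst - ssr - ssc                 # residual
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  res <- function(est, lo, hi) {
    structure(list(estimate = est, ci_lower = lo, ci_upper = hi,
                   conf_level = conf_level, n = n, k = k,
                   n_dropped = n_dropped, variant = variant,
                   ms = list(msr = msr, msc = msc, mse = mse)),
              class = "icc_result")
  }
  if (sst < 1e-12) return(res(1, 1, 1))        # perfect-agreement limit
  if (msr < 1e-12) {
    warning("zero between-subject variance: ICC defined as 0")
    return(res(0, NA_real_, NA_real_))
  }
  alpha <- 1 - conf_level
  if (variant == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse < 1e-300) return(res(1, 1, 1))
    fobs <- msr / mse
    df1 <- n - 1; df2 <- (n - 1) * (k - 1)
    fl <- fobs / qf(1 - alpha / 2, df1, df2)
    fu <- fobs * qf(1 - alpha / 2, df2, df1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (mse < 1e-300 && msc < 1e-300) return(res(1, 1, 1))
    # Satterthwaite df for the agreement-form interval
    fj <- msc / mse
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * fj + b)^2 /
      (a^2 * fj^2 / (k - 1) + b^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  res(est, min(lo, est), max(hi, est))
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(%s) = %.3f [%s, %s] (%d subjects x %d raters, %g%% CI)\n",
              if (x$variant == "agreement") "2,1" else "3,1",
              x$estimate,
              formatC(x$ci_lower, digits = 3, format = "f"),
              formatC(x$ci_upper, digits = 3, format = "f"),
              x$n, x$k, 100 * x$conf_level))
  if (x$n_dropped > 0L)
    cat(sprintf("  (%d incomplete subject(s) dropped)\n", x$n_dropped))
  invisible(x)
}

#' Stratify TC scores into the standard reporting ranges
#'
#' Bins are \code{[0,0]} (no tumour cells), \code{(0,b1]}, \code{(b1,b2]}
#' and \code{(b2,100]} with default interior breaks 30 and 70, i.e. the
#' ranges reported as 0\%, 1--30\%, 31--70\% and >70\%.
#'
#' @param scores Numeric scores in [0,100].
#' @param breaks Two increasing interior break points (default
#'   \code{c(30, 70)}).
#' @return Named integer vector of counts; the names label the ranges and
#'   the counts sum to \code{length(scores)}.
#' @export
stratify_scores <- function(scores, breaks = c(30, 70)) {
  if (any(scores < 0 | scores > 100))
    stop("scores must lie in [0,100]")
  stopifnot(length(breaks) == 2L, breaks[1] > 0, breaks[2] > breaks[1],
            breaks[2] < 100)
  counts <- c(sum(scores == 0),
              sum(scores > 0 & scores <= breaks[1]),
              sum(scores > breaks[1] & scores <= breaks[2]),
              sum(scores > breaks[2]))
  names(counts) <- c("0%",
                     sprintf("1-%g%%", breaks[1]),
                     sprintf("%g-%g%%", breaks[1] + 1, breaks[2]),
                     sprintf(">%g%%", breaks[2]))
  counts
}

#' Binary healthy-versus-cancer accuracy
#'
#' Both score vectors are binarised as healthy iff the score equals 0
#' (the convention that patches without tumour cells are scored exactly
#' 0\%); the returned accuracy is the fraction of agreeing patches.
#'
#' @param predicted,reference Equal-length numeric score vectors.
#' @return Accuracy in [0,1].
#' @export
binary_accuracy <- function(predicted, reference) {
  if (length(predicted) != length(reference))
    stop("predicted and reference must have equal length")
  if (length(predicted) == 0L) stop("empty score vectors")
  mean((predicted == 0) == (reference == 0))
}

#' Pairwise agreement analysis between raters / methods
#'
#' Joins per-rater score tables on shared patch identifiers and computes,
#' for every pair, the two-way ICC with confidence interval and a
#' least-squares line (slope/intercept) for scatter summaries.
#'
#' @param score_tables Named list of data frames \code{patch_id,score}.
#' @param variant,conf_level Passed to \code{\link{icc_two_way}}.
#' @return Object of class \code{"agreement_report"}: list with
#'   \code{icc}, \code{ci_lower}, \code{ci_upper} (symmetric matrices),
#'   \code{fits} (data frame \code{rater_a,rater_b,slope,intercept}),
#'   \code{scores} (the joined wide table) and \code{n}.
#' @export
evaluate_methods <- function(score_tables, variant = "agreement",
                             conf_level = 0.95) {
  stopifnot(is.list(score_tables), length(score_tables) >= 2L)
  nm <- names(score_tables)
  if (is.null(nm) || any(nm == ""))
    nm <- names(score_tables) <- paste0("rater", seq_along(score_tables))
  for (tb in score_tables)
    stopifnot(all(c("patch_id", "score") %in% names(tb)))
  wide <- Reduce(function(a, b) merge(a, b, by = "patch_id"),
                 mapply(function(tb, nm1) {
                   out <- tb[, c("patch_id", "score")]
                   names(out)[2] <- nm1
                   out
                 }, score_tables, nm, SIMPLIFY = FALSE))
  if (nrow(wide) == 0L)
    stop("no shared patch_ids across score tables")
  r <- length(nm)
  icc <- lo <- hi <- matrix(NA_real_, r, r, dimnames = list(nm, nm))
  diag(icc) <- 1; diag(lo) <- 1; diag(hi) <- 1
  fits <- list()
  for (i in seq_len(r - 1L)) for (j in (i + 1L):r) {
    m <- as.matrix(wide[, c(nm[i], nm[j])])
    z <- icc_two_way(m, variant = variant, conf_level = conf_level)
    icc[i, j] <- icc[j, i] <- z$estimate
    lo[i, j] <- lo[j, i] <- z$ci_lower
    hi[i, j] <- hi[j, i] <- z$ci_upper
    cf <- coef(lm(m[, 2] ~ m[, 1]))
    fits[[length(fits) + 1L]] <-
      data.frame(rater_a = nm[i], rater_b = nm[j],
                 slope = unname(cf[2]), intercept = unname(cf[1]),
                 stringsAsFactors = FALSE)
  }
  structure(list(icc = icc, ci_lower = lo, ci_upper = hi,
                 fits = do.call(rbind, fits), scores = wide,
                 n = nrow(wide), variant = variant,
                 conf_level = conf_level),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("agreement report (%d shared patches, ICC variant %s)\n",
              x$n, x$variant))
  est <- x$icc
  for (i in seq_len(nrow(est) - 1L)) for (j in (i + 1L):ncol(est))
    cat(sprintf("  %s vs %s: ICC %.3f [%.3f, %.3f]\n",
                rownames(est)[i], colnames(est)[j], est[i, j],
                x$ci_lower[i, j], x$ci_upper[i, j]))
  invisible(x)
}

#' Pairwise scatter plots for an agreement report
#'
#' @param x An \code{\link{evaluate_methods}} result.
#' @param ... Unused.
#' @export
plot.agreement_report <- function(x, ...) {
  nm <- rownames(x$icc)
  np <- nrow(x$fits)
  old <- par(mfrow = c(1, np), mar = c(4, 4, 2, 1))
  on.exit(par(old))
  for (i in seq_len(np)) {
    a <- x$fits$rater_a[i]; b <- x$fits$rater_b[i]
    plot(x$scores[[a]], x$scores[[b]], xlim = c(0, 100), ylim = c(0, 100),
         xlab = a, ylab = b, pch = 19, cex = 0.5,
         main = sprintf("ICC %.2f", x$icc[a, b]))
    abline(0, 1, col = "grey60", lty = 2)
    abline(x$fits$intercept[i], x$fits$slope[i], col = "red3")
  }
  invisible(x)
}
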