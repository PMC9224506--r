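# Validation statistics: R2, Q2 (leave-one-out), Q2F3, CCC, IIC, CII,
# MAE, RMSE and the Fisher F-ratio.
#
# R2 is the squared Pearson correlation between observed and predicted
# values (the convention consistent with reconstructing the published
# F-ratios from the published R2 and n).

.check_vec <- function(x, y, nmin, what) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y)) {
    stop(sprintf("%s: inputs must be numeric vectors of equal length", what))
  }
  if (length(x) < nmin) {
    stop(sprintf("%s: need at least %d observations", what, nmin))
  }
  if (anyNA(x) || anyNA(y)) stop(sprintf("%s: missing values", what))
}

#' Determination coefficient R2
#'
#' Squared Pearson correlation between observed and predicted values.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return R2 in `[0, 1]`.
#' @export
r2 <- function(y, yhat) {
  .check_vec(y, yhat, 3L, "r2")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    stop("r2 undefined: constant input vector")
  }
  stats::cor(y, yhat)^2
}

#' Leave-one-out cross-validated Q2
#'
#' Q2 = 1 - PRESS / TSS for the one-variable least-squares regression of `y`
#' on `dcw`, computed with the closed-form leverage identity
#' `e_(i) = e_i / (1 - h_i)`.
#'
#' @param dcw Descriptor values (the single predictor).
#' @param y Observed endpoint values.
#' @return Q2 (at most the corresponding R2; can be negative).
#' @export
q2_loo <- function(dcw, y) {
  .check_vec(dcw, y, 4L, "q2_loo")
  if (stats::sd(dcw) == 0) stop("q2_loo undefined: degenerate descriptor")
  n <- length(y)
  xc <- dcw - mean(dcw)
  sxx <- sum(xc^2)
  b1 <- sum(xc * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * mean(dcw)
  e <- y - (b0 + b1 * dcw)
  h <- 1 / n + xc^2 / sxx
  press <- sum((e / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' External predictivity Q2F3
#'
#' `1 - [SSE_ext / n_ext] / [TSS_train / n_train]`: external mean squared
#' error scaled by the training-set variance of the endpoint.
#'
#' @param y_ext Observed values of the external set.
#' @param yhat_ext Predictions for the external set.
#' @param y_train Observed endpoint values of the (active) training set.
#' @return Q2F3 (1 for perfect external predictions; negative when worse
#'   than predicting the training mean).
#' @export
q2_f3 <- function(y_ext, yhat_ext, y_train) {
  .check_vec(y_ext, yhat_ext, 2L, "q2_f3")
  if (!is.numeric(y_train) || length(y_train) < 2L) {
    stop("q2_f3: training vector too short")
  }
  vtr <- sum((y_train - mean(y_train))^2) / length(y_train)
  if (vtr == 0) stop("q2_f3 undefined: zero training variance")
  1 - (sum((y_ext - yhat_ext)^2) / length(y_ext)) / vtr
}

#' Concordance correlation coefficient
#'
#' Lin's CCC with population (1/n) moments:
#' `2 cov / (var_y + var_yhat + (mean_y - mean_yhat)^2)`.
#'
#' @inheritParams r2
#' @return CCC in `[-1, 1]`.
#' @export
ccc <- function(y, yhat) {
  .check_vec(y, yhat, 2L, "ccc")
  n <- length(y)
  my <- mean(y); mp <- mean(yhat)
  vy <- sum((y - my)^2) / n
  vp <- sum((yhat - mp)^2) / n
  cv <- sum((y - my) * (yhat - mp)) / n
  den <- vy + vp + (my - mp)^2
  if (den == 0) stop("ccc undefined: degenerate inputs")
  2 * cv / den
}

#' Index of ideality of correlation
#'
#' `r(y, yhat) * min(MAEneg, MAEpos) / max(MAEneg, MAEpos)`, where `MAEneg`
#' is the mean absolute residual over observations with `y - yhat < 0` and
#' `MAEpos` over those with `y - yhat >= 0`. When either residual class is
#' empty (or the correlation is undefined) the index is 0 by convention.
#'
#' @inheritParams r2
#' @return IIC in `[-1, 1]`.
#' @export
iic <- function(y, yhat) {
  .check_vec(y, yhat, 2L, "iic")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) return(0)
  res <- y - yhat
  neg <- res[res < 0]
  pos <- res[res >= 0]
  if (length(neg) == 0L || length(pos) == 0L) return(0)
  mn <- mean(abs(neg)); mp <- mean(abs(pos))
  stats::cor(y, yhat) * min(mn, mp) / max(mn, mp)
}

# Leave-one-out squared correlations between x and y, vectorised over the
# excluded index.
.loo_r2 <- function(x, y) {
  n <- length(x)
  Sx <- sum(x); Sy <- sum(y)
  Sxx <- sum(x * x); Syy <- sum(y * y); Sxy <- sum(x * y)
  n1 <- n - 1
  sx <- Sx - x; sy <- Sy - y
  cv <- (Sxy - x * y) - sx * sy / n1
  vx <- (Sxx - x * x) - sx^2 / n1
  vy <- (Syy - y * y) - sy^2 / n1
  r2k <- (cv * cv) / (vx * vy)
  r2k[!is.finite(r2k)] <- NA_real_
  r2k
}

#' Correlation intensity index
#'
#' `1 - sum_k max(0, R2_(-k) - R2)`, where `R2_(-k)` is the determination
#' coefficient of the one-variable fit recomputed without compound `k`. Each
#' positive term is the "protest" of a compound whose removal improves the
#' correlation.
#'
#' @inheritParams q2_loo
#' @return CII (1 when no single removal improves the correlation).
#' @export
cii <- function(dcw, y) {
  .check_vec(dcw, y, 5L, "cii")
  if (stats::sd(dcw) == 0 || stats::sd(y) == 0) {
    stop("cii undefined: constant input vector")
  }
  r2all <- stats::cor(dcw, y)^2
  r2k <- .loo_r2(dcw, y)
  r2k[is.na(r2k)] <- r2all
  1 - sum(pmax(0, r2k - r2all))
}

#' Fisher F-ratio of the one-predictor model
#'
#' `F = R2 (n - 2) / (1 - R2)`.
#'
#' @param r2 Determination coefficient.
#' @param n Number of observations.
#' @return The F statistic (`Inf` as `r2` approaches 1).
#' @export
f_ratio <- function(r2, n) {
  stopifnot(is.numeric(r2), length(r2) == 1L, r2 >= 0, r2 <= 1,
            is.numeric(n), n > 2)
  if (1 - r2 < 1e-12) return(Inf)
  r2 * (n - 2) / (1 - r2)
}

#' Assemble a metric report for one subset
#'
#' Computes the full panel of validation statistics for one set of
#' observed/predicted values, following the layout of the published model
#' summary tables: Q2 is reported only when descriptor values are supplied
#' (training-style subsets), Q2F3 only when a training endpoint vector is
#' supplied (external subsets).
#'
#' @inheritParams r2
#' @param dcw Optional descriptor values; enables the leave-one-out Q2 and
#'   the CII.
#' @param y_train Optional active-training endpoint values; enables Q2F3.
#' @param set Optional subset label.
#' @return One-row data frame with columns `set`, `n`, `r2`, `ccc`, `iic`,
#'   `q2`, `q2f3`, `rmse`, `mae`, `f` (unavailable entries `NA`).
#' @export
metric_report <- function(y, yhat, dcw = NULL, y_train = NULL, set = NA_character_) {
  .check_vec(y, yhat, 3L, "metric_report")
  n <- length(y)
  rr <- r2(y, yhat)
  data.frame(
    set = set,
    n = n,
    r2 = rr,
    ccc = ccc(y, yhat),
    iic = iic(y, yhat),
    q2 = if (!is.null(dcw) && n >= 4L) q2_loo(dcw, y) else NA_real_,
    q2f3 = if (!is.null(y_train)) q2_f3(y, yhat, y_train) else NA_real_,
    rmse = sqrt(mean((y - yhat)^2)),
    mae = mean(abs(y - yhat)),
    f = f_ratio(rr, n),
    stringsAsFactors = FALSE
  )
}

#' Write a metric table as TSV
#'
#' Writes subset metric rows in the standard column order
#' (set, n, R2, CCC, IIC, Q2, Q2F3, RMSE, MAE, F).
#'
#' @param report Data frame of rows from [metric_report()].
#' @param path Output file path.
#' @return Invisibly, the reordered data frame.
#' @export
write_metrics_tsv <- function(report, path) {
  cols <- c("set", "n", "r2", "ccc", "iic", "q2", "q2f3", "rmse", "mae", "f")
  out <- report[, cols]
  names(out) <- c("set", "n", "R2", "CCC", "IIC", "Q2", "Q2F3", "RMSE", "MAE", "F")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
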