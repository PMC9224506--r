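# S3 methods for fitted cwqsar models.

#' @export
print.cwqsar <- function(x, ...) {
  cat("Correlation-weight QSAR model\n")
  cat(sprintf("  %s = %.7f + %.7f * DCW(%d, %d)\n",
              x$endpoint_label, x$c0, x$c1, x$config$T, x$config$N))
  cat(sprintf("  %d active attributes, %d blocked; seed %s\n",
              length(x$weights), length(x$blocked), format(x$seed)))
  if (!is.na(x$calibration_r2)) {
    cat(sprintf("  calibration R2 = %.4f, final target function = %.4f\n",
                x$calibration_r2, x$tf_final))
  }
  cat(sprintf("  applicability-domain threshold (2 * D_bar) = %.4g\n",
              x$ad$threshold))
  invisible(x)
}

#' @export
coef.cwqsar <- function(object, ...) {
  c(c0 = object$c0, c1 = object$c1)
}

# DCW values for a vector of SMILES under a fitted model.
.model_dcw <- function(object, smiles) {
  vapply(smiles, function(s) {
    as.numeric(compute_dcw(extract_attributes(build_hsg(s), object$config),
                           object$weights, object$config, object$blocked))
  }, numeric(1), USE.NAMES = FALSE)
}

#' Predict endpoint values for new molecules
#'
#' Computes the descriptor, the predicted endpoint `c0 + c1 * DCW`, the
#' statistical SMILES defect and the applicability-domain flag for each
#' molecule. Attributes unseen during training contribute 0 to the
#' descriptor and raise the defect, signalling extrapolation.
#'
#' @param object A fitted `cwqsar` model.
#' @param newdata Character vector of SMILES, or a data frame with a
#'   `smiles` column. Defaults to the active training set of the fit.
#' @param ... Unused.
#' @return Data frame with columns `smiles`, `dcw`, `prediction`, `defect`,
#'   `threshold`, `in_domain`.
#' @export
predict.cwqsar <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    if (is.null(object$split)) {
      stop("no newdata supplied and the model carries no training data")
    }
    newdata <- object$split$active_training
  }
  smiles <- if (is.data.frame(newdata)) {
    if (!("smiles" %in% names(newdata))) stop("newdata lacks a 'smiles' column")
    as.character(newdata$smiles)
  } else {
    as.character(newdata)
  }
  dcw <- .model_dcw(object, smiles)
  defect <- vapply(smiles, function(s) {
    smiles_defect(s, object$ad, object)
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(
    smiles = smiles,
    dcw = dcw,
    prediction = object$c0 + object$c1 * dcw,
    defect = defect,
    threshold = object$ad$threshold,
    in_domain = defect < object$ad$threshold,
    stringsAsFactors = FALSE
  )
}

#' @export
fitted.cwqsar <- function(object, ...) {
  if (is.null(object$split)) stop("model carries no training data")
  object$c0 + object$c1 * .model_dcw(object, object$split$active_training$smiles)
}

#' @export
residuals.cwqsar <- function(object, ...) {
  if (is.null(object$split)) stop("model carries no training data")
  object$split$active_training$value - fitted(object)
}

#' Summarise a fitted model over its four subsets
#'
#' Builds the standard per-subset statistics table: R2, CCC, IIC, RMSE, MAE
#' and F for every subset; leave-one-out Q2 for the active training, passive
#' training and calibration subsets; Q2F3 (anchored on the active-training
#' variance) for the calibration and validation subsets.
#'
#' @param object A fitted `cwqsar` (with its training split attached).
#' @param ... Unused.
#' @return An object of class `summary.cwqsar` whose `table` element is a
#'   data frame with one row per subset.
#' @export
summary.cwqsar <- function(object, ...) {
  if (is.null(object$split)) stop("model carries no training data")
  y_train <- object$split$active_training$value
  rows <- lapply(
    c("active_training", "passive_training", "calibration", "validation"),
    function(s) {
      df <- object$split[[s]]
      dcw <- .model_dcw(object, df$smiles)
      yhat <- object$c0 + object$c1 * dcw
      metric_report(
        df$value, yhat,
        dcw = if (s != "validation") dcw else NULL,
        y_train = if (s %in% c("calibration", "validation")) y_train else NULL,
        set = s
      )
    })
  structure(list(model = object, table = do.call(rbind, rows)),
            class = "summary.cwqsar")
}

#' @export
print.summary.cwqsar <- function(x, digits = 3, ...) {
  print(x$model)
  cat("\nSubset statistics:\n")
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Diagnostic plots for a fitted model
#'
#' `which = 1` draws observed versus predicted values for the four subsets;
#' `which = 2` draws the per-epoch optimisation trace (target function and
#' calibration R2).
#'
#' @param x A fitted `cwqsar`.
#' @param which Integer subset of `1:2`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.cwqsar <- function(x, which = 1L, ...) {
  if (1L %in% which) {
    if (is.null(x$split)) stop("model carries no training data")
    sets <- c("active_training", "passive_training", "calibration", "validation")
    cols <- c("black", "grey50", "dodgerblue3", "firebrick3")
    obs <- numeric(0); pred <- numeric(0); col <- character(0)
    for (i in seq_along(sets)) {
      df <- x$split[[sets[i]]]
      p <- x$c0 + x$c1 * .model_dcw(x, df$smiles)
      obs <- c(obs, df$value); pred <- c(pred, p)
      col <- c(col, rep(cols[i], nrow(df)))
    }
    graphics::plot(pred, obs, col = col, pch = 16, cex = 0.7,
                   xlab = "predicted", ylab = "observed",
                   main = sprintf("%s: observed vs predicted", x$endpoint_label),
                   ...)
    graphics::abline(0, 1, lty = 2)
    graphics::legend("topleft", legend = sets, col = cols, pch = 16,
                     bty = "n", cex = 0.8)
  }
  if (2L %in% which && !is.null(x$trace)) {
    graphics::plot(x$trace$epoch, x$trace$tf, type = "b", pch = 16, cex = 0.6,
                   xlab = "epoch", ylab = "target function",
                   main = "Monte Carlo trace", ...)
    graphics::par(new = TRUE)
    graphics::plot(x$trace$epoch, x$trace$r2_cal, type = "l", col = "dodgerblue3",
                   axes = FALSE, xlab = "", ylab = "")
    graphics::axis(4, col.axis = "dodgerblue3")
    graphics::mtext("calibration R2", side = 4, line = 2, col = "dodgerblue3",
                    cex = 0.8)
  }
  invisible(x)
}

#' Simulate endpoint values from a fitted model
#'
#' Draws new endpoint vectors for the active training set from the fitted
#' line plus Gaussian noise with the residual standard deviation.
#'
#' @param object A fitted `cwqsar`.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with `nsim` columns, one simulated response per
#'   column.
#' @export
simulate.cwqsar <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- fitted(object)
  sigma <- stats::sd(residuals(object))
  draw <- function() mu + stats::rnorm(length(mu), 0, sigma)
  sims <- if (is.null(seed)) {
    replicate(nsim, draw(), simplify = FALSE)
  } else {
    with_seed(seed, replicate(nsim, draw(), simplify = FALSE))
  }
  out <- as.data.frame(sims, col.names = paste0("sim_", seq_len(nsim)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
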