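# Monte Carlo optimisation of correlation weights.
#
# The dataset is split into four disjoint subsets with distinct roles: the
# active training set drives the weight updates, the passive training set
# guards against weights that only work for the compounds they were tuned
# on, the calibration set detects overtraining (epoch snapshots are selected
# on its R2, and IIC/CII inside the target function are evaluated on it),
# and the validation set is reserved for the final external assessment.

#' Split a dataset into the four modelling subsets
#'
#' Uniform random permutation under `seed`, partitioned into active
#' training, passive training, calibration and validation subsets. The first
#' three subset sizes are `floor(fraction * n)`; the remainder goes to
#' validation (so 561 records at equal fractions give 140/140/140/141).
#'
#' @param records Data frame of dataset records (must contain at least
#'   `smiles` and `value` columns for model fitting).
#' @param fractions Four non-negative fractions summing to 1.
#' @param seed Integer seed.
#' @return An object of class `qsar_split`: list with elements
#'   `active_training`, `passive_training`, `calibration`, `validation`
#'   (data frames), `seed` and `fractions`.
#' @export
split_dataset <- function(records, fractions = rep(0.25, 4), seed = 1) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (n < 12L) stop("need at least 12 records to split into four subsets")
  if (length(fractions) != 4L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must be four non-negative numbers summing to 1")
  }
  perm <- with_seed(seed, sample.int(n))
  k <- floor(fractions[1:3] * n)
  b1 <- perm[seq_len(k[1])]
  b2 <- perm[k[1] + seq_len(k[2])]
  b3 <- perm[k[1] + k[2] + seq_len(k[3])]
  b4 <- perm[(k[1] + k[2] + k[3] + 1):n]
  structure(list(
    active_training = records[b1, , drop = FALSE],
    passive_training = records[b2, , drop = FALSE],
    calibration = records[b3, , drop = FALSE],
    validation = records[b4, , drop = FALSE],
    seed = seed,
    fractions = fractions
  ), class = "qsar_split")
}

#' @export
print.qsar_split <- function(x, ...) {
  cat(sprintf(
    "<qsar_split> active %d / passive %d / calibration %d / validation %d (seed %s)\n",
    nrow(x$active_training), nrow(x$passive_training),
    nrow(x$calibration), nrow(x$validation), format(x$seed)))
  invisible(x)
}

# Lightweight IIC for the optimisation inner loop (convention: 0 when either
# residual class is empty or the correlation is undefined).
.fast_iic <- function(y, yhat) {
  if (stats::sd(yhat) == 0) return(0)
  res <- y - yhat
  neg <- res < 0
  nn <- sum(neg); np <- length(res) - nn
  if (nn == 0L || np == 0L) return(0)
  mn <- -sum(res[neg]) / nn
  mp <- sum(res[!neg]) / np
  stats::cor(y, yhat) * min(mn, mp) / max(mn, mp)
}

# Lightweight CII for the inner loop (0 when undefined).
.fast_cii <- function(x, y) {
  if (stats::sd(x) == 0) return(0)
  r2all <- stats::cor(x, y)^2
  r2k <- .loo_r2(x, y)
  r2k[is.na(r2k)] <- r2all
  1 - sum(pmax(0, r2k - r2all))
}

# Target-function evaluation on raw DCW/endpoint vectors. Returns NULL when
# a training-subset correlation is undefined (caller decides how to react).
.tf_eval <- function(dcw_at, y_at, dcw_pt, y_pt, dcw_c, y_c, config) {
  if (stats::sd(dcw_at) == 0 || stats::sd(dcw_pt) == 0) return(NULL)
  r_at <- stats::cor(dcw_at, y_at)
  r_pt <- stats::cor(dcw_pt, y_pt)
  iic_c <- 0
  cii_c <- 0
  if (config$iic_w > 0 || config$cii_w > 0) {
    if (config$iic_w > 0) {
      cf <- fit_linear(dcw_at, y_at)
      iic_c <- .fast_iic(y_c, cf[["c0"]] + cf[["c1"]] * dcw_c)
    }
    if (config$cii_w > 0) cii_c <- .fast_cii(dcw_c, y_c)
  }
  tf <- r_at + r_pt - config$tf_balance * abs(r_at - r_pt) +
    config$iic_w * iic_c + config$cii_w * cii_c
  list(r_at = r_at, r_pt = r_pt, iic_c = iic_c, cii_c = cii_c, tf = tf)
}

#' Target function of the Monte Carlo optimiser
#'
#' Evaluates `tf = r_AT + r_PT - tf_balance * |r_AT - r_PT| +
#' iic_w * IIC_C + cii_w * CII_C` for a given weight table:
#' Pearson correlations between DCW and endpoint on the active and passive
#' training sets, plus the IIC and CII of the calibration set.
#'
#' @param weights Named numeric vector of correlation weights.
#' @param split A `qsar_split`.
#' @param config A `cw_config`.
#' @return An object of class `tf_report`: list with `r_at`, `r_pt`,
#'   `iic_c`, `cii_c`, `tf`.
#' @export
target_function <- function(weights, split, config) {
  stopifnot(inherits(split, "qsar_split"), inherits(config, "cw_config"))
  dcw_of <- function(df) {
    vapply(df$smiles, function(s) {
      as.numeric(compute_dcw(extract_attributes(build_hsg(s), config),
                             weights, config))
    }, numeric(1), USE.NAMES = FALSE)
  }
  out <- .tf_eval(dcw_of(split$active_training), split$active_training$value,
                  dcw_of(split$passive_training), split$passive_training$value,
                  dcw_of(split$calibration), split$calibration$value,
                  config)
  if (is.null(out)) {
    stop("degenerate descriptor: zero-variance DCW on a training subset")
  }
  structure(out, class = "tf_report")
}

#' @export
print.tf_report <- function(x, ...) {
  cat(sprintf("<tf_report> tf = %.4f (r_AT %.4f, r_PT %.4f, IIC_C %.4f, CII_C %.4f)\n",
              x$tf, x$r_at, x$r_pt, x$iic_c, x$cii_c))
  invisible(x)
}

# Attribute-multiplicity matrix (molecules x active keys).
.attr_matrix <- function(attr_list, keys) {
  X <- matrix(0, nrow = length(attr_list), ncol = length(keys),
              dimnames = list(NULL, keys))
  for (i in seq_along(attr_list)) {
    a <- attr_list[[i]]
    common <- intersect(names(a), keys)
    if (length(common)) X[i, common] <- a[common]
  }
  X
}

#' Fit a correlation-weight QSAR model
#'
#' Trains a one-variable CORAL-style model `value = c0 + c1 * DCW` by Monte
#' Carlo hill climbing. The procedure: (1) extract the attributes enabled by
#' `config` for every molecule and block attributes seen in fewer than
#' `config$T` active-training molecules; (2) initialise every active
#' correlation weight at 1; (3) for `config$N` epochs, visit the active
#' attributes in seeded random order, perturb each weight by a uniform step
#' on `[-0.1, 0.1]`, and accept the move only if the target function
#' increases; (4) after every epoch record the calibration-set R2 and keep
#' the weight snapshot that maximises it (overtraining control); (5)
#' calibrate `(c0, c1)` by least squares on the active training set and
#' attach the applicability-domain statistics.
#'
#' @param data Data frame with columns `smiles` and `value` (endpoint on the
#'   log10 scale); ignored when `split` is supplied.
#' @param config A `cw_config` from [model_config()] or [preset_config()].
#' @param split Optional pre-made `qsar_split`; when `NULL`, `data` is split
#'   with [split_dataset()] under `seed`.
#' @param fractions Subset fractions passed to [split_dataset()].
#' @param seed Integer seed driving the split (when made here) and the Monte
#'   Carlo proposals. Identical data, configuration and seed give a
#'   bit-identical model.
#' @param step Half-width of the uniform proposal step (default 0.1).
#' @param endpoint_label Label stored with the model (e.g. `"NOAEL"`).
#' @return An object of class `cwqsar`; see [predict.cwqsar()],
#'   [summary.cwqsar()], [save_model()].
#' @examples
#' lib <- generate_library(60, seed = 7)
#' cfg <- model_config(alpha = 1, gamma = 0, x1 = 1, x2 = 0, x3 = 0,
#'                     iic_w = 0, cii_w = 0, T = 1, N = 5)
#' pl <- plant_and_label(lib, cfg, noise_sigma = 0, seed = 7)
#' fit <- cwqsar(pl$data, cfg, seed = 7)
#' coef(fit)
#' @export
cwqsar <- function(data = NULL, config = model_config(), split = NULL,
                   fractions = rep(0.25, 4), seed = 1, step = 0.1,
                   endpoint_label = "endpoint") {
  stopifnot(inherits(config, "cw_config"))
  if (is.null(split)) {
    if (is.null(data)) stop("supply either `data` or a pre-made `split`")
    split <- split_dataset(data, fractions, seed)
  }
  stopifnot(inherits(split, "qsar_split"))
  for (s in c("active_training", "passive_training", "calibration", "validation")) {
    if (!all(c("smiles", "value") %in% names(split[[s]]))) {
      stop(sprintf("subset '%s' lacks smiles/value columns", s))
    }
  }

  extract_set <- function(df) {
    lapply(df$smiles, function(s) extract_attributes(build_hsg(s), config))
  }
  attrs_at <- extract_set(split$active_training)
  attrs_pt <- extract_set(split$passive_training)
  attrs_c <- extract_set(split$calibration)

  freq_active <- .presence_freq(attrs_at)
  blocked <- block_rare(freq_active, config$T)
  active_keys <- setdiff(names(freq_active), blocked)
  K <- length(active_keys)
  if (K == 0L) {
    stop("no active attributes after blocking; lower T or enable more families")
  }

  X_at <- .attr_matrix(attrs_at, active_keys)
  X_pt <- .attr_matrix(attrs_pt, active_keys)
  X_c <- .attr_matrix(attrs_c, active_keys)
  y_at <- split$active_training$value
  y_pt <- split$passive_training$value
  y_c <- split$calibration$value

  w <- rep(1, K)
  dcw_at <- drop(X_at %*% w)
  dcw_pt <- drop(X_pt %*% w)
  dcw_c <- drop(X_c %*% w)
  cur <- .tf_eval(dcw_at, y_at, dcw_pt, y_pt, dcw_c, y_c, config)
  if (is.null(cur)) {
    stop("degenerate descriptor after blocking: zero-variance DCW on a ",
         "training subset; lower T or enable more attribute families")
  }

  cal_r2 <- function(d) {
    if (stats::sd(d) == 0 || stats::sd(y_c) == 0) return(-Inf)
    stats::cor(d, y_c)^2
  }
  best_r2c <- cal_r2(dcw_c)
  best_w <- w
  trace <- vector("list", config$N)

  with_seed(seed, {
    for (epoch in seq_len(config$N)) {
      ord <- sample.int(K)
      for (j in ord) {
        u <- stats::runif(1, -step, step)
        cand_at <- dcw_at + u * X_at[, j]
        cand_pt <- dcw_pt + u * X_pt[, j]
        cand_c <- dcw_c + u * X_c[, j]
        prop <- .tf_eval(cand_at, y_at, cand_pt, y_pt, cand_c, y_c, config)
        if (!is.null(prop) && prop$tf > cur$tf) {
          w[j] <- w[j] + u
          dcw_at <- cand_at; dcw_pt <- cand_pt; dcw_c <- cand_c
          cur <- prop
        }
      }
      r2c <- cal_r2(dcw_c)
      trace[[epoch]] <- data.frame(
        epoch = epoch, tf = cur$tf, r_at = cur$r_at, r_pt = cur$r_pt,
        iic_c = cur$iic_c, cii_c = cur$cii_c,
        r2_cal = if (is.finite(r2c)) r2c else NA_real_
      )
      if (r2c > best_r2c) {
        best_r2c <- r2c
        best_w <- w
      }
    }
  })

  w <- best_w
  dcw_at <- drop(X_at %*% w)
  dcw_pt <- drop(X_pt %*% w)
  dcw_c <- drop(X_c %*% w)
  cf <- fit_linear(dcw_at, y_at)
  final <- .tf_eval(dcw_at, y_at, dcw_pt, y_pt, dcw_c, y_c, config)
  ad <- ad_statistics(attrs_at, attrs_c, blocked)

  structure(list(
    config = config,
    endpoint_label = endpoint_label,
    weights = stats::setNames(w, active_keys),
    blocked = blocked,
    freq_active = freq_active,
    freq_calib = .presence_freq(attrs_c),
    c0 = cf[["c0"]],
    c1 = cf[["c1"]],
    ad = ad,
    seed = seed,
    sizes = c(active_training = nrow(split$active_training),
              passive_training = nrow(split$passive_training),
              calibration = nrow(split$calibration),
              validation = nrow(split$validation)),
    tf_final = final$tf,
    calibration_r2 = if (is.finite(best_r2c)) best_r2c else NA_real_,
    training_y_var = sum((y_at - mean(y_at))^2) / length(y_at),
    training_n = length(y_at),
    split = split,
    trace = do.call(rbind, trace),
    call = match.call()
  ), class = "cwqsar")
}

#' Grid search for the rare-feature threshold and epoch count
#'
#' Trains one model per `(T, N)` cell of the grid on a common split and
#' returns the pair maximising the calibration-set R2, breaking ties towards
#' the smaller threshold and then the smaller epoch count.
#'
#' @param records Data frame of records (split internally under `seed`).
#' @param config Template `cw_config`; its `T` and `N` are overridden per
#'   grid cell.
#' @param T_range,N_range Integer vectors of candidate thresholds / epochs.
#' @param seed Integer seed shared by the split and every training run.
#' @param fractions Subset fractions for the internal split.
#' @return List with elements `T`, `N` (the winners) and `model` (the
#'   corresponding fitted `cwqsar`).
#' @export
select_hyperparams <- function(records, config, T_range, N_range, seed = 1,
                               fractions = rep(0.25, 4)) {
  stopifnot(length(T_range) >= 1L, length(N_range) >= 1L)
  split <- split_dataset(records, fractions, seed)
  best <- NULL
  for (Tc in sort(unique(as.integer(T_range)))) {
    for (Nc in sort(unique(as.integer(N_range)))) {
      cfg <- config
      cfg$T <- Tc
      cfg$N <- Nc
      fit <- tryCatch(cwqsar(config = cfg, split = split, seed = seed),
                      error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$calibration_r2)) next
      if (is.null(best) || fit$calibration_r2 > best$model$calibration_r2) {
        best <- list(T = Tc, N = Nc, model = fit)
      }
    }
  }
  if (is.null(best)) {
    stop("every grid cell produced a degenerate descriptor")
  }
  best
}

#' Write the per-epoch optimisation trace as TSV
#'
#' @param model A fitted `cwqsar` with a trace (models reloaded from JSON
#'   have none).
#' @param path Output file path.
#' @return Invisibly, the trace data frame.
#' @export
write_trace_tsv <- function(model, path) {
  stopifnot(inherits(model, "cwqsar"))
  if (is.null(model$trace)) stop("model carries no optimisation trace")
  utils::write.table(model$trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(model$trace)
}
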