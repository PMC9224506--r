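# Correlation-weight descriptor: rare-feature blocking, DCW computation,
# the one-variable linear calibration, and model (de)serialisation.

.MODEL_SCHEMA <- "cwqsar-model/1"

#' Identify rare attributes to block
#'
#' An attribute seen in fewer than `T` active-training molecules is "rare"
#' and is excluded from the descriptor; model building never involves rare
#' features. Frequencies count molecules containing the attribute, not total
#' occurrences, so `T = 1` blocks nothing that has been seen at least once.
#' Attributes absent from the frequency table are treated as blocked at
#' prediction time regardless of `T`.
#'
#' @param frequency Named integer vector: attribute key -> number of
#'   active-training molecules containing it.
#' @param T Positive integer threshold.
#' @return Character vector of blocked keys.
#' @export
block_rare <- function(frequency, T) {
  stopifnot(is.numeric(frequency), is.numeric(T), length(T) == 1L, T >= 1)
  names(frequency)[frequency < T]
}

# Molecule-presence frequency of attribute keys over a list of attribute sets.
.presence_freq <- function(attr_list) {
  keys <- unlist(lapply(attr_list, function(a) unique(names(a))),
                 use.names = FALSE)
  if (length(keys) == 0L) return(stats::setNames(integer(0), character(0)))
  tab <- table(keys)
  stats::setNames(as.integer(tab), names(tab))
}

# 0/1 block multiplier per attribute family under a configuration.
.family_multiplier <- function(families, config) {
  m <- numeric(length(families))
  m[families == "S"] <- config$alpha * config$x1
  m[families == "SS"] <- config$alpha * config$x2
  m[families == "SSS"] <- config$alpha * config$x3
  m[families %in% c("EC1", "EC2", "EC3", "NNC")] <- config$beta
  m[families == "APP"] <- max(config$gamma, config$delta)
  m
}

#' Descriptor of correlation weights (DCW)
#'
#' Sums `multiplicity x correlation weight` over a molecule's non-blocked
#' attributes, applying the 0/1 block toggles of the configuration per
#' attribute family. Attributes that are neither weighted nor blocked
#' (unseen at training time) contribute 0 and are reported in the
#' `"unknown"` attribute of the result.
#'
#' @param attrs Named numeric vector of attribute multiplicities (from
#'   [extract_attributes()]).
#' @param weights Named numeric vector of correlation weights.
#' @param config A `cw_config`.
#' @param blocked Character vector of blocked attribute keys.
#' @return The DCW value (numeric scalar) with attribute `"unknown"` listing
#'   attribute keys that carried no weight.
#' @export
compute_dcw <- function(attrs, weights, config, blocked = character(0)) {
  stopifnot(inherits(config, "cw_config"))
  if (length(attrs) == 0L) {
    return(structure(0, unknown = character(0)))
  }
  keep <- !(names(attrs) %in% blocked)
  attrs <- attrs[keep]
  mult <- .family_multiplier(key_family(names(attrs)), config)
  w <- weights[names(attrs)]
  unknown <- names(attrs)[is.na(w)]
  w[is.na(w)] <- 0
  structure(sum(as.numeric(attrs) * mult * as.numeric(w)), unknown = unknown)
}

#' One-variable least-squares calibration
#'
#' Fits `y = c0 + c1 * dcw` by ordinary least squares on the active training
#' set.
#'
#' @param dcw Descriptor values.
#' @param y Endpoint values.
#' @return Named numeric vector `c(c0, c1)`.
#' @export
fit_linear <- function(dcw, y) {
  .check_vec(dcw, y, 3L, "fit_linear")
  if (stats::sd(dcw) == 0) {
    stop("degenerate descriptor: DCW is constant, cannot calibrate")
  }
  c1 <- stats::cov(dcw, y) / stats::var(dcw)
  c0 <- mean(y) - c1 * mean(dcw)
  c(c0 = c0, c1 = c1)
}

#' Save a trained model as JSON
#'
#' Serialises a fitted `cwqsar` model (configuration, correlation weights,
#' blocked attributes, frequency tables, calibration coefficients and
#' applicability-domain statistics) with full floating-point precision, so a
#' save/load round trip reproduces predictions bit-for-bit.
#'
#' @param model A fitted `cwqsar` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cwqsar"))
  payload <- list(
    schema_version = .MODEL_SCHEMA,
    endpoint_label = model$endpoint_label,
    config = unclass(model$config),
    weights = as.list(model$weights),
    blocked = as.list(model$blocked),
    freq_active = as.list(model$freq_active),
    freq_calib = as.list(model$freq_calib),
    c0 = model$c0,
    c1 = model$c1,
    ad = list(
      p_active = as.list(model$ad$p_active),
      p_calib = as.list(model$ad$p_calib),
      n_active = as.list(model$ad$n_active),
      n_calib = as.list(model$ad$n_calib),
      d_bar = model$ad$d_bar,
      threshold = model$ad$threshold
    ),
    seed = model$seed,
    sizes = as.list(model$sizes),
    tf_final = model$tf_final,
    calibration_r2 = model$calibration_r2,
    training_y_var = model$training_y_var,
    training_n = model$training_n
  )
  # digits = I(17): 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

.named_num <- function(x) {
  if (length(x) == 0L) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
}

#' Load a trained model from JSON
#'
#' @param path Path to a file written by [save_model()].
#' @return A `cwqsar` object (without the training data and optimisation
#'   trace, which are not serialised).
#' @export
load_model <- function(path) {
  payload <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("cannot read model file '%s': %s",
                                     path, conditionMessage(e)))
  )
  if (!identical(payload$schema_version, .MODEL_SCHEMA)) {
    stop(sprintf("model schema mismatch: expected '%s', found '%s'",
                 .MODEL_SCHEMA,
                 payload$schema_version %||% "<missing>"))
  }
  cfg <- do.call(model_config, payload$config[setdiff(names(payload$config), NULL)])
  ad <- structure(list(
    p_active = .named_num(payload$ad$p_active),
    p_calib = .named_num(payload$ad$p_calib),
    n_active = .named_num(payload$ad$n_active),
    n_calib = .named_num(payload$ad$n_calib),
    d_bar = as.numeric(payload$ad$d_bar),
    threshold = as.numeric(payload$ad$threshold)
  ), class = "ad_stats")
  structure(list(
    config = cfg,
    endpoint_label = payload$endpoint_label %||% "endpoint",
    weights = .named_num(payload$weights),
    blocked = as.character(unlist(payload$blocked)),
    freq_active = .named_num(payload$freq_active),
    freq_calib = .named_num(payload$freq_calib),
    c0 = as.numeric(payload$c0),
    c1 = as.numeric(payload$c1),
    ad = ad,
    seed = as.numeric(payload$seed),
    sizes = .named_num(payload$sizes),
    tf_final = as.numeric(payload$tf_final),
    calibration_r2 = as.numeric(payload$calibration_r2),
    training_y_var = as.numeric(payload$training_y_var),
    training_n = as.numeric(payload$training_n),
    split = NULL,
    trace = NULL
  ), class = "cwqsar")
}
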