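# Descriptor / optimiser configuration.

#' Descriptor and optimiser configuration
#'
#' Assembles the configuration controlling which attribute families enter the
#' correlation-weight descriptor and how the Monte Carlo optimiser runs. The
#' descriptor is a sum of up to four blocks: `alpha` (SMILES n-grams `S`,
#' `SS`, `SSS`, gated individually by `x1`, `x2`, `x3`), `beta` (graph
#' attributes `EC1`-`EC3` and nearest-neighbour codes `NNC`), `gamma`
#' (chlorine atom-pair proportions `APP[Cl,N]`, `APP[Cl,O]`, `APP[Cl,S]`,
#' `APP[Cl,P]`, gated by `y1`-`y4`) and `delta` (atom-pair proportions over
#' all unordered pairs of `F, Cl, Br, N, O, S, P, =, #`).
#'
#' @param alpha,beta,gamma,delta 0/1 toggles enabling the four descriptor
#'   blocks. At least one must be enabled.
#' @param x1,x2,x3 0/1 toggles for the S / SS / SSS n-gram families (used
#'   only when `alpha = 1`).
#' @param y1,y2,y3,y4 0/1 toggles for the four chlorine atom-pair families
#'   (used only when `gamma = 1`).
#' @param T Rare-feature threshold (positive integer): an attribute seen in
#'   fewer than `T` active-training molecules is blocked and never
#'   contributes to the descriptor.
#' @param N Number of Monte Carlo epochs; one epoch is a full pass over all
#'   active attributes in seeded random order.
#' @param iic_w,cii_w Non-negative weights of the index of ideality of
#'   correlation and the correlation intensity index (both evaluated on the
#'   calibration set) inside the optimisation target function.
#' @param tf_balance Non-negative weight of the `|r_AT - r_PT|` balance
#'   penalty in the target function (default 0.1).
#' @return An object of class `cw_config` (a named list of the above fields).
#' @seealso [preset_config()] for the eight published model configurations.
#' @examples
#' model_config(alpha = 1, x1 = 1, x2 = 1, x3 = 0, T = 1, N = 30)
#' @export
model_config <- function(alpha = 1, beta = 0, gamma = 1, delta = 0,
                         x1 = 1, x2 = 1, x3 = 1,
                         y1 = 1, y2 = 1, y3 = 1, y4 = 1,
                         T = 1, N = 30, iic_w = 0.25, cii_w = 0.30,
                         tf_balance = 0.1) {
  cfg <- list(alpha = alpha, beta = beta, gamma = gamma, delta = delta,
              x1 = x1, x2 = x2, x3 = x3,
              y1 = y1, y2 = y2, y3 = y3, y4 = y4,
              T = T, N = N, iic_w = iic_w, cii_w = cii_w,
              tf_balance = tf_balance)
  toggles <- c("alpha", "beta", "gamma", "delta",
               "x1", "x2", "x3", "y1", "y2", "y3", "y4")
  for (f in toggles) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !(v %in% c(0, 1))) {
      stop(sprintf("config field '%s' must be 0 or 1", f))
    }
    cfg[[f]] <- as.integer(v)
  }
  if (cfg$alpha == 0 && cfg$beta == 0 && cfg$gamma == 0 && cfg$delta == 0) {
    stop("at least one of alpha, beta, gamma, delta must be enabled")
  }
  if (!is.numeric(cfg$T) || cfg$T < 1 || cfg$T != round(cfg$T)) {
    stop("T must be a positive integer")
  }
  if (!is.numeric(cfg$N) || cfg$N < 1 || cfg$N != round(cfg$N)) {
    stop("N must be a positive integer")
  }
  for (f in c("iic_w", "cii_w", "tf_balance")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] < 0) {
      stop(sprintf("config field '%s' must be a non-negative number", f))
    }
  }
  cfg$T <- as.integer(cfg$T)
  cfg$N <- as.integer(cfg$N)
  structure(cfg, class = "cw_config")
}

#' @export
print.cw_config <- function(x, ...) {
  cat("<cw_config>\n")
  cat(sprintf("  blocks: alpha=%d beta=%d gamma=%d delta=%d\n",
              x$alpha, x$beta, x$gamma, x$delta))
  cat(sprintf("  n-grams: x1=%d x2=%d x3=%d   Cl-pairs: y1=%d y2=%d y3=%d y4=%d\n",
              x$x1, x$x2, x$x3, x$y1, x$y2, x$y3, x$y4))
  cat(sprintf("  T=%d N=%d iic_w=%g cii_w=%g tf_balance=%g\n",
              x$T, x$N, x$iic_w, x$cii_w, x$tf_balance))
  invisible(x)
}

# Published configurations M1-M8 (general / kidney / brain / liver models for
# NOAEL and LOAEL): block toggles, correlation-index weights, best threshold
# T* and best epoch count N*.
.PRESETS <- list(
  M1 = list(alpha = 1, beta = 0, gamma = 1, delta = 0, x1 = 1, x2 = 1, x3 = 1,
            y1 = 1, y2 = 1, y3 = 1, y4 = 1, iic_w = 0.25, cii_w = 0.30, T = 1, N = 30),
  M2 = list(alpha = 1, beta = 0, gamma = 1, delta = 0, x1 = 1, x2 = 1, x3 = 1,
            y1 = 1, y2 = 1, y3 = 1, y4 = 1, iic_w = 0.20, cii_w = 0, T = 1, N = 30),
  M3 = list(alpha = 1, beta = 0, gamma = 1, delta = 0, x1 = 1, x2 = 1, x3 = 1,
            y1 = 1, y2 = 1, y3 = 0, y4 = 0, iic_w = 0.25, cii_w = 0, T = 1, N = 10),
  M4 = list(alpha = 1, beta = 0, gamma = 0, delta = 0, x1 = 1, x2 = 1, x3 = 1,
            y1 = 0, y2 = 0, y3 = 0, y4 = 0, iic_w = 0.20, cii_w = 0, T = 1, N = 10),
  M5 = list(alpha = 1, beta = 0, gamma = 0, delta = 1, x1 = 1, x2 = 0, x3 = 0,
            y1 = 0, y2 = 0, y3 = 0, y4 = 0, iic_w = 0.50, cii_w = 0, T = 1, N = 33),
  M6 = list(alpha = 1, beta = 0, gamma = 0, delta = 0, x1 = 1, x2 = 1, x3 = 0,
            y1 = 0, y2 = 0, y3 = 0, y4 = 0, iic_w = 0.20, cii_w = 0, T = 1, N = 4),
  M7 = list(alpha = 1, beta = 1, gamma = 0, delta = 0, x1 = 1, x2 = 1, x3 = 1,
            y1 = 0, y2 = 0, y3 = 0, y4 = 0, iic_w = 0.15, cii_w = 0, T = 2, N = 15),
  M8 = list(alpha = 1, beta = 1, gamma = 0, delta = 0, x1 = 1, x2 = 1, x3 = 1,
            y1 = 0, y2 = 0, y3 = 0, y4 = 0, iic_w = 0.25, cii_w = 0, T = 2, N = 14)
)

#' Published model configurations
#'
#' Returns one of the eight published CORAL model configurations (`M1`-`M8`)
#' for the general, kidney, brain and liver NOAEL/LOAEL endpoints. The same
#' configurations ship as JSON fixtures under
#' `system.file("extdata", "configs", package = "cwqsar")`.
#'
#' @param id One of `"M1"` ... `"M8"` (general NOAEL/LOAEL, kidney
#'   NOAEL/LOAEL, brain NOAEL/LOAEL, liver NOAEL/LOAEL, in that order).
#' @return A `cw_config` object.
#' @examples
#' preset_config("M1")
#' @export
preset_config <- function(id) {
  if (!is.character(id) || length(id) != 1L || !(id %in% names(.PRESETS))) {
    stop(sprintf("unknown preset '%s'; available: %s",
                 as.character(id)[1], paste(names(.PRESETS), collapse = ", ")))
  }
  do.call(model_config, .PRESETS[[id]])
}
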