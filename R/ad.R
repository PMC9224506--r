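# Applicability domain: the probabilistic statistical SMILES defect.
#
# Each attribute's defect compares its distribution between the active
# training and calibration sets:
#   d_k = |P(S_k) - P'(S_k)| / (N(S_k) + N'(S_k))
# with P, N the probability and frequency (molecule-presence) in the active
# training set and P', N' in the calibration set. The defect of a molecule is
# the sum of d_k over its distinct non-blocked attributes; a molecule is in
# domain when its defect is strictly below twice the mean defect of the
# active-training molecules.

#' Applicability-domain statistics
#'
#' Builds the per-attribute probability and frequency tables from the active
#' training and calibration sets and the in-domain threshold `2 * D_bar`,
#' where `D_bar` is the mean statistical defect over active-training
#' molecules. Blocked attributes are excluded throughout.
#'
#' @param attrs_active List of attribute sets (from [extract_attributes()])
#'   for the active-training molecules.
#' @param attrs_calib List of attribute sets for the calibration molecules.
#' @param blocked Character vector of blocked attribute keys.
#' @return An object of class `ad_stats`: list with `p_active`, `p_calib`,
#'   `n_active`, `n_calib` (named vectors over the union of observed keys),
#'   `d_bar` and `threshold = 2 * d_bar`.
#' @export
ad_statistics <- function(attrs_active, attrs_calib, blocked = character(0)) {
  stopifnot(is.list(attrs_active), is.list(attrs_calib))
  drop_blocked <- function(a) a[!(names(a) %in% blocked)]
  attrs_active <- lapply(attrs_active, drop_blocked)
  attrs_calib <- lapply(attrs_calib, drop_blocked)
  fa <- .presence_freq(attrs_active)
  fc <- .presence_freq(attrs_calib)
  keys <- union(names(fa), names(fc))
  na <- stats::setNames(rep(0, length(keys)), keys)
  nc <- na
  na[names(fa)] <- fa
  nc[names(fc)] <- fc
  stats <- structure(list(
    p_active = na / max(length(attrs_active), 1L),
    p_calib = nc / max(length(attrs_calib), 1L),
    n_active = na,
    n_calib = nc,
    d_bar = NA_real_,
    threshold = NA_real_
  ), class = "ad_stats")
  defects <- vapply(attrs_active, function(a) {
    smiles_defect_keys(unique(names(a)), stats)
  }, numeric(1))
  stats$d_bar <- if (length(defects) > 0L) mean(defects) else 0
  stats$threshold <- 2 * stats$d_bar
  stats
}

#' @export
print.ad_stats <- function(x, ...) {
  cat(sprintf("<ad_stats> %d attributes, D_bar = %.4g, threshold = %.4g\n",
              length(x$p_active), x$d_bar, x$threshold))
  invisible(x)
}

#' Statistical defect of one attribute
#'
#' `|P - P'| / (N + N')` for an attribute present in at least one of the two
#' sets; an attribute absent from both is maximally novel and has defect 1.
#'
#' @param key Attribute key.
#' @param stats An `ad_stats` object.
#' @return The defect (non-negative scalar).
#' @export
attribute_defect <- function(key, stats) {
  stopifnot(inherits(stats, "ad_stats"), is.character(key), length(key) == 1L)
  if (!(key %in% names(stats$n_active))) return(1)
  tot <- stats$n_active[[key]] + stats$n_calib[[key]]
  if (tot == 0) return(1)
  abs(stats$p_active[[key]] - stats$p_calib[[key]]) / tot
}

# Defect of a molecule given its distinct non-blocked attribute keys.
smiles_defect_keys <- function(keys, stats) {
  if (length(keys) == 0L) return(0)
  known <- keys %in% names(stats$n_active)
  d <- sum(!known)  # unseen attributes each contribute 1
  if (any(known)) {
    k <- keys[known]
    tot <- stats$n_active[k] + stats$n_calib[k]
    dk <- abs(stats$p_active[k] - stats$p_calib[k]) / tot
    dk[tot == 0] <- 1
    d <- d + sum(dk)
  }
  d
}

#' Statistical SMILES defect of a molecule
#'
#' Sum of [attribute_defect()] over the molecule's distinct non-blocked
#' attributes, extracted under the model configuration.
#'
#' @param molecule A `molecule` (or SMILES string).
#' @param stats An `ad_stats` object.
#' @param model A fitted `cwqsar` model (supplies the configuration and the
#'   blocked set).
#' @return The molecule's defect (non-negative scalar).
#' @export
smiles_defect <- function(molecule, stats, model) {
  stopifnot(inherits(stats, "ad_stats"), inherits(model, "cwqsar"))
  if (is.character(molecule)) molecule <- build_hsg(molecule)
  attrs <- extract_attributes(molecule, model$config)
  keys <- setdiff(unique(names(attrs)), model$blocked)
  smiles_defect_keys(keys, stats)
}

#' Applicability-domain membership
#'
#' A molecule is inside the domain when its statistical SMILES defect is
#' strictly below the threshold `2 * D_bar`; a defect exactly equal to the
#' threshold falls outside.
#'
#' @inheritParams smiles_defect
#' @return `TRUE` when the molecule is inside the applicability domain.
#' @export
in_domain <- function(molecule, stats, model) {
  smiles_defect(molecule, stats, model) < stats$threshold
}
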