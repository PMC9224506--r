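# Dataset input and curation.
#
# Endpoint datasets are CSV files with header columns id, cas, smiles, value
# (and optionally value2 for paired NOAEL/LOAEL tables). Endpoint values are
# stored on the log10 mg/kg bw/day scale after reading.

.DEFAULT_WHITELIST <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "H")

#' Read an endpoint dataset
#'
#' Reads a CSV with columns `id`, `cas`, `smiles`, `value` (and optionally
#' `value2`). Values supplied on the linear mg/kg bw/day scale are converted
#' to log10; values already on the log scale are taken as-is.
#'
#' @param path CSV file path.
#' @param value_scale `"log10"` (default) or `"linear"`.
#' @return Data frame of records in file order.
#' @export
read_dataset <- function(path, value_scale = c("log10", "linear")) {
  value_scale <- match.arg(value_scale)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("id", "cas", "smiles", "value")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("dataset '%s' lacks required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  }
  parse_value <- function(col) {
    raw <- df[[col]]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !is.na(raw) & nzchar(raw))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric %s '%s' at row %d of '%s'",
                   col, raw[bad[1]], bad[1], path))
    }
    if (value_scale == "linear") {
      nonpos <- which(!is.na(v) & v <= 0)
      if (length(nonpos) > 0L) {
        stop(sprintf("non-positive linear %s at row %d of '%s' cannot be log-transformed",
                     col, nonpos[1], path))
      }
      v <- log10(v)
    }
    v
  }
  df$value <- parse_value("value")
  if ("value2" %in% names(df)) df$value2 <- parse_value("value2")
  df
}

# Elements appearing in a SMILES string (bracket atoms reduced to their
# element symbol, aromatic atoms uppercased); NULL when unparseable.
.smiles_elements <- function(smiles) {
  toks <- tryCatch(tokenize_smiles(smiles), error = function(e) NULL)
  if (is.null(toks)) return(NULL)
  at <- toks[.is_atom_token(toks)]
  el <- vapply(at, .token_element, character(1), USE.NAMES = FALSE)
  ifelse(nchar(el) == 1L, toupper(el), el)
}

#' Curate an endpoint dataset
#'
#' Applies the standard curation rules, in order: records with unparseable
#' SMILES are rejected (`malformed_smiles`); multi-fragment SMILES
#' (mixtures, salts — any string containing `.`) are rejected
#' (`multi_fragment`); records with elements outside the organic whitelist
#' are rejected (`non_organic`); when a paired table carries both endpoints
#' (`value` = NOAEL, `value2` = LOAEL) rows violating NOAEL <= LOAEL are
#' dropped (`noael_gt_loael`); duplicates sharing a canonical key (CAS when
#' present, otherwise the exact SMILES string) are collapsed keeping the
#' lowest — most conservative — value, the others rejected (`duplicate`);
#' values outside the plausible range are rejected (`out_of_range`); and,
#' optionally, records in sparsely populated bins at the extremes of the
#' value distribution are trimmed (`low_frequency_tail`).
#'
#' @param records Data frame with columns `id`, `cas`, `smiles`, `value`
#'   (values on the log10 scale) and optionally `value2`.
#' @param whitelist Allowed element symbols.
#' @param value_range Plausible log10 range; values outside are rejected.
#' @param tail_min_count When positive, drop records falling into bins
#'   (width `tail_bin_width`) at either extreme of the value distribution
#'   holding fewer than this many records. Default 0 (off).
#' @param tail_bin_width Bin width for the tail trim.
#' @return List with elements `kept` (curated data frame) and `rejected`
#'   (data frame of rejected records with a `reason` column).
#' @export
curate_dataset <- function(records, whitelist = .DEFAULT_WHITELIST,
                           value_range = c(-Inf, Inf),
                           tail_min_count = 0, tail_bin_width = 0.5) {
  stopifnot(is.data.frame(records),
            all(c("id", "cas", "smiles", "value") %in% names(records)))
  n <- nrow(records)
  reason <- rep(NA_character_, n)

  for (i in seq_len(n)) {
    smi <- records$smiles[i]
    if (is.na(smi) || !nzchar(smi)) {
      reason[i] <- "malformed_smiles"
      next
    }
    if (grepl(".", smi, fixed = TRUE)) {
      reason[i] <- "multi_fragment"
      next
    }
    el <- .smiles_elements(smi)
    if (is.null(el)) {
      reason[i] <- "malformed_smiles"
    } else if (!all(el %in% whitelist)) {
      reason[i] <- "non_organic"
    }
  }

  ok <- is.na(reason)
  bad_val <- ok & (!is.finite(records$value) |
                   records$value < value_range[1] |
                   records$value > value_range[2])
  reason[bad_val] <- "out_of_range"
  ok <- is.na(reason)

  if ("value2" %in% names(records)) {
    viol <- ok & is.finite(records$value2) & records$value > records$value2
    reason[viol] <- "noael_gt_loael"
    ok <- is.na(reason)
  }

  # duplicate collapse: keep the lowest value per canonical key
  key <- ifelse(!is.na(records$cas) & nzchar(records$cas),
                paste0("cas:", records$cas),
                paste0("smi:", records$smiles))
  for (k in unique(key[ok])) {
    idx <- which(ok & key == k)
    if (length(idx) > 1L) {
      keep <- idx[which.min(records$value[idx])]
      reason[setdiff(idx, keep)] <- "duplicate"
      ok <- is.na(reason)
    }
  }

  if (tail_min_count > 0) {
    vals <- records$value[ok]
    if (length(vals) > 0L) {
      lo <- floor(min(vals) / tail_bin_width) * tail_bin_width
      bins <- floor((records$value - lo) / tail_bin_width)
      counts <- table(bins[ok])
      sparse <- as.integer(names(counts)[counts < tail_min_count])
      # trim only contiguous sparse bins at the distribution extremes
      all_bins <- sort(unique(bins[ok]))
      drop_bins <- integer(0)
      for (b in all_bins) {
        if (b %in% sparse) drop_bins <- c(drop_bins, b) else break
      }
      for (b in rev(all_bins)) {
        if (b %in% sparse) drop_bins <- c(drop_bins, b) else break
      }
      trim <- ok & bins %in% drop_bins
      reason[trim] <- "low_frequency_tail"
      ok <- is.na(reason)
    }
  }

  rejected <- records[!ok, , drop = FALSE]
  if (nrow(rejected) > 0L) rejected$reason <- reason[!ok]
  else rejected$reason <- character(0)
  list(kept = records[ok, , drop = FALSE], rejected = rejected)
}

#' Write a curated dataset and its rejection log
#'
#' @param curated The list returned by [curate_dataset()].
#' @param path Output CSV path for the kept records.
#' @param rejects_path Optional CSV path for the rejection log (`id`,
#'   `reason` and the original columns).
#' @return Invisibly, `curated`.
#' @export
write_dataset <- function(curated, path, rejects_path = NULL) {
  utils::write.csv(curated$kept, path, row.names = FALSE, quote = TRUE)
  if (!is.null(rejects_path)) {
    utils::write.csv(curated$rejected, rejects_path, row.names = FALSE,
                     quote = TRUE)
  }
  invisible(curated)
}
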