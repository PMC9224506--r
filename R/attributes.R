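# Attribute extraction: the four families of molecular features whose
# correlation weights the optimiser learns.
#
# Attribute keys are strings of the form "<FAMILY>:<code>", e.g. "S:Cl",
# "SS:C~O", "EC1:C/EC1=2", "NNC:C/N[C,O]", "APP:(Cl.N)..1.2". An attribute
# set is a named numeric vector of multiplicities.

.APP_ALPHABET <- c("F", "Cl", "Br", "N", "O", "S", "P", "=", "#")

#' SMILES n-gram attributes (S, SS, SSS)
#'
#' Counts windows of 1, 2 or 3 adjacent SMILES tokens. Two- and three-token
#' windows are normalised to a canonical orientation (the lexicographically
#' smaller of the window and its reversal) so a string and its mirror image
#' yield identical keys.
#'
#' @param molecule A `molecule` from [build_hsg()].
#' @param order Window length, 1, 2 or 3.
#' @return Named numeric vector of key multiplicities (families `S`, `SS`,
#'   `SSS`).
#' @examples
#' extract_sequence(build_hsg("CCO"), 2)
#' @export
extract_sequence <- function(molecule, order) {
  stopifnot(inherits(molecule, "molecule"))
  if (!(is.numeric(order) && length(order) == 1L && order %in% 1:3)) {
    stop("order must be 1, 2 or 3")
  }
  toks <- molecule$tokens
  if (length(toks) < order) return(stats::setNames(numeric(0), character(0)))
  fam <- c("S", "SS", "SSS")[order]
  if (order == 1L) {
    keys <- toks
  } else {
    n <- length(toks) - order + 1L
    keys <- vapply(seq_len(n), function(i) {
      w <- toks[i:(i + order - 1L)]
      a <- paste(w, collapse = "~")
      b <- paste(rev(w), collapse = "~")
      if (a <= b) a else b
    }, character(1))
  }
  tab <- table(keys)
  stats::setNames(as.numeric(tab), paste0(fam, ":", names(tab)))
}

# Morgan extended-connectivity values of a given order for every vertex.
# EC0(v) = degree(v); ECk(v) = sum over neighbours u of EC(k-1)(u).
.ec_values <- function(molecule, order) {
  adj <- .adjacency(molecule)
  ec <- as.numeric(molecule_degrees(molecule))
  for (k in seq_len(order)) {
    ec <- vapply(seq_along(adj), function(v) {
      if (length(adj[[v]]) == 0L) 0 else sum(ec[adj[[v]]])
    }, numeric(1))
  }
  ec
}

#' Morgan extended-connectivity attributes (EC1-EC3)
#'
#' Element-tagged Morgan connectivity codes on the hydrogen-suppressed graph.
#' The order-0 value of a vertex is its degree; the order-k value is the sum
#' of the order-(k-1) values of its neighbours. Keys have the form
#' `element/ECk=value`.
#'
#' @inheritParams extract_sequence
#' @param order Connectivity order, 1, 2 or 3.
#' @return Named numeric vector of key multiplicities (family `EC<order>`).
#' @examples
#' extract_ec(build_hsg("CCC"), 1)  # all three carbons have EC1 = 2
#' @export
extract_ec <- function(molecule, order) {
  stopifnot(inherits(molecule, "molecule"))
  if (!(is.numeric(order) && length(order) == 1L && order %in% 1:3)) {
    stop("order must be 1, 2 or 3")
  }
  if (length(molecule$atoms) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  ec <- .ec_values(molecule, order)
  keys <- sprintf("EC%d:%s/EC%d=%s", order, molecule$atoms, order,
                  format(ec, trim = TRUE, scientific = FALSE))
  tab <- table(keys)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Nearest-neighbour code attributes (NNC)
#'
#' One code per vertex: the vertex element followed by the sorted multiset of
#' its neighbours' element symbols, e.g. `C/N[C,O]` for a carbon bonded to a
#' carbon and an oxygen. This element + sorted-neighbour-multiset code is
#' this package's concrete definition of the nearest-neighbour code family.
#'
#' @inheritParams extract_sequence
#' @return Named numeric vector of key multiplicities (family `NNC`).
#' @examples
#' extract_nnc(build_hsg("CCO"))
#' @export
extract_nnc <- function(molecule) {
  stopifnot(inherits(molecule, "molecule"))
  if (length(molecule$atoms) == 0L) {
    return(stats::setNames(numeric(0), character(0)))
  }
  adj <- .adjacency(molecule)
  keys <- vapply(seq_along(adj), function(v) {
    nb <- sort(molecule$atoms[adj[[v]]])
    sprintf("NNC:%s/N[%s]", molecule$atoms[v], paste(nb, collapse = ","))
  }, character(1))
  tab <- table(keys)
  stats::setNames(as.numeric(tab), names(tab))
}

#' Atom-pair proportion attributes (APP)
#'
#' For each requested pair of symbols from `F, Cl, Br, N, O, S, P, =, #`
#' (elements counted over heavy atoms, `=` and `#` as bond-token
#' occurrences), emits one key `(A.B)..nA.nB` recording the joint counts,
#' provided both counts are at least 1. A molecule with one chlorine and two
#' nitrogens yields `(Cl.N)..1.2`; two chlorines and one nitrogen yield
#' `(Cl.N)..2.1`.
#'
#' @inheritParams extract_sequence
#' @param pairs A list of length-2 character vectors naming the symbol pairs.
#' @return Named numeric vector with multiplicity 1 per emitted key (family
#'   `APP`).
#' @examples
#' extract_app(build_hsg("ClCCNCN"), list(c("Cl", "N")))
#' @export
extract_app <- function(molecule, pairs) {
  stopifnot(inherits(molecule, "molecule"), is.list(pairs))
  keys <- character(0)
  for (p in pairs) {
    if (length(p) != 2L || !all(p %in% .APP_ALPHABET)) {
      stop(sprintf("APP pair (%s) outside alphabet {%s}",
                   paste(p, collapse = ","),
                   paste(.APP_ALPHABET, collapse = ",")))
    }
    ca <- molecule$counts[[p[1]]]
    cb <- molecule$counts[[p[2]]]
    if (ca >= 1L && cb >= 1L) {
      keys <- c(keys, sprintf("APP:(%s.%s)..%d.%d", p[1], p[2], ca, cb))
    }
  }
  keys <- unique(keys)
  stats::setNames(rep(1, length(keys)), keys)
}

# The unordered symbol pairs of the delta block: the upper triangle of the
# 9x9 matrix over F, Cl, Br, N, O, S, P, =, # in that fixed order.
.delta_pairs <- function() {
  idx <- utils::combn(length(.APP_ALPHABET), 2)
  lapply(seq_len(ncol(idx)), function(k) .APP_ALPHABET[idx[, k]])
}

#' Extract all attributes enabled by a configuration
#'
#' Unions the attribute families switched on by `config`: the `alpha` block
#' contributes S/SS/SSS n-grams (gated by `x1`-`x3`), `beta` contributes
#' EC1-EC3 and NNC, `gamma` contributes the four chlorine atom-pair families
#' (gated by `y1`-`y4`), and `delta` contributes atom-pair proportions over
#' all unordered pairs of the nine-symbol alphabet. APP keys enter with
#' multiplicity 1; when `gamma` and `delta` overlap on a key it is kept once.
#'
#' @inheritParams extract_sequence
#' @param config A `cw_config` from [model_config()].
#' @return Named numeric vector of attribute multiplicities.
#' @examples
#' extract_attributes(build_hsg("ClCN"), preset_config("M1"))
#' @export
extract_attributes <- function(molecule, config) {
  stopifnot(inherits(molecule, "molecule"), inherits(config, "cw_config"))
  out <- stats::setNames(numeric(0), character(0))
  if (config$alpha == 1L) {
    if (config$x1 == 1L) out <- c(out, extract_sequence(molecule, 1))
    if (config$x2 == 1L) out <- c(out, extract_sequence(molecule, 2))
    if (config$x3 == 1L) out <- c(out, extract_sequence(molecule, 3))
  }
  if (config$beta == 1L) {
    out <- c(out, extract_ec(molecule, 1), extract_ec(molecule, 2),
             extract_ec(molecule, 3), extract_nnc(molecule))
  }
  app_pairs <- list()
  if (config$gamma == 1L) {
    gp <- list(c("Cl", "N"), c("Cl", "O"), c("Cl", "S"), c("Cl", "P"))
    on <- c(config$y1, config$y2, config$y3, config$y4) == 1L
    app_pairs <- c(app_pairs, gp[on])
  }
  if (config$delta == 1L) {
    app_pairs <- c(app_pairs, .delta_pairs())
  }
  if (length(app_pairs) > 0L) {
    out <- c(out, extract_app(molecule, app_pairs))
  }
  # unordered-pair overlap between the gamma and delta blocks: keep keys once
  out <- out[!duplicated(names(out))]
  out
}

#' Dump the attribute set of a SMILES string as TSV
#'
#' Debug helper mirroring the extraction used in model building: writes (or
#' returns) a table with columns `family`, `key`, `count`.
#'
#' @param smiles A SMILES string.
#' @param config A `cw_config`.
#' @param path Optional file path; when `NULL` the data frame is returned
#'   only.
#' @return Invisibly, a data frame with columns `family`, `key`, `count`.
#' @export
dump_attributes <- function(smiles, config, path = NULL) {
  attrs <- extract_attributes(build_hsg(smiles), config)
  df <- data.frame(
    family = key_family(names(attrs)),
    key = sub("^[^:]*:", "", names(attrs)),
    count = as.numeric(attrs),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}
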