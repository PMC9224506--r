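# Synthetic SMILES libraries with planted linear truth.
#
# The generator emulates the kind of datasets the method is applied to: a
# few hundred small organic molecules over the elements C, F, Cl, Br, N, O,
# S, P with double and triple bonds, labelled by a known linear function of
# a known descriptor plus Gaussian noise, with endpoints spanning roughly
# the -1 to 4.3 log10 mg/kg bw/day range observed in sub-chronic
# repeated-dose datasets. Molecules are assembled from templates (never
# random grammar walks) so every generated string parses without a
# chemistry toolkit.

# Deterministic template molecules guaranteeing that every symbol of the
# atom-pair alphabet occurs in at least five molecules.
.coverage_templates <- function(halogen_free = FALSE) {
  halo <- c(
    "FC", "FCC", "FCCC", "CC(F)C", "FCCF",
    "ClC", "ClCC", "ClCCC", "CC(Cl)C", "ClCCl",
    "BrC", "BrCC", "BrCCC", "CC(Br)C", "BrCCBr",
    "ClCCN", "FCCO", "BrCCS", "ClCCNCN", "ClC(Cl)CN"
  )
  halo_arene <- c("Fc1ccccc1", "Clc1ccccc1", "Brc1ccccc1",
                  "Clc1ccc(Cl)cc1", "Fc1ccc(C)cc1")
  core <- c(
    "NC", "NCC", "CNC", "CCNC", "CN(C)C",
    "OC", "OCC", "COC", "CCOC", "OCCO",
    "SC", "SCC", "CSC", "CCSC", "SCCS",
    "CP", "CCP", "CPC", "COP(=O)(O)C", "CCOP(=O)(O)OC",
    "C=C", "C=CC", "C=CCC", "CC=CC", "C=C(C)C",
    "C#C", "C#CC", "CC#CC", "C#CCC", "CC#N", "CCC#N", "N#CCC#N",
    "c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "Nc1ccccc1",
    "Sc1ccccc1", "Cc1ccc(C)cc1", "Cc1ccc(O)cc1", "Nc1ccc(C)cc1",
    "CC", "CCC", "CCCC", "CC(C)C", "CCCCC"
  )
  if (halogen_free) core else c(halo, halo_arene, core)
}

# One random template-based molecule as a SMILES string. Aromatic
# chemistry is drawn with elevated probability: organic toxicity datasets
# are aromatic-rich, and a well-supported aromatic attribute block keeps
# every attribute family represented across random subsets.
.random_molecule <- function(halogen_free = FALSE) {
  subs <- c("F", "Cl", "Br", "N", "O", "S", "C")
  if (halogen_free) subs <- c("N", "O", "S", "C")
  family <- sample(c("alkane", "subst", "hetero", "ene", "yne", "arene",
                     "phos", "amine"), 1,
                   prob = c(0.10, 0.18, 0.12, 0.08, 0.06, 0.33, 0.06, 0.07))
  len <- sample(2:8, 1)
  chain <- function(l) paste(rep("C", l), collapse = "")
  switch(family,
    alkane = {
      if (stats::runif(1) < 0.4 && len >= 3) {
        pos <- sample(2:(len - 1), 1)
        paste0(chain(pos), "(C)", chain(len - pos))
      } else chain(len)
    },
    subst = {
      x <- sample(subs, 1)
      if (len >= 3 && stats::runif(1) < 0.5) {
        pos <- sample(2:(len - 1), 1)
        paste0(chain(pos), "(", x, ")", chain(len - pos))
      } else paste0(x, chain(len))
    },
    hetero = {
      x <- sample(c("N", "O", "S"), 1)
      paste0(chain(max(1, len - 2)), x, chain(sample(1:3, 1)))
    },
    ene = paste0(chain(sample(1:3, 1)), "=", chain(max(1, len - 2))),
    yne = paste0(chain(sample(1:2, 1)), "#", chain(max(1, len - 2))),
    arene = {
      kind <- sample(1:3, 1)
      x <- sample(c(subs, "CC", "CCC", "OC", "NC"), 1)
      if (kind == 1) paste0(x, "c1ccccc1")
      else if (kind == 2) {
        y <- sample(subs, 1)
        paste0(x, "c1ccc(", y, ")cc1")
      } else paste0(chain(sample(1:4, 1)), "c1ccccc1")
    },
    phos = sample(c(
      paste0(chain(sample(1:3, 1)), "OP(=O)(O)O", chain(sample(1:2, 1))),
      paste0(chain(sample(1:3, 1)), "P(", sample(c("C", "O"), 1), ")C")
    ), 1),
    amine = {
      k <- sample(1:3, 1)
      if (k == 1) paste0("N", chain(len))
      else if (k == 2) paste0(chain(sample(1:3, 1)), "N", chain(sample(1:3, 1)))
      else paste0(chain(sample(1:2, 1)), "N(C)", chain(sample(1:2, 1)))
    }
  )
}

#' Generate a synthetic SMILES library
#'
#' Returns `n` unique, parseable SMILES strings assembled from templates
#' (linear and branched alkanes, halogenated alkanes, amines, ethers,
#' thioethers, phosphates, alkenes, alkynes and simple aromatics). For
#' `n >= 60` every symbol of the atom-pair alphabet `F, Cl, Br, N, O, S, P,
#' =, #` is guaranteed to appear in at least five molecules.
#'
#' @param n Library size.
#' @param seed Integer seed; the same seed reproduces the same library.
#' @param halogen_free When `TRUE`, restrict templates to halogen-free
#'   chemistry (used for applicability-domain challenges).
#' @return Character vector of `n` unique SMILES.
#' @export
generate_library <- function(n = 200, seed = 1, halogen_free = FALSE) {
  stopifnot(is.numeric(n), n >= 1)
  with_seed(seed, {
    out <- unique(.coverage_templates(halogen_free))
    if (length(out) > n) out <- out[seq_len(n)]
    attempts <- 0L
    max_attempts <- 200L * n
    while (length(out) < n && attempts < max_attempts) {
      out <- union(out, .random_molecule(halogen_free))
      attempts <- attempts + 1L
    }
    if (length(out) < n) {
      stop(sprintf("could not assemble %d unique molecules (template space too small)", n))
    }
    out[seq_len(n)]
  })
}

#' Plant a linear truth on a SMILES library
#'
#' Draws a "true" correlation weight uniformly in `[0.5, 2.5]` for every
#' attribute occurring in the library (under `config`), computes the true
#' descriptor of every molecule, and scales an affine map so the labels span
#' the requested endpoint range, adding Gaussian noise:
#' `value = c0 + c1 * DCW_true + Normal(0, noise_sigma)`.
#'
#' @param library Character vector of SMILES (e.g. from
#'   [generate_library()]).
#' @param config A `cw_config` describing which attributes carry truth.
#' @param noise_sigma Label noise standard deviation (log10 units).
#' @param seed Integer seed.
#' @param value_range Target range of the noise-free labels (log10 mg/kg
#'   bw/day; default matches sub-chronic endpoint datasets).
#' @param paired When `TRUE`, also emit a `value2` column with
#'   `value2 = value + U(0.05, 0.5)` so that `value <= value2` (a paired
#'   NOAEL/LOAEL table) holds by construction.
#' @return List with `data` (data frame `id`, `cas`, `smiles`, `value`
#'   and optionally `value2`) and `planted` (list `true_weights`, `true_c0`,
#'   `true_c1`, `noise_sigma`, `seed`).
#' @export
plant_and_label <- function(library, config, noise_sigma = 0, seed = 1,
                            value_range = c(-1, 4.3), paired = FALSE) {
  stopifnot(is.character(library), length(library) >= 4L,
            inherits(config, "cw_config"), noise_sigma >= 0)
  attrs <- lapply(library, function(s) extract_attributes(build_hsg(s), config))
  keys <- sort(unique(unlist(lapply(attrs, names), use.names = FALSE)))
  if (length(keys) == 0L) stop("no attributes extracted under this configuration")
  with_seed(seed, {
    tw <- stats::setNames(stats::runif(length(keys), 0.5, 2.5), keys)
    dcw_true <- vapply(attrs, function(a) sum(as.numeric(a) * tw[names(a)]),
                       numeric(1))
    if (max(dcw_true) == min(dcw_true)) {
      stop("degenerate planted descriptor: all molecules identical under config")
    }
    c1 <- diff(value_range) / (max(dcw_true) - min(dcw_true))
    c0 <- value_range[1] - c1 * min(dcw_true)
    value <- c0 + c1 * dcw_true + stats::rnorm(length(library), 0, noise_sigma)
    data <- data.frame(
      id = sprintf("SYN%04d", seq_along(library)),
      cas = "",
      smiles = library,
      value = value,
      stringsAsFactors = FALSE
    )
    if (paired) data$value2 <- data$value + stats::runif(length(library), 0.05, 0.5)
    list(
      data = data,
      planted = list(true_weights = tw, true_c0 = c0, true_c1 = c1,
                     noise_sigma = noise_sigma, seed = seed)
    )
  })
}

#' Build an applicability-domain challenge
#'
#' Generates a halogen-free training-like library and a perhalogenated
#' challenge set. Every challenge molecule contains halogen-bearing
#' attributes absent from the training chemistry, so its statistical defect
#' is driven up and the in-domain rate of the challenge set falls below that
#' of the training-like set.
#'
#' @param seed Integer seed.
#' @param n_train Size of the halogen-free training-like library.
#' @param n_challenge Size of the perhalogenated challenge set.
#' @return List with character vectors `train` and `challenge`.
#' @export
make_ad_challenge <- function(seed = 1, n_train = 120, n_challenge = 40) {
  train <- generate_library(n_train, seed = seed, halogen_free = TRUE)
  challenge <- with_seed(seed, {
    out <- character(0)
    halos <- c("F", "Cl", "Br")
    attempts <- 0L
    while (length(out) < n_challenge && attempts < 200L * n_challenge) {
      k <- sample(1:3, 1)  # carbons in the backbone
      parts <- vapply(seq_len(k), function(i) {
        nh <- if (k == 1) 4L else if (i %in% c(1L, k)) 3L else 2L
        h <- sample(halos, nh, replace = TRUE)
        if (i == 1L) {
          paste0(h[1], "C", paste0("(", h[-1], ")", collapse = ""))
        } else {
          paste0("C", paste0("(", h[-nh], ")", collapse = ""), h[nh])
        }
      }, character(1))
      out <- union(out, paste(parts, collapse = ""))
      attempts <- attempts + 1L
    }
    if (length(out) < n_challenge) {
      stop("could not assemble enough unique perhalogenated molecules")
    }
    out[seq_len(n_challenge)]
  })
  list(train = train, challenge = challenge)
}
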