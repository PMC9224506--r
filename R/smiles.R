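# SMILES tokenisation and hydrogen-suppressed molecular graphs.
#
# The dialect is a Daylight-style subset sufficient for small organic
# molecules: organic-subset atoms (B, C, N, O, S, P, F, I plus two-character
# Cl and Br), aromatic lowercase atoms, bracket atoms as single tokens, ring
# closures (digits and %nn), branches, and the bond symbols - = # : / \.
# Stereo markers are kept as tokens but carry no graph semantics: every
# attribute downstream is a string or graph count, not a geometric feature.

.ATOM_UPPER <- c("B", "C", "N", "O", "S", "P", "F", "I")
.ATOM_LOWER <- c("b", "c", "n", "o", "s", "p")
.BOND_TOKENS <- c("-", "=", "#", ":", "/", "\\")

#' Tokenize a SMILES string
#'
#' Splits a SMILES string into its lexical tokens. Two-character element
#' symbols (`Cl`, `Br`) and complete bracket atoms (`[...]`) are single
#' tokens; ring-closure digits (and `%nn` pairs), bond symbols and
#' parentheses are one token each. Joining the tokens reproduces the input
#' exactly.
#'
#' @param smiles A single non-empty SMILES string.
#' @return Character vector of tokens, in input order.
#' @examples
#' tokenize_smiles("ClCCl")    # "Cl" "C" "Cl"
#' tokenize_smiles("C(=O)O")
#' @export
tokenize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("malformed SMILES: expected a single non-empty string")
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  tokens <- character(0)
  i <- 1L
  depth <- 0L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) {
        stop(sprintf("malformed SMILES: unclosed '[' at position %d", i))
      }
      tokens <- c(tokens, paste(chars[i:j], collapse = ""))
      i <- j + 1L
    } else if (ch == "]") {
      stop(sprintf("malformed SMILES: unmatched ']' at position %d", i))
    } else if (ch == "%") {
      if (i + 2L > n || !all(grepl("[0-9]", chars[(i + 1L):(i + 2L)]))) {
        stop(sprintf("malformed SMILES: '%%' needs two digits at position %d", i))
      }
      tokens <- c(tokens, paste(chars[i:(i + 2L)], collapse = ""))
      i <- i + 3L
    } else if (ch %in% c("C", "B") && i < n && chars[i + 1L] %in% c("l", "r") &&
               paste0(ch, chars[i + 1L]) %in% c("Cl", "Br")) {
      tokens <- c(tokens, paste0(ch, chars[i + 1L]))
      i <- i + 2L
    } else if (ch == "(") {
      depth <- depth + 1L
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else if (ch == ")") {
      if (depth == 0L) {
        stop(sprintf("malformed SMILES: unmatched ')' at position %d", i))
      }
      depth <- depth - 1L
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else if (ch %in% .ATOM_UPPER || ch %in% .ATOM_LOWER ||
               ch %in% .BOND_TOKENS || grepl("[0-9]", ch) || ch == ".") {
      tokens <- c(tokens, ch)
      i <- i + 1L
    } else {
      stop(sprintf("malformed SMILES: unexpected character '%s' at position %d",
                   ch, i))
    }
  }
  if (depth > 0L) {
    stop("malformed SMILES: unclosed '(' at end of string")
  }
  tokens
}

# Element symbol of an atom token; bracket atoms are stripped of isotope,
# H-count, charge and chirality so "[NH4+]" -> "N", "[nH]" -> "n".
.token_element <- function(tok) {
  if (startsWith(tok, "[")) {
    inner <- sub("^\\[", "", sub("\\]$", "", tok))
    inner <- sub("^[0-9]+", "", inner)  # isotope
    m <- regmatches(inner, regexpr("^([A-Z][a-z]?|[a-z])", inner))
    if (length(m) == 0L || !nzchar(m)) {
      stop(sprintf("malformed SMILES: bracket atom '%s' has no element", tok))
    }
    m
  } else {
    tok
  }
}

.is_atom_token <- function(tok) {
  startsWith(tok, "[") | tok %in% c(.ATOM_UPPER, .ATOM_LOWER, "Cl", "Br")
}

#' Build a hydrogen-suppressed molecular graph
#'
#' Parses a SMILES string into a molecular graph whose vertices are the
#' non-hydrogen atoms in token order and whose edges follow SMILES adjacency
#' including branches and ring closures. Explicit bracket hydrogens are
#' dropped. Aromatic bonds are recorded with order 1 (degree counting treats
#' the aromatic system as single bonds); `=` and `#` give orders 2 and 3.
#'
#' @param smiles A SMILES string.
#' @return An object of class `molecule`: a list with elements `smiles`,
#'   `tokens`, `atoms` (element symbols, lowercase for aromatic atoms),
#'   `edges` (data frame `from`, `to`, `order`) and `counts`, a named integer
#'   vector of occurrences of `F, Cl, Br, N, O, S, P` (atoms, aromatic forms
#'   counted with their uppercase element) and of the bond tokens `=`, `#`.
#' @examples
#' m <- build_hsg("CCO")
#' molecule_degrees(m)  # 1 2 1
#' @export
build_hsg <- function(smiles) {
  tokens <- tokenize_smiles(smiles)
  atoms <- character(0)
  is_h <- logical(0)
  from <- integer(0); to <- integer(0); ord <- integer(0)
  prev <- NA_integer_
  pending <- NA_integer_
  stack <- integer(0)
  ring <- list()  # closure label -> list(atom, bond)
  add_edge <- function(a, b, o) {
    from <<- c(from, a); to <<- c(to, b); ord <<- c(ord, o)
  }
  for (tok in tokens) {
    if (.is_atom_token(tok)) {
      elem <- .token_element(tok)
      idx <- length(atoms) + 1L
      atoms <- c(atoms, elem)
      is_h <- c(is_h, toupper(elem) == "H")
      if (!is.na(prev)) {
        add_edge(prev, idx, if (is.na(pending)) 1L else pending)
      }
      prev <- idx
      pending <- NA_integer_
    } else if (tok %in% .BOND_TOKENS) {
      pending <- switch(tok, "=" = 2L, "#" = 3L, 1L)
    } else if (tok == "(") {
      if (is.na(prev)) stop("malformed SMILES: branch with no preceding atom")
      stack <- c(stack, prev)
    } else if (tok == ")") {
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
    } else if (grepl("^%?[0-9]", tok)) {
      if (is.na(prev)) stop("malformed SMILES: ring closure with no atom")
      lab <- tok
      if (!is.null(ring[[lab]])) {
        open <- ring[[lab]]
        o <- if (!is.na(pending)) pending else if (!is.na(open$bond)) open$bond else 1L
        add_edge(open$atom, prev, o)
        ring[[lab]] <- NULL
      } else {
        ring[[lab]] <- list(atom = prev, bond = pending)
      }
      pending <- NA_integer_
    } else if (tok == ".") {
      prev <- NA_integer_
      pending <- NA_integer_
    }
    # stereo tokens (/ \) already mapped to bond order 1 above; '@', '+' etc.
    # occur only inside bracket tokens and never reach this loop
  }
  if (length(ring) > 0L) {
    stop(sprintf("malformed SMILES: unmatched ring-closure digit(s) %s",
                 paste(names(ring), collapse = ", ")))
  }
  # drop explicit hydrogens
  if (any(is_h)) {
    keep <- which(!is_h)
    remap <- integer(length(atoms))
    remap[keep] <- seq_along(keep)
    ke <- !is_h[from] & !is_h[to]
    from <- remap[from[ke]]; to <- remap[to[ke]]; ord <- ord[ke]
    atoms <- atoms[keep]
  }
  elems <- c("F", "Cl", "Br", "N", "O", "S", "P")
  up <- ifelse(nchar(atoms) == 1L, toupper(atoms), atoms)
  counts <- vapply(elems, function(e) sum(up == e), integer(1))
  counts <- c(counts,
              "=" = sum(tokens == "="),
              "#" = sum(tokens == "#"))
  structure(
    list(smiles = smiles, tokens = tokens, atoms = atoms,
         edges = data.frame(from = from, to = to, order = ord),
         counts = counts),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %s: %d heavy atoms, %d bonds\n",
              x$smiles, length(x$atoms), nrow(x$edges)))
  invisible(x)
}

#' Vertex degrees of a molecule
#'
#' @param molecule A `molecule` from [build_hsg()].
#' @return Integer vector of vertex degrees, one per heavy atom.
#' @export
molecule_degrees <- function(molecule) {
  stopifnot(inherits(molecule, "molecule"))
  nv <- length(molecule$atoms)
  deg <- integer(nv)
  for (k in seq_len(nrow(molecule$edges))) {
    deg[molecule$edges$from[k]] <- deg[molecule$edges$from[k]] + 1L
    deg[molecule$edges$to[k]] <- deg[molecule$edges$to[k]] + 1L
  }
  deg
}

# Adjacency list (list of integer vectors) for a molecule.
.adjacency <- function(molecule) {
  nv <- length(molecule$atoms)
  adj <- vector("list", nv)
  for (k in seq_len(nrow(molecule$edges))) {
    a <- molecule$edges$from[k]; b <- molecule$edges$to[k]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}
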