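# Brute-force oracles, written independently of the package internals:
# explicit loops and matrix algebra only, no shared helper code.

# --- attribute oracles -----------------------------------------------------

# n-gram counts by direct string windows over the token list
oracle_sequence <- function(tokens, order) {
  fam <- c("S", "SS", "SSS")[order]
  out <- new.env()
  if (length(tokens) < order) return(setNames(numeric(0), character(0)))
  for (i in seq_len(length(tokens) - order + 1L)) {
    w <- tokens[i:(i + order - 1L)]
    a <- paste(w, collapse = "~")
    b <- paste(rev(w), collapse = "~")
    key <- paste0(fam, ":", if (a <= b) a else b)
    out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + 1
  }
  v <- unlist(as.list(out))
  v[order(names(v))]
}

# adjacency matrix of a molecule from its edge list
oracle_adjacency <- function(mol) {
  nv <- length(mol$atoms)
  A <- matrix(0, nv, nv)
  for (k in seq_len(nrow(mol$edges))) {
    i <- mol$edges$from[k]; j <- mol$edges$to[k]
    A[i, j] <- 1; A[j, i] <- 1
  }
  A
}

# Morgan extended connectivity by matrix power: EC_k = A^k %*% degree
oracle_ec <- function(mol, order) {
  A <- oracle_adjacency(mol)
  v <- rowSums(A)
  for (k in seq_len(order)) v <- drop(A %*% v)
  keys <- sprintf("EC%d:%s/EC%d=%s", order, mol$atoms, order,
                  format(v, trim = TRUE, scientific = FALSE))
  tab <- table(keys)
  setNames(as.numeric(tab), names(tab))
}

oracle_nnc <- function(mol) {
  A <- oracle_adjacency(mol)
  keys <- character(length(mol$atoms))
  for (v in seq_along(mol$atoms)) {
    nb <- sort(mol$atoms[which(A[v, ] == 1)])
    keys[v] <- sprintf("NNC:%s/N[%s]", mol$atoms[v], paste(nb, collapse = ","))
  }
  tab <- table(keys)
  setNames(as.numeric(tab), names(tab))
}

# atom-pair proportions by direct symbol counting over tokens
oracle_app <- function(mol, pairs) {
  count_symbol <- function(s) {
    if (s %in% c("=", "#")) return(sum(mol$tokens == s))
    up <- ifelse(nchar(mol$atoms) == 1L, toupper(mol$atoms), mol$atoms)
    sum(up == s)
  }
  keys <- character(0)
  for (p in pairs) {
    ca <- count_symbol(p[1]); cb <- count_symbol(p[2])
    if (ca >= 1 && cb >= 1) {
      keys <- c(keys, sprintf("APP:(%s.%s)..%d.%d", p[1], p[2], ca, cb))
    }
  }
  keys <- unique(keys)
  setNames(rep(1, length(keys)), keys)
}

# compare two key->count maps exactly
expect_same_counts <- function(a, b) {
  a <- a[order(names(a))]; b <- b[order(names(b))]
  expect_identical(names(a), names(b))
  expect_equal(unname(as.numeric(a)), unname(as.numeric(b)))
}

# --- metric oracles (explicit loops) --------------------------------------

oracle_r2 <- function(y, yhat) {
  n <- length(y)
  my <- sum(y) / n; mp <- sum(yhat) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (y[i] - my) * (yhat[i] - mp)
    sxx <- sxx + (y[i] - my)^2
    syy <- syy + (yhat[i] - mp)^2
  }
  (sxy / sqrt(sxx * syy))^2
}

oracle_q2_loo <- function(x, y) {
  n <- length(y)
  press <- 0
  for (k in seq_len(n)) {
    fit <- lm(y[-k] ~ x[-k])
    pred <- unname(coef(fit)[1] + coef(fit)[2] * x[k])
    press <- press + (y[k] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

oracle_q2_f3 <- function(y_ext, yhat_ext, y_train) {
  num <- sum((y_ext - yhat_ext)^2) / length(y_ext)
  den <- sum((y_train - mean(y_train))^2) / length(y_train)
  1 - num / den
}

oracle_ccc <- function(y, yhat) {
  n <- length(y)
  my <- mean(y); mp <- mean(yhat)
  sy <- 0; sp <- 0; sc <- 0
  for (i in seq_len(n)) {
    sy <- sy + (y[i] - my)^2
    sp <- sp + (yhat[i] - mp)^2
    sc <- sc + (y[i] - my) * (yhat[i] - mp)
  }
  (2 * sc / n) / (sy / n + sp / n + (my - mp)^2)
}

oracle_iic <- function(y, yhat) {
  res <- y - yhat
  neg <- abs(res[res < 0]); pos <- abs(res[res >= 0])
  if (length(neg) == 0 || length(pos) == 0) return(0)
  cor(y, yhat) * min(mean(neg), mean(pos)) / max(mean(neg), mean(pos))
}

oracle_cii <- function(x, y) {
  r2all <- cor(x, y)^2
  tot <- 0
  for (k in seq_along(x)) {
    fit <- lm(y[-k] ~ x[-k])
    r2k <- cor(y[-k], fitted(fit))^2
    if (r2k > r2all) tot <- tot + (r2k - r2all)
  }
  1 - tot
}

oracle_f <- function(r2, n) r2 * (n - 2) / (1 - r2)

# --- shared fixtures -------------------------------------------------------

# small-molecule fixture library (<= 8 heavy atoms), template-generated plus
# hand-picked structures exercising brackets, rings and stereo tokens
fixture_library <- function(n = 100) {
  hand <- c("C", "CC", "ClCCl", "C(=O)O", "c1ccccc1", "ClC(Cl)Cl",
            "C1CC1", "C1CCC1C", "[NH4+]", "C[N+](C)(C)C", "O=C(O)C",
            "N#CC", "FC(F)F", "C/C=C/C", "CC(=O)OC", "S=C=S")
  lib <- generate_library(3 * n, seed = 11)
  heavy <- vapply(lib, function(s) length(build_hsg(s)$atoms), numeric(1))
  unique(c(hand, lib[heavy <= 8]))[seq_len(n)]
}

# configuration used in parameter-recovery experiments: SMILES 1- and 2-gram
# attributes, pure correlation target (no IIC/CII terms)
recovery_config <- function(T = 1, N = 30) {
  model_config(alpha = 1, beta = 0, gamma = 0, delta = 0,
               x1 = 1, x2 = 1, x3 = 0, iic_w = 0, cii_w = 0, T = T, N = N)
}

# full-family configuration for attribute extraction tests
all_family_config <- function() {
  model_config(alpha = 1, beta = 1, gamma = 1, delta = 1,
               x1 = 1, x2 = 1, x3 = 1, y1 = 1, y2 = 1, y3 = 1, y4 = 1,
               T = 1, N = 1)
}
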