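test_that("n-gram extraction matches hand examples and normalises direction", {
  m <- build_hsg("CCO")
  expect_same_counts(extract_sequence(m, 2),
                     c("SS:C~C" = 1, "SS:C~O" = 1))
  # a string and its reverse yield identical 2-gram keys
  expect_same_counts(extract_sequence(build_hsg("OCC"), 2),
                     extract_sequence(m, 2))
  expect_same_counts(extract_sequence(build_hsg("ClCCl"), 1),
                     c("S:C" = 1, "S:Cl" = 2))
  expect_error(extract_sequence(m, 4), "order")
})

test_that("Morgan extended connectivity follows the hand-computed recursion", {
  # ethane: both vertices degree 1, EC1 = neighbour degree = 1
  expect_same_counts(extract_ec(build_hsg("CC"), 1), c("EC1:C/EC1=1" = 2))
  # propane: degrees (1,2,1); every vertex sums neighbour degrees to 2
  expect_same_counts(extract_ec(build_hsg("CCC"), 1), c("EC1:C/EC1=2" = 3))
  # benzene: every vertex has two degree-2 neighbours
  expect_same_counts(extract_ec(build_hsg("c1ccccc1"), 1), c("EC1:c/EC1=4" = 6))
})

test_that("nearest-neighbour codes encode the sorted neighbour multiset", {
  nnc <- extract_nnc(build_hsg("CCO"))
  expect_equal(nnc[["NNC:C/N[C,O]"]], 1)
  expect_same_counts(extract_nnc(build_hsg("CC")), c("NNC:C/N[C]" = 2))
  expect_same_counts(extract_nnc(build_hsg("C")), c("NNC:C/N[]" = 1))
})

test_that("atom-pair proportions encode joint counts", {
  # one chlorine, two nitrogens
  expect_identical(names(extract_app(build_hsg("ClCCNCN"), list(c("Cl", "N")))),
                   "APP:(Cl.N)..1.2")
  # two chlorines, one nitrogen
  expect_identical(names(extract_app(build_hsg("ClC(Cl)CN"), list(c("Cl", "N")))),
                   "APP:(Cl.N)..2.1")
  # absent element emits nothing
  expect_length(extract_app(build_hsg("CCN"), list(c("Cl", "N"))), 0)
  expect_error(extract_app(build_hsg("CC"), list(c("C", "N"))), "alphabet")
})

test_that("extraction agrees with brute-force oracles on the fixture library", {
  for (smi in fixture_library(100)) {
    mol <- build_hsg(smi)
    for (ord in 1:3) {
      expect_same_counts(extract_sequence(mol, ord),
                         oracle_sequence(mol$tokens, ord))
      expect_same_counts(extract_ec(mol, ord), oracle_ec(mol, ord))
    }
    expect_same_counts(extract_nnc(mol), oracle_nnc(mol))
    pairs <- list(c("Cl", "N"), c("F", "O"), c("=", "#"), c("S", "P"),
                  c("Br", "="))
    expect_same_counts(extract_app(mol, pairs), oracle_app(mol, pairs))
  }
})

test_that("graph families are invariant to branch reordering, string families need not be", {
  pairs <- list(
    c("CC(Cl)(N)O", "CC(O)(N)Cl"),
    c("CC(C)(CC)N", "CC(N)(C)CC"),
    c("c1ccccc1C(N)O", "c1ccccc1C(O)N")
  )
  app <- list(c("Cl", "N"), c("Cl", "O"), c("N", "O"))
  for (p in pairs) {
    a <- build_hsg(p[1]); b <- build_hsg(p[2])
    for (ord in 1:3) {
      expect_same_counts(extract_ec(a, ord), extract_ec(b, ord))
    }
    expect_same_counts(extract_nnc(a), extract_nnc(b))
    expect_same_counts(extract_app(a, app), extract_app(b, app))
  }
})

test_that("total 1-gram count equals the number of tokens", {
  for (smi in fixture_library(40)) {
    mol <- build_hsg(smi)
    expect_equal(sum(extract_sequence(mol, 1)), length(mol$tokens))
  }
})

test_that("extract_attributes honours the configuration toggles", {
  cfg_m5 <- preset_config("M5")  # alpha (S only) + delta
  a <- extract_attributes(build_hsg("ClCCl"), cfg_m5)
  # S keys only: one listed element (Cl), so no delta pair fires
  expect_setequal(names(a), c("S:C", "S:Cl"))

  cfg_m1 <- preset_config("M1")  # alpha (S,SS,SSS) + gamma
  b <- extract_attributes(build_hsg("ClCN"), cfg_m1)
  expect_true("APP:(Cl.N)..1.1" %in% names(b))
  fams <- sub(":.*$", "", names(b))
  expect_true(all(fams %in% c("S", "SS", "SSS", "APP")))

  # delta block: upper-triangle pairs over the fixed alphabet
  cfg_d <- model_config(alpha = 0, beta = 1, gamma = 0, delta = 1)
  d <- extract_attributes(build_hsg("ClCCN"), cfg_d)
  expect_true("APP:(Cl.N)..1.1" %in% names(d))
  expect_false(any(grepl("APP:\\(N\\.Cl\\)", names(d))))
})

test_that("dump_attributes reports family, key and count", {
  df <- dump_attributes("ClCN", preset_config("M1"))
  expect_named(df, c("family", "key", "count"))
  expect_true("APP" %in% df$family)
  tmp <- tempfile(fileext = ".tsv")
  dump_attributes("ClCN", preset_config("M1"), tmp)
  expect_true(file.exists(tmp))
  unlink(tmp)
})
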