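test_that("rare-feature blocking follows the threshold convention", {
  freq <- c(A = 5L, B = 1L)
  expect_identical(block_rare(freq, 2), "B")
  expect_identical(block_rare(freq, 1), character(0))
})

test_that("DCW is the weighted multiplicity sum with toggle semantics", {
  cfg <- model_config(alpha = 1, gamma = 0, x1 = 1, x2 = 1, x3 = 0)
  attrs <- c("S:C" = 3, "SS:C~C" = 2)
  w <- c("S:C" = 2, "SS:C~C" = 0.5)
  expect_equal(as.numeric(compute_dcw(attrs, w, cfg)), 3 * 2 + 2 * 0.5)
  # all-zero weights
  expect_equal(as.numeric(compute_dcw(attrs, w * 0, cfg)), 0)
  # x2 = 0 zeroes the SS family even when keys are present
  cfg2 <- model_config(alpha = 1, gamma = 0, x1 = 1, x2 = 0, x3 = 0)
  expect_equal(as.numeric(compute_dcw(c("SS:C~C" = 2), w, cfg2)), 0)
  # blocked keys contribute exactly zero
  expect_equal(as.numeric(compute_dcw(attrs, w, cfg, blocked = "S:C")), 1)
  # unknown keys contribute zero and are reported
  d <- compute_dcw(c(attrs, "S:Zz" = 1), w, cfg)
  expect_equal(as.numeric(d), 7)
  expect_identical(attr(d, "unknown"), "S:Zz")
})

test_that("DCW equals the brute-force dot product on fixture molecules", {
  cfg <- all_family_config()
  set.seed(5)
  for (smi in fixture_library(30)) {
    attrs <- extract_attributes(build_hsg(smi), cfg)
    w <- setNames(runif(length(attrs), -1, 2), names(attrs))
    manual <- 0
    for (k in names(attrs)) manual <- manual + attrs[[k]] * w[[k]]
    expect_equal(as.numeric(compute_dcw(attrs, w, cfg)), manual,
                 tolerance = 1e-12)
  }
})

test_that("raising a present weight raises DCW; blocking never raises |DCW|", {
  cfg <- all_family_config()
  attrs <- extract_attributes(build_hsg("ClCCN"), cfg)
  w <- setNames(rep(1, length(attrs)), names(attrs))
  base <- as.numeric(compute_dcw(attrs, w, cfg))
  for (k in names(attrs)[1:min(5, length(attrs))]) {
    w2 <- w; w2[k] <- w2[k] + 0.5
    expect_gt(as.numeric(compute_dcw(attrs, w2, cfg)), base)
  }
  for (k in names(attrs)) {
    expect_lte(abs(as.numeric(compute_dcw(attrs, w, cfg, blocked = k))),
               abs(base))
  }
})

test_that("linear calibration recovers exact affine data and rejects constants", {
  d <- c(0, 1, 2, 3)
  cf <- fit_linear(d, 2 + 3 * d)
  expect_equal(unname(cf), c(2, 3), tolerance = 1e-12)
  expect_error(fit_linear(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("predictions are affine in DCW with the stored coefficients", {
  lib <- generate_library(80, seed = 3)
  cfg <- recovery_config(N = 5)
  pl <- plant_and_label(lib, cfg, noise_sigma = 0.2, seed = 3)
  fit <- cwqsar(pl$data, cfg, seed = 3)
  pred <- predict(fit, pl$data$smiles[1:10])
  expect_equal(pred$prediction, fit$c0 + fit$c1 * pred$dcw, tolerance = 1e-12)
  # doubling every weight doubles (value - c0)
  fit2 <- fit
  fit2$weights <- fit$weights * 2
  pred2 <- predict(fit2, pl$data$smiles[1:10])
  expect_equal(pred2$prediction - fit2$c0, 2 * (pred$prediction - fit$c0),
               tolerance = 1e-10)
})

test_that("published-form coefficients give the published intercept at DCW 0", {
  # arithmetic check of value = c0 + c1 * dcw with reference coefficients
  c0 <- 2.1123367; c1 <- 0.1651535
  expect_equal(c0 + c1 * 0, 2.1123367)
  expect_equal(c0 + c1 * 10, 3.7638717, tolerance = 1e-7)
})

test_that("model JSON round trip reproduces predictions bit-for-bit", {
  lib <- generate_library(60, seed = 9)
  cfg <- recovery_config(N = 5)
  pl <- plant_and_label(lib, cfg, noise_sigma = 0.1, seed = 9)
  fit <- cwqsar(pl$data, cfg, seed = 9)
  tmp <- tempfile(fileext = ".json")
  save_model(fit, tmp)
  back <- load_model(tmp)
  expect_identical(back$weights, fit$weights)
  expect_identical(back$c0, fit$c0)
  expect_identical(back$blocked, fit$blocked)
  expect_identical(back$ad$threshold, fit$ad$threshold)
  p1 <- predict(fit, pl$data$smiles)
  p2 <- predict(back, pl$data$smiles)
  expect_identical(p1$prediction, p2$prediction)
  expect_identical(p1$in_domain, p2$in_domain)
  # empty blocked set round-trips as character(0), not NULL
  expect_true(is.character(back$blocked))
  unlink(tmp)
})

test_that("model files with wrong or missing schema are refused", {
  tmp <- tempfile(fileext = ".json")
  writeLines('{"schema_version": "other/9"}', tmp)
  expect_error(load_model(tmp), "schema")
  writeLines('{"c0": 1}', tmp)
  expect_error(load_model(tmp), "schema")
  writeLines('{"truncated', tmp)
  expect_error(load_model(tmp), "cannot read")
  unlink(tmp)
})
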