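make_records <- function(n, seed = 1) {
  data.frame(id = sprintf("R%03d", 1:n), cas = "",
             smiles = generate_library(n, seed = seed),
             value = rnorm(n), stringsAsFactors = FALSE)
}

test_that("the four-subset split matches the requested fractions", {
  rec <- data.frame(id = as.character(1:561), cas = "", smiles = "C",
                    value = rnorm(561), stringsAsFactors = FALSE)
  sp <- split_dataset(rec, rep(0.25, 4), seed = 1)
  expect_equal(nrow(sp$active_training), 140)
  expect_equal(nrow(sp$passive_training), 140)
  expect_equal(nrow(sp$calibration), 140)
  expect_equal(nrow(sp$validation), 141)
  # disjoint and exhaustive
  ids <- c(sp$active_training$id, sp$passive_training$id,
           sp$calibration$id, sp$validation$id)
  expect_setequal(ids, rec$id)
  expect_equal(anyDuplicated(ids), 0)
})

test_that("splits are deterministic under seed and vary across seeds", {
  rec <- make_records(60, seed = 2)
  a <- split_dataset(rec, seed = 5)
  b <- split_dataset(rec, seed = 5)
  expect_identical(a$active_training$id, b$active_training$id)
  differs <- vapply(1:5, function(s) {
    !identical(split_dataset(rec, seed = s)$active_training$id,
               a$active_training$id)
  }, logical(1))
  expect_true(any(differs))
  expect_error(split_dataset(rec, c(0.3, 0.3, 0.3, 0.2)), "summing to 1")
  expect_error(split_dataset(rec[1:5, ], seed = 1), "at least 12")
})

test_that("the target function combines its components as configured", {
  lib <- generate_library(48, seed = 4)
  cfg <- recovery_config(N = 1)
  pl <- plant_and_label(lib, cfg, noise_sigma = 0, seed = 4)
  sp <- split_dataset(pl$data, seed = 4)
  # planted weights give perfect correlation on both training subsets
  tf <- target_function(pl$planted$true_weights, sp, cfg)
  expect_equal(tf$r_at, 1, tolerance = 1e-9)
  expect_equal(tf$r_pt, 1, tolerance = 1e-9)
  expect_equal(tf$tf, 2, tolerance = 1e-9)
  # IIC/CII weights enter exactly as configured
  cfg2 <- cfg; cfg2$iic_w <- 0.25; cfg2$cii_w <- 0.30
  tf2 <- target_function(pl$planted$true_weights, sp, cfg2)
  expect_equal(tf2$tf,
               tf2$r_at + tf2$r_pt - 0.1 * abs(tf2$r_at - tf2$r_pt) +
                 0.25 * tf2$iic_c + 0.30 * tf2$cii_c,
               tolerance = 1e-12)
})

test_that("training is deterministic and the accepted-move trace is monotone", {
  lib <- generate_library(80, seed = 6)
  cfg <- recovery_config(N = 10)
  pl <- plant_and_label(lib, cfg, noise_sigma = 0.3, seed = 6)
  f1 <- cwqsar(pl$data, cfg, seed = 11)
  f2 <- cwqsar(pl$data, cfg, seed = 11)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$c0, f2$c0)
  expect_identical(f1$c1, f2$c1)
  # per-epoch tf is non-decreasing (accepted moves only increase it)
  expect_true(all(diff(f1$trace$tf) >= 0))
  f3 <- cwqsar(pl$data, cfg, seed = 12)
  expect_false(identical(f1$weights, f3$weights))
})

test_that("planted noise-free data is recovered with high validation quality", {
  cfg <- recovery_config(T = 1, N = 30)
  for (seed in 1:2) {
    lib <- generate_library(200, seed = seed)
    pl <- plant_and_label(lib, cfg, noise_sigma = 0, seed = seed)
    fit <- cwqsar(pl$data, cfg, seed = seed)
    tab <- summary(fit)$table
    val <- tab[tab$set == "validation", ]
    expect_gte(val$r2, 0.95)
    expect_gte(val$q2f3, 0.9)
    # learned DCW correlates with the planted DCW on the validation set
    dcw_true <- vapply(fit$split$validation$smiles, function(s) {
      a <- extract_attributes(build_hsg(s), cfg)
      sum(as.numeric(a) * pl$planted$true_weights[names(a)])
    }, numeric(1))
    dcw_learn <- predict(fit, fit$split$validation)$dcw
    expect_gte(cor(dcw_true, dcw_learn), 0.97)
  }
})

test_that("validation quality degrades with label noise", {
  cfg <- recovery_config(N = 15)
  val_r2 <- vapply(c(0, 0.3, 0.6), function(sig) {
    mean(vapply(1:3, function(seed) {
      lib <- generate_library(120, seed = seed)
      pl <- plant_and_label(lib, cfg, noise_sigma = sig, seed = seed)
      fit <- cwqsar(pl$data, cfg, seed = seed)
      tab <- summary(fit)$table
      tab[tab$set == "validation", "r2"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(val_r2) <= 0))
})

test_that("degenerate descriptors are diagnosed with advice", {
  # identical molecules -> constant DCW on every subset
  rec <- data.frame(id = as.character(1:16), cas = "", smiles = "CCO",
                    value = rnorm(16), stringsAsFactors = FALSE)
  cfg <- recovery_config(N = 2)
  expect_error(cwqsar(rec, cfg, seed = 1), "degenerate|no active")
  # a threshold larger than any frequency blocks everything
  rec2 <- make_records(20, seed = 3)
  cfg2 <- recovery_config(T = 100, N = 2)
  expect_error(cwqsar(rec2, cfg2, seed = 1), "no active|lower T")
})

test_that("hyperparameter grid search maximises calibration R2 with ordered ties", {
  lib <- generate_library(90, seed = 8)
  cfg <- recovery_config()
  pl <- plant_and_label(lib, cfg, noise_sigma = 0.3, seed = 8)
  best <- select_hyperparams(pl$data, cfg, T_range = c(1, 2),
                             N_range = c(3, 8), seed = 8)
  # exhaustive check against the four individually trained models
  sp <- split_dataset(pl$data, seed = 8)
  grid <- expand.grid(T = c(1, 2), N = c(3, 8))
  r2s <- apply(grid, 1, function(g) {
    cfg2 <- cfg; cfg2$T <- as.integer(g["T"]); cfg2$N <- as.integer(g["N"])
    cwqsar(config = cfg2, split = sp, seed = 8)$calibration_r2
  })
  expect_equal(best$model$calibration_r2, max(r2s))
  # single-cell grid returns that cell
  one <- select_hyperparams(pl$data, cfg, T_range = 2, N_range = 3, seed = 8)
  expect_equal(one$T, 2)
  expect_equal(one$N, 3)
})

test_that("fitted model methods expose the standard interface", {
  lib <- generate_library(70, seed = 10)
  cfg <- recovery_config(N = 5)
  pl <- plant_and_label(lib, cfg, noise_sigma = 0.2, seed = 10)
  fit <- cwqsar(pl$data, cfg, seed = 10)
  expect_named(coef(fit), c("c0", "c1"))
  expect_equal(mean(residuals(fit)), 0, tolerance = 1e-9)
  expect_length(fitted(fit), nrow(fit$split$active_training))
  expect_output(print(fit), "Correlation-weight QSAR")
  expect_output(print(summary(fit)), "Subset statistics")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(length(fitted(fit)), 2))
  sims2 <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(sims, sims2)
  tmp <- tempfile(fileext = ".tsv")
  tr <- write_trace_tsv(fit, tmp)
  expect_named(tr, c("epoch", "tf", "r_at", "r_pt", "iic_c", "cii_c", "r2_cal"))
  unlink(tmp)
  tmp2 <- tempfile(fileext = ".png")
  grDevices::png(tmp2); plot(fit, which = 1:2); grDevices::dev.off()
  expect_true(file.exists(tmp2))
  unlink(tmp2)
})
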