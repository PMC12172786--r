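# Synthetic-data generator: determinism, normalization, ground-truth
# recovery.

test_that("make_signature yields unit-norm weights and an orthogonal map", {
  g <- volume_grid(c(8, 8, 8))
  s <- make_signature(g, seed = 7)
  expect_equal(sum(s$weights^2), 1, tolerance = 1e-12)
  expect_equal(sum(s$nuisance^2), 1, tolerance = 1e-12)
  expect_lt(abs(sum(s$weights * s$nuisance)), 1e-12)
  s2 <- make_signature(g, seed = 7)
  expect_identical(s$weights, s2$weights)
  s3 <- make_signature(g, seed = 8)
  expect_false(identical(s$weights, s3$weights))
})

test_that("noise-free beta maps score back to the exact true expression", {
  cfg <- sim_config(list(list(n_ed = 3, n_hc = 3, n_runs = 2)),
                    noise_orthogonal_sd = 0, noise_iid_sd = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  sc <- score_dataset(sim$betas, sim$signatures)
  expect_lt(max(abs(sc$expression - sim$truth$expression)), 1e-9)
})

test_that("orthogonal-map noise never reaches the expression score", {
  base <- list(list(n_ed = 3, n_hc = 3, n_runs = 1))
  cfg0 <- sim_config(base, noise_orthogonal_sd = 0, noise_iid_sd = 0.2,
                     seed = 5)
  cfg10 <- sim_config(base, noise_orthogonal_sd = 10, noise_iid_sd = 0.2,
                      seed = 5)
  s0 <- score_dataset(simulate_dataset(cfg0)$betas,
                      simulate_dataset(cfg0)$signatures)
  s10 <- score_dataset(simulate_dataset(cfg10)$betas,
                       simulate_dataset(cfg10)$signatures)
  expect_lt(max(abs(s0$expression - s10$expression)), 1e-9)
})

test_that("the same seed reproduces the dataset bit for bit", {
  cfg <- sim_config(list(list(n_ed = 2, n_hc = 2, n_runs = 2)),
                    n_signatures = 2, seed = 123)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$betas[[5]]$values, b$betas[[5]]$values)
})

test_that("adding a signature leaves existing draws untouched", {
  cfg1 <- sim_config(list(list(n_ed = 3, n_hc = 3, n_runs = 2)),
                     n_signatures = 1, seed = 77)
  cfg2 <- sim_config(list(list(n_ed = 3, n_hc = 3, n_runs = 2)),
                     n_signatures = 2, seed = 77)
  t1 <- simulate_expression(cfg1)
  t2 <- simulate_expression(cfg2)
  expect_identical(t1$expression,
                   t2$expression[t2$signature == "sig1"])
})

test_that("simulated deltas have the configured mean, variance, and icc", {
  cfg <- sim_config(list(list(n_ed = 2000, n_hc = 2000, n_runs = 2)),
                    d_within = 0.8, d_between = 0.5, icc = 0.6, seed = 19)
  tr <- simulate_expression(cfg)
  d <- tr[tr$condition == "negative", ]
  expect_equal(mean(d$delta_true), 0.8, tolerance = 0.05)
  # unit variance is the conditional (within-group) variance of delta
  centered <- d$delta_true - ave(d$delta_true, d$group)
  expect_equal(var(centered), 1, tolerance = 0.05)
  gap <- mean(d$delta_true[d$group == "ED"]) -
    mean(d$delta_true[d$group == "HC"])
  expect_equal(gap, 0.5, tolerance = 0.07)
  m <- matrix(d$delta_true, nrow = 2)   # runs x participants
  expect_equal(cor(m[1, ], m[2, ]), 0.6, tolerance = 0.04)
})

test_that("scored noisy maps recover the true within-person effect size", {
  cfg <- sim_config(list(list(n_ed = 100, n_hc = 100, n_runs = 1)),
                    d_within = 1.0, noise_orthogonal_sd = 1,
                    noise_iid_sd = 0.1, seed = 29)
  sim <- simulate_dataset(cfg)
  sc <- score_dataset(sim$betas, sim$signatures)
  rx <- compute_reactivity(sc)
  d <- cohens_d_within(rx$delta)$estimate
  expect_equal(d, 1.0, tolerance = 0.2)
})

test_that("simulate_dataset writes readable NIfTI maps and a manifest", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(list(list(n_ed = 1, n_hc = 1, n_runs = 1)), seed = 3)
  sim <- simulate_dataset(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(sim$manifest$path)))
  vol <- read_volume(sim$manifest$path[1])
  expect_equal(vol$values, sim$betas[[1]]$values, tolerance = 1e-6)
  sig_path <- file.path(dir, "signature_sig1.nii.gz")
  expect_true(file.exists(sig_path))
})

test_that("the three-study preset has the published sample structure", {
  cfg <- sim_preset("three_study", seed = 1)
  sizes <- vapply(cfg$studies, function(s) c(s$n_ed, s$n_hc, s$n_runs),
                  numeric(3))
  expect_equal(sizes[, 1], c(29, 28, 3))
  expect_equal(sizes[, 2], c(20, 20, 3))
  expect_equal(sizes[, 3], c(62, 33, 1))
})
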