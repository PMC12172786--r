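# Reactivity, run averaging, reliability, forced choice.

test_that("compute_reactivity pairs conditions and skips incomplete keys", {
  rec <- make_records(neg = c(5, 2, 1), neu = c(2, 2, 4))
  rx <- compute_reactivity(rec)
  expect_equal(rx$delta, c(3, 0, -3))

  # 3 participants x 2 runs complete, 1 participant missing neutral in run 2
  rec2 <- rbind(
    make_records(neg = 1:4, neu = rep(0, 4), run = "run1"),
    make_records(neg = 1:4, neu = rep(0, 4), run = "run2"))
  rec2 <- rec2[!(rec2$participant == "p4" & rec2$run == "run2" &
                   rec2$condition == "neutral"), ]
  expect_message(rx2 <- compute_reactivity(rec2), "1 incomplete")
  expect_equal(nrow(rx2), 7L)
  expect_equal(nrow(attr(rx2, "skipped")), 1L)

  expect_error(compute_reactivity(rec[0, ]), "empty")
  expect_error(compute_reactivity(rbind(rec, rec[1, ])), "duplicated")
})

test_that("average_runs takes unweighted means and flags partial coverage", {
  rx <- rbind(
    data.frame(study = "s1", participant = "p1", run = paste0("run", 1:3),
               group = NA, signature = "sig", delta = c(1, 2, 3)),
    data.frame(study = "s1", participant = "p2", run = paste0("run", 1:2),
               group = NA, signature = "sig", delta = c(1, 2)))
  av <- average_runs(rx)
  expect_equal(av$delta[av$participant == "p1"], 2)
  expect_equal(av$delta[av$participant == "p2"], 1.5)
  expect_false(av$partial[av$participant == "p1"])
  expect_true(av$partial[av$participant == "p2"])

  single <- rx[rx$run == "run1" & rx$participant == "p1", ]
  expect_equal(average_runs(single)$delta, 1)
})

test_that("reactivity-then-average equals average-then-difference", {
  set.seed(5)
  neg <- matrix(rnorm(12), 4, 3)  # 4 participants x 3 runs
  neu <- matrix(rnorm(12), 4, 3)
  rec <- do.call(rbind, lapply(1:3, function(r)
    make_records(neg[, r], neu[, r], run = paste0("run", r))))
  via_rx <- average_runs(compute_reactivity(rec))
  direct <- rowMeans(neg) - rowMeans(neu)
  expect_equal(via_rx$delta[order(via_rx$participant)],
               direct[order(paste0("p", 1:4))], tolerance = 1e-12)
})

test_that("cronbach_alpha matches the covariance-based oracle formula", {
  mat <- cbind(c(1, 2, 3, 4), c(2, 1, 4, 3))
  a <- cronbach_alpha(mat)
  k <- 2
  cv <- stats::cov(mat)
  vbar <- mean(diag(cv))
  cbar <- mean(cv[upper.tri(cv)])
  oracle <- k * cbar / (vbar + (k - 1) * cbar)
  expect_equal(as.numeric(a), oracle, tolerance = 1e-12)

  set.seed(8)
  for (k in c(3, 5)) {
    m <- matrix(rnorm(40 * k), 40, k) + rnorm(40)
    a <- as.numeric(cronbach_alpha(m))
    cv <- stats::cov(m)
    vbar <- mean(diag(cv))
    cbar <- mean(cv[row(cv) != col(cv)])
    expect_equal(a, k * cbar / (vbar + (k - 1) * cbar), tolerance = 1e-12)
  }
})

test_that("cronbach_alpha handles perfect, null, and invalid inputs", {
  x <- c(1.2, 3.4, 2.2, 5.1)
  expect_equal(as.numeric(cronbach_alpha(cbind(x, x))), 1.0)

  set.seed(99)  # two independent runs: alpha near zero
  m <- matrix(rnorm(2e4), 1e4, 2)
  expect_lt(abs(as.numeric(cronbach_alpha(m))), 0.05)

  expect_error(cronbach_alpha(matrix(1:4, 4, 1)), "2 runs")
  expect_error(cronbach_alpha(matrix(1, 4, 2)), "zero total variance")
  mm <- cbind(c(1, 2, 3, NA), c(2, 1, 4, 3))
  expect_message(a <- cronbach_alpha(mm), "dropped")
  expect_equal(attr(a, "n"), 3L)
})

test_that("cronbach_alpha is invariant to run shifts and common rescaling", {
  set.seed(12)
  m <- matrix(rnorm(60), 20, 3)
  a0 <- as.numeric(cronbach_alpha(m))
  shifted <- sweep(m, 2, c(10, -4, 0.5), "+")
  expect_equal(as.numeric(cronbach_alpha(shifted)), a0, tolerance = 1e-12)
  expect_equal(as.numeric(cronbach_alpha(3.7 * m)), a0, tolerance = 1e-12)
})

test_that("alpha on exchangeable runs follows the Spearman-Brown form", {
  set.seed(21)
  n <- 4000; k <- 3; r <- 0.6
  u <- rnorm(n, 0, sqrt(r))
  m <- u + matrix(rnorm(n * k, 0, sqrt(1 - r)), n, k)
  expected <- k * r / (1 + (k - 1) * r)
  expect_equal(as.numeric(cronbach_alpha(m)), expected, tolerance = 0.04)
})

test_that("inter_run_correlation is a Pearson correlation over shared ids", {
  base <- data.frame(study = "s", participant = paste0("p", 1:10),
                     run = "a", delta = rnorm(10))
  rec <- rbind(base,
               transform(base, run = "b", delta = 2 * base$delta + 1))
  expect_equal(as.numeric(inter_run_correlation(rec, "a", "b")), 1.0)
  rec2 <- rbind(base, transform(base, run = "b", delta = -base$delta))
  expect_equal(as.numeric(inter_run_correlation(rec2, "a", "b")), -1.0)

  set.seed(31)
  rho <- 0.57; n <- 5000
  x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  rec3 <- rbind(
    data.frame(study = "s", participant = paste0("p", 1:n), run = "a",
               delta = x),
    data.frame(study = "s", participant = paste0("p", 1:n), run = "b",
               delta = y))
  expect_equal(as.numeric(inter_run_correlation(rec3, "a", "b")), rho,
               tolerance = 0.03)

  expect_error(inter_run_correlation(base[1:2, ], "a", "b"), "shared")
})

test_that("forced-choice accuracy counts exceedances with ties at 0.5", {
  rec <- make_records(neg = c(3, 2), neu = c(1, 2))  # one win, one tie
  expect_equal(as.numeric(forced_choice_accuracy(rec)), 0.75)
  rec2 <- make_records(neg = c(3, 2, 5), neu = c(1, 0, 2))
  expect_equal(as.numeric(forced_choice_accuracy(rec2)), 1.0)
})

test_that("forced-choice accuracy is invariant under monotone transforms", {
  set.seed(44)
  rec <- make_records(neg = rnorm(50, 1), neu = rnorm(50))
  a0 <- as.numeric(forced_choice_accuracy(rec))
  rec_t <- rec
  rec_t$expression <- exp(rec$expression)      # strictly increasing
  expect_equal(as.numeric(forced_choice_accuracy(rec_t)), a0)
  rec_t$expression <- atan(rec$expression) * 3 + 2
  expect_equal(as.numeric(forced_choice_accuracy(rec_t)), a0)
})

test_that("forced-choice accuracy matches the Gaussian exceedance rate", {
  set.seed(77)
  d <- 2.07; n <- 10000
  deltas <- rnorm(n, d, 1)
  rec <- make_records(neg = deltas, neu = rep(0, n))
  expect_equal(as.numeric(forced_choice_accuracy(rec)), pnorm(d),
               tolerance = 0.01)
})
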