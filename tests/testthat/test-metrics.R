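# metrics and evaluation: MCC closed form, prediction scoring, scaling fits

test_that("mcc matches closed-form and handles degenerate tables", {
  expect_equal(mcc(10, 0, 10, 0), 1)
  expect_equal(mcc(5, 5, 5, 5), 0)
  expect_equal(mcc(90, 10, 80, 20),
               (90 * 80 - 10 * 20) / sqrt(100 * 110 * 90 * 100))
  expect_equal(mcc(0, 0, 100, 0), 0) # zero denominator factor
  expect_error(mcc(-1, 0, 0, 0), "non-negative")
})

test_that("mcc equals the Pearson correlation of the binary vectors", {
  set.seed(5)
  for (k in 1:1000) {
    n <- sample(10:60, 1L)
    y <- stats::rbinom(n, 1L, stats::runif(1L, 0.1, 0.9))
    p <- stats::rbinom(n, 1L, stats::runif(1L, 0.1, 0.9))
    tp <- sum(p & y); fp <- sum(p & !y)
    tn <- sum(!p & !y); fn <- sum(!p & y)
    r <- suppressWarnings(stats::cor(p, y))
    expect_equal(mcc(tp, fp, tn, fn), if (is.na(r)) 0 else r, tolerance = 1e-12)
  }
})

test_that("evaluate_predictions scores all three granularities", {
  pt <- parse_dotbracket("(((...)))")
  y <- as.numeric(!is.na(pt$partner))
  perfect <- evaluate_predictions(list(y), list(pt), "per-base")
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$f1, 1)

  flipped <- evaluate_predictions(list(1 - y), list(pt), "per-base")
  expect_equal(flipped$mcc, -1)

  m <- structure_matrix(pt)
  pe <- evaluate_predictions(list(m), list(pt), "per-entry")
  expect_equal(pe$mcc, 1)
  pp <- evaluate_predictions(list(m), list(pt), "per-pair")
  expect_equal(pp$f1, 1) # precision = recall = 1

  expect_error(evaluate_predictions(list(y[-1L]), list(pt), "per-base"),
               "mismatch")
})

test_that("chance-level predictions give |MCC| < 0.05 at 1e5 positions", {
  set.seed(8)
  y <- stats::rbinom(1e5L, 1L, 0.5)
  shuffled <- sample(y)
  expect_lt(abs(binary_metrics(shuffled, y)$mcc), 0.05)
})

test_that("scaling fits separate planted linear from quadratic growth", {
  lens <- seq(30, 250, by = 20)
  set.seed(2)
  linear <- 0.3 * lens + stats::rnorm(length(lens), 0, 0.3)
  fit <- scaling_fit(lens, linear)
  expect_false(fit$quadratic_significant)
  expect_equal(fit$slope, 0.3, tolerance = 0.05)
  expect_lte(fit$rss_quadratic, fit$rss_linear) # nested models

  quad <- 0.002 * lens^2 + 0.05 * lens + stats::rnorm(length(lens), 0, 0.3)
  fit2 <- scaling_fit(lens, quad)
  expect_true(fit2$quadratic_significant)
  expect_gt(fit2$quad_coefficient, 0)

  expect_error(scaling_fit(c(30, 40), c(1, 2)), "3 length bins")
})
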