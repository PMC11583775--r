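test_that("propagation adds means and adds variances", {
  tot <- propagate_total(partial_error("SegE", 0.1, 3),
                         partial_error("DEE", 0.1, 4),
                         partial_error("PrE", 0.1, 0))
  expect_equal(tot$d_mean_total, 0.3)
  expect_equal(tot$sigma_total, 5)
  expect_equal(tot$six_sigma, 30)
  zero <- propagate_total(partial_error("SegE", 0, 0),
                          partial_error("DEE", 0, 0),
                          partial_error("PrE", 0, 0))
  expect_equal(zero$d_mean_total, 0)
  expect_equal(zero$sigma_total, 0)
})

test_that("opposite partial means cancel while the spread still grows", {
  tot <- propagate_total(partial_error("SegE", 0.2, 0.1),
                         partial_error("DEE", -0.2, 0.2),
                         partial_error("PrE", 0, 0.05))
  expect_equal(tot$d_mean_total, 0)
  expect_gt(tot$sigma_total, 0)
})

test_that("propagation is permutation invariant and dominates each partial", {
  set.seed(21)
  for (i in 1:20) {
    s <- runif(3, 0, 2)
    m <- runif(3, -1, 1)
    parts <- list(partial_error("SegE", m[1], s[1]),
                  partial_error("DEE", m[2], s[2]),
                  partial_error("PrE", m[3], s[3]))
    t1 <- propagate_total(parts[[1]], parts[[2]], parts[[3]])
    t2 <- propagate_total(parts[[3]], parts[[1]], parts[[2]])
    expect_identical(glance(t1), glance(t2))
    expect_true(all(t1$sigma_total >= s - 1e-12))
  }
  # repeated calls are bit-identical
  a <- propagate_total(partial_error("SegE", 0.11, 0.3),
                       partial_error("DEE", -0.02, 0.4),
                       partial_error("PrE", 0.05, 0.1))
  b <- propagate_total(partial_error("SegE", 0.11, 0.3),
                       partial_error("DEE", -0.02, 0.4),
                       partial_error("PrE", 0.05, 0.1))
  expect_identical(a, b)
})

test_that("duplicate or missing stage labels are rejected", {
  expect_error(propagate_total(partial_error("SegE", 0, 1),
                               partial_error("SegE", 0, 1),
                               partial_error("PrE", 0, 1)),
               "exactly one")
  expect_error(propagate_total(partial_error("SegE", 0, 1),
                               partial_error("DEE", 0, 1)),
               "exactly one|must be")
  expect_error(partial_error("Other", 0, 1))
  expect_error(partial_error("SegE", 0, -1), ">= 0")
})

test_that("six-sigma interval is 6 sigma, independent of the mean", {
  expect_equal(six_sigma_interval(0, 1), 6)
  expect_equal(six_sigma_interval(123.4, 0), 0)
  expect_equal(six_sigma_interval(-5, 0.5), 3)
  expect_equal(six_sigma_interval(0.0093, 0.2265), 1.359)
  expect_error(six_sigma_interval(0, -0.1), ">= 0")
})

test_that("3-sigma coverage matches the closed form and simulation", {
  cov <- normal_coverage_3sigma()
  expect_equal(round(cov, 4), 0.9973)
  expect_equal(cov, pnorm(3) - pnorm(-3))
  # 1-sigma analog sanity
  expect_equal(round(pnorm(1) - pnorm(-1), 4), 0.6827)
  set.seed(31)
  x <- rnorm(1e6)
  expect_lt(abs(mean(abs(x) <= 3) - cov), 5e-4)
})

test_that("tidy/glance expose the propagation as tables", {
  tot <- propagate_total(partial_error("SegE", 0.1, 3),
                         partial_error("DEE", 0.1, 4),
                         partial_error("PrE", 0.1, 0))
  td <- tidy(tot)
  expect_equal(td$label, c("SegE", "DEE", "PrE", "Total"))
  expect_equal(td$sigma[4], 5)
  expect_equal(glance(tot)$six_sigma, 30)
})
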