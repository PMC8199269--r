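test_that("2x2 cross-product odds ratio matches hand arithmetic", {
  # male-gender split of a 3014-subject cohort: 413/267 cases, 1122/1212 controls
  est <- contingency_or(413, 267, 1122, 1212, factor = "male")
  expect_equal(est$odds_ratio, (413 * 1212) / (267 * 1122), tolerance = 1e-12)
  expect_lt(abs(est$odds_ratio - 1.67), 0.005)
  expect_lt(est$p_value, 0.001)
  expect_true(est$ci_low < est$odds_ratio && est$odds_ratio < est$ci_high)

  flat <- contingency_or(10, 10, 10, 10)
  expect_equal(flat$odds_ratio, 1)
  expect_equal(flat$p_value, 1)

  # swapping exposure labels inverts the estimate
  a <- contingency_or(20, 5, 30, 45)
  b <- contingency_or(5, 20, 45, 30)
  expect_equal(a$odds_ratio, 1 / b$odds_ratio, tolerance = 1e-12)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)

  zero <- contingency_or(0, 10, 10, 10)
  expect_true(zero$continuity)
  expect_error(contingency_or(-1, 1, 1, 1), "non-negative")
})

test_that("group tests reproduce chi-square behaviour on known splits", {
  # identical group proportions -> no association
  n0 <- 200; n1 <- 100
  cohort <- data.frame(
    id = seq_len(n0 + n1),
    age = c(rnorm(n0, 76, 5), rnorm(n1, 80, 5)),
    male = rep(c(TRUE, FALSE), length.out = n0 + n1),
    af_status = factor(rep(c("no_af", "silent_af"), c(n0, n1)),
                       levels = c("no_af", "symptomatic_af", "silent_af"))
  )
  out <- group_tests(cohort, "saf", factors = "male")
  expect_equal(out$p_value[out$characteristic == "male"], 1, tolerance = 1e-12)

  # a strongly imbalanced split: 413/680 male cases vs 1122/2334 male controls
  big <- data.frame(
    id = seq_len(3014),
    age = rnorm(3014, 77, 8),
    male = c(rep(c(TRUE, FALSE), c(1122, 1212)),
             rep(c(TRUE, FALSE), c(413, 267))),
    af_status = factor(rep(c("no_af", "silent_af"), c(2334, 680)),
                       levels = c("no_af", "symptomatic_af", "silent_af"))
  )
  out <- group_tests(big, "saf", factors = "male")
  expect_lt(out$p_value[out$characteristic == "male"], 0.001)

  # chi-square on a 2x2 equals the squared two-proportion z statistic
  set.seed(1)
  for (i in 1:20) {
    m0 <- sample(50:300, 1); m1 <- sample(50:300, 1)
    x0 <- rbinom(1, m0 - 2, 0.4) + 1; x1 <- rbinom(1, m1 - 2, 0.55) + 1
    tab <- rbind(c(x0, m0 - x0), c(x1, m1 - x1))
    chi <- suppressWarnings(chisq.test(tab, correct = FALSE)$statistic)
    p0 <- x0 / m0; p1 <- x1 / m1; pp <- (x0 + x1) / (m0 + m1)
    z <- (p1 - p0) / sqrt(pp * (1 - pp) * (1 / m0 + 1 / m1))
    expect_equal(unname(chi), z^2, tolerance = 1e-10)
  }
})

test_that("logistic regression agrees with the 2x2 oracle and handles nulls", {
  set.seed(10)
  for (i in 1:20) {
    n <- 400
    x <- rbinom(n, 1, runif(1, 0.2, 0.8))
    y <- rbinom(n, 1, plogis(-1 + runif(1, -1, 1) * x))
    a <- sum(x & y); b <- sum(!x & y); c <- sum(x & !y); d <- sum(!x & !y)
    if (min(a, b, c, d) == 0) next
    fit <- fit_logistic(data.frame(x = x), y)
    oracle <- contingency_or(a, b, c, d)
    expect_equal(fit$odds_ratio, oracle$odds_ratio, tolerance = 1e-6)
    expect_equal(fit$ci_low, oracle$ci_low, tolerance = 1e-5)
    # compare p-values on the log scale: tiny p makes relative diffs unstable
    expect_equal(log(fit$p_value), log(oracle$p_value), tolerance = 1e-4)
  }

  # no association: small log-ORs on a large sample
  set.seed(11)
  n <- 10000
  X <- data.frame(a = rbinom(n, 1, 0.5), b = rbinom(n, 1, 0.3),
                  c = rnorm(n))
  y <- rbinom(n, 1, 0.2)
  est <- fit_logistic(X, y)
  expect_true(all(abs(log(est$odds_ratio)) < 0.25))
})

test_that("weights act as frequency weights", {
  set.seed(12)
  n <- 300
  X <- data.frame(x1 = rbinom(n, 1, 0.4), x2 = rnorm(n))
  y <- rbinom(n, 1, plogis(-1 + X$x1 + 0.5 * X$x2))
  unweighted <- fit_logistic(X, y)
  all_ones <- fit_logistic(X, y, weights = rep(1, n))
  expect_equal(log(all_ones$odds_ratio), log(unweighted$odds_ratio),
               tolerance = 1e-10)
  # weight 2 is equivalent to duplicating each row
  doubled <- fit_logistic(rbind(X, X), c(y, y))
  weighted <- fit_logistic(X, y, weights = rep(2, n))
  expect_equal(log(weighted$odds_ratio), log(doubled$odds_ratio),
               tolerance = 1e-8)
})

test_that("rank deficiency and separation fail loudly", {
  set.seed(13)
  n <- 100
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, 0.4)
  expect_error(fit_logistic(data.frame(x = x, x_copy = x), y),
               "x_copy")
  expect_error(fit_logistic(data.frame(x = y), y), "separation")
  expect_error(fit_logistic(data.frame(x = x), rep(TRUE, n)), "both classes")
})

test_that("poststratification weights hit their targets", {
  d <- data.frame(g = rep(c("a", "b"), each = 50))
  expect_equal(poststratify(d, "g", c(a = 0.5, b = 0.5)), rep(1, 100))
  w <- poststratify(d, "g", c(a = 0.6, b = 0.4))
  expect_equal(unique(w[d$g == "a"]), 1.2)
  expect_equal(unique(w[d$g == "b"]), 0.8)
  expect_equal(mean(w), 1)
  # weighted prevalence of a stratum variable equals its target share
  d2 <- data.frame(g = rep(c("a", "b"), c(30, 70)))
  w2 <- poststratify(d2, "g", c(a = 0.45, b = 0.55))
  expect_equal(sum(w2 * (d2$g == "a")) / sum(w2), 0.45, tolerance = 1e-12)
  expect_error(poststratify(d, "g", c(a = 0.7, b = 0.7)), "sum to 1")
  expect_error(poststratify(d, "g", c(a = 0.6, c = 0.4)), "b")
})
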