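tab1 <- table1_bank()

test_that("GRM category probabilities match the boundary-logistic oracle", {
  it <- item_parameters("d", "GRM", a = 1, b = 0)
  expect_equal(grm_category_probs(it, 0), c(0.5, 0.5), tolerance = 1e-12)

  # frozen from direct hand evaluation of the three boundary logistics
  expect_equal(round(grm_category_probs(tab1[[1]], 0), 4),
               c(0.3604, 0.5288, 0.0945, 0.0163))
  for (j in c(1, 7, 15)) {
    for (th in c(-2, 0, 1.5)) {
      expect_equal(grm_category_probs(tab1[[j]], th),
                   oracle_grm_probs(tab1[[j]]$a, tab1[[j]]$b, th),
                   tolerance = 1e-12)
    }
  }

  # lower-asymptote limit
  expect_gt(grm_category_probs(tab1[[5]], -50)[1], 1 - 1e-9)

  # ordering violations rejected
  expect_error(item_parameters("bad", "GRM", a = 1, b = c(1, 0.5)),
               "increasing")
  it2 <- tab1[[2]]
  it2$b <- rev(it2$b)
  expect_error(grm_category_probs(it2, 0), "increasing")
})

test_that("probability vectors are valid across models over a theta sweep", {
  set.seed(11)
  th <- seq(-6, 6, by = 0.4)
  for (r in 1:8) {
    K <- sample(3:5, 1)
    a <- runif(1, 0.5, 2.5)
    bg <- sort(runif(K - 1, -3, 3)) + cumsum(rep(0.05, K - 1))
    grm <- item_parameters("g", "GRM", a = a, b = bg)
    gpc <- item_parameters("p", "GPCM", a = a, b = runif(K - 1, -2, 2))
    for (it in list(grm, gpc)) {
      p <- category_probs(it, th)
      expect_true(all(p >= 0))
      expect_equal(rowSums(p), rep(1, length(th)), tolerance = 1e-12)
    }
    # GRM boundary probabilities P(X >= k) decrease in k at fixed theta
    p <- category_probs(grm, th)
    upper <- t(apply(p, 1, function(r) rev(cumsum(rev(r)))))
    expect_true(all(apply(upper, 1, diff) <= 1e-12))
  }
})

test_that("GPCM matches enumeration oracle and reduces to RSM on shared steps", {
  it <- item_parameters("d", "GPCM", a = 1, b = 0)
  expect_equal(gpcm_category_probs(it, 0), c(0.5, 0.5), tolerance = 1e-12)

  # partial-credit enumeration oracle: 3 categories, a = 1, theta = 1
  delta <- c(-0.5, 0.8)
  it3 <- item_parameters("p", "GPCM", a = 1, b = delta)
  z <- c(0, cumsum(1 * (1 - delta)))
  expect_equal(gpcm_category_probs(it3, 1), exp(z) / sum(exp(z)),
               tolerance = 1e-12)

  # RSM is the GPCM constrained to shared steps
  steps <- c(-1, 0.3, 1.2)
  for (loc in c(-0.7, 0, 1.1)) {
    rsm <- item_parameters("r", "RSM", a = 1, location = loc, steps = steps)
    gpc <- item_parameters("g", "GPCM", a = 1, b = loc + steps)
    expect_identical(rsm_category_probs(rsm, 0.4),
                     gpcm_category_probs(gpc, 0.4))
  }
  # equal locations => identical probability vectors across items
  r1 <- item_parameters("r1", "RSM", a = 1, location = 0.5, steps = steps)
  r2 <- item_parameters("r2", "RSM", a = 1, location = 0.5, steps = steps)
  expect_identical(rsm_category_probs(r1, -1.3), rsm_category_probs(r2, -1.3))
})

test_that("Fisher information matches closed form and finite differences", {
  it <- item_parameters("d", "GRM", a = 2, b = 0)
  expect_equal(item_information(it, 0), 1, tolerance = 1e-12)

  # central finite differences on category probabilities, I = sum dP^2 / P
  fd_info <- function(item, th, h = 1e-5) {
    p0 <- category_probs(item, th)
    dp <- (category_probs(item, th + h) - category_probs(item, th - h)) / (2 * h)
    sum(dp^2 / p0)
  }
  set.seed(21)
  th_grid <- seq(-3, 3, by = 0.75)
  items <- c(list(tab1[[10]]),
             lapply(1:5, function(i) {
               K <- sample(3:5, 1)
               item_parameters(paste0("x", i),
                               sample(c("GRM", "GPCM"), 1),
                               a = runif(1, 0.6, 2.4),
                               b = sort(runif(K - 1, -2.5, 2.5)) +
                                   cumsum(rep(0.05, K - 1)))
             }))
  for (it in items)
    for (th in th_grid)
      expect_equal(item_information(it, th), fd_info(it, th), tolerance = 1e-5)

  # tail limit
  expect_lt(item_information(tab1[[3]], 50), 1e-8)
  expect_lt(item_information(tab1[[3]], -50), 1e-8)
})

test_that("pattern log-likelihood is additive and handles missing data", {
  b3 <- tab1[1:3]
  expect_identical(pattern_loglik(b3, rep(NA_integer_, 3), 0.7), 0)

  bd <- item_bank(list(item_parameters("d", "GRM", a = 1, b = 0)))
  expect_equal(pattern_loglik(bd, 1L, 0), log(0.5), tolerance = 1e-12)

  x <- c(2L, 0L, 3L)
  single <- vapply(1:3, function(j) {
    pattern_loglik(b3[j], x[j], 0.3)
  }, numeric(1))
  expect_equal(pattern_loglik(b3, x, 0.3), sum(single), tolerance = 1e-12)

  expect_error(pattern_loglik(b3, c(5L, 0L, 0L), 0), "out of range")
})

test_that("item bank CSV round-trip preserves parameters", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_item_bank(tab1, path)
  back <- read_item_bank(path)
  expect_identical(item_ids(back), item_ids(tab1))
  for (j in seq_along(tab1$items)) {
    expect_equal(back[[j]]$a, tab1[[j]]$a)
    expect_equal(back[[j]]$b, tab1[[j]]$b)
  }
  expect_error(item_bank(list(tab1[[1]], tab1[[1]])), "unique")
})
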