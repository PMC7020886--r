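# EM calibration. Note on the dichotomous recovery case: a single item's
# (a, b) are not identified by marginal maximum likelihood (the marginal
# likelihood of one dichotomous item depends only on the endorsement
# probability), so recovery is checked on a small bank of replicate items.

fast_cfg <- calib_config(tol = 1e-3, max_cycles = 150)

test_that("fit index identities hold", {
  fi <- fit_indices(neg2LL = 100, n_params = 10, n_persons = 100)
  expect_equal(fi$AIC, 120)
  expect_equal(fi$BIC, 100 + 10 * log(100), tolerance = 1e-10)
  expect_gte(fi$AIC, fi$neg2LL)
})

test_that("dichotomous parameters are recovered from replicate items", {
  bank <- item_bank(lapply(1:6, function(j)
    item_parameters(paste0("d", j), "GRM", a = 1.5, b = 0.5)))
  errs <- sapply(c(101, 202), function(s) {
    sim <- simulate_responses(bank, cohort_spec(n_persons = 2000, seed = s))
    f <- fit_model(sim$responses, "GRM", fast_cfg)
    ah <- vapply(f$bank$items, `[[`, numeric(1), "a")
    bh <- vapply(f$bank$items, function(it) it$b, numeric(1))
    c(a = mean(ah) - 1.5, b = mean(bh) - 0.5)
  })
  expect_lt(max(abs(rowMeans(errs))), 0.15)
})

test_that("EM is monotone, converges, and counts parameters correctly", {
  bank <- tab1_fit()$bank[c(1:3, 11:12)]        # mixed 4- and 5-category
  sim <- simulate_responses(bank, cohort_spec(n_persons = 400, seed = 17))
  f <- fit_model(sim$responses, "GRM", fast_cfg)
  expect_true(f$converged)
  expect_true(all(diff(f$loglik_trace) > -1e-8))
  expect_identical(f$fit$n_params, sum(item_categories(bank)))  # sum_j K_j
  expect_equal(f$fit$AIC, f$fit$neg2LL + 2 * f$fit$n_params)
  # GRM thresholds come back ordered, structurally
  for (it in f$bank$items) expect_true(all(diff(it$b) > 0))
})

test_that("balanced symmetric data yields thresholds symmetric about zero", {
  bank <- item_bank(lapply(1:4, function(j)
    item_parameters(paste0("s", j), "GRM", a = 1.2, b = c(-1, 1))))
  sim <- simulate_responses(bank, cohort_spec(n_persons = 1500, seed = 23))
  f <- fit_model(sim$responses, "GRM", fast_cfg)
  bmat <- t(vapply(f$bank$items, `[[`, numeric(2), "b"))
  expect_lt(max(abs(rowMeans(bmat))), 0.15)     # b1 ~ -b2
})

test_that("recovery error shrinks with sample size", {
  bank <- item_bank(lapply(1:5, function(j)
    item_parameters(paste0("d", j), "GRM", a = 1.5, b = 0.5)))
  err_at <- function(n) {
    mean(sapply(c(7, 8), function(s) {
      sim <- simulate_responses(bank, cohort_spec(n_persons = n, seed = s))
      f <- fit_model(sim$responses, "GRM", fast_cfg)
      ah <- vapply(f$bank$items, `[[`, numeric(1), "a")
      bh <- vapply(f$bank$items, function(it) it$b, numeric(1))
      mean(abs(c(ah - 1.5, bh - 0.5)))
    }))
  }
  expect_gt(err_at(250), err_at(4000))
})

test_that("never-observed categories are collapsed or rejected per config", {
  bank <- tab1_fit()$bank[1:3]
  sim <- simulate_responses(bank, cohort_spec(n_persons = 300, seed = 31))
  resp <- sim$responses
  resp[resp[, 2] == 2, 2] <- 3L                  # category 2 never observed
  f <- fit_model(resp, "GRM", fast_cfg)
  expect_identical(f$category_maps[[2]], c(0L, 1L, 3L))
  expect_identical(f$bank[[2]]$n_categories, 3L)
  expect_error(
    fit_model(resp, "GRM", calib_config(tol = 1e-3, unobserved = "reject")),
    "never-observed")
})

test_that("model comparison recovers the generating family", {
  # GRM-generated data: GRM attains the lowest AIC in a majority of seeds
  # (4-category items only so the RSM is also a candidate)
  bank <- tab1_fit()$bank[1:8]
  grm_wins <- sum(sapply(c(41, 42, 43), function(s) {
    sim <- simulate_responses(bank, cohort_spec(n_persons = 500, seed = s))
    cmp <- compare_models(sim$responses, config = fast_cfg)
    cmp$model[which.min(cmp$AIC)] == "GRM"
  }))
  expect_gte(grm_wins, 2)

  # RSM-generated data: BIC (penalizing the extra parameters) prefers RSM
  steps <- c(-1, 0.2, 1.1)
  set.seed(5)
  rbank <- item_bank(lapply(1:8, function(j)
    item_parameters(paste0("r", j), "RSM", a = 1,
                    location = runif(1, -1, 1), steps = steps)))
  rsm_wins <- sum(sapply(c(51, 52, 53), function(s) {
    sim <- simulate_responses(rbank, cohort_spec(n_persons = 400, seed = s))
    cmp <- compare_models(sim$responses, config = fast_cfg)
    cmp$model[which.min(cmp$BIC)] == "RSM"
  }))
  expect_gte(rsm_wins, 2)
})
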