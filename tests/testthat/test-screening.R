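test_that("polychoric correlation matches its generative oracle", {
  set.seed(4)
  n <- 5000
  z1 <- rnorm(n)
  z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(n)
  cuts <- c(-0.8, 0.2, 1.1)
  x <- findInterval(z1, cuts)
  y <- findInterval(z2, cuts)
  expect_lt(abs(polychoric_corr(x, y) - 0.5), 0.05)
  expect_gte(polychoric_corr(x, x), 0.99)
  expect_lt(abs(polychoric_corr(x, sample(y))), 0.05)
  expect_error(polychoric_corr(rep(1L, 10), c(rep(0:1, 5))), "degenerate")
})

test_that("unidimensionality filter keeps clean banks and drops noise items", {
  shared <- tab1_fit()
  rep0 <- unidimensionality_filter(shared$sim$responses)
  expect_lte(length(setdiff(seq_len(20), rep0$retained)), 1)
  expect_gte(rep0$eigenvalue_ratio, 4)
  expect_gte(rep0$first_factor_variance_pct, 20)
  expect_true(rep0$passed)

  pd <- plant_defects(shared$sim$responses, shared$bank,
                      list(list(type = "noise", item = 3)),
                      theta = shared$sim$theta, seed = 2)
  rep1 <- unidimensionality_filter(pd$responses)
  expect_true(item_ids(shared$bank)[3] %in% rep1$iterations[[1]]$removed)
})

test_that("Q3 is symmetric with unit diagonal, small under local independence,
           and large for a planted dependent pair", {
  shared <- tab1_fit()
  Q3 <- q3_matrix(shared$sim$responses, shared$fit$bank)
  expect_equal(Q3, t(Q3))
  expect_equal(unname(diag(Q3)), rep(1, 20))
  off <- abs(Q3[upper.tri(Q3)])
  expect_lt(mean(off > 0.36), 0.05)

  for (s in c(61, 62)) {
    pd <- plant_defects(shared$sim$responses, shared$bank,
                        list(list(type = "dependent_pair", item = 4,
                                  item2 = 5, copy_prob = 0.8)),
                        theta = shared$sim$theta, seed = s)
    cal <- fit_model(pd$responses, "GRM", calib_config(tol = 1e-3,
                                                       max_cycles = 150))
    Q3p <- q3_matrix(pd$responses, cal$bank)
    expect_gt(Q3p[4, 5], 0.36)
  }
})

test_that("discrimination filter removes exactly the low-a items", {
  shared <- tab1_fit()
  d <- discrimination_filter(shared$bank, 0.7)
  expect_length(d$removed, 0)                    # all fixture a >= 0.816
  weak <- item_bank(c(shared$bank$items,
                      list(item_parameters("weak", "GRM", a = 0.3, b = 0))))
  d2 <- discrimination_filter(weak, 0.7)
  expect_identical(d2$removed, "weak")
  expect_length(discrimination_filter(weak, 0)$removed, 0)
})

test_that("summed-score recursion equals its base case and enumeration", {
  grid <- theta_grid(5, c(-2, 2))
  b3 <- table1_bank()[c(1, 11)]
  tabs <- lapply(b3$items, function(it) category_probs(it, grid$nodes))

  # single item: distribution equals the item's own category probabilities
  S1 <- summed_score_distribution(tabs[1])
  expect_equal(S1, tabs[[1]], tolerance = 1e-14)

  # two dichotomous items at theta = 0.7: exhaustive enumeration
  d2 <- item_bank(list(item_parameters("u", "GRM", a = 1.1, b = -0.4),
                       item_parameters("v", "GRM", a = 0.8, b = 0.9)))
  pv <- lapply(d2$items, function(it) category_probs(it, 0.7))
  S <- summed_score_distribution(lapply(pv, function(p) matrix(p, 1)))
  expect_equal(drop(S), oracle_sumscore(pv), tolerance = 1e-12)

  # probabilities over total scores sum to 1 at every node
  Sall <- summed_score_distribution(tabs)
  expect_equal(rowSums(Sall), rep(1, 5), tolerance = 1e-10)
})

test_that("S-X2 keeps its type-I rate low and flags a misfitting item", {
  shared <- tab1_fit()
  ft <- s_chi2_item_fit(shared$sim$responses, shared$fit$bank)
  expect_true(all(ft$p_value >= 0 & ft$p_value <= 1, na.rm = TRUE))
  expect_true(all(ft$df >= 1, na.rm = TRUE))
  expect_lte(mean(ft$p_value < 0.01, na.rm = TRUE), 0.10)

  pd <- plant_defects(shared$sim$responses, shared$bank,
                      list(list(type = "misfit", item = 6)),
                      theta = shared$sim$theta, seed = 9)
  cal <- fit_model(pd$responses, "GRM", calib_config(tol = 1e-3,
                                                     max_cycles = 150))
  ftm <- s_chi2_item_fit(pd$responses, cal$bank)
  expect_lt(ftm$p_value[6], 0.01)
})

test_that("proportional-odds ML matches a brute-force grid search", {
  # 12-observation toy dataset, 3 categories, one covariate
  y <- c(0L, 0L, 1L, 0L, 1L, 1L, 2L, 1L, 2L, 2L, 2L, 1L)
  x <- c(-1.5, -1.0, -0.8, -0.4, -0.2, 0.1, 0.3, 0.6, 0.9, 1.2, 1.6, 0.0)
  fit <- prop_odds_fit(y, cbind(x))
  ref <- oracle_po_grid(y, cbind(x))
  expect_equal(fit$zeta, ref$zeta, tolerance = 1e-3)
  expect_equal(unname(fit$beta), unname(ref$beta), tolerance = 1e-3)
  expect_gte(fit$loglik, ref$loglik - 1e-6)

  # McFadden pseudo-R2 in [0, 1); nested likelihoods non-decreasing
  g <- rep(0:1, 6)
  m1 <- prop_odds_fit(y, cbind(x))
  m2 <- prop_odds_fit(y, cbind(x, g))
  m3 <- prop_odds_fit(y, cbind(x, g, x * g))
  expect_gte(m2$loglik, m1$loglik - 1e-6)
  expect_gte(m3$loglik, m2$loglik - 1e-6)
  r2 <- mcfadden_r2(m3$loglik, m3$loglik_null)
  expect_gte(r2, 0)
  expect_lt(r2, 1)
})

test_that("DIF scan is quiet under the null and flags planted DIF", {
  shared <- tab1_fit()
  set.seed(71)
  group <- rbinom(nrow(shared$sim$responses), 1, 0.5)
  d0 <- dif_scan(shared$sim$responses, group, bank = shared$fit$bank)
  expect_false(any(d0$flagged))

  # planted uniform DIF (shift +0.8) on a well-discriminating item: the
  # McFadden R2 change for a fixed threshold shift scales with the host
  # item's a^2, so DIF is planted where a matches the strong items of a
  # validated bank (a ~ 1.5); on weak items a 0.8 shift is a small effect
  # by this very effect-size measure
  pd <- plant_defects(shared$sim$responses, shared$bank,
                      list(list(type = "dif", item = 17, shift = 0.8)),
                      theta = shared$sim$theta, seed = 5)
  cal <- fit_model(pd$responses, "GRM", calib_config(tol = 1e-3,
                                                     max_cycles = 150))
  d1 <- dif_scan(pd$responses, pd$group, bank = cal$bank)
  expect_true(item_ids(shared$bank)[17] %in% d1$item_id[d1$removed])
  # purification removed it; survivors are clean
  expect_false(any(d1$flagged[!d1$removed]))
})

test_that("the screening pipeline is deterministic with nested stages", {
  shared <- tab1_fit()
  pd <- plant_defects(shared$sim$responses, shared$bank,
                      list(list(type = "noise", item = 2),
                           list(type = "dependent_pair", item = 11,
                                item2 = 12, copy_prob = 0.9)),
                      theta = shared$sim$theta, seed = 13)
  cfg <- screening_config(calib = calib_config(tol = 1e-3, max_cycles = 120))
  set.seed(99)
  r1 <- run_screening_pipeline(pd$responses, group = NULL, config = cfg)
  set.seed(99)
  r2 <- run_screening_pipeline(pd$responses, group = NULL, config = cfg)
  expect_identical(r1$final_items, r2$final_items)
  expect_identical(as.data.frame(r1$final_bank), as.data.frame(r2$final_bank))

  # nesting: each stage's survivors are a subset of the previous stage's
  stages <- r1$stages
  for (i in seq_along(stages)[-1]) {
    expect_true(all(stages[[i]]$survivors %in% stages[[i - 1]]$survivors))
    expect_setequal(stages[[i]]$items_before, stages[[i - 1]]$survivors)
  }
  # the planted defects were caught at their stages
  expect_true(item_ids(shared$bank)[2] %in% stages$unidimensionality$removed)
  expect_true(item_ids(shared$bank)[12] %in% stages$local_independence$removed)

  # audit trail writers
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_screening_report(r1, jp, cp)
  audit <- utils::read.csv(cp)
  expect_true(all(c(item_ids(shared$bank)[2], item_ids(shared$bank)[12])
                  %in% audit$item_id))
})
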