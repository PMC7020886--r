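# Independent oracle implementations used to cross-check package code.
# These deliberately re-derive everything from the defining formulas and
# never call the code paths they are used to verify.

# direct boundary-logistic GRM category probabilities at scalar theta
oracle_grm_probs <- function(a, b, theta) {
  ps <- c(1, 1 / (1 + exp(-a * (theta - b))), 0)
  ps[-length(ps)] - ps[-1]
}

# same, vectorized over a theta grid (still the raw formula)
oracle_grm_probs_grid <- function(a, b, theta) {
  ps <- cbind(1, 1 / (1 + exp(-a * outer(theta, b, `-`))), 0)
  ps[, -ncol(ps), drop = FALSE] - ps[, -1, drop = FALSE]
}

# brute-force fine-grid EAP under a standard-normal prior
oracle_eap <- function(bank, x, n_grid = 10001L, bounds = c(-6, 6)) {
  g <- seq(bounds[1], bounds[2], length.out = n_grid)
  ll <- numeric(n_grid)
  for (j in seq_along(x)) {
    if (is.na(x[j])) next
    it <- bank[[j]]
    pj <- oracle_grm_probs_grid(it$a, it$b, g)[, x[j] + 1L]
    ll <- ll + log(pmax(pj, 1e-300))
  }
  p <- dnorm(g) * exp(ll - max(ll))
  p <- p / sum(p)
  eap <- sum(p * g)
  list(eap = eap, se = sqrt(sum(p * (g - eap)^2)))
}

# exhaustive pair-counting AUC (ties half-weight)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# total-score distribution at scalar theta by exhaustive pattern
# enumeration over <= 3 items (tables: list of category prob vectors)
oracle_sumscore <- function(prob_vecs) {
  grid <- expand.grid(lapply(prob_vecs, function(p) seq_along(p) - 1L))
  pr <- apply(grid, 1L, function(x)
    prod(mapply(function(p, k) p[k + 1L], prob_vecs, x)))
  tot <- rowSums(grid)
  out <- numeric(sum(vapply(prob_vecs, length, integer(1)) - 1L) + 1L)
  for (i in seq_along(tot)) out[tot[i] + 1L] <- out[tot[i] + 1L] + pr[i]
  out
}

# brute-force proportional-odds ML by nested grid refinement
# (y 0-based with K categories, X a design matrix without intercept)
oracle_po_grid <- function(y, X, n_rounds = 8L, width = 4, res = 9L) {
  K <- max(y) + 1L
  npar <- (K - 1L) + ncol(X)
  ll <- function(par) {
    zeta <- sort(par[seq_len(K - 1L)])
    beta <- par[-seq_len(K - 1L)]
    eta <- drop(X %*% beta)
    cz <- c(-Inf, zeta, Inf)
    sum(log(pmax(plogis(cz[y + 2L] - eta) - plogis(cz[y + 1L] - eta), 1e-12)))
  }
  centre <- rep(0, npar)
  for (r in seq_len(n_rounds)) {
    grids <- lapply(centre, function(c0) seq(c0 - width, c0 + width,
                                             length.out = res))
    cand <- as.matrix(expand.grid(grids))
    vals <- apply(cand, 1L, ll)
    centre <- cand[which.max(vals), ]
    width <- width * 2.2 / res            # shrink around the incumbent
  }
  centre <- unname(centre)
  list(zeta = sort(centre[seq_len(K - 1L)]),
       beta = centre[-seq_len(K - 1L)], loglik = ll(centre))
}

# shared calibrated fixture: one simulated clean dataset from the packaged
# bank, calibrated once and reused by the Q3 / S-X2 / DIF tests
.shared <- new.env(parent = emptyenv())
tab1_fit <- function() {
  if (is.null(.shared$fit)) {
    bank <- table1_bank()
    sim <- simulate_responses(bank, cohort_spec(n_persons = 800, seed = 301))
    fit <- fit_model(sim$responses, "GRM",
                     calib_config(tol = 1e-3, max_cycles = 150))
    .shared$fit <- list(bank = bank, sim = sim, fit = fit)
  }
  .shared$fit
}
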