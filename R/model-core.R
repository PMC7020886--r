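# Probability, information and likelihood functions for the three
# polytomous IRT models. Logistic metric throughout with scaling constant
# D = 1: all thresholds in this package live on the same logistic scale as
# the packaged parameter fixture. A floor of PROB_FLOOR is applied before
# logs and divisions so extreme theta never produces -Inf.

PROB_FLOOR <- 1e-10

#' Category probabilities under the graded response model
#'
#' Boundary ("operating characteristic") form: the probability of scoring
#' in category `k` or above is `P*_k(theta) = plogis(a * (theta - b_k))`,
#' with `P*_0 = 1` and `P*_K = 0`; the category-`k` probability is the
#' difference of adjacent boundaries.
#'
#' @param item An [item_parameters()] object (model `"GRM"`).
#' @param theta Latent-trait value(s); scalar or vector.
#' @return For scalar `theta`, a probability vector of length `K`; for a
#'   vector, a `length(theta) x K` matrix. Rows sum to one.
#' @examples
#' it <- item_parameters("x", "GRM", a = 1, b = 0)
#' grm_category_probs(it, 0)  # 0.5 0.5
#' @export
grm_category_probs <- function(item, theta) {
  if (any(diff(item$b) <= 0))
    stop("GRM thresholds must be strictly increasing (ordering violation)")
  p <- .grm_probs(item$a, item$b, theta)
  if (length(theta) == 1L) drop(p) else p
}

.grm_probs <- function(a, b, theta) {
  # theta vector -> matrix n x K
  ps <- stats::plogis(a * outer(theta, b, `-`))      # n x (K-1)
  p <- cbind(1, ps) - cbind(ps, 0)
  p[p < 0] <- 0
  p
}

#' Category probabilities under the GPCM and RSM
#'
#' Adjacent-category logit (divide-by-total) form: the log-odds of category
#' `k` versus `k - 1` is `a * (theta - b_k)`. The rating scale model is the
#' GPCM constrained to steps shared across items, each item contributing
#' only a location shift; `rsm_category_probs()` evaluates the composed
#' `location + steps` vector stored on the item and is numerically identical
#' to `gpcm_category_probs()` on that vector.
#'
#' @inheritParams grm_category_probs
#' @return As for [grm_category_probs()].
#' @export
gpcm_category_probs <- function(item, theta) {
  p <- .gpcm_probs(item$a, item$b, theta)
  if (length(theta) == 1L) drop(p) else p
}

#' @rdname gpcm_category_probs
#' @export
rsm_category_probs <- function(item, theta) {
  p <- .gpcm_probs(item$a, item$b, theta)
  if (length(theta) == 1L) drop(p) else p
}

.gpcm_probs <- function(a, b, theta) {
  z <- a * outer(theta, b, `-`)                      # n x (K-1)
  num <- cbind(0, t(apply(z, 1L, cumsum)))
  if (length(theta) == 1L) num <- matrix(c(0, cumsum(z[1L, ])), 1L)
  num <- num - apply(num, 1L, max)
  e <- exp(num)
  e / rowSums(e)
}

#' Category probabilities for any supported item
#'
#' Dispatches on the item's model family.
#' @inheritParams grm_category_probs
#' @export
category_probs <- function(item, theta) {
  switch(item$model,
         GRM = grm_category_probs(item, theta),
         GPCM = gpcm_category_probs(item, theta),
         RSM = rsm_category_probs(item, theta),
         stop("unknown model: ", item$model))
}

#' Fisher item information
#'
#' `I(theta) = sum_k P'_k(theta)^2 / P_k(theta)`, the expected curvature of
#' the item log-likelihood. For the GRM the derivative uses the boundary
#' form `P'_k = a (Q_k - Q_{k+1})` with `Q = P*(1 - P*)`; for the GPCM/RSM
#' the closed form `a^2 Var(K | theta)` of the category index applies.
#' Test information for a bank is the sum over items.
#'
#' @inheritParams grm_category_probs
#' @return Nonnegative numeric vector, one value per `theta`.
#' @examples
#' it <- item_parameters("x", "GRM", a = 2, b = 0)
#' item_information(it, 0)  # a^2 P(1-P) = 1
#' @export
item_information <- function(item, theta) {
  if (item$model == "GRM") {
    ps <- stats::plogis(item$a * outer(theta, item$b, `-`))
    q <- ps * (1 - ps)
    # P'_k = a (Q_k - Q_{k+1}) with Q_0 = Q_K = 0
    dp <- item$a * (cbind(0, q) - cbind(q, 0))
    p <- cbind(1, ps) - cbind(ps, 0)
    p[p < PROB_FLOOR] <- PROB_FLOOR
    info <- rowSums(dp^2 / p)
  } else {
    p <- .gpcm_probs(item$a, item$b, theta)
    k <- seq_len(ncol(p)) - 1
    m1 <- drop(p %*% k)
    m2 <- drop(p %*% k^2)
    info <- item$a^2 * (m2 - m1^2)
  }
  pmax(info, 0)
}

#' Log-likelihood of a response pattern
#'
#' Sum of log category probabilities over the observed items at a given
#' `theta`; missing (`NA`) responses contribute nothing (MCAR omission).
#'
#' @param bank An [item_bank()].
#' @param responses Integer vector, one 0-based category per bank item;
#'   `NA` marks a missing response.
#' @param theta Scalar or vector of latent-trait values.
#' @return Numeric vector, one log-likelihood per `theta`.
#' @export
pattern_loglik <- function(bank, responses, theta) {
  stopifnot(length(responses) == length(bank))
  ll <- numeric(length(theta))
  for (j in seq_along(responses)) {
    x <- responses[j]
    if (is.na(x)) next
    it <- bank[[j]]
    if (x < 0 || x >= it$n_categories || x != round(x))
      stop(sprintf("response %s out of range for item '%s' (0..%d)",
                   x, it$item_id, it$n_categories - 1L))
    p <- category_probs(it, theta)
    p <- if (is.matrix(p)) p[, x + 1L] else p[x + 1L]
    ll <- ll + log(pmax(p, PROB_FLOOR))
  }
  ll
}

# ---- vectorized bank-level kernels (hot paths) --------------------------

# category probabilities for every item at a scalar theta: n_items x maxK.
# Padded thresholds are +Inf, so probabilities past each item's last
# category are exactly 0 for both model families.
bank_probs_at <- function(arr, theta) {
  if (arr$model == "GRM") {
    ps <- stats::plogis(arr$a * (theta - arr$bmat))  # n x (maxK-1)
    cbind(1, ps) - cbind(ps, 0)
  } else {
    z <- arr$a * (theta - arr$bmat)
    z[!is.finite(z)] <- -745                          # exp() underflows to 0
    num <- cbind(0, t(apply(z, 1L, cumsum)))
    num <- num - apply(num, 1L, max)
    e <- exp(num)
    e / rowSums(e)
  }
}

# Fisher information for every item at a scalar theta
bank_info_at <- function(arr, theta) {
  if (arr$model == "GRM") {
    ps <- stats::plogis(arr$a * (theta - arr$bmat))
    q <- ps * (1 - ps)                                # 0 at padded +Inf
    dp <- arr$a * (cbind(0, q) - cbind(q, 0))
    p <- cbind(1, ps) - cbind(ps, 0)
    contrib <- dp^2 / pmax(p, PROB_FLOOR)
    contrib[p < PROB_FLOOR & abs(dp) < 1e-12] <- 0
    pmax(rowSums(contrib), 0)
  } else {
    p <- bank_probs_at(arr, theta)
    k <- seq_len(ncol(p)) - 1
    m1 <- drop(p %*% k)
    pmax(arr$a^2 * (drop(p %*% k^2) - m1^2), 0)
  }
}

# list over items of (n_nodes x K_j) probability matrices on a grid
bank_prob_tables <- function(bank, grid) {
  lapply(bank$items, function(it) {
    p <- category_probs(it, grid$nodes)
    if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
    p
  })
}

# log-likelihood matrix persons x nodes for a response matrix
response_loglik_matrix <- function(responses, tables) {
  n <- nrow(responses)
  q <- nrow(tables[[1L]])
  ll <- matrix(0, n, q)
  for (j in seq_along(tables)) {
    x <- responses[, j]
    ok <- !is.na(x)
    if (!any(ok)) next
    lp <- log(pmax(tables[[j]], PROB_FLOOR))          # q x K
    ll[ok, ] <- ll[ok, ] + t(lp[, x[ok] + 1L, drop = FALSE])
  }
  ll
}
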