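# Marginal maximum likelihood (Bock-Aitkin EM) calibration for the GRM,
# GPCM and RSM, with the usual fit indices for model comparison.
#
# Identification: the latent trait prior is fixed at N(0, 1) on the same
# quadrature grid the EAP scorer uses. The M-step is a quasi-Newton update
# of each item's expected complete-data log-likelihood (a joint update over
# locations + shared steps for the RSM); a partial M-step keeps the
# generalized-EM monotonicity of the marginal likelihood. GRM threshold
# ordering is enforced structurally by optimizing (b1, log gaps).

#' Calibration configuration
#'
#' @param n_quad Number of quadrature nodes (default 61 on `[-6, 6]`).
#' @param bounds Grid bounds.
#' @param tol EM convergence tolerance: maximum absolute parameter change.
#' @param max_cycles Maximum EM cycles.
#' @param unobserved What to do with an item category that is never
#'   observed: `"collapse"` merges it into its neighbour (responses are
#'   relabelled to consecutive observed categories), `"reject"` errors.
#' @param mstep_maxit Quasi-Newton iterations per item per M-step.
#' @return A list of class `calib_config`.
#' @export
calib_config <- function(n_quad = 61L, bounds = c(-6, 6), tol = 1e-4,
                         max_cycles = 500L, unobserved = c("collapse", "reject"),
                         mstep_maxit = 25L) {
  structure(list(n_quad = as.integer(n_quad), bounds = bounds, tol = tol,
                 max_cycles = as.integer(max_cycles),
                 unobserved = match.arg(unobserved),
                 mstep_maxit = as.integer(mstep_maxit)),
            class = "calib_config")
}

#' Model-fit indices
#'
#' `AIC = -2LL + 2 p` and `BIC = -2LL + p log n` with `p` free item
#' parameters and `n` persons.
#'
#' @param neg2LL Minus twice the marginal log-likelihood.
#' @param n_params Number of free parameters.
#' @param n_persons Number of persons.
#' @return A one-row data frame with class `fit_indices`.
#' @export
fit_indices <- function(neg2LL, n_params, n_persons) {
  structure(data.frame(neg2LL = neg2LL, AIC = neg2LL + 2 * n_params,
                       BIC = neg2LL + n_params * log(n_persons),
                       n_params = n_params, n_persons = n_persons),
            class = c("fit_indices", "data.frame"))
}

# number of free item parameters for a model on a response matrix
count_params <- function(model, ncat) {
  switch(model,
         GRM = sum(ncat),                       # a + (K-1) thresholds per item
         GPCM = sum(ncat),
         # RSM: one location per item + shared steps, one constraint
         RSM = length(ncat) + (ncat[1L] - 1L) - 1L,
         stop("unknown model"))
}

#' Calibrate an item bank by marginal maximum likelihood
#'
#' Bock-Aitkin EM with fixed Gaussian quadrature. Responses are 0-based
#' integer categories; `NA` is missing and is omitted from the likelihood.
#'
#' @param responses Integer matrix, persons x items; column names become
#'   item ids (columns are named `item1..itemJ` otherwise).
#' @param model `"GRM"`, `"GPCM"` or `"RSM"` (RSM requires all items to
#'   share one category count).
#' @param config A [calib_config()].
#' @return A `calibration_result`: fields `bank` ([item_bank()]),
#'   `fit` ([fit_indices()]), `converged`, `n_cycles`, `loglik_trace`,
#'   `category_maps` (non-NULL where unobserved categories were collapsed).
#' @export
fit_model <- function(responses, model = c("GRM", "GPCM", "RSM"),
                      config = calib_config()) {
  model <- match.arg(model)
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  nj <- ncol(responses)
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("item", seq_len(nj))
  if (any(rowSums(!is.na(responses)) < 1L))
    stop("every person needs at least one observed response")

  # per-item category handling
  maps <- vector("list", nj)
  ncat <- integer(nj)
  for (j in seq_len(nj)) {
    x <- responses[, j]
    obs <- sort(unique(x[!is.na(x)]))
    if (length(obs) < 2L)
      stop(sprintf("item %d has fewer than 2 observed categories", j))
    kmax <- max(obs)
    full <- 0:kmax
    if (!all(full %in% obs) || min(obs) != 0L) {
      if (config$unobserved == "reject")
        stop(sprintf("item %d has never-observed categories", j))
      map <- match(x, obs) - 1L
      responses[, j] <- map
      maps[[j]] <- obs
      ncat[j] <- length(obs)
    } else ncat[j] <- kmax + 1L
  }
  if (model == "RSM" && length(unique(ncat)) != 1L)
    stop("RSM requires a common number of categories across items")

  grid <- theta_grid(config$n_quad, config$bounds)
  n <- nrow(responses)

  # starting values: a = 1, thresholds at logistic quantiles of the
  # observed category frequencies (deterministic)
  start <- lapply(seq_len(nj), function(j) {
    x <- responses[, j]
    pk <- tabulate(x + 1L, ncat[j]) + 0.5
    pk <- pk / sum(pk)
    cum <- rev(cumsum(rev(pk)))[-1L]                  # P(X >= k), k = 1..K-1
    b <- -stats::qlogis(pmin(pmax(cum, 0.02), 0.98))
    b <- pmin(pmax(b, -4), 4)
    # enforce strictly increasing starts
    for (k in seq_along(b)[-1L]) b[k] <- max(b[k], b[k - 1L] + 0.2)
    list(a = 1, b = b)
  })

  if (model == "RSM") {
    res <- em_rsm(responses, ncat, grid, start, config)
  } else {
    res <- em_per_item(responses, ncat, grid, start, config, model)
  }

  items <- lapply(seq_len(nj), function(j)
    item_parameters(colnames(responses)[j], model,
                    a = res$a[j], b = res$b[[j]]))
  bank <- item_bank(items)
  np <- count_params(model, ncat)
  fit <- fit_indices(-2 * res$loglik, np, n)
  structure(list(bank = bank, fit = fit, converged = res$converged,
                 n_cycles = res$cycles, loglik_trace = res$trace,
                 category_maps = maps, model = model),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result: %s, %d items, %s after %d EM cycles>\n",
              x$model, length(x$bank),
              if (x$converged) "converged" else "NOT converged", x$n_cycles))
  print(x$fit)
  invisible(x)
}

# ---- EM internals --------------------------------------------------------

# E-step: posterior weights (n x Q) and marginal loglik, given prob tables
estep <- function(responses, tables, grid) {
  ll <- response_loglik_matrix(responses, tables)
  ll <- sweep(ll, 2L, log(grid$weights), `+`)
  m <- apply(ll, 1L, max)
  e <- exp(ll - m)
  s <- rowSums(e)
  list(post = e / s, loglik = sum(log(s) + m))
}

# expected counts r_qk (Q x K) for one item
expected_counts <- function(post, x, K) {
  r <- matrix(0, ncol(post), K)
  ok <- !is.na(x)
  for (k in 0:(K - 1L)) {
    sel <- ok & x == k
    if (any(sel)) r[, k + 1L] <- colSums(post[sel, , drop = FALSE])
  }
  r
}

# expected complete-data negative log-likelihood for one item
ecdl_nll <- function(pfun, par, nodes, r) {
  p <- pfun(par, nodes)
  -sum(r * log(pmax(p, PROB_FLOOR)))
}

# GRM parameterization: (log a, b1, log gaps)
grm_pack <- function(a, b) c(log(a), b[1L], if (length(b) > 1L) log(pmax(diff(b), 1e-3)))
grm_unpack <- function(par) {
  a <- exp(par[1L])
  b <- par[2L]
  if (length(par) > 2L) b <- cumsum(c(par[2L], exp(par[-(1:2)])))
  list(a = a, b = b)
}
grm_pfun <- function(par, nodes) {
  u <- grm_unpack(par)
  .grm_probs(u$a, u$b, nodes)
}

gpcm_pack <- function(a, b) c(log(a), b)
gpcm_pfun <- function(par, nodes) .gpcm_probs(exp(par[1L]), par[-1L], nodes)

em_per_item <- function(responses, ncat, grid, start, config, model) {
  nj <- length(ncat)
  a <- vapply(start, `[[`, numeric(1), "a")
  b <- lapply(start, `[[`, "b")
  pack <- if (model == "GRM") grm_pack else gpcm_pack
  pfun <- if (model == "GRM") grm_pfun else gpcm_pfun
  trace <- numeric(0)
  converged <- FALSE
  cycles <- 0L
  for (cyc in seq_len(config$max_cycles)) {
    cycles <- cyc
    tables <- lapply(seq_len(nj), function(j) pfun(pack(a[j], b[[j]]), grid$nodes))
    es <- estep(responses, tables, grid)
    trace <- c(trace, es$loglik)
    delta <- 0
    for (j in seq_len(nj)) {
      r <- expected_counts(es$post, responses[, j], ncat[j])
      par0 <- pack(a[j], b[[j]])
      opt <- stats::optim(par0, ecdl_nll, pfun = pfun, nodes = grid$nodes,
                          r = r, method = "BFGS",
                          control = list(maxit = config$mstep_maxit))
      if (model == "GRM") {
        u <- grm_unpack(opt$par)
      } else {
        u <- list(a = exp(opt$par[1L]), b = opt$par[-1L])
      }
      delta <- max(delta, abs(u$a - a[j]), max(abs(u$b - b[[j]])))
      a[j] <- u$a
      b[[j]] <- u$b
    }
    if (delta < config$tol) { converged <- TRUE; break }
  }
  tables <- lapply(seq_len(nj), function(j) pfun(pack(a[j], b[[j]]), grid$nodes))
  loglik <- estep(responses, tables, grid)$loglik
  if (!converged)
    warning(sprintf("EM did not converge in %d cycles (max change %.2g)",
                    cycles, config$tol))
  list(a = a, b = b, loglik = loglik, trace = c(trace, loglik),
       converged = converged, cycles = cycles)
}

# RSM: common a = 1; delta_jk = beta_j + tau_k, mean(tau) = 0.
# Joint quasi-Newton M-step over (beta_1..J, tau_free_1..K-2).
em_rsm <- function(responses, ncat, grid, start, config) {
  nj <- length(ncat)
  K <- ncat[1L]
  beta <- vapply(start, function(s) mean(s$b), numeric(1))
  tau <- Reduce(`+`, lapply(start, function(s) s$b - mean(s$b))) / nj
  tau <- tau - mean(tau)
  pack <- function(beta, tau) c(beta, tau[seq_len(K - 2L)])
  unpack <- function(par) {
    beta <- par[seq_len(nj)]
    tf <- par[-seq_len(nj)]
    tau <- c(tf, -sum(tf))                            # mean-zero steps
    list(beta = beta, tau = tau)
  }
  nll <- function(par, rlist) {
    u <- unpack(par)
    tot <- 0
    for (j in seq_len(nj)) {
      p <- .gpcm_probs(1, u$beta[j] + u$tau, grid$nodes)
      tot <- tot - sum(rlist[[j]] * log(pmax(p, PROB_FLOOR)))
    }
    tot
  }
  trace <- numeric(0)
  converged <- FALSE
  cycles <- 0L
  for (cyc in seq_len(config$max_cycles)) {
    cycles <- cyc
    tables <- lapply(seq_len(nj), function(j) .gpcm_probs(1, beta[j] + tau, grid$nodes))
    es <- estep(responses, tables, grid)
    trace <- c(trace, es$loglik)
    rlist <- lapply(seq_len(nj), function(j)
      expected_counts(es$post, responses[, j], K))
    opt <- stats::optim(pack(beta, tau), nll, rlist = rlist, method = "BFGS",
                        control = list(maxit = config$mstep_maxit))
    u <- unpack(opt$par)
    delta <- max(abs(c(u$beta - beta, u$tau - tau)))
    beta <- u$beta
    tau <- u$tau
    if (delta < config$tol) { converged <- TRUE; break }
  }
  tables <- lapply(seq_len(nj), function(j) .gpcm_probs(1, beta[j] + tau, grid$nodes))
  loglik <- estep(responses, tables, grid)$loglik
  if (!converged)
    warning(sprintf("EM did not converge in %d cycles", cycles))
  list(a = rep(1, nj), b = lapply(beta, function(bb) bb + tau),
       loglik = loglik, trace = c(trace, loglik),
       converged = converged, cycles = cycles)
}

#' Compare polytomous IRT models on one response matrix
#'
#' Fits each candidate model and tabulates `-2LL`, AIC and BIC; smaller is
#' better. Non-convergent candidates are excluded from the ranking with a
#' warning.
#'
#' @inheritParams fit_model
#' @param models Character vector of candidates.
#' @return A data frame (one row per converged model) ordered by AIC, with
#'   the full `calibration_result`s in `attr(, "fits")`.
#' @export
compare_models <- function(responses, models = c("GRM", "GPCM", "RSM"),
                           config = calib_config()) {
  fits <- list()
  for (m in models) {
    f <- tryCatch(fit_model(responses, m, config),
                  error = function(e) {
                    warning(sprintf("%s failed: %s", m, conditionMessage(e)))
                    NULL
                  })
    if (!is.null(f) && !f$converged) {
      warning(sprintf("%s did not converge; excluded from ranking", m))
      f <- NULL
    }
    fits[[m]] <- f
  }
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) stop("no candidate model converged")
  tab <- do.call(rbind, lapply(names(fits)[keep], function(m) {
    cbind(data.frame(model = m), as.data.frame(fits[[m]]$fit))
  }))
  tab <- tab[order(tab$AIC), ]
  tab$rank_AIC <- rank(tab$AIC)
  tab$rank_BIC <- rank(tab$BIC)
  tab$rank_neg2LL <- rank(tab$neg2LL)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits[keep]
  tab
}

#' Read a response matrix from CSV
#'
#' Persons x items, integer categories, empty cells are missing. An
#' `origin` flag handles 1-based Likert codings.
#'
#' @param path CSV path.
#' @param origin Integer subtracted from every response (0 for already
#'   0-based data, 1 for 1-based).
#' @return Integer matrix with `NA` for missing.
#' @export
read_responses <- function(path, origin = 0L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "integer"
  m - as.integer(origin)
}
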