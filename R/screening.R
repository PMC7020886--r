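# The five-filter item-bank screening pipeline: iterative one-factor
# loading filter on polychoric correlations (unidimensionality), GRM
# calibration, Yen's Q3 local-independence screen, discrimination filter,
# Orlando-Thissen S-X2 item fit, and logistic-regression DIF with McFadden
# pseudo-R2 change and purification. No multiplicity correction anywhere:
# the raw conventional cutoffs (0.40 / 0.36 / 0.7 / 0.01 / 0.02) are
# applied, each configurable.

# ---- polychoric correlation ----------------------------------------------

#' Two-step polychoric correlation
#'
#' Thresholds are set from the inverse-normal marginal category
#' proportions; the correlation then maximizes the bivariate-normal cell
#' likelihood of the contingency table (golden-section search on
#' `[-0.999, 0.999]`). Cell probabilities use Gauss-Legendre quadrature of
#' the conditional normal CDF.
#'
#' @param x,y Ordinal integer vectors (each with at least two observed
#'   categories); pairs with `NA` in either are dropped.
#' @return The polychoric correlation estimate in `[-1, 1]`.
#' @export
polychoric_corr <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("polychoric correlation undefined for a degenerate (constant) vector")
  tab <- table(x, y)
  polychoric_from_table(unclass(tab))
}

# 24-point Gauss-Legendre nodes/weights on [-1, 1]
gl24 <- local({
  g <- function() {
    # Golub-Welsch via symmetric tridiagonal eigen-decomposition
    n <- 24L
    k <- seq_len(n - 1L)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1L)] <- beta
    J[cbind(k + 1L, k)] <- beta
    e <- eigen(J, symmetric = TRUE)
    list(nodes = e$values, weights = 2 * e$vectors[1L, ]^2)
  }
  g()
})

polychoric_from_table <- function(tab) {
  rp <- rowSums(tab) / sum(tab)
  cp <- colSums(tab) / sum(tab)
  ta <- stats::qnorm(cumsum(rp))[-length(rp)]         # row thresholds
  tb <- stats::qnorm(cumsum(cp))[-length(cp)]         # col thresholds
  lo <- c(-7.5, ta); hi <- c(ta, 7.5)
  # quadrature nodes per row band, fixed across rho
  nodes <- weights <- NULL
  for (i in seq_along(lo)) {
    half <- (hi[i] - lo[i]) / 2
    nodes <- c(nodes, lo[i] + half * (gl24$nodes + 1))
    weights <- c(weights, half * gl24$weights)
  }
  phi <- stats::dnorm(nodes)
  band <- rep(seq_along(lo), each = length(gl24$nodes))
  tbx <- c(tb, 7.5)
  nll <- function(rho) {
    s <- sqrt(1 - rho^2)
    cf <- stats::pnorm(outer(tbx, nodes, function(t, x) (t - rho * x) / s))
    cf <- rbind(0, cf)                                # (ncol+1) x nodes
    cellw <- (cf[-1L, , drop = FALSE] - cf[-nrow(cf), , drop = FALSE])
    p <- rowsum(t(cellw) * (weights * phi), band)     # nrow x ncol
    -sum(tab * log(pmax(p, 1e-12)))
  }
  stats::optimize(nll, c(-0.999, 0.999))$minimum
}

#' Polychoric correlation matrix of a response matrix
#'
#' @param responses Persons x items ordinal integer matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
polychoric_matrix <- function(responses) {
  p <- ncol(responses)
  R <- diag(p)
  for (i in seq_len(p - 1L))
    for (j in (i + 1L):p)
      R[i, j] <- R[j, i] <- polychoric_corr(responses[, i], responses[, j])
  dimnames(R) <- list(colnames(responses), colnames(responses))
  R
}

# ---- unidimensionality ----------------------------------------------------

#' Iterative one-factor loading filter and unidimensionality check
#'
#' Loadings are first-principal-component loadings of the polychoric
#' correlation matrix. Items loading below `loading_cutoff` are dropped
#' (all at once) and the analysis refit, until every retained loading is at
#' or above the cutoff. The check then passes when the first factor
#' explains at least `var_pct_min` percent of the test variance and the
#' first/second eigenvalue ratio is at least `ratio_min`.
#'
#' @param responses Persons x items ordinal matrix.
#' @param loading_cutoff Minimum retained loading (default 0.40).
#' @param var_pct_min Minimum first-factor variance percentage (default 20).
#' @param ratio_min Minimum first/second eigenvalue ratio (default 4).
#' @return A `dimensionality_report`: `iterations` (list of
#'   `removed`/`min_loading` per pass), `loadings` (final),
#'   `first_factor_variance_pct`, `eigenvalue_ratio`, `passed`,
#'   `retained` (column indices into the input).
#' @export
unidimensionality_filter <- function(responses, loading_cutoff = 0.40,
                                     var_pct_min = 20, ratio_min = 4) {
  if (ncol(responses) < 3L) stop("need at least 3 items")
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("item", seq_len(ncol(responses)))
  keep <- seq_len(ncol(responses))
  iterations <- list()
  repeat {
    if (length(keep) < 3L)
      stop("unidimensionality filter removed all (or nearly all) items")
    R <- polychoric_matrix(responses[, keep, drop = FALSE])
    e <- eigen(R, symmetric = TRUE)
    v1 <- e$vectors[, 1L]
    if (sum(v1) < 0) v1 <- -v1                        # orient positively
    load <- v1 * sqrt(max(e$values[1L], 0))
    low <- which(load < loading_cutoff)
    iterations[[length(iterations) + 1L]] <-
      list(removed = colnames(responses)[keep][low], min_loading = min(load))
    if (!length(low)) {
      ev <- e$values
      varpct <- 100 * ev[1L] / length(keep)
      ratio <- ev[1L] / ev[2L]
      return(structure(list(iterations = iterations,
                            loadings = stats::setNames(load, colnames(responses)[keep]),
                            first_factor_variance_pct = varpct,
                            eigenvalue_ratio = ratio,
                            passed = varpct >= var_pct_min && ratio >= ratio_min,
                            retained = keep),
                       class = "dimensionality_report"))
    }
    keep <- keep[-low]
  }
}

#' @export
print.dimensionality_report <- function(x, ...) {
  cat(sprintf(paste0("<dimensionality_report: %d items retained after %d pass(es); ",
                     "first factor %.1f%%, ratio %.2f, %s>\n"),
              length(x$retained), length(x$iterations),
              x$first_factor_variance_pct, x$eigenvalue_ratio,
              if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

# ---- Yen's Q3 -------------------------------------------------------------

#' Yen's Q3 local-dependence matrix
#'
#' Residuals are `x_ij - E[x_ij | theta_hat_i]` with `theta_hat` the EAP
#' estimate under the calibrated bank and `E` the model-implied expected
#' item score; `Q3(j, k)` is the Pearson correlation of the two items'
#' residuals over persons observed on both. Pairs with fewer than 3 joint
#' observations are `NA`.
#'
#' @param responses Persons x items matrix the bank was calibrated on.
#' @param bank Calibrated [item_bank()].
#' @param theta Optional trait estimates; defaults to [batch_eap()].
#' @param grid A [theta_grid()].
#' @return Symmetric matrix of Q3 values with unit diagonal.
#' @export
q3_matrix <- function(responses, bank, theta = NULL, grid = theta_grid()) {
  responses <- as.matrix(responses)
  stopifnot(ncol(responses) == length(bank))
  if (is.null(theta)) theta <- batch_eap(responses, bank, grid)$eap
  resid <- responses
  for (j in seq_len(ncol(responses))) {
    p <- category_probs(bank[[j]], theta)
    if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
    escore <- drop(p %*% (seq_len(ncol(p)) - 1))
    resid[, j] <- responses[, j] - escore
  }
  Q3 <- suppressWarnings(stats::cor(resid, use = "pairwise.complete.obs"))
  njoint <- crossprod(!is.na(responses))
  Q3[njoint < 3L] <- NA
  diag(Q3) <- 1
  dimnames(Q3) <- list(item_ids(bank), item_ids(bank))
  Q3
}

#' Remove items with low discrimination
#'
#' @param bank A calibrated [item_bank()].
#' @param cutoff Items with `a < cutoff` are removed (default 0.7).
#' @return List: `bank` (retained items), `removed` (ids), `a` (named
#'   discriminations).
#' @export
discrimination_filter <- function(bank, cutoff = 0.7) {
  a <- stats::setNames(vapply(bank$items, `[[`, numeric(1), "a"),
                       item_ids(bank))
  low <- which(a < cutoff)
  list(bank = if (length(low)) bank[-low] else bank,
       removed = names(a)[low], a = a)
}

# ---- Orlando-Thissen S-X2 -------------------------------------------------

#' Summed-score distribution by the Lord-Wingersky recursion
#'
#' Generalized (polytomous) recursion: given per-item category probability
#' matrices over theta nodes, returns the probability of each total score
#' at each node. With a single item this is the item's own category
#' distribution; columns sum to one at every node.
#'
#' @param tables List of `n_nodes x K_j` probability matrices (as from the
#'   items of a bank evaluated on a grid).
#' @return Matrix `n_nodes x (max_score + 1)`; column `s + 1` is
#'   `P(total = s | theta)`.
#' @export
summed_score_distribution <- function(tables) {
  q <- nrow(tables[[1L]])
  S <- matrix(1, q, 1L)
  for (tb in tables) {
    K <- ncol(tb)
    newS <- matrix(0, q, ncol(S) + K - 1L)
    for (k in seq_len(K))
      newS[, (k - 1L) + seq_len(ncol(S))] <-
        newS[, (k - 1L) + seq_len(ncol(S)), drop = FALSE] + S * tb[, k]
    S <- newS
  }
  S
}

#' Orlando-Thissen S-X2 item fit
#'
#' For each item, observed category frequencies within total-summed-score
#' groups are compared with their model-implied expectations
#' `E_jk(s) = int P_jk(t) S_(-j)(s - k | t) f(t) dt / int S(s | t) f(t) dt`,
#' computed with the generalized Lord-Wingersky recursion integrated over
#' the prior. Within each score group, cells are collapsed from the extreme
#' categories inward until every expected count is at least `min_expected`;
#' groups left with a single cell are merged into their neighbour.
#' `df = sum_s (cells_s - 1) - n_item_params`.
#'
#' @param responses Complete-case persons x items matrix (persons with any
#'   missing response are dropped, with a message).
#' @param bank Calibrated [item_bank()].
#' @param grid A [theta_grid()].
#' @param min_expected Collapsing floor for expected cell counts.
#' @return Data frame: `item_id`, `s_chi2`, `df`, `p_value` (NA, with a
#'   warning, for items whose table leaves no degrees of freedom).
#' @export
s_chi2_item_fit <- function(responses, bank, grid = theta_grid(),
                            min_expected = 1) {
  responses <- as.matrix(responses)
  stopifnot(ncol(responses) == length(bank))
  cc <- stats::complete.cases(responses)
  if (!all(cc)) {
    message(sum(!cc), " persons with missing responses dropped for S-X2")
    responses <- responses[cc, , drop = FALSE]
  }
  n <- nrow(responses)
  tables <- bank_prob_tables(bank, grid)
  total <- rowSums(responses)
  w <- grid$weights
  nj <- length(bank)
  out <- data.frame(item_id = item_ids(bank), s_chi2 = NA_real_,
                    df = NA_integer_, p_value = NA_real_)
  Sfull <- summed_score_distribution(tables)          # q x (maxS+1)
  denom <- drop(w %*% Sfull)                          # P(total = s)
  for (j in seq_len(nj)) {
    K <- ncol(tables[[j]])
    Srest <- summed_score_distribution(tables[-j])    # q x (maxS-K+2)
    maxS <- ncol(Sfull) - 1L
    # expected P(X_j = k, total = s) = int P_jk S_rest(s-k)
    E <- matrix(0, maxS + 1L, K)
    for (k in 0:(K - 1L)) {
      pk <- tables[[j]][, k + 1L]
      smax_rest <- ncol(Srest) - 1L
      for (s in k:(k + smax_rest))
        E[s + 1L, k + 1L] <- sum(w * pk * Srest[, s - k + 1L])
    }
    probs_cond <- E / pmax(denom, 1e-300)             # conditional on total
    # observed counts per score group
    O <- matrix(0, maxS + 1L, K)
    for (i in seq_len(n))
      O[total[i] + 1L, responses[i, j] + 1L] <- O[total[i] + 1L, responses[i, j] + 1L] + 1
    Ns <- rowSums(O)
    # interior score groups only (extremes are structurally degenerate)
    groups <- which(Ns > 0 & seq_len(maxS + 1L) > 1L & seq_len(maxS + 1L) < maxS + 1L)
    cells_o <- list(); cells_e <- list()
    for (s in groups) {
      e <- Ns[s] * probs_cond[s, ]
      o <- O[s, ]
      col <- collapse_cells(o, e, min_expected)
      if (length(col$e) >= 2L) {
        cells_o[[length(cells_o) + 1L]] <- col$o
        cells_e[[length(cells_e) + 1L]] <- col$e
      } else if (length(cells_o)) {                   # merge into previous group
        i0 <- length(cells_o)
        cells_o[[i0]] <- c(cells_o[[i0]][-length(cells_o[[i0]])],
                           cells_o[[i0]][length(cells_o[[i0]])] + sum(col$o))
        cells_e[[i0]] <- c(cells_e[[i0]][-length(cells_e[[i0]])],
                           cells_e[[i0]][length(cells_e[[i0]])] + sum(col$e))
      }
    }
    if (!length(cells_o)) {
      warning("item ", out$item_id[j], " skipped: no usable score groups")
      next
    }
    chi2 <- sum(vapply(seq_along(cells_o), function(i)
      sum((cells_o[[i]] - cells_e[[i]])^2 / pmax(cells_e[[i]], 1e-12)),
      numeric(1)))
    df <- sum(vapply(cells_o, length, integer(1)) - 1L) - bank[[j]]$n_categories
    if (df < 1L) {
      warning("item ", out$item_id[j], " skipped: non-positive df")
      next
    }
    out$s_chi2[j] <- chi2
    out$df[j] <- df
    out$p_value[j] <- stats::pchisq(chi2, df, lower.tail = FALSE)
  }
  out
}

# collapse cells from the extreme categories inward until expected >= floor
collapse_cells <- function(o, e, floor) {
  while (length(e) > 1L && min(e) < floor) {
    i <- which.min(e)
    # merge toward the interior
    tgt <- if (i == 1L) 2L else if (i == length(e)) length(e) - 1L
           else if (e[i - 1L] < e[i + 1L]) i - 1L else i + 1L
    e[tgt] <- e[tgt] + e[i]; o[tgt] <- o[tgt] + o[i]
    e <- e[-i]; o <- o[-i]
  }
  list(o = o, e = e)
}

# ---- proportional-odds model & DIF ---------------------------------------

#' Fit a cumulative-logit (proportional odds) model by maximum likelihood
#'
#' `P(y <= k) = plogis(zeta_k - X beta)` with increasing intercepts
#' (enforced by a log-gap reparameterization). Used by the DIF scan; the
#' null (intercepts-only) log-likelihood is also returned for McFadden
#' pseudo-R2 computation.
#'
#' @param y Integer ordinal response, 0-based.
#' @param X Numeric design matrix (no intercept column), or NULL for the
#'   intercepts-only model.
#' @return List: `zeta`, `beta`, `loglik`, `loglik_null`, `converged`.
#' @export
prop_odds_fit <- function(y, X = NULL) {
  y <- as.integer(y)
  K <- max(y) + 1L
  stopifnot(K >= 2L, min(y) >= 0L)
  n <- length(y)
  cum <- cumsum(tabulate(y + 1L, K))[-K] / n
  cum <- pmin(pmax(cum, 1 / (2 * n)), 1 - 1 / (2 * n))
  zeta0 <- stats::qlogis(cum)
  ll_null <- po_loglik(y, zeta0, NULL, NULL)
  if (is.null(X)) {
    return(list(zeta = zeta0, beta = numeric(0), loglik = ll_null,
                loglik_null = ll_null, converged = TRUE))
  }
  X <- as.matrix(X)
  pack <- function(zeta, beta)
    c(zeta[1L], if (K > 2L) log(pmax(diff(zeta), 1e-4)), beta)
  unpack <- function(par) {
    nz <- K - 1L
    zeta <- if (nz > 1L) cumsum(c(par[1L], exp(par[2:nz]))) else par[1L]
    list(zeta = zeta, beta = par[-seq_len(nz)])
  }
  nll <- function(par) {
    u <- unpack(par)
    -po_loglik(y, u$zeta, X, u$beta)
  }
  opt <- stats::optim(pack(zeta0, rep(0, ncol(X))), nll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  u <- unpack(opt$par)
  list(zeta = u$zeta, beta = u$beta, loglik = -opt$value,
       loglik_null = ll_null, converged = opt$convergence == 0L)
}

po_loglik <- function(y, zeta, X, beta) {
  eta <- if (is.null(X)) 0 else drop(X %*% beta)
  cz <- c(-Inf, zeta, Inf)
  pl <- stats::plogis(cz[y + 2L] - eta)
  pu <- stats::plogis(cz[y + 1L] - eta)
  sum(log(pmax(pl - pu, PROB_FLOOR)))
}

#' McFadden pseudo-R2
#'
#' `1 - loglik(model) / loglik(null)`; lies in `[0, 1)` for a model nesting
#' the intercepts-only null.
#'
#' @param loglik,loglik_null Model and null log-likelihoods.
#' @export
mcfadden_r2 <- function(loglik, loglik_null) {
  max(0, 1 - loglik / loglik_null)
}

#' Logistic-regression DIF scan with purification
#'
#' Per item, three nested proportional-odds models of the ordinal response
#' are fit: M1 (`theta`), M2 (`theta + group`), M3
#' (`theta + group + theta:group`). An item is flagged when the McFadden
#' pseudo-R2 change `R2(M3) - R2(M1)` exceeds `r2_cutoff`. When a
#' calibrated `bank` is supplied, flagged items are removed one at a time
#' (largest change first), the trait is re-estimated by EAP from the
#' remaining items, and the scan repeats until no item is flagged
#' (purification).
#'
#' @param responses Persons x items matrix.
#' @param group Binary group labels (0 = reference, 1 = focal).
#' @param theta Trait estimates; required when `bank` is NULL, otherwise
#'   recomputed each purification round.
#' @param bank Optional calibrated [item_bank()] enabling purification.
#' @param r2_cutoff Flagging threshold on the pseudo-R2 change (default 0.02).
#' @param min_group Minimum persons per group (default 50).
#' @param grid A [theta_grid()].
#' @return A `dif_result` data frame: `item_id`, `pseudo_r2_change`,
#'   `flagged`, `removed`, `round` — one row per item per scan round for
#'   removed items, final-round rows otherwise.
#' @export
dif_scan <- function(responses, group, theta = NULL, bank = NULL,
                     r2_cutoff = 0.02, min_group = 50L, grid = theta_grid()) {
  responses <- as.matrix(responses)
  group <- as.integer(group)
  stopifnot(length(group) == nrow(responses), all(group %in% 0:1))
  if (min(table(group)) < min_group)
    stop("both groups need at least ", min_group, " persons")
  ids <- colnames(responses)
  if (is.null(ids)) ids <- paste0("item", seq_len(ncol(responses)))
  if (is.null(theta)) {
    if (is.null(bank)) stop("supply `theta` or a calibrated `bank`")
    theta <- batch_eap(responses, bank, grid)$eap
  }
  active <- seq_len(ncol(responses))
  removed_rows <- NULL
  round <- 0L
  repeat {
    round <- round + 1L
    r2ch <- vapply(active, function(j) {
      item_dif_r2(responses[, j], theta, group)
    }, numeric(1))
    flagged <- r2ch > r2_cutoff
    res <- data.frame(item_id = ids[active], pseudo_r2_change = r2ch,
                      flagged = flagged, removed = FALSE, round = round)
    if (!any(flagged) || is.null(bank) || length(active) <= 2L) {
      out <- rbind(removed_rows, res)
      rownames(out) <- NULL
      class(out) <- c("dif_result", "data.frame")
      return(out)
    }
    worst <- which.max(r2ch)
    res$removed[worst] <- TRUE
    removed_rows <- rbind(removed_rows, res[worst, ])
    active <- active[-worst]
    theta <- batch_eap(responses[, active, drop = FALSE],
                       bank[match(ids[active], item_ids(bank))], grid)$eap
  }
}

# pseudo-R2 change for one item; separation / failed fits are treated as
# not-DIF with a warning
item_dif_r2 <- function(y, theta, group) {
  obs <- sort(unique(y))
  y2 <- match(y, obs) - 1L                            # consecutive categories
  f <- function(X) prop_odds_fit(y2, X)
  m1 <- tryCatch(f(cbind(theta = theta)), error = function(e) NULL)
  m3 <- tryCatch(f(cbind(theta = theta, group = group, ix = theta * group)),
                 error = function(e) NULL)
  if (is.null(m1) || is.null(m3) || !m1$converged || !m3$converged) {
    warning("DIF fit unestimable for an item; treated as no DIF")
    return(0)
  }
  r1 <- mcfadden_r2(m1$loglik, m1$loglik_null)
  r3 <- mcfadden_r2(m3$loglik, m3$loglik_null)
  max(0, r3 - r1)
}

# ---- the pipeline ---------------------------------------------------------

#' Screening pipeline configuration
#'
#' @param loading_cutoff,var_pct_min,ratio_min Unidimensionality stage.
#' @param q3_cutoff Local-independence stage (absolute Q3 above this flags
#'   a pair; the pair member with the lower discrimination is removed).
#' @param a_cutoff Discrimination stage.
#' @param p_cutoff Item-fit stage (S-X2 p below this removes the item).
#' @param r2_cutoff,min_group DIF stage.
#' @param calib A [calib_config()] used for every (re)calibration.
#' @export
screening_config <- function(loading_cutoff = 0.40, var_pct_min = 20,
                             ratio_min = 4, q3_cutoff = 0.36, a_cutoff = 0.7,
                             p_cutoff = 0.01, r2_cutoff = 0.02,
                             min_group = 50L, calib = calib_config()) {
  structure(list(loading_cutoff = loading_cutoff, var_pct_min = var_pct_min,
                 ratio_min = ratio_min, q3_cutoff = q3_cutoff,
                 a_cutoff = a_cutoff, p_cutoff = p_cutoff,
                 r2_cutoff = r2_cutoff, min_group = min_group, calib = calib),
            class = "screening_config")
}

#' Run the full item-bank screening pipeline
#'
#' Stages in order: unidimensionality (iterative loading filter) ->
#' GRM calibration -> local independence (Q3) -> discrimination ->
#' item fit (S-X2) -> DIF (when `group` is given), recalibrating after
#' every stage that removed items. Aborts if any stage empties the bank.
#'
#' @param responses Persons x items ordinal matrix (0-based).
#' @param group Optional binary labels for the DIF stage.
#' @param config A [screening_config()].
#' @return A `screening_report`: `stages` (named list with survivors,
#'   removals and per-stage detail), `final_bank` (calibrated
#'   [item_bank()]), `final_items` (ids), `dimensionality`, `q3_summary`.
#' @export
run_screening_pipeline <- function(responses, group = NULL,
                                   config = screening_config()) {
  responses <- as.matrix(responses)
  if (is.null(colnames(responses)))
    colnames(responses) <- paste0("item", seq_len(ncol(responses)))
  stages <- list()
  note_stage <- function(name, before, removed, detail = NULL) {
    stages[[name]] <<- list(items_before = before,
                            removed = removed,
                            survivors = setdiff(before, removed),
                            detail = detail)
    if (!length(setdiff(before, removed)))
      stop("screening stage '", name, "' removed every item; aborting")
  }
  ids <- colnames(responses)

  # 1. unidimensionality
  dim_rep <- unidimensionality_filter(responses, config$loading_cutoff,
                                      config$var_pct_min, config$ratio_min)
  keep <- ids[dim_rep$retained]
  note_stage("unidimensionality", ids, setdiff(ids, keep), dim_rep)

  recal <- function(keep) fit_model(responses[, keep, drop = FALSE], "GRM",
                                    config$calib)
  cal <- recal(keep)

  # 2. local independence (Q3): greedily resolve flagged pairs, dropping
  # the lower-discrimination member of each
  Q3 <- q3_matrix(responses[, keep, drop = FALSE], cal$bank)
  q3_removed <- character(0)
  repeat {
    q <- abs(Q3)
    diag(q) <- 0
    q[is.na(q)] <- 0
    alive <- setdiff(keep, q3_removed)
    q <- q[alive, alive, drop = FALSE]
    if (!length(q) || max(q) <= config$q3_cutoff) break
    ij <- which(q == max(q), arr.ind = TRUE)[1L, ]
    pair <- alive[ij]
    a <- vapply(pair, function(id) cal$bank[[match(id, item_ids(cal$bank))]]$a,
                numeric(1))
    q3_removed <- c(q3_removed, pair[which.min(a)])
  }
  q3_summary <- list(max_abs = max(abs(Q3[upper.tri(Q3)]), na.rm = TRUE),
                     n_flagged_pairs = sum(abs(Q3[upper.tri(Q3)]) > config$q3_cutoff,
                                           na.rm = TRUE))
  note_stage("local_independence", keep, q3_removed,
             list(q3 = Q3, summary = q3_summary))
  keep <- setdiff(keep, q3_removed)
  if (length(q3_removed)) cal <- recal(keep)

  # 3. discrimination
  disc <- discrimination_filter(cal$bank, config$a_cutoff)
  note_stage("discrimination", keep, disc$removed, disc$a)
  keep <- setdiff(keep, disc$removed)
  if (length(disc$removed)) cal <- recal(keep)

  # 4. item fit
  fit_tab <- s_chi2_item_fit(responses[, keep, drop = FALSE], cal$bank,
                             theta_grid(config$calib$n_quad, config$calib$bounds))
  misfits <- fit_tab$item_id[!is.na(fit_tab$p_value) &
                             fit_tab$p_value < config$p_cutoff]
  note_stage("item_fit", keep, misfits, fit_tab)
  keep <- setdiff(keep, misfits)
  if (length(misfits)) cal <- recal(keep)

  # 5. DIF
  if (!is.null(group)) {
    dif <- dif_scan(responses[, keep, drop = FALSE], group, bank = cal$bank,
                    r2_cutoff = config$r2_cutoff, min_group = config$min_group,
                    grid = theta_grid(config$calib$n_quad, config$calib$bounds))
    dif_removed <- dif$item_id[dif$removed]
    note_stage("dif", keep, dif_removed, dif)
    keep <- setdiff(keep, dif_removed)
    if (length(dif_removed)) cal <- recal(keep)
  }

  structure(list(stages = stages, final_bank = cal$bank, final_items = keep,
                 dimensionality = dim_rep, q3_summary = q3_summary,
                 calibration = cal),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-18s %3d -> %3d  (removed: %s)\n", nm,
                length(st$items_before), length(st$survivors),
                if (length(st$removed)) paste(st$removed, collapse = ", ")
                else "none"))
  }
  invisible(x)
}

#' Write a screening report's audit trail
#'
#' Serializes per-stage survivors and removals as JSON and the removed-item
#' audit as CSV.
#'
#' @param report A `screening_report`.
#' @param json_path,csv_path Output files (either may be NULL to skip).
#' @export
write_screening_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "screening_report"))
  if (!is.null(json_path)) {
    payload <- lapply(report$stages, function(st)
      list(items_before = st$items_before, removed = st$removed,
           survivors = st$survivors))
    payload$final_items <- report$final_items
    jsonlite::write_json(payload, json_path, auto_unbox = FALSE, pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(names(report$stages), function(nm) {
      rem <- report$stages[[nm]]$removed
      if (!length(rem)) return(NULL)
      data.frame(stage = nm, item_id = rem)
    }))
    if (is.null(rows)) rows <- data.frame(stage = character(0),
                                          item_id = character(0))
    utils::write.csv(rows, csv_path, row.names = FALSE)
  }
  invisible(report)
}
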