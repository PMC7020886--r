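# The adaptive test engine: entry theta = 0, maximum Fisher information
# item selection (ties broken by lowest item index), EAP scoring on the
# shared quadrature grid, and termination by fixed length and/or an SE
# threshold with a forced maximum length. Because item selection is greedy
# and does not depend on the stopping rule, a single full-length trajectory
# per person determines the result of every rule; `simulate_cohort()`
# exploits that, and `run_cat()` is the plain reference loop.

#' Stopping rule for a CAT
#'
#' At least one of `fixed_length` / `se_threshold` must be given. With an
#' SE threshold, the test ends as soon as the posterior SD drops below the
#' threshold (checked after each item, never before the first) or when
#' `max_items` have been given ("forced termination").
#'
#' @param fixed_length Optional fixed number of items.
#' @param se_threshold Optional SE(theta) threshold.
#' @param max_items Forced cap used with `se_threshold` (default 13).
#' @param label Optional display label.
#' @return A `stopping_rule` object.
#' @export
stopping_rule <- function(fixed_length = NULL, se_threshold = NULL,
                          max_items = 13L, label = NULL) {
  if (is.null(fixed_length) && is.null(se_threshold))
    stop("at least one of fixed_length / se_threshold is required")
  if (!is.null(fixed_length) && fixed_length < 1L)
    stop("fixed_length must be >= 1")
  if (is.null(label)) {
    label <- if (!is.null(fixed_length)) sprintf("length=%d", fixed_length)
             else sprintf("SE<%g|max=%d", se_threshold, max_items)
  }
  if (!is.null(fixed_length)) fixed_length <- as.integer(fixed_length)
  structure(list(fixed_length = fixed_length, se_threshold = se_threshold,
                 max_items = as.integer(max_items), label = label),
            class = "stopping_rule")
}

#' Posterior state over the latent trait
#'
#' `posterior_init()` returns the prior state (EAP 0, SE ~ 1 up to
#' quadrature error under the standard-normal prior); [eap_update()]
#' multiplies in one item's category likelihood.
#'
#' @param grid A [theta_grid()].
#' @return A `posterior_state` with fields `grid`, `density` (unnormalized),
#'   `eap`, `se`, `n_items`.
#' @export
posterior_init <- function(grid = theta_grid()) {
  st <- list(grid = grid, density = grid$weights, n_items = 0L)
  st[c("eap", "se")] <- posterior_moments(grid$nodes, grid$weights)
  structure(st, class = "posterior_state")
}

posterior_moments <- function(nodes, dens) {
  s <- sum(dens)
  eap <- sum(dens * nodes) / s
  list(eap = eap, se = sqrt(sum(dens * (nodes - eap)^2) / s))
}

#' Update a posterior with one item response (EAP scoring)
#'
#' @param state A `posterior_state`.
#' @param item An [item_parameters()] object.
#' @param response Observed 0-based category.
#' @return The updated `posterior_state`.
#' @export
eap_update <- function(state, item, response) {
  if (is.na(response) || response < 0 || response >= item$n_categories)
    stop("response out of range for item ", item$item_id)
  lik <- category_probs(item, state$grid$nodes)[, response + 1L]
  d <- state$density * pmax(lik, PROB_FLOOR)
  m <- max(d)
  if (m <= 0 || !is.finite(m)) stop("posterior mass underflow")
  d <- d / m                                          # rescale, never zero out
  state$density <- d
  state[c("eap", "se")] <- posterior_moments(state$grid$nodes, d)
  state$n_items <- state$n_items + 1L
  state
}

#' Select the next item by maximum Fisher information
#'
#' Evaluates every not-yet-administered item's information at the current
#' EAP estimate and returns the index of the maximum; ties go to the lowest
#' item index.
#'
#' @param state A `posterior_state`.
#' @param bank An [item_bank()].
#' @param administered Integer indices of items already given.
#' @return The selected item's index into the bank, or `NA` if exhausted.
#' @export
select_next_item <- function(state, bank, administered = integer(0)) {
  arr <- bank_arrays(bank)
  info <- bank_info_at(arr, state$eap)
  info[administered] <- -Inf
  if (all(!is.finite(info))) return(NA_integer_)
  which.max(info)                                     # first max = lowest index
}

# full-length greedy trajectory for one person: administer every item the
# person has a response for, in maximum-information order.
cat_trajectory <- function(resp, arr, tables, grid, n_steps = NULL) {
  avail <- which(!is.na(resp))
  if (is.null(n_steps)) n_steps <- length(avail)
  n_steps <- min(n_steps, length(avail))
  dens <- grid$weights
  mom <- posterior_moments(grid$nodes, dens)
  order_ix <- integer(n_steps)
  eaps <- numeric(n_steps)
  ses <- numeric(n_steps)
  taken <- rep(FALSE, length(resp))
  taken[is.na(resp)] <- TRUE
  for (s in seq_len(n_steps)) {
    info <- bank_info_at(arr, mom$eap)
    info[taken] <- -Inf
    j <- which.max(info)
    taken[j] <- TRUE
    dens <- dens * pmax(tables[[j]][, resp[j] + 1L], PROB_FLOOR)
    dens <- dens / max(dens)
    mom <- posterior_moments(grid$nodes, dens)
    order_ix[s] <- j
    eaps[s] <- mom$eap
    ses[s] <- mom$se
  }
  list(items = order_ix, eap = eaps, se = ses)
}

# index at which a trajectory terminates under a rule
rule_stop_index <- function(rule, ses, n_avail) {
  if (!is.null(rule$fixed_length))
    return(min(rule$fixed_length, as.integer(n_avail)))
  cap <- min(rule$max_items, as.integer(n_avail))
  hit <- which(ses[seq_len(cap)] < rule$se_threshold)
  if (length(hit)) hit[1L] else cap
}

#' Run a post-hoc CAT for one person
#'
#' Simulates the adaptive test against a person's complete response vector:
#' loop select - read recorded response - EAP update, until the stopping
#' rule fires. At least one item is always administered.
#'
#' @param responses_row Integer vector of 0-based responses, one per bank
#'   item (`NA` allowed; see `on_missing`).
#' @param bank An [item_bank()].
#' @param rule A [stopping_rule()].
#' @param grid A [theta_grid()]; the calibration/EAP default is shared so a
#'   full-bank CAT reproduces the batch EAP exactly.
#' @param on_missing If a selected item has no recorded response:
#'   `"skip"` makes it unavailable for selection, `"abort"` errors.
#' @return A `cat_result`: `item_ids`, `item_index`, `responses`,
#'   `trajectory` (data frame of eap/se after each item), `eap`, `se`,
#'   `n_items`.
#' @export
run_cat <- function(responses_row, bank, rule, grid = theta_grid(),
                    on_missing = c("skip", "abort")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(rule, "stopping_rule"),
            length(responses_row) == length(bank))
  if (!is.null(rule$fixed_length) && rule$fixed_length > length(bank))
    stop("fixed_length exceeds bank size")
  if (on_missing == "abort" && anyNA(responses_row))
    stop("missing response in post-hoc mode with on_missing = 'abort'")
  n_avail <- sum(!is.na(responses_row))
  if (n_avail < 1L) stop("person has no usable responses")
  arr <- bank_arrays(bank)
  tables <- bank_prob_tables(bank, grid)
  cap <- if (!is.null(rule$fixed_length)) rule$fixed_length else rule$max_items
  traj <- cat_trajectory(as.integer(responses_row), arr, tables, grid,
                         n_steps = min(cap, n_avail))
  stop_at <- rule_stop_index(rule, traj$se, n_avail)
  ix <- traj$items[seq_len(stop_at)]
  structure(list(item_ids = item_ids(bank)[ix], item_index = ix,
                 responses = as.integer(responses_row)[ix],
                 trajectory = data.frame(step = seq_len(stop_at),
                                         item = ix,
                                         eap = traj$eap[seq_len(stop_at)],
                                         se = traj$se[seq_len(stop_at)]),
                 eap = traj$eap[stop_at], se = traj$se[stop_at],
                 n_items = stop_at, rule = rule$label),
            class = "cat_result")
}

#' @export
print.cat_result <- function(x, ...) {
  cat(sprintf("<cat_result: %d items, eap = %.3f, se = %.3f (rule %s)>\n",
              x$n_items, x$eap, x$se, x$rule))
  invisible(x)
}

#' Batch EAP scoring of complete response patterns
#'
#' @param responses Persons x items integer matrix (0-based, `NA` missing).
#' @param bank An [item_bank()].
#' @param grid A [theta_grid()].
#' @return Data frame with columns `eap`, `se`.
#' @export
batch_eap <- function(responses, bank, grid = theta_grid()) {
  responses <- as.matrix(responses)
  tables <- bank_prob_tables(bank, grid)
  ll <- response_loglik_matrix(responses, tables)
  ll <- sweep(ll, 2L, log(grid$weights), `+`)
  m <- apply(ll, 1L, max)
  post <- exp(ll - m)
  s <- rowSums(post)
  eap <- drop(post %*% grid$nodes) / s
  v <- drop(post %*% grid$nodes^2) / s - eap^2
  data.frame(eap = eap, se = sqrt(pmax(v, 0)))
}

#' Simulate a CAT cohort under several stopping rules
#'
#' Runs the post-hoc CAT for every person once at full length and evaluates
#' each stopping rule on the shared trajectory (exactly equivalent to
#' running [run_cat()] per rule, since greedy selection is rule-free). Per
#' rule it reports the mean and SD of items used, mean SE, marginal
#' reliability of the EAPs, and the Pearson correlation with the complete
#' -pattern EAP.
#'
#' @param responses Complete persons x items response matrix.
#' @param bank An [item_bank()].
#' @param rules List of [stopping_rule()]s, or the string `"none"` inside
#'   the list for the administer-everything rule.
#' @param grid A [theta_grid()].
#' @return A `cat_cohort` object: `summary` (one row per rule, the
#'   stopping-rule characteristics table), `persons` (list of per-rule data
#'   frames with `eap`, `se`, `n_items`), and `full` (batch EAP results).
#' @export
simulate_cohort <- function(responses, bank, rules, grid = theta_grid()) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  stopifnot(ncol(responses) == length(bank))
  rules <- lapply(rules, function(r) {
    if (identical(r, "none"))
      stopping_rule(fixed_length = length(bank), label = "none")
    else r
  })
  arr <- bank_arrays(bank)
  tables <- bank_prob_tables(bank, grid)
  n <- nrow(responses)
  maxlen <- max(vapply(rules, function(r)
    if (!is.null(r$fixed_length)) r$fixed_length else r$max_items, numeric(1)))
  full <- batch_eap(responses, bank, grid)

  per_rule <- lapply(rules, function(r)
    data.frame(eap = numeric(n), se = numeric(n), n_items = integer(n)))
  fails <- character(0)
  for (i in seq_len(n)) {
    resp <- responses[i, ]
    n_avail <- sum(!is.na(resp))
    if (n_avail < 1L) { fails <- c(fails, sprintf("person %d: no responses", i)); next }
    traj <- cat_trajectory(resp, arr, tables, grid,
                           n_steps = min(maxlen, n_avail))
    for (k in seq_along(rules)) {
      s <- rule_stop_index(rules[[k]], traj$se, n_avail)
      per_rule[[k]][i, ] <- list(traj$eap[s], traj$se[s], s)
    }
  }
  if (length(fails)) warning(paste(fails, collapse = "; "))
  summary <- do.call(rbind, lapply(seq_along(rules), function(k) {
    d <- per_rule[[k]]
    data.frame(rule = rules[[k]]$label,
               items_used_mean = mean(d$n_items),
               items_used_sd = stats::sd(d$n_items),
               mean_se = mean(d$se),
               marginal_reliability = marginal_reliability(d$eap, d$se),
               corr_with_full = stats::cor(d$eap, full$eap))
  }))
  structure(list(summary = summary, persons = per_rule, full = full,
                 rules = rules), class = "cat_cohort")
}

#' @export
print.cat_cohort <- function(x, ...) {
  cat(sprintf("<cat_cohort: %d persons, %d rules>\n",
              nrow(x$full), length(x$rules)))
  print(x$summary, digits = 3)
  invisible(x)
}
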