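# Seeded generators for every input the toolkit consumes: latent traits,
# graded-response response matrices, external criterion scores, synthetic
# banks, and response matrices with planted defects for exercising the
# screening pipeline.

#' Cohort specification for synthetic respondents
#'
#' Defaults emulate the validation cohort the package's methods target: a
#' standard-normal latent trait (matching the EAP prior) and a criterion
#' scale scored 0-56 whose total dichotomizes at > 28 into a "high stress"
#' label. `criterion_noise_sd` defaults to 9.9 so that, with the slope of 8
#' used by [simulate_criterion()], the trait-criterion correlation sits
#' near 0.63 — the validity regime of a well-validated paper-and-pencil
#' stress scale.
#'
#' @param n_persons Number of respondents.
#' @param theta_mean,theta_sd Latent-trait normal parameters.
#' @param seed Integer seed; every generator taking the spec is
#'   reproducible from it.
#' @param criterion_noise_sd SD of the Gaussian noise added on the
#'   criterion's raw-score scale.
#' @param high_cut Criterion dichotomization point (default 28).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_persons = 972L, theta_mean = 0, theta_sd = 1,
                        seed = 1L, criterion_noise_sd = 9.9, high_cut = 28) {
  stopifnot(n_persons >= 1L, theta_sd > 0, criterion_noise_sd >= 0)
  structure(list(n_persons = as.integer(n_persons), theta_mean = theta_mean,
                 theta_sd = theta_sd, seed = as.integer(seed),
                 criterion_noise_sd = criterion_noise_sd, high_cut = high_cut),
            class = "cohort_spec")
}

#' Simulate a response matrix from an item bank
#'
#' Draws `theta_i ~ N(mean, sd)` and each response from the item's model
#' -implied category distribution at `theta_i`.
#'
#' @param bank An [item_bank()].
#' @param spec A [cohort_spec()].
#' @return List: `responses` (persons x items integer matrix, 0-based,
#'   columns named by item id) and `theta` (true latent traits).
#' @export
simulate_responses <- function(bank, spec = cohort_spec()) {
  set.seed(spec$seed)
  n <- spec$n_persons
  theta <- stats::rnorm(n, spec$theta_mean, spec$theta_sd)
  resp <- draw_responses(bank, theta)
  list(responses = resp, theta = theta)
}

# responses for given thetas (uses the ambient RNG stream)
draw_responses <- function(bank, theta, items = seq_along(bank$items)) {
  n <- length(theta)
  resp <- matrix(NA_integer_, n, length(items),
                 dimnames = list(NULL, item_ids(bank)[items]))
  for (jj in seq_along(items)) {
    p <- category_probs(bank[[items[jj]]], theta)
    if (!is.matrix(p)) p <- matrix(p, nrow = 1L)
    cum <- t(apply(p, 1L, cumsum))
    u <- stats::runif(n)
    resp[, jj] <- rowSums(u > cum[, -ncol(cum), drop = FALSE])
  }
  resp
}

#' The packaged 20-item graded-response parameter fixture
#'
#' Twenty calibrated GRM items from a published 93-item stress bank: items
#' 1-10 with four categories (three thresholds) and items 84-93 with five
#' categories (four thresholds), thresholds strictly increasing within each
#' item. Shipped as a plain CSV under `inst/extdata` and read through the
#' standard bank reader.
#'
#' @return An [item_bank()] of 20 GRM items.
#' @export
table1_bank <- function() {
  path <- system.file("extdata", "grm_bank_20items.csv", package = "catstress",
                      mustWork = TRUE)
  read_item_bank(path)
}

#' Generate a random GRM item bank
#'
#' Discriminations are uniform on `a_range`; each item's thresholds are
#' drawn uniformly on `b_range`, sorted, and pushed apart to a minimum gap
#' so they are strictly increasing. Defaults mirror the published bank's
#' spread (a between about 0.8 and 2.8; thresholds spanning roughly -2 to
#' 4.5) and the 4/5-category Likert formats of the source scales.
#'
#' @param n_items Number of items.
#' @param n_categories Integer vector recycled across items (4 and/or 5).
#' @param a_range,b_range Ranges for the uniform draws.
#' @param seed Integer seed.
#' @param min_gap Minimum threshold separation.
#' @return An [item_bank()] of GRM items named `"it01"`, `"it02"`, ...
#' @export
synth_bank <- function(n_items, n_categories = c(4L, 5L),
                       a_range = c(0.8, 2.8), b_range = c(-2, 4.5),
                       seed = 1L, min_gap = 0.3) {
  stopifnot(n_items >= 1L, all(a_range > 0))
  set.seed(seed)
  ncat <- rep_len(as.integer(n_categories), n_items)
  items <- lapply(seq_len(n_items), function(j) {
    a <- stats::runif(1, a_range[1], a_range[2])
    b <- sort(stats::runif(ncat[j] - 1L, b_range[1], b_range[2]))
    for (k in seq_along(b)[-1L]) b[k] <- max(b[k], b[k - 1L] + min_gap)
    item_parameters(sprintf("it%02d", j), "GRM", a = a, b = b)
  })
  item_bank(items)
}

#' Plant screening defects into a simulated response matrix
#'
#' Each defect is a list with a `type` and an `item` (index into the bank);
#' planted items must be disjoint. Supported types:
#' \describe{
#'   \item{`noise`}{replace the column with uniform random categories,
#'     independent of theta.}
#'   \item{`low_a`}{regenerate the column from the item with discrimination
#'     `a` (default 0.3).}
#'   \item{`dif`}{assign a focal group (fraction `focal_fraction`, default
#'     0.5) and regenerate focal-group responses with all thresholds
#'     shifted by `shift` (default +0.8, making the item harder for the
#'     focal group at matched theta).}
#'   \item{`dependent_pair`}{with probability `copy_prob` (default 0.8)
#'     overwrite item `item2`'s response with item `item`'s (the two items
#'     must share a category count).}
#'   \item{`misfit`}{regenerate the column from the item's own category
#'     curves evaluated at `|theta|` instead of `theta` — a non-monotone
#'     (U-shaped) regression on the trait that no graded response item can
#'     represent.}
#' }
#'
#' @param responses Persons x items matrix from [simulate_responses()].
#' @param bank The generating [item_bank()].
#' @param defects List of defect specifications (see Details).
#' @param theta True latent traits (required by `low_a`, `dif`, `misfit`).
#' @param seed Integer seed.
#' @return List: `responses` (modified matrix), `group` (0/1 focal labels,
#'   or NULL when no DIF defect was planted), `defects` (echo with filled
#'   defaults).
#' @export
plant_defects <- function(responses, bank, defects, theta = NULL, seed = 1L) {
  set.seed(seed)
  resp <- as.matrix(responses)
  planted <- unlist(lapply(defects, function(d) c(d$item, d$item2)))
  if (anyDuplicated(planted)) stop("planted items must be disjoint")
  if (length(planted) && any(planted > length(bank)))
    stop("defect on nonexistent item")
  group <- NULL
  n <- nrow(resp)
  for (i in seq_along(defects)) {
    d <- defects[[i]]
    j <- d$item
    K <- bank[[j]]$n_categories
    switch(d$type,
      noise = {
        resp[, j] <- sample.int(K, n, replace = TRUE) - 1L
      },
      low_a = {
        stopifnot(!is.null(theta))
        d$a <- d$a %||% 0.3
        weak <- item_parameters(bank[[j]]$item_id, "GRM", a = d$a,
                                b = bank[[j]]$b)
        resp[, j] <- draw_responses(item_bank(list(weak)), theta)[, 1L]
      },
      dif = {
        stopifnot(!is.null(theta))
        d$shift <- d$shift %||% 0.8
        d$focal_fraction <- d$focal_fraction %||% 0.5
        if (is.null(group))
          group <- as.integer(stats::runif(n) < d$focal_fraction)
        shifted <- item_parameters(bank[[j]]$item_id, "GRM", a = bank[[j]]$a,
                                   b = bank[[j]]$b + d$shift)
        focal <- which(group == 1L)
        resp[focal, j] <- draw_responses(item_bank(list(shifted)),
                                         theta[focal])[, 1L]
      },
      dependent_pair = {
        j2 <- d$item2
        if (is.null(j2)) stop("dependent_pair needs `item2`")
        if (bank[[j2]]$n_categories != K)
          stop("dependent_pair items must share a category count")
        d$copy_prob <- d$copy_prob %||% 0.8
        copy <- stats::runif(n) < d$copy_prob
        resp[copy, j2] <- resp[copy, j]
      },
      misfit = {
        stopifnot(!is.null(theta))
        resp[, j] <- draw_responses(item_bank(list(bank[[j]])), abs(theta))[, 1L]
      },
      stop("unknown defect type: ", d$type))
    defects[[i]] <- d
  }
  if (is.null(group) &&
      any(vapply(defects, function(d) identical(d$type, "dif"), logical(1))))
    stop("internal: DIF defect without group")
  list(responses = resp, group = group, defects = defects)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an external criterion score and high-stress label
#'
#' The criterion stands in for a 0-56 paper-and-pencil stress total: a
#' linear transform of the true trait, `28 + 8 * theta` plus Gaussian noise
#' (`spec$criterion_noise_sd`), clamped to `[0, 56]`; the binary label is
#' `criterion > spec$high_cut`.
#'
#' @param theta True latent traits.
#' @param spec A [cohort_spec()]; its `seed` is offset so the criterion
#'   noise is independent of the response draws.
#' @return List: `criterion_sum`, `high_label` (0/1).
#' @export
simulate_criterion <- function(theta, spec = cohort_spec()) {
  set.seed(spec$seed + 104729L)                       # decoupled stream
  raw <- 28 + 8 * theta + stats::rnorm(length(theta), 0, spec$criterion_noise_sd)
  crit <- pmin(pmax(raw, 0), 56)
  list(criterion_sum = crit, high_label = as.integer(crit > spec$high_cut))
}
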