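#' Construct a single item's parameter set
#'
#' An item is described by its model family, a discrimination parameter
#' `a > 0`, and a vector of `K - 1` threshold/step parameters for an item
#' with `K` ordered response categories. Under the graded response model
#' (GRM) the thresholds are boundary locations and must be strictly
#' increasing; under the generalized partial credit model (GPCM) and the
#' rating scale model (RSM) they are adjacent-category step parameters and
#' need not be ordered. For RSM items the steps decompose as
#' `location + shared category steps`; pass them via `location` and `steps`
#' or pre-composed through `b`.
#'
#' @param item_id Character scalar; unique label for the item.
#' @param model One of `"GRM"`, `"GPCM"`, `"RSM"`.
#' @param a Discrimination parameter, positive. RSM items conventionally use
#'   `a = 1`.
#' @param b Numeric vector of `K - 1` thresholds (GRM) or steps (GPCM/RSM).
#' @param location,steps Alternative RSM parameterisation: scalar item
#'   location plus the shared step vector; `b` is then `location + steps`.
#' @return An object of class `irt_item`.
#' @examples
#' item_parameters("it1", "GRM", a = 0.942, b = c(-0.609, 2.211, 4.352))
#' @export
item_parameters <- function(item_id, model = c("GRM", "GPCM", "RSM"),
                            a, b = NULL, location = NULL, steps = NULL) {
  model <- match.arg(model)
  if (is.null(b)) {
    if (is.null(location) || is.null(steps))
      stop("supply either `b` or both `location` and `steps`")
    b <- location + steps
  }
  b <- as.numeric(b)
  a <- as.numeric(a)
  if (length(a) != 1L || !is.finite(a) || a <= 0)
    stop("`a` must be a single positive number")
  if (length(b) < 1L || anyNA(b))
    stop("`b` must hold at least one finite threshold (K >= 2)")
  if (model == "GRM" && any(diff(b) <= 0))
    stop("GRM thresholds must be strictly increasing (ordering violation): ",
         paste(signif(b, 4), collapse = ", "))
  out <- list(item_id = as.character(item_id), model = model,
              a = a, b = b, n_categories = length(b) + 1L)
  if (!is.null(location)) {
    out$location <- as.numeric(location)
    out$steps <- as.numeric(steps)
  }
  structure(out, class = "irt_item")
}

#' @export
print.irt_item <- function(x, ...) {
  cat(sprintf("<%s item '%s'>  a = %.3f  b = (%s)\n", x$model, x$item_id,
              x$a, paste(sprintf("%.3f", x$b), collapse = ", ")))
  invisible(x)
}

#' Construct an item bank
#'
#' An ordered collection of [item_parameters()] objects sharing one model
#' family, with unique item ids.
#'
#' @param items List of `irt_item` objects.
#' @param metadata Optional named list (e.g. scale-of-origin tags).
#' @return An object of class `item_bank`; behaves like a list of items.
#' @export
item_bank <- function(items, metadata = list()) {
  if (inherits(items, "irt_item")) items <- list(items)
  stopifnot(length(items) >= 1L,
            all(vapply(items, inherits, logical(1), "irt_item")))
  ids <- vapply(items, `[[`, character(1), "item_id")
  if (anyDuplicated(ids)) stop("item ids must be unique")
  models <- unique(vapply(items, `[[`, character(1), "model"))
  if (length(models) > 1L)
    stop("all items in a bank must share one model family; found: ",
         paste(models, collapse = ", "))
  structure(list(items = items, metadata = metadata), class = "item_bank")
}

#' @export
length.item_bank <- function(x) length(x$items)

#' @export
`[.item_bank` <- function(x, i) item_bank(x$items[i], x$metadata)

#' @export
`[[.item_bank` <- function(x, i) x$items[[i]]

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank: %d %s items>\n", length(x), x$items[[1]]$model))
  print(utils::head(as.data.frame(x), 6))
  if (length(x) > 6) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.item_bank <- function(x, ...) {
  maxk <- max(item_categories(x))
  rows <- lapply(x$items, function(it) {
    b <- c(it$b, rep(NA_real_, maxk - 1L - length(it$b)))
    c(list(item_id = it$item_id, model = it$model,
           n_categories = it$n_categories, a = it$a),
      stats::setNames(as.list(b), paste0("b", seq_len(maxk - 1L))))
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' @rdname item_bank
#' @param x An `item_bank`.
#' @export
item_ids <- function(x) vapply(x$items, `[[`, character(1), "item_id")

#' @rdname item_bank
#' @export
item_categories <- function(x) vapply(x$items, `[[`, integer(1), "n_categories")

#' Read / write an item bank as CSV
#'
#' The file has columns `item_id, model, n_categories, a, b1, b2, ...`;
#' unused threshold cells are blank, mirroring the usual printed-table
#' convention for items with fewer categories.
#'
#' @param path File path.
#' @return `read_item_bank()` returns an [item_bank()].
#' @export
read_item_bank <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item_id", "model", "n_categories", "a")
  if (!all(need %in% names(df)))
    stop("item-bank CSV must have columns: ", paste(need, collapse = ", "))
  bcols <- grep("^b[0-9]+$", names(df), value = TRUE)
  bcols <- bcols[order(as.integer(sub("^b", "", bcols)))]
  items <- lapply(seq_len(nrow(df)), function(i) {
    k <- df$n_categories[i]
    b <- as.numeric(df[i, bcols[seq_len(k - 1L)]])
    item_parameters(df$item_id[i], df$model[i], a = df$a[i], b = b)
  })
  item_bank(items)
}

#' @rdname read_item_bank
#' @param bank An [item_bank()].
#' @export
write_item_bank <- function(bank, path) {
  utils::write.csv(as.data.frame(bank), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Quadrature grid over the latent trait
#'
#' Equally spaced nodes with standard-normal prior weights, renormalized to
#' sum to one. This grid is shared by the EM calibration and the EAP scorer
#' so that a full-bank CAT and a batch EAP on the same responses agree
#' exactly.
#'
#' @param n Number of nodes (default 61).
#' @param bounds Range of the grid (default `c(-6, 6)`).
#' @param mean,sd Prior mean and standard deviation.
#' @return An object of class `theta_grid` with fields `nodes`, `weights`.
#' @export
theta_grid <- function(n = 61L, bounds = c(-6, 6), mean = 0, sd = 1) {
  stopifnot(n >= 3L, bounds[2] > bounds[1], sd > 0)
  nodes <- seq(bounds[1], bounds[2], length.out = n)
  w <- stats::dnorm(nodes, mean, sd)
  w <- w / sum(w)
  structure(list(nodes = nodes, weights = w), class = "theta_grid")
}

# ---- internal flat-array view of a bank, used on hot paths --------------
# Missing thresholds are padded with +Inf so boundary probabilities and
# category weights vanish identically past each item's last category.
bank_arrays <- function(bank) {
  n <- length(bank)
  ncat <- item_categories(bank)
  maxb <- max(ncat) - 1L
  bmat <- matrix(Inf, n, maxb)
  for (i in seq_len(n)) bmat[i, seq_len(ncat[i] - 1L)] <- bank[[i]]$b
  list(a = vapply(bank$items, `[[`, numeric(1), "a"),
       bmat = bmat, ncat = ncat, maxk = max(ncat),
       model = bank[[1]]$model, ids = item_ids(bank))
}
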