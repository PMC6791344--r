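#' Library-preparation cost parameters for the five methods
#'
#' Loads the packaged parameter table for the five library-preparation
#' strategies: (1) standard primers with y-yoke ligation and an indexed
#' second PCR per sample, (2) standard primers then an indexed-fusion
#' PCR with pooled second PCR, (3) indexed primers with pooled y-yoke
#' ligation and pooled second PCR, (4) non-indexed fusion primers with
#' an indexed second PCR per sample, and (5) indexed fusion primers
#' with a pooled second PCR.  Prices are vendor list prices (January
#' 2019) and are deliberately data, not code: point `path` at your own
#' file to reprice.
#'
#' @param path optional CSV overriding the packaged one; columns
#'   `method`, `itru_buy_in`, `oligo_buy_in`, `fixed_per_sample`,
#'   `variable_per_pool` (NA for unpooled methods), `pooled`.
#' @return Data frame of per-method parameters.
#' @export
method_cost_params <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "method_costs.csv",
                        package = "amplitag", mustWork = TRUE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$pooled <- as.logical(df$pooled)
  df
}

.method_row <- function(method, params) {
  i <- match(method, params$method)
  if (is.na(i)) stop("unknown method: ", method)
  params[i, , drop = FALSE]
}

#' Minimum number of PCR reactions for an experiment
#'
#' Methods 1 and 4 need two reactions per sample (a first-round PCR and
#' an individual indexed second-round PCR).  Method 2 needs two
#' first-round reactions per sample (standard then indexed-fusion) plus
#' one pooled second-round reaction per pool.  Methods 3 and 5 need one
#' first-round reaction per sample plus one pooled second-round
#' reaction per pool.  For 96 samples in one pool this gives
#' 192/193/97/192/97 reactions for methods 1-5.
#'
#' @param method method number 1-5.
#' @param n_samples number of samples (>= 1).
#' @param n_pools number of pools for pooled methods (default: one per
#'   96-well plate).
#' @param params see [method_cost_params()].
#' @return Integer count of PCR reactions.
#' @examples
#' pcr_count(5, 96, 1)   # 97
#' @export
pcr_count <- function(method, n_samples,
                      n_pools = ceiling(n_samples / 96),
                      params = method_cost_params()) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  row <- .method_row(method, params)
  if (row$pooled && n_pools < 1)
    stop("pooled method ", method, " needs n_pools >= 1")
  n <- switch(as.character(method),
              "1" = 2L * n_samples,
              "2" = 2L * n_samples + n_pools,
              "3" = n_samples + n_pools,
              "4" = 2L * n_samples,
              "5" = n_samples + n_pools,
              stop("unknown method: ", method))
  as.integer(n)
}

#' Total and per-sample cost of an amplicon experiment
#'
#' Cost model: a one-time buy-in for the indexed universal primer set
#' plus a per-method oligo buy-in, a fixed per-sample library-prep
#' cost, and -- for methods that pool before the second PCR -- a
#' variable cost per pooled second-round reaction:
#' `total = itru_buy_in + oligo_buy_in + n_samples * fixed +
#' n_pools * variable` (variable term only for pooled methods).
#'
#' @inheritParams pcr_count
#' @return An object of class `prep_plan` with elements `method`,
#'   `n_samples`, `n_pools`, `total_cost`, `per_sample_cost` and
#'   `pcr_count` (USD).
#' @examples
#' # 18 plates of 96 samples under method 5: under $2 per library
#' total_cost(5, 18 * 96, 18)$per_sample_cost
#' @export
total_cost <- function(method, n_samples,
                       n_pools = ceiling(n_samples / 96),
                       params = method_cost_params()) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  row <- .method_row(method, params)
  if (row$pooled && (is.na(n_pools) || n_pools < 1))
    stop("pooled method ", method, " needs n_pools >= 1")
  total <- row$itru_buy_in + row$oligo_buy_in +
    n_samples * row$fixed_per_sample +
    if (row$pooled) n_pools * row$variable_per_pool else 0
  structure(list(method = method, n_samples = n_samples,
                 n_pools = if (row$pooled) n_pools else NA_integer_,
                 total_cost = total,
                 per_sample_cost = total / n_samples,
                 pcr_count = pcr_count(method, n_samples, n_pools,
                                       params)),
            class = "prep_plan")
}

#' @export
print.prep_plan <- function(x, ...) {
  cat(sprintf("Method %s: %d samples%s\n", x$method, x$n_samples,
              if (!is.na(x$n_pools))
                sprintf(" in %d pool(s)", x$n_pools) else ""))
  cat(sprintf("  total cost:      $%.2f\n", x$total_cost))
  cat(sprintf("  per sample:      $%.2f\n", x$per_sample_cost))
  cat(sprintf("  PCR reactions:   %d\n", x$pcr_count))
  invisible(x)
}

#' Rank methods by total cost at a given scale
#'
#' Evaluates [total_cost()] for all five methods at the given number of
#' samples and pools and ranks them cheapest first.  At large scales
#' (beyond about a dozen 96-well plates) the pooled indexed-fusion
#' strategy (method 5) wins; at a handful of samples the low-buy-in
#' unpooled methods do.
#'
#' @inheritParams pcr_count
#' @return Data frame ranked by ascending total cost with columns
#'   `method`, `total_cost`, `per_sample_cost`, `pcr_count`.
#' @examples
#' cheapest_method(18 * 96, 18)$method[1]   # 5
#' @export
cheapest_method <- function(n_samples,
                            n_pools = ceiling(n_samples / 96),
                            params = method_cost_params()) {
  plans <- lapply(params$method, total_cost, n_samples = n_samples,
                  n_pools = n_pools, params = params)
  df <- do.call(rbind, lapply(plans, function(p)
    data.frame(method = p$method, total_cost = p$total_cost,
               per_sample_cost = p$per_sample_cost,
               pcr_count = p$pcr_count)))
  df <- df[order(df$total_cost), , drop = FALSE]
  rownames(df) <- NULL
  df
}
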