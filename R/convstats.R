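# Convergence statistics.
#
# The null model: losses happen independently in each parasite (or host)
# lineage, each with its marginal probability (fraction of clusters with loss
# in that species), so the chance probability that one cluster is lost in ALL
# lineages is the product of the marginals. The observed number of convergent
# clusters x out of n is compared with Binomial(n, p0) by a two-sided exact
# test using the point-probability ("minlike") convention: the p-value sums
# Binomial(j; n, p0) over every outcome j whose point probability does not
# exceed that of x (up to a relative tolerance of 1e-7 to absorb floating
# point noise at ties).

#' Marginal loss (or gain) probability of one species
#'
#' The fraction of orthologous clusters in which the event was called for the
#' given species.
#'
#' @param table a `call_table`.
#' @param species a parasite or host species id appearing in the table's
#'   lineage pairing.
#' @param event `"loss"` or `"gain"`.
#' @return fraction in \[0,1\].
#' @export
marginal_event_prob <- function(table, species, event = c("loss", "gain")) {
  stopifnot(inherits(table, "call_table"))
  event <- match.arg(event)
  n <- attr(table, "n")
  if (n == 0) stop("computation error: empty call table")
  in_p <- table$parasite == species
  in_h <- table$host == species
  if (!any(in_p) && !any(in_h)) {
    stop("species ", species, " does not appear in the call table pairing")
  }
  col <- if (any(in_p)) paste0("parasite_", event) else paste0("host_", event)
  rows <- if (any(in_p)) in_p else in_h
  sum(table[[col]][rows]) / n
}

#' Expected probability of convergent loss under independence
#'
#' @param marginals per-species event probabilities.
#' @return their product — the chance that the event hits the same cluster in
#'   every lineage independently.
#' @export
expected_convergent_prob <- function(marginals) {
  marginals <- as.numeric(marginals)
  stopifnot(all(marginals >= 0 & marginals <= 1))
  prod(marginals)
}

#' Two-sided exact binomial test (point-probability convention)
#'
#' @param x observed successes.
#' @param n trials.
#' @param p0 null success probability.
#' @return the two-sided p-value.
#' @examples
#' binom_test_two_sided(18, 307, 0.0164)
#' @export
binom_test_two_sided <- function(x, n, p0) {
  stopifnot(length(x) == 1L, length(n) == 1L, length(p0) == 1L)
  if (is.na(x) || is.na(n) || x != round(x) || n != round(n) ||
      x < 0 || n < 1 || x > n) {
    stop("domain error: need integers 0 <= x <= n, n >= 1")
  }
  if (p0 < 0 || p0 > 1) stop("domain error: p0 must be in [0,1]")
  d <- stats::dbinom(0:n, n, p0)
  min(1, sum(d[d <= d[x + 1] * (1 + 1e-7)]))
}

# minlike two-sided p-values for all outcomes 0..n at once:
# p_j = sum of point probabilities <= d_j * (1 + tol)
.binom_minlike_pvals <- function(n, p0) {
  d <- stats::dbinom(0:n, n, p0)
  ord <- order(d)
  cum <- cumsum(d[ord])
  pos <- findInterval(d * (1 + 1e-7), d[ord])
  pmin(1, cum[pos])
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Obtained by inverting the binomial tail tests (beta-quantile form): the
#' lower bound solves the upper-tail equation P(X >= x) = alpha/2 (0 when
#' x = 0), the upper bound the lower-tail equation (1 when x = n).
#'
#' @param x observed successes.
#' @param n trials.
#' @param conf_level confidence level.
#' @return numeric vector `c(low, high)`.
#' @examples
#' clopper_pearson(18, 307)
#' @export
clopper_pearson <- function(x, n, conf_level = 0.95) {
  stopifnot(x == round(x), n == round(n), x >= 0, x <= n, n >= 1,
            conf_level > 0, conf_level < 1)
  a <- 1 - conf_level
  low <- if (x == 0) 0 else stats::qbeta(a / 2, x, n - x + 1)
  high <- if (x == n) 1 else stats::qbeta(1 - a / 2, x + 1, n - x)
  c(low = low, high = high)
}

#' Power of the two-sided exact binomial test
#'
#' Exact method: enumerate the rejection region
#' `R = {j : binom_test_two_sided(j, n, p0) <= alpha}` and sum
#' Binomial(j; n, p1) over it. Simulation method: the fraction of `B` draws
#' from Binomial(n, p1) that fall in the rejection region.
#'
#' @param n trials.
#' @param p0 null probability.
#' @param p1 alternative probability.
#' @param alpha test level.
#' @param method `"exact"` or `"simulate"`.
#' @param B number of simulation draws (simulate method).
#' @param seed optional seed for the simulate method.
#' @return list with `power`, `method` and the inputs.
#' @export
binom_power <- function(n, p0, p1, alpha = 0.05,
                        method = c("exact", "simulate"), B = 1e4,
                        seed = NULL) {
  method <- match.arg(method)
  stopifnot(n == round(n), n >= 1, p0 >= 0, p0 <= 1, p1 >= 0, p1 <= 1,
            alpha > 0, alpha < 1)
  reject <- .binom_minlike_pvals(n, p0) <= alpha
  if (method == "exact") {
    power <- sum(stats::dbinom(which(reject) - 1L, n, p1))
  } else {
    if (B < 1e4) stop("simulate method requires B >= 10^4")
    if (!is.null(seed)) set.seed(seed)
    draws <- stats::rbinom(B, n, p1)
    power <- mean(reject[draws + 1L])
  }
  list(power = power, method = method, n = n, p0 = p0, p1 = p1,
       alpha = alpha, B = if (method == "simulate") B else NA_integer_)
}

#' Test for convergent loss (or gain) across independent lineages
#'
#' Assembles the full convergence test from a call table: per-species
#' marginals, their product `p0` (the chance expectation), the observed count
#' `x` of clusters with the event in every lineage, the observed probability
#' `x/n` with its Clopper-Pearson interval, the two-sided exact binomial
#' p-value of `x` against Binomial(n, p0), and the power of the test at the
#' observed probability (both exact and, when requested, simulated).
#'
#' @param table a `call_table`.
#' @param side `"parasite"` or `"host"`: which member of each pair is scored.
#' @param event `"loss"` or `"gain"`.
#' @param alpha level used for the power computation.
#' @param conf_level Clopper-Pearson confidence level.
#' @param power_method `"exact"` or `"simulate"` (see [binom_power()]).
#' @param B,seed simulation controls for `power_method = "simulate"`.
#' @return object of class `conv_test`.
#' @export
convergence_test <- function(table, side = c("parasite", "host"),
                             event = c("loss", "gain"),
                             alpha = 0.05, conf_level = 0.95,
                             power_method = c("exact", "simulate"),
                             B = 1e4, seed = NULL) {
  stopifnot(inherits(table, "call_table"))
  side <- match.arg(side)
  event <- match.arg(event)
  power_method <- match.arg(power_method)
  lineages <- attr(table, "lineages")
  n <- attr(table, "n")
  if (n < 1) stop("computation error: empty call table")

  species <- unname(vapply(lineages, `[[`, character(1), side))
  marginals <- vapply(species, marginal_event_prob, numeric(1),
                      table = table, event = event)
  names(marginals) <- species
  p0 <- expected_convergent_prob(marginals)
  flag <- paste0(side, "_convergent_", event)
  x <- sum(convergence_flags(table)[[flag]])
  p_obs <- x / n
  pw <- binom_power(n, p0, p_obs, alpha = alpha, method = power_method,
                    B = B, seed = seed)
  structure(list(side = side, event = event, x = x, n = n,
                 marginals = marginals, p0 = p0, p_obs = p_obs,
                 ci = clopper_pearson(x, n, conf_level),
                 p_value = binom_test_two_sided(x, n, p0),
                 power = pw$power, power_method = pw$method,
                 alpha = alpha, conf_level = conf_level),
            class = "conv_test")
}

#' @export
print.conv_test <- function(x, digits = 4, ...) {
  cat("\n\tExact binomial test of convergent", x$event,
      paste0("(", x$side, " side)\n\n"))
  cat(sprintf("marginals: %s\n",
              paste(sprintf("%s=%.4f", names(x$marginals), x$marginals),
                    collapse = ", ")))
  cat(sprintf("expected prob. = %.4g; observed prob. [%d%% CI] = %.4f [%.4f-%.4f]; n = %d\n",
              x$p0, round(100 * x$conf_level), x$p_obs, x$ci[["low"]],
              x$ci[["high"]], x$n))
  cat(sprintf("x = %d convergent clusters; P = %.4g; power = %.4f (%s, alpha = %g)\n",
              x$x, x$p_value, x$power, x$power_method, x$alpha))
  invisible(x)
}

#' Subfamily enrichment for convergent events
#'
#' Per ancestral subfamily with at least one assigned cluster, tests the
#' observed convergent fraction against the family-wide expected probability
#' with the two-sided exact binomial test, then adjusts across subfamilies by
#' Benjamini-Hochberg.
#'
#' @param table a `call_table`.
#' @param subfamilies named character vector (cluster id -> subfamily label);
#'   clusters with `NA` labels are ignored.
#' @param p0 null probability; defaults to the family-wide product of
#'   marginals computed by [convergence_test()] on the same table.
#' @param side,event as in [convergence_test()].
#' @param conf_level Clopper-Pearson level for the per-subfamily interval.
#' @param adjust multiple-testing procedure (Benjamini-Hochberg).
#' @return data frame (class `enrichment`) with one row per subfamily,
#'   sorted by adjusted p-value.
#' @export
subfamily_enrichment <- function(table, subfamilies, p0 = NULL,
                                 side = "parasite", event = "loss",
                                 conf_level = 0.95, adjust = "BH") {
  stopifnot(inherits(table, "call_table"))
  adjust <- match.arg(adjust, "BH")
  if (is.null(p0)) {
    p0 <- convergence_test(table, side = side, event = event,
                           conf_level = conf_level)$p0
  }
  conv <- convergence_flags(table)
  flag <- paste0(side, "_convergent_", event)
  lab <- subfamilies[conv$cluster_id]
  keep <- !is.na(lab)
  if (!any(keep)) {
    return(structure(data.frame(subfamily = character(), x = integer(),
                                n = integer(), p_obs = numeric(),
                                ci_low = numeric(), ci_high = numeric(),
                                p_raw = numeric(), p_adj = numeric()),
                     class = c("enrichment", "data.frame"), p0 = p0))
  }
  rows <- do.call(rbind, lapply(split(which(keep), lab[keep]), function(idx) {
    x_s <- sum(conv[[flag]][idx])
    n_s <- length(idx)
    ci <- clopper_pearson(x_s, n_s, conf_level)
    data.frame(subfamily = lab[idx[1]], x = x_s, n = n_s,
               p_obs = x_s / n_s, ci_low = ci[["low"]], ci_high = ci[["high"]],
               p_raw = binom_test_two_sided(x_s, n_s, p0),
               stringsAsFactors = FALSE)
  }))
  rows$p_adj <- bh_adjust(rows$p_raw)
  rows <- rows[order(rows$p_adj, rows$subfamily), ]
  rownames(rows) <- NULL
  structure(rows, class = c("enrichment", "data.frame"), p0 = p0)
}

#' Test for equality of proportions
#'
#' Pearson chi-square on the 2-by-k success/failure table, with Yates
#' continuity correction in the two-group case when requested (repertoire
#' size and turnover-rate style comparisons).
#'
#' @param successes,totals equal-length integer vectors, `k >= 2` groups.
#' @param correction apply the continuity correction when `k = 2`.
#' @return list (class `prop_test_result`) with `statistic`, `df`, `p_value`.
#' @export
prop_test <- function(successes, totals, correction = TRUE) {
  stopifnot(length(successes) == length(totals), length(totals) >= 2)
  if (any(totals <= 0)) stop("domain error: all totals must be positive")
  if (any(successes < 0 | successes > totals)) {
    stop("domain error: successes must lie in [0, totals]")
  }
  ht <- suppressWarnings(stats::prop.test(successes, totals,
                                          correct = correction))
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value),
            class = "prop_test_result")
}

#' @export
print.prop_test_result <- function(x, ...) {
  cat(sprintf("Equality of proportions: X-squared = %.4g, df = %d, P = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values; order-preserving, each adjusted value is at
#' least the raw one and at most 1.
#'
#' @param pvalues raw p-values in \[0,1\].
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  stopifnot(all(is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)))
  stats::p.adjust(pvalues, method = "BH")
}
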