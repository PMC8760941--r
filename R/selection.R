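# Post-processing of externally estimated selection-intensity results.
#
# Each record carries the RELAX-style selection intensity k for one cluster
# (test branches = parasite branches, reference branches = host branches),
# the likelihood-ratio p-value, and the maximum branch dN/dS. Clusters with
# any dN/dS > 10 are excluded before FDR correction; k < 1 with FDR < 0.05
# means relaxed selection on the parasite branches, k > 1 intensified.

#' Load selection-intensity records
#'
#' @param tsv path to a TSV with header columns `cluster_id`, `k`, `p_lrt`,
#'   `max_omega`.
#' @param omega_cutoff exclusion threshold on the maximum branch dN/dS.
#' @return data frame (class `selection_records`) with added columns
#'   `excluded` (max_omega above the cutoff) and `fdr` (Benjamini-Hochberg
#'   over the non-excluded records; `NA` for excluded ones).
#' @export
load_selection_records <- function(tsv, omega_cutoff = 10) {
  d <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  need <- c("cluster_id", "k", "p_lrt", "max_omega")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop("selection table format error; missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (any(d$k < 0, na.rm = TRUE)) {
    stop("validation error: selection intensity k must be >= 0")
  }
  if (any(d$p_lrt < 0 | d$p_lrt > 1, na.rm = TRUE)) {
    stop("validation error: p_lrt must be in [0,1]")
  }
  d$excluded <- d$max_omega > omega_cutoff
  d$fdr <- NA_real_
  d$fdr[!d$excluded] <- bh_adjust(d$p_lrt[!d$excluded])
  class(d) <- c("selection_records", "data.frame")
  d
}

#' Flag clusters under convergently relaxed or intensified selection
#'
#' @param records a `selection_records` data frame (FDR already computed).
#' @param fdr_threshold significance threshold on the FDR-adjusted LRT
#'   p-value.
#' @return list with `counts` (named: relaxed, intensified), `relaxed` and
#'   `intensified` cluster id vectors.
#' @export
flag_convergent_relaxation <- function(records, fdr_threshold = 0.05) {
  stopifnot(inherits(records, "data.frame"), "fdr" %in% names(records))
  ok <- !records$excluded & !is.na(records$fdr)
  relaxed <- records$cluster_id[ok & records$k < 1 &
                                  records$fdr < fdr_threshold]
  intensified <- records$cluster_id[ok & records$k > 1 &
                                      records$fdr < fdr_threshold]
  list(counts = c(relaxed = length(relaxed),
                  intensified = length(intensified)),
       relaxed = relaxed, intensified = intensified)
}

#' Classify clusters by how many lineages lost the parasite ortholog
#'
#' @param table a `call_table`.
#' @return named factor (cluster id -> `none` / `one` / `multiple`), where
#'   `multiple` means parasite loss in two or more lineages.
#' @export
classify_loss_category <- function(table) {
  stopifnot(inherits(table, "call_table"))
  k <- tapply(table$parasite_loss, table$cluster_id, sum)
  cat_ <- ifelse(k == 0, "none", ifelse(k == 1, "one", "multiple"))
  factor(stats::setNames(cat_, names(k)),
         levels = c("none", "one", "multiple"))
}

#' Wilcoxon rank-sum comparison of selection intensities
#'
#' Two-sided test with midranks for ties. The statistic W is the rank sum of
#' the first group minus its minimum (the Mann-Whitney U of group `a`, the
#' convention of [stats::wilcox.test()]). The p-value is exact by permutation
#' when there are no ties and `n1 * n2 <= 10^4`, otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param a,b numeric vectors (e.g. k values of two loss categories).
#' @return list (class `wilcoxon_result`) with `W`, `p_value`, `n1`, `n2`,
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!length(a) || !length(b)) stop("domain error: both groups must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) * length(b) <= 1e4
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  structure(list(W = unname(ht$statistic), p_value = ht$p.value,
                 n1 = length(a), n2 = length(b),
                 method = if (exact) "exact" else "normal"),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank sum (%s): W = %g, P = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$W, x$p_value, x$n1, x$n2))
  invisible(x)
}

#' Compare selection intensity across loss categories
#'
#' Joins selection records with loss categories and runs the pairwise
#' rank-sum comparisons of k between the `none` category and each of `one`
#' and `multiple`, alongside the convergent relaxation/intensification
#' counts.
#'
#' @param records a `selection_records` data frame.
#' @param table a `call_table` for the same clusters.
#' @param fdr_threshold threshold for the relaxation flags.
#' @return list (class `selection_report`) with per-category group sizes,
#'   the two `wilcoxon_result`s and the flag counts.
#' @export
selection_report <- function(records, table, fdr_threshold = 0.05) {
  categories <- classify_loss_category(table)
  keep <- !records$excluded & records$cluster_id %in% names(categories)
  d <- records[keep, ]
  d$category <- categories[d$cluster_id]
  ks <- split(d$k, d$category)
  cmp <- list(none_vs_one = NULL, none_vs_multiple = NULL)
  if (length(ks$none) && length(ks$one)) {
    cmp$none_vs_one <- wilcoxon_rank_sum(ks$none, ks$one)
  }
  if (length(ks$none) && length(ks$multiple)) {
    cmp$none_vs_multiple <- wilcoxon_rank_sum(ks$none, ks$multiple)
  }
  structure(list(group_sizes = vapply(ks, length, integer(1)),
                 comparisons = cmp,
                 flags = flag_convergent_relaxation(records, fdr_threshold),
                 records = d),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("Selection-intensity report\n  group sizes:",
      paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
            collapse = " "), "\n")
  for (nm in names(x$comparisons)) {
    if (!is.null(x$comparisons[[nm]])) {
      cat(" ", sub("_", " ", nm), "- ")
      print(x$comparisons[[nm]])
    }
  }
  cat(sprintf("  convergently relaxed: %d; intensified: %d\n",
              x$flags$counts[["relaxed"]], x$flags$counts[["intensified"]]))
  invisible(x)
}
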