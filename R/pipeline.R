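# End-to-end orchestration: tree IO -> clustering -> calls -> convergence
# statistics (-> selection post-processing), with machine-readable reports.

#' Run the full convergent-loss inference chain
#'
#' Parses each gene tree, optionally roots it on a given outgroup, collapses
#' weakly supported branches, identifies orthologous clusters across all
#' trees, builds the clusters-by-lineages call table, and computes the four
#' convergence tests (parasite/host x loss/gain). When an anchor table is
#' supplied, clusters receive subfamily labels and the subfamily enrichment
#' is computed; when selection records are supplied, the selection report is
#' added. With `out_dir` set, all stage outputs are written as TSV/JSON plus
#' a log of the run parameters and conventions.
#'
#' @param trees character vector of newick strings, or a path to a file with
#'   one newick per line.
#' @param mapping gene-to-species mapping: named vector, data frame, or TSV
#'   path (see [read_mapping()]); `NULL` uses the `"SPECIES|gene"` leaf-name
#'   convention.
#' @param roles a [species_config()] or path to a roles TSV/YAML.
#' @param anchors optional anchor table (named vector, data frame or TSV
#'   path).
#' @param selection optional selection-record TSV path or
#'   `selection_records` data frame.
#' @param outgroup optional character vector of outgroup gene ids used to
#'   root each tree that contains them; trees are otherwise used as parsed.
#' @param out_dir optional output directory.
#' @param support_threshold support-collapsing threshold.
#' @param alpha test level (power computation and selection flags).
#' @param conf_level Clopper-Pearson confidence level.
#' @param power_method `"exact"` or `"simulate"`.
#' @param seed seed echoed to stochastic components.
#' @param curation optional curation override (see [apply_curation()]).
#' @return object of class `convloss_run` with elements `clusters`, `calls`,
#'   `convergence` (list of four `conv_test`s), `enrichment`, `selection`,
#'   `config` and `params`.
#' @export
run_convloss <- function(trees, mapping = NULL, roles,
                         anchors = NULL, selection = NULL, outgroup = NULL,
                         out_dir = NULL, support_threshold = 0.7,
                         alpha = 0.05, conf_level = 0.95,
                         power_method = "exact", seed = 1, curation = NULL) {
  stopifnot(support_threshold >= 0, support_threshold <= 1,
            alpha > 0, alpha < 1, conf_level > 0, conf_level < 1)
  if (is.character(roles) && length(roles) == 1L) {
    roles <- read_species_config(roles)
  }
  if (is.character(mapping) && length(mapping) == 1L && file.exists(mapping)) {
    mapping <- read_mapping(mapping)
  }
  if (is.character(anchors) && length(anchors) == 1L) {
    anchors <- read_anchor_table(anchors)
  }
  if (is.character(trees) && length(trees) == 1L && file.exists(trees)) {
    trees <- readLines(trees)
    trees <- trees[nzchar(trimws(trees))]
  }
  if (!length(trees)) stop("stage treeio: no input trees")

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE)
    })
  }

  clusters <- list()
  for (i in seq_along(trees)) {
    ctx <- paste0("tree ", i)
    tr <- stage(paste("treeio,", ctx),
                parse_gene_tree(trees[[i]], mapping = mapping, quiet = TRUE))
    if (!is.null(outgroup)) {
      og <- intersect(outgroup, tr$phy$tip.label)
      if (length(og)) {
        tr <- stage(paste("rooting,", ctx), root_by_outgroup(tr, og))
      }
    }
    tr <- stage(paste("collapsing,", ctx),
                collapse_low_support(tr, support_threshold))
    cl <- stage(paste("clustering,", ctx),
                find_ortholog_clusters(tr, roles,
                                       id_prefix = sprintf("T%03d_OC", i)))
    clusters <- c(clusters, unclass(cl))
  }
  clusters <- structure(clusters, class = "ortholog_clusters",
                        focal = roles$focal)
  if (!is.null(curation)) {
    clusters <- stage("curation", apply_curation(clusters, curation))
  }
  if (!is.null(anchors)) {
    clusters <- structure(lapply(clusters, assign_subfamily, anchor_table = anchors),
                          class = "ortholog_clusters", focal = roles$focal)
  }

  calls <- stage("gainloss", build_call_table(clusters, roles))

  conv <- list()
  for (side in c("parasite", "host")) {
    for (event in c("loss", "gain")) {
      conv[[paste(side, event, sep = "_")]] <-
        stage("convstats",
              convergence_test(calls, side = side, event = event,
                               alpha = alpha, conf_level = conf_level,
                               power_method = power_method, seed = seed))
    }
  }

  enrichment <- NULL
  if (!is.null(anchors)) {
    subfam <- stats::setNames(vapply(clusters, `[[`, character(1), "subfamily"),
                              vapply(clusters, `[[`, character(1), "cluster_id"))
    enrichment <- stage("enrichment",
                        subfamily_enrichment(calls, subfam,
                                             p0 = conv$parasite_loss$p0,
                                             conf_level = conf_level))
  } else {
    warning("no anchor table supplied; subfamily enrichment stage skipped")
  }

  sel <- NULL
  if (!is.null(selection)) {
    if (is.character(selection)) {
      selection <- stage("selection", load_selection_records(selection))
    }
    sel <- stage("selection", selection_report(selection, calls,
                                               fdr_threshold = alpha))
  }

  params <- list(support_threshold = support_threshold, alpha = alpha,
                 conf_level = conf_level, power_method = power_method,
                 seed = seed, n_trees = length(trees))
  run <- structure(list(clusters = clusters, calls = calls,
                        convergence = conv, enrichment = enrichment,
                        selection = sel, config = roles, params = params),
                   class = "convloss_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' Write all stage outputs of a run
#'
#' @param run a `convloss_run`.
#' @param out_dir directory (created if missing).
#' @return invisibly, the named list of files written.
#' @export
write_run <- function(run, out_dir) {
  stopifnot(inherits(run, "convloss_run"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(clusters = file.path(out_dir, "clusters.tsv"),
                calls = file.path(out_dir, "calls.tsv"),
                convergence = file.path(out_dir, "convergence.json"),
                log = file.path(out_dir, "run_log.txt"))
  utils::write.table(as.data.frame(run$clusters), paths$clusters,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(run$calls), paths$calls,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  conv <- lapply(run$convergence, function(ct) {
    list(side = ct$side, event = ct$event, x = ct$x, n = ct$n,
         marginals = as.list(ct$marginals), p0 = ct$p0, p_obs = ct$p_obs,
         ci = as.list(ct$ci), p_value = ct$p_value, power = ct$power,
         power_method = ct$power_method, alpha = ct$alpha,
         conf_level = ct$conf_level)
  })
  jsonlite::write_json(conv, paths$convergence, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(run$enrichment)) {
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
    utils::write.table(as.data.frame(run$enrichment), paths$enrichment,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(run$selection)) {
    paths$selection <- file.path(out_dir, "selection_report.tsv")
    utils::write.table(run$selection$records, paths$selection,
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  log <- c(
    paste0("convloss ", as.character(utils::packageVersion("convloss")),
           " / R ", as.character(getRversion())),
    paste0("seed: ", run$params$seed),
    paste0("trees: ", run$params$n_trees,
           "; clusters: ", length(run$clusters)),
    paste0("support threshold: ", run$params$support_threshold,
           " (strict <; 0-100 support dialect auto-rescaled to [0,1];",
           " absent supports retained)"),
    "two-sided p-value convention: point-probability (minlike), rel. tol 1e-7",
    paste0("power method: ", run$params$power_method,
           " (alpha = ", run$params$alpha, ")"),
    paste0("multiple-testing adjustment: Benjamini-Hochberg")
  )
  writeLines(log, paths$log)
  invisible(paths)
}

#' @export
print.convloss_run <- function(x, ...) {
  cat("convloss run:", length(x$clusters), "clusters,",
      length(attr(x$calls, "lineages")), "lineage pairs\n")
  ct <- x$convergence$parasite_loss
  cat(sprintf("  parasite convergent loss: x = %d / n = %d (p0 = %.4g, P = %.4g)\n",
              ct$x, ct$n, ct$p0, ct$p_value))
  ct <- x$convergence$host_loss
  cat(sprintf("  host convergent loss:     x = %d / n = %d (p0 = %.4g, P = %.4g)\n",
              ct$x, ct$n, ct$p0, ct$p_value))
  invisible(x)
}

#' @export
summary.convloss_run <- function(object, ...) {
  out <- list(calls = summary(object$calls),
              convergence = object$convergence,
              enrichment = object$enrichment,
              selection = object$selection)
  class(out) <- "summary.convloss_run"
  out
}

#' @export
print.summary.convloss_run <- function(x, ...) {
  print(x$calls)
  for (ct in x$convergence) print(ct)
  if (!is.null(x$enrichment)) {
    cat("\nSubfamily enrichment (top rows):\n")
    print(utils::head(as.data.frame(x$enrichment)), row.names = FALSE)
  }
  if (!is.null(x$selection)) print(x$selection)
  invisible(x)
}

#' Plot convergent event counts against the chance expectation
#'
#' Bar chart of the observed numbers of convergently lost and gained
#' clusters per side, with a diamond marking the expected count under the
#' product-of-marginals null (`n * p0`).
#'
#' @param x a `convloss_run`.
#' @param ... passed to [graphics::barplot()].
#' @export
plot.convloss_run <- function(x, ...) {
  obs <- vapply(x$convergence, `[[`, numeric(1), "x")
  expd <- vapply(x$convergence, function(ct) ct$n * ct$p0, numeric(1))
  bp <- graphics::barplot(obs, names.arg = sub("_", "\n", names(obs)),
                          ylab = "convergent clusters",
                          ylim = c(0, max(obs, expd) * 1.15 + 1), ...)
  graphics::points(bp, expd, pch = 23, bg = "gold", cex = 1.4)
  graphics::legend("topright", legend = "chance expectation (n x p0)",
                   pch = 23, pt.bg = "gold", bty = "n")
  invisible(x)
}
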