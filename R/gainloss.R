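# Per-cluster, per-lineage gain and loss calls.
#
# A parasite loss in a cluster is a negative difference between the parasite's
# post-collapse ortholog count and its paired host's; a positive difference is
# a host loss. Gains are species-specific expansions recorded at collapse
# time. An event is convergent when it occurred in every lineage pair.

#' Call gain/loss for one cluster against one parasite-host pair
#'
#' @param cluster an `ortholog_cluster`.
#' @param lineage named character vector `c(parasite = ..., host = ...)`.
#' @param lineage_id label stored in the call.
#' @return one-row data frame with the count difference
#'   `delta = parasite - host` and the four call flags.
#' @export
call_pair <- function(cluster, lineage, lineage_id = NA_character_) {
  stopifnot(inherits(cluster, "ortholog_cluster"))
  p <- lineage[["parasite"]]
  h <- lineage[["host"]]
  if (!all(c(p, h) %in% names(cluster$counts))) {
    stop("configuration error: species ", p, " / ", h,
         " not among cluster count columns")
  }
  delta <- cluster$counts[[p]] - cluster$counts[[h]]
  data.frame(cluster_id = cluster$cluster_id,
             lineage_id = lineage_id,
             parasite = p, host = h,
             parasite_count = cluster$counts[[p]],
             host_count = cluster$counts[[h]],
             delta = delta,
             parasite_loss = delta < 0,
             host_loss = delta > 0,
             parasite_gain = cluster$gains[[p]],
             host_gain = cluster$gains[[h]],
             stringsAsFactors = FALSE)
}

#' Build the clusters-by-lineages call table
#'
#' Evaluates [call_pair()] for every cluster against every lineage pair and
#' derives per-cluster convergence flags: an event is convergent when it
#' occurred in all lineages. Clusters with no call in a lineage (both counts
#' zero) still count towards the total `n`.
#'
#' @param clusters an `ortholog_clusters` set (or plain list of
#'   `ortholog_cluster` objects).
#' @param config a [species_config()].
#' @param lineages optional pairing override (same structure as
#'   `config$lineages`); the default uses the configured parasite-host pairs.
#'   Supplying e.g. host-vs-nonhost pairs reuses the same call machinery for
#'   turnover-rate comparisons.
#' @return a `call_table`: data frame of calls with attributes `convergence`
#'   (per-cluster flag data frame), `n` (number of clusters), `lineages` and
#'   `config`.
#' @export
build_call_table <- function(clusters, config, lineages = NULL) {
  if (is.null(lineages)) lineages <- config$lineages
  if (!length(clusters)) stop("no clusters to call")
  if (!length(lineages)) stop("no lineage pairs configured")
  ids <- vapply(clusters, `[[`, character(1), "cluster_id")
  counts <- do.call(rbind, lapply(clusters, `[[`, "counts"))
  gains <- do.call(rbind, lapply(clusters, `[[`, "gains"))
  species <- unique(unlist(lineages))
  miss <- setdiff(species, colnames(counts))
  if (length(miss)) {
    stop("configuration error: species ", paste(miss, collapse = ", "),
         " not among cluster count columns")
  }
  per_lineage <- lapply(names(lineages), function(ln) {
    p <- lineages[[ln]][["parasite"]]
    h <- lineages[[ln]][["host"]]
    delta <- counts[, p] - counts[, h]
    data.frame(cluster_id = ids, lineage_id = ln, parasite = p, host = h,
               parasite_count = counts[, p], host_count = counts[, h],
               delta = delta,
               parasite_loss = delta < 0, host_loss = delta > 0,
               parasite_gain = gains[, p], host_gain = gains[, h],
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, per_lineage)
  calls <- calls[order(calls$cluster_id, calls$lineage_id), ]
  rownames(calls) <- NULL
  .as_call_table(calls, length(clusters), lineages, config)
}

# assemble the call_table class from a finished call data frame
.as_call_table <- function(calls, n, lineages, config) {
  k <- length(lineages)
  tot <- rowsum(cbind(pl = as.integer(calls$parasite_loss),
                      hl = as.integer(calls$host_loss),
                      pg = as.integer(calls$parasite_gain),
                      hg = as.integer(calls$host_gain)),
                calls$cluster_id)
  conv <- data.frame(cluster_id = rownames(tot),
                     parasite_convergent_loss = tot[, "pl"] == k,
                     host_convergent_loss = tot[, "hl"] == k,
                     parasite_convergent_gain = tot[, "pg"] == k,
                     host_convergent_gain = tot[, "hg"] == k,
                     stringsAsFactors = FALSE)
  rownames(conv) <- NULL
  structure(calls, class = c("call_table", "data.frame"),
            convergence = conv, n = n, lineages = lineages, config = config)
}

#' Per-species loss/gain totals of a call table
#'
#' @param object a `call_table`.
#' @param ... unused.
#' @return list with `n`, per-species data frame `species` (clusters with
#'   loss, clusters with gain) and convergence counts for the four
#'   (side, event) combinations.
#' @export
summary.call_table <- function(object, ...) {
  lineages <- attr(object, "lineages")
  conv <- attr(object, "convergence")
  per_species <- do.call(rbind, lapply(names(lineages), function(ln) {
    g <- object[object$lineage_id == ln, ]
    data.frame(
      species_id = c(lineages[[ln]][["parasite"]], lineages[[ln]][["host"]]),
      role = c("parasite", "host"),
      lineage_id = ln,
      losses = c(sum(g$parasite_loss), sum(g$host_loss)),
      gains = c(sum(g$parasite_gain), sum(g$host_gain)),
      stringsAsFactors = FALSE
    )
  }))
  out <- list(
    n = attr(object, "n"),
    species = per_species,
    convergent = c(parasite_loss = sum(conv$parasite_convergent_loss),
                   host_loss = sum(conv$host_convergent_loss),
                   parasite_gain = sum(conv$parasite_convergent_gain),
                   host_gain = sum(conv$host_convergent_gain))
  )
  class(out) <- "summary.call_table"
  out
}

#' @export
print.summary.call_table <- function(x, ...) {
  cat("Call table over", x$n, "clusters\n")
  print(x$species, row.names = FALSE)
  cat("Convergent events (all lineages):\n")
  print(x$convergent)
  invisible(x)
}

#' @export
print.call_table <- function(x, ...) {
  cat("Call table:", attr(x, "n"), "clusters x",
      length(attr(x, "lineages")), "lineages\n")
  NextMethod()
}

#' Per-cluster convergence flags of a call table
#'
#' @param table a `call_table`.
#' @return data frame with the four convergence flags per cluster.
#' @export
convergence_flags <- function(table) {
  stopifnot(inherits(table, "call_table"))
  attr(table, "convergence")
}
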