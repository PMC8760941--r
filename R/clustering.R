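# Ortholog cluster identification.
#
# A cluster is a maximal clade whose leaves all belong to focal (non-reference)
# species; maximality forces at least one reference leaf elsewhere under the
# clade's parent, which is the reference-outgroup condition. Within each
# cluster, species-specific expansions (in-paralogs, including those exposed
# by multifurcations after support collapsing) are collapsed to a single
# representative per maximal single-species clade; any such merge marks the
# cluster as a gain for that species.

#' Identify orthologous clusters by the reference-outgroup rule
#'
#' Scans a rooted (and normally support-collapsed) gene tree for the maximal
#' clades containing only focal-species genes. Each such clade is one
#' orthologous cluster; its anchors are the reference-species leaves found in
#' the sister subtree(s) at the clade's parent. Every focal leaf belongs to
#' exactly one cluster and clusters are disjoint.
#'
#' @param tree a rooted `gene_tree`.
#' @param config a [species_config()].
#' @param collapse collapse species-specific expansions within each cluster
#'   (see [collapse_expansions()]); almost always wanted.
#' @param id_prefix prefix for generated cluster ids.
#' @return an object of class `ortholog_clusters`: a list of clusters, each
#'   with `cluster_id`, `raw_counts` and `counts` (named integer vectors over
#'   all focal species), `gains` (logical), `anchors` (reference gene ids),
#'   `anchor_depths` (edges from the cluster's parent node to each anchor),
#'   `genes` (data frame of member genes with representative flags) and
#'   `subfamily` (`NA` until [assign_subfamily()]).
#' @export
find_ortholog_clusters <- function(tree, config, collapse = TRUE,
                                   id_prefix = "OC") {
  stopifnot(inherits(tree, "gene_tree"), inherits(config, "species_config"))
  if (!ape::is.rooted(tree$phy)) stop("tree must be rooted")
  unknown <- setdiff(unique(tree$species), names(config$roles))
  if (length(unknown)) {
    stop("species in tree absent from config: ", paste(unknown, collapse = ", "))
  }
  root <- .phylo_to_node(tree$phy, tree$species)
  is_ref <- function(sp) config$roles[[sp]] == "reference"

  found <- list()
  # returns TRUE when the subtree contains a reference leaf; collects maximal
  # reference-free (= focal-only) children of reference-containing nodes
  walk <- function(node) {
    if (node$leaf) return(is_ref(node$species))
    has_ref <- vapply(node$children, walk, logical(1))
    if (any(has_ref)) {
      anchors <- .ref_leaf_depths(node, is_ref)
      for (i in which(!has_ref)) {
        found[[length(found) + 1L]] <<- list(subtree = node$children[[i]],
                                             anchors = anchors)
      }
      TRUE
    } else FALSE
  }
  root_has_ref <- walk(root)
  if (!root_has_ref) {
    stop("configuration error: tree contains no reference-species leaf")
  }
  if (!length(found)) {
    warning("tree contains no focal-species leaf; no clusters")
    return(structure(list(), class = "ortholog_clusters",
                     focal = config$focal))
  }

  clusters <- vector("list", length(found))
  width <- max(3L, nchar(length(found)))
  for (i in seq_along(found)) {
    cl <- .make_cluster(found[[i]]$subtree, found[[i]]$anchors,
                        sprintf("%s%0*d", id_prefix, width, i),
                        config, collapse)
    clusters[[i]] <- cl
  }
  structure(clusters, class = "ortholog_clusters", focal = config$focal)
}

# reference leaves under `node` with their edge depth below it
.ref_leaf_depths <- function(node, is_ref) {
  acc <- list()
  dig <- function(n, d) {
    if (n$leaf) {
      if (is_ref(n$species)) acc[[length(acc) + 1L]] <<- c(n$name, d)
    } else {
      for (ch in n$children) dig(ch, d + 1L)
    }
  }
  dig(node, 0L)
  depths <- vapply(acc, function(a) as.integer(a[2]), integer(1))
  names(depths) <- vapply(acc, `[`, character(1), 1)
  depths
}

.make_cluster <- function(subtree, anchor_depths, id, config, collapse) {
  leaves <- .node_leaves(subtree)
  genes <- data.frame(
    gene_id = vapply(leaves, `[[`, character(1), "name"),
    species_id = vapply(leaves, `[[`, character(1), "species"),
    stringsAsFactors = FALSE
  )
  focal <- config$focal
  raw <- table(factor(genes$species_id, levels = focal))
  raw_counts <- stats::setNames(as.integer(raw), focal)
  if (collapse) {
    ce <- collapse_expansions(subtree)
    counts <- stats::setNames(as.integer(table(factor(ce$species, levels = focal))),
                              focal)
    genes$representative <- genes$gene_id %in% ce$rep_genes
  } else {
    counts <- raw_counts
    genes$representative <- TRUE
  }
  structure(list(cluster_id = id,
                 raw_counts = raw_counts,
                 counts = counts,
                 gains = raw_counts > counts,
                 anchors = names(anchor_depths),
                 anchor_depths = anchor_depths,
                 genes = genes,
                 subfamily = NA_character_),
            class = "ortholog_cluster")
}

#' Collapse species-specific expansions within a cluster subtree
#'
#' Replaces every maximal single-species clade by a single representative
#' leaf (the lexicographically smallest gene id); at a multifurcating node,
#' sibling subtrees that each consist solely of the same species are likewise
#' merged into one representative. The procedure is applied post-order, so
#' nested in-paralogs collapse in one pass.
#'
#' @param subtree internal nested-node representation of one cluster's clade
#'   (as stored by [find_ortholog_clusters()]), or a `gene_tree` whose whole
#'   topology should be treated as one cluster.
#' @return list with `rep_genes` (representative gene ids kept), `species`
#'   (their species), `merged_species` (species for which any merge occurred)
#'   and `node` (the collapsed subtree).
#' @export
collapse_expansions <- function(subtree) {
  if (inherits(subtree, "gene_tree")) {
    subtree <- .phylo_to_node(subtree$phy, subtree$species)
  }
  merged <- character(0)
  collapse <- function(node) {
    if (node$leaf) return(node)
    node$children <- lapply(node$children, collapse)
    # after recursion every pure single-species child is a single leaf;
    # merge same-species leaf children
    is_leaf <- vapply(node$children, `[[`, logical(1), "leaf")
    if (any(is_leaf)) {
      sp <- vapply(node$children[is_leaf], `[[`, character(1), "species")
      for (s in unique(sp[duplicated(sp)])) {
        idx <- which(is_leaf)[sp == s]
        reps <- vapply(node$children[idx], `[[`, character(1), "name")
        keep <- idx[order(reps)[1]]
        drop <- setdiff(idx, keep)
        node$children <- node$children[-drop]
        is_leaf <- vapply(node$children, `[[`, logical(1), "leaf")
        merged <<- union(merged, s)
      }
    }
    if (length(node$children) == 1L && node$children[[1]]$leaf) {
      leaf <- node$children[[1]]
      leaf$length <- node$length
      return(leaf)
    }
    node
  }
  out <- collapse(subtree)
  leaves <- .node_leaves(out)
  list(rep_genes = vapply(leaves, `[[`, character(1), "name"),
       species = vapply(leaves, `[[`, character(1), "species"),
       merged_species = merged,
       node = out)
}

#' Assign an ancestral subfamily label to a cluster
#'
#' The label is the majority subfamily among the cluster's reference anchors
#' that appear in the anchor table. Ties are broken by the anchor with the
#' shortest path (fewest edges) to the cluster's parent node, then
#' lexicographically by label. Clusters whose anchors are all absent from the
#' table stay unassigned.
#'
#' @param cluster an `ortholog_cluster`.
#' @param anchor_table named character vector (reference gene id -> subfamily
#'   label) or a data frame with columns `gene_id`, `subfamily`.
#' @return the cluster with its `subfamily` field set (possibly `NA`).
#' @export
assign_subfamily <- function(cluster, anchor_table) {
  stopifnot(inherits(cluster, "ortholog_cluster"))
  if (is.data.frame(anchor_table)) {
    anchor_table <- stats::setNames(as.character(anchor_table$subfamily),
                                    as.character(anchor_table$gene_id))
  }
  known <- intersect(cluster$anchors, names(anchor_table))
  if (!length(known)) {
    cluster$subfamily <- NA_character_
    return(cluster)
  }
  labs <- anchor_table[known]
  votes <- table(labs)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    depths <- cluster$anchor_depths[known]
    cand <- vapply(top, function(lb) min(depths[labs == lb]), numeric(1))
    top <- top[cand == min(cand)]
    top <- sort(top)[1]
  }
  cluster$subfamily <- top
  cluster
}

#' Apply a curation override to a cluster set
#'
#' Reassigns listed genes to the named clusters (an auditable replacement for
#' manual cluster splitting/merging). Raw counts are recounted from the new
#' memberships; a gene keeps its representative (post-collapse) status when it
#' moves, and if a species ends up with member genes but no representative in
#' a cluster its lexicographically smallest gene is promoted. Emptied clusters
#' are removed; an override naming a new cluster id creates that cluster
#' (inheriting the anchors of the gene's source cluster).
#'
#' @param clusters an `ortholog_clusters` set.
#' @param override named character vector (gene id -> target cluster id) or a
#'   data frame with columns `gene_id`, `cluster_id`. An empty override is the
#'   identity.
#' @return the updated `ortholog_clusters`.
#' @export
apply_curation <- function(clusters, override) {
  stopifnot(inherits(clusters, "ortholog_clusters"))
  if (is.data.frame(override)) {
    override <- stats::setNames(as.character(override$cluster_id),
                                as.character(override$gene_id))
  }
  if (!length(override)) return(clusters)
  focal <- attr(clusters, "focal")
  all_genes <- unlist(lapply(clusters, function(cl) cl$genes$gene_id))
  unknown <- setdiff(names(override), all_genes)
  if (length(unknown)) {
    stop("curation override names unknown gene(s): ",
         paste(unknown, collapse = ", "))
  }
  by_id <- stats::setNames(clusters, vapply(clusters, `[[`, character(1),
                                            "cluster_id"))
  for (g in names(override)) {
    src_id <- NULL
    for (id in names(by_id)) {
      if (g %in% by_id[[id]]$genes$gene_id) { src_id <- id; break }
    }
    dst_id <- override[[g]]
    if (identical(src_id, dst_id)) next
    row <- by_id[[src_id]]$genes[by_id[[src_id]]$genes$gene_id == g, ]
    by_id[[src_id]]$genes <-
      by_id[[src_id]]$genes[by_id[[src_id]]$genes$gene_id != g, ]
    if (is.null(by_id[[dst_id]])) {
      src <- by_id[[src_id]]
      by_id[[dst_id]] <- structure(
        list(cluster_id = dst_id,
             raw_counts = stats::setNames(integer(length(focal)), focal),
             counts = stats::setNames(integer(length(focal)), focal),
             gains = stats::setNames(logical(length(focal)), focal),
             anchors = src$anchors, anchor_depths = src$anchor_depths,
             genes = row[0, ], subfamily = NA_character_),
        class = "ortholog_cluster")
    }
    by_id[[dst_id]]$genes <- rbind(by_id[[dst_id]]$genes, row)
  }
  # drop emptied clusters, recount, re-establish representative invariant
  by_id <- Filter(function(cl) nrow(cl$genes) > 0, by_id)
  out <- lapply(by_id, function(cl) {
    g <- cl$genes[order(cl$genes$gene_id), , drop = FALSE]
    for (s in unique(g$species_id)) {
      rows <- g$species_id == s
      if (!any(g$representative[rows])) {
        g$representative[which(rows)[1]] <- TRUE
      }
    }
    cl$genes <- g
    cl$raw_counts <- stats::setNames(
      as.integer(table(factor(g$species_id, levels = focal))), focal)
    cl$counts <- stats::setNames(
      as.integer(table(factor(g$species_id[g$representative],
                              levels = focal))), focal)
    cl$gains <- cl$raw_counts > cl$counts
    cl
  })
  structure(unname(out), class = "ortholog_clusters", focal = focal)
}

#' @export
print.ortholog_cluster <- function(x, ...) {
  cat("Ortholog cluster", x$cluster_id,
      if (!is.na(x$subfamily)) paste0("[subfamily ", x$subfamily, "]") else "",
      "\n  counts:",
      paste(sprintf("%s=%d", names(x$counts), x$counts), collapse = " "),
      "\n  anchors:", paste(x$anchors, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.ortholog_clusters <- function(x, ...) {
  cat("Ortholog cluster set:", length(x), "clusters over",
      length(attr(x, "focal")), "focal species\n")
  invisible(x)
}

#' Tabulate an ortholog cluster set
#'
#' @param x an `ortholog_clusters` set.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data frame with one row per cluster: id, subfamily, per-species
#'   raw and collapsed counts, and gain flags.
#' @export
as.data.frame.ortholog_clusters <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  focal <- attr(x, "focal")
  base <- data.frame(
    cluster_id = vapply(x, `[[`, character(1), "cluster_id"),
    subfamily = vapply(x, `[[`, character(1), "subfamily"),
    n_anchors = vapply(x, function(cl) length(cl$anchors), integer(1)),
    stringsAsFactors = FALSE
  )
  for (s in focal) {
    base[[paste0("raw_", s)]] <- vapply(x, function(cl) cl$raw_counts[[s]],
                                        integer(1))
    base[[paste0("n_", s)]] <- vapply(x, function(cl) cl$counts[[s]],
                                      integer(1))
    base[[paste0("gain_", s)]] <- vapply(x, function(cl) cl$gains[[s]],
                                         logical(1))
  }
  base
}

#' Read an ancestral-subfamily anchor table
#'
#' @param path TSV with header columns `gene_id`, `subfamily`.
#' @return named character vector (reference gene id -> subfamily label).
#' @export
read_anchor_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "subfamily") %in% names(d))) {
    stop("anchor table must have columns gene_id, subfamily")
  }
  stats::setNames(as.character(d$subfamily), as.character(d$gene_id))
}
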