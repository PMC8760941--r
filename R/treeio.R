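# Gene-tree input/output and preprocessing.
#
# A gene tree is stored as an ape "phylo" object whose node labels carry
# internal-node support values (normalized to [0,1]) plus a gene -> species
# annotation for every leaf. All downstream stages (rooting, support
# collapsing, ortholog clustering) operate on this container.

#' Construct a gene tree object
#'
#' Wraps an [ape::read.tree()] style `phylo` object together with a
#' gene-to-species annotation for its leaves. Users normally call
#' [parse_gene_tree()] instead.
#'
#' @param phy a rooted or unrooted `phylo` object; node labels, if present,
#'   must be support values on the 0-1 scale (or empty).
#' @param species named character vector mapping every tip label (gene id) to
#'   a species id.
#' @return an object of class `gene_tree`.
#' @export
gene_tree <- function(phy, species) {
  stopifnot(inherits(phy, "phylo"))
  tips <- phy$tip.label
  if (anyDuplicated(tips)) {
    stop("duplicate gene ids in tree: ",
         paste(unique(tips[duplicated(tips)]), collapse = ", "))
  }
  if (any(!nzchar(tips))) stop("empty gene id in tree")
  missing <- setdiff(tips, names(species))
  if (length(missing)) {
    stop("leaves without species mapping: ", paste(missing, collapse = ", "))
  }
  sup <- .parse_supports(phy)
  if (any(sup < 0 | sup > 1, na.rm = TRUE)) {
    stop("support values outside [0,1] after normalization")
  }
  structure(list(phy = phy, species = species[tips]), class = "gene_tree")
}

#' @export
print.gene_tree <- function(x, ...) {
  cat("Gene tree:", length(x$phy$tip.label), "leaves,",
      length(unique(x$species)), "species,",
      if (ape::is.rooted(x$phy)) "rooted" else "unrooted", "\n")
  sup <- supports(x)
  if (any(!is.na(sup))) {
    cat(sprintf("  internal supports: %d/%d present, range [%.2f, %.2f]\n",
                sum(!is.na(sup)), length(sup),
                min(sup, na.rm = TRUE), max(sup, na.rm = TRUE)))
  }
  invisible(x)
}

# numeric supports from node labels; non-numeric / empty labels -> NA
.parse_supports <- function(phy) {
  if (is.null(phy$node.label)) return(rep(NA_real_, phy$Nnode))
  suppressWarnings(as.numeric(phy$node.label))
}

#' Internal-node support values of a gene tree
#'
#' @param tree a `gene_tree`.
#' @return numeric vector of length `Nnode` on the 0-1 scale; `NA` where a
#'   node carries no support value.
#' @export
supports <- function(tree) {
  stopifnot(inherits(tree, "gene_tree"))
  .parse_supports(tree$phy)
}

# minimal structural validation so parse errors can name a character position
.check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("newick format error: unmatched ')' at character ", i)
      }
    }
  }
  if (depth != 0L) {
    stop("newick format error: ", depth,
         " unclosed '(' (string ends at character ", length(chars), ")")
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("newick format error: missing ';' terminator at character ",
         length(chars) + 1L)
  }
  invisible(TRUE)
}

#' Parse a newick gene tree and annotate its leaves with species
#'
#' Internal-node labels are interpreted as support values. Both common support
#' dialects are accepted: fractions in \[0,1\] (FastTree local supports) and
#' percentages in \[0,100\] (typical bootstrap labels). If any support value
#' exceeds 1 the whole tree is taken to be on the 0-100 scale and every value
#' is divided by 100, so a single collapsing threshold means the same thing
#' for all inputs.
#'
#' @param newick_text newick string (supports as internal node labels, branch
#'   lengths optional).
#' @param mapping optional named character vector (or two-column data frame
#'   `gene_id`, `species_id`) mapping leaf names to species. When omitted,
#'   leaf names are split at the first `delim` and the prefix is taken as the
#'   species id (`"SPECIES|gene"` convention).
#' @param delim single character used for the leaf-name convention.
#' @param quiet suppress the message emitted when the 0-100 dialect is
#'   detected and rescaled.
#' @return a `gene_tree`.
#' @examples
#' tr <- parse_gene_tree("((A|g1:0.1,B|g2:0.1)0.95:0.05,REF|r1:0.2);")
#' supports(tr)
#' @export
parse_gene_tree <- function(newick_text, mapping = NULL, delim = "|",
                            quiet = FALSE) {
  stopifnot(is.character(newick_text), length(newick_text) == 1L)
  .check_newick_syntax(newick_text)
  phy <- tryCatch(ape::read.tree(text = newick_text),
                  error = function(e) NULL)
  if (is.null(phy)) stop("newick format error: unparseable tree string")

  # support dialect detection and rescaling
  sup <- .parse_supports(phy)
  if (any(sup > 1, na.rm = TRUE)) {
    sup <- sup / 100
    if (!quiet) message("support values on 0-100 scale detected; rescaled to [0,1]")
  }
  phy$node.label <- ifelse(is.na(sup), "", .fmt_num(sup))

  if (!is.null(mapping)) {
    if (is.data.frame(mapping)) {
      mapping <- stats::setNames(as.character(mapping$species_id),
                                 as.character(mapping$gene_id))
    }
    unmapped <- setdiff(phy$tip.label, names(mapping))
    if (length(unmapped)) {
      stop("gene-to-species mapping error; unmapped leaves: ",
           paste(unmapped, collapse = ", "))
    }
    species <- mapping[phy$tip.label]
  } else {
    has_delim <- grepl(delim, phy$tip.label, fixed = TRUE)
    if (any(!has_delim)) {
      stop("gene-to-species mapping error; leaves without '", delim,
           "' delimiter and no mapping supplied: ",
           paste(phy$tip.label[!has_delim], collapse = ", "))
    }
    species <- vapply(strsplit(phy$tip.label, delim, fixed = TRUE),
                      `[[`, character(1), 1L)
    names(species) <- phy$tip.label
  }
  gene_tree(phy, species)
}

# compact numeric formatting for newick output (no scientific notation,
# trailing zeros stripped)
.fmt_num <- function(x) {
  s <- sprintf("%.10f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Serialize a gene tree to newick
#'
#' Supports are written as internal node labels so that a
#' parse -> write -> parse round trip preserves topology, leaf set and
#' support values.
#'
#' @param tree a `gene_tree`.
#' @param file optional path; when given the newick string is also written to
#'   the file.
#' @return the newick string, invisibly when `file` is given.
#' @export
write_gene_tree <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "gene_tree"))
  txt <- ape::write.tree(tree$phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Root a gene tree on a designated outgroup
#'
#' Places the root on the branch separating the outgroup genes (for example
#' the odorant receptor co-receptor clade) from all other leaves. Support
#' values are carried as edge (bipartition) annotations during re-rooting so
#' they stay attached to the correct splits.
#'
#' @param tree a `gene_tree`.
#' @param outgroup character vector of gene ids; must be non-empty, present in
#'   the tree, and monophyletic in the unrooted topology.
#' @return a rooted `gene_tree`.
#' @export
root_by_outgroup <- function(tree, outgroup) {
  stopifnot(inherits(tree, "gene_tree"))
  outgroup <- as.character(outgroup)
  if (!length(outgroup)) stop("outgroup gene set is empty")
  missing <- setdiff(outgroup, tree$phy$tip.label)
  if (length(missing)) {
    stop("outgroup lookup error; genes not in tree: ",
         paste(missing, collapse = ", "))
  }
  phy <- tree$phy
  if (length(outgroup) < length(phy$tip.label)) {
    un <- if (ape::is.rooted(phy)) ape::unroot(phy) else phy
    if (!ape::is.monophyletic(un, outgroup)) {
      # report the smallest set of non-outgroup leaves breaking monophyly:
      # the extra leaves inside the outgroup's smallest containing clade,
      # evaluated on the tree rooted at a non-outgroup leaf
      probe <- ape::root(un, setdiff(un$tip.label, outgroup)[1],
                         resolve.root = TRUE)
      mrca <- ape::getMRCA(probe, outgroup)
      inside <- ape::extract.clade(probe, mrca)$tip.label
      stop("outgroup is not monophyletic; conflicting leaves: ",
           paste(setdiff(inside, outgroup), collapse = ", "))
    }
    phy <- ape::root(un, outgroup, resolve.root = TRUE, edgelabel = TRUE)
  }
  gene_tree(phy, tree$species)
}

# ---- internal recursive tree representation -------------------------------
#
# Contraction and clustering are most naturally expressed on a nested-list
# tree; conversion back to phylo goes through a newick string (written by
# .node_to_newick, read by ape) so the resulting object is always a valid
# phylo.

.phylo_to_node <- function(phy, species = NULL) {
  ntip <- length(phy$tip.label)
  sup <- .parse_supports(phy)
  len <- phy$edge.length
  kids <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]
    kids[[p]] <- c(kids[[p]], list(c(phy$edge[i, 2], i)))
  }
  build <- function(id, edge_len) {
    if (id <= ntip) {
      nm <- phy$tip.label[id]
      list(leaf = TRUE, name = nm,
           species = if (is.null(species)) NA_character_ else unname(species[nm]),
           length = edge_len, support = NA_real_, children = list())
    } else {
      ch <- lapply(kids[[id]], function(ci) {
        build(ci[1], if (is.null(len)) NA_real_ else len[ci[2]])
      })
      list(leaf = FALSE, name = NULL, species = NA_character_,
           length = edge_len, support = sup[id - ntip], children = ch)
    }
  }
  build(ntip + 1L, NA_real_)
}

.node_to_newick <- function(node) {
  deparse1 <- function(n) {
    if (n$leaf) {
      out <- n$name
    } else {
      out <- paste0("(", paste(vapply(n$children, deparse1, character(1)),
                               collapse = ","), ")")
      if (!is.na(n$support)) out <- paste0(out, .fmt_num(n$support))
    }
    if (!is.na(n$length)) out <- paste0(out, ":", .fmt_num(n$length))
    out
  }
  paste0(deparse1(node), ";")
}

.node_leaves <- function(node) {
  if (node$leaf) return(list(node))
  do.call(c, lapply(node$children, .node_leaves))
}

#' Collapse weakly supported branches into multifurcations
#'
#' Contracts every internal edge whose child node carries a support value
#' strictly below `threshold`: the child's children are attached to its
#' parent, producing a multifurcation. Nested weak nodes are contracted in
#' the same pass (the result is a fixed point, so the operation is
#' idempotent). Edges without a support value are retained. The contracted
#' edge's branch length, when present, is added to the lengths of the
#' re-attached child edges so root-to-tip path lengths are preserved.
#'
#' @param tree a rooted `gene_tree`.
#' @param threshold support fraction in \[0,1\]; edges with support
#'   `< threshold` are contracted, edges at exactly the threshold are kept.
#' @return a `gene_tree` with the same leaf set.
#' @examples
#' tr <- parse_gene_tree("((A|a:1,B|b:1)0.5:1,(C|c:1,D|d:1)0.9:1);")
#' write_gene_tree(collapse_low_support(tr, 0.7))
#' @export
collapse_low_support <- function(tree, threshold = 0.7) {
  stopifnot(inherits(tree, "gene_tree"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold >= 0, threshold <= 1)
  contract <- function(node) {
    if (node$leaf) return(node)
    node$children <- lapply(node$children, contract)
    keep <- list()
    for (ch in node$children) {
      if (!ch$leaf && !is.na(ch$support) && ch$support < threshold) {
        for (g in ch$children) {
          if (!is.na(g$length) && !is.na(ch$length)) {
            g$length <- g$length + ch$length
          }
          keep <- c(keep, list(g))
        }
      } else {
        keep <- c(keep, list(ch))
      }
    }
    node$children <- keep
    node
  }
  root <- contract(.phylo_to_node(tree$phy))
  phy <- ape::read.tree(text = .node_to_newick(root))
  gene_tree(phy, tree$species)
}

# ---- tabular inputs -------------------------------------------------------

#' Read a gene-to-species mapping table
#'
#' @param path TSV with header columns `gene_id` and `species_id`.
#' @return named character vector (gene id -> species id).
#' @export
read_mapping <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "species_id")
  if (!all(need %in% names(d))) {
    stop("mapping table must have columns: ", paste(need, collapse = ", "))
  }
  stats::setNames(as.character(d$species_id), as.character(d$gene_id))
}

#' Define species roles and parasite-host lineage pairs
#'
#' @param roles named character vector, species id -> one of `"parasite"`,
#'   `"host"`, `"nonhost"`, `"reference"`.
#' @param lineages named list; each element is
#'   `c(parasite = <species>, host = <species>)` and the element name is the
#'   lineage id.
#' @return an object of class `species_config` with elements `roles`,
#'   `lineages`, `reference`, `focal` (all non-reference species).
#' @export
species_config <- function(roles, lineages) {
  roles <- unlist(roles)
  ok <- c("parasite", "host", "nonhost", "reference")
  if (any(!roles %in% ok)) {
    stop("unknown role(s): ", paste(setdiff(roles, ok), collapse = ", "))
  }
  if (anyDuplicated(names(roles))) {
    stop("species with more than one role: ",
         paste(unique(names(roles)[duplicated(names(roles))]), collapse = ", "))
  }
  if (!any(roles == "reference")) stop("at least one reference species required")
  lineages <- lapply(lineages, function(l) {
    l <- unlist(l)
    if (!all(c("parasite", "host") %in% names(l))) {
      stop("each lineage needs exactly one parasite and one host")
    }
    if (roles[l[["parasite"]]] != "parasite" || roles[l[["host"]]] != "host") {
      stop("lineage pairing inconsistent with species roles")
    }
    l[c("parasite", "host")]
  })
  structure(list(roles = roles, lineages = lineages,
                 reference = names(roles)[roles == "reference"],
                 focal = names(roles)[roles != "reference"]),
            class = "species_config")
}

#' @export
print.species_config <- function(x, ...) {
  cat("Species config:", length(x$roles), "species,",
      length(x$lineages), "lineage pair(s),",
      length(x$reference), "reference\n")
  for (ln in names(x$lineages)) {
    cat(sprintf("  %s: %s (parasite) ~ %s (host)\n", ln,
                x$lineages[[ln]][["parasite"]], x$lineages[[ln]][["host"]]))
  }
  invisible(x)
}

#' Read a species-role/pairing configuration
#'
#' Accepts either a TSV with columns `species_id`, `role`, `lineage_id`
#' (lineage id empty for nonhost and reference species) or a YAML file with
#' top-level fields `roles` (species -> role) and `lineages`
#' (lineage -> \{parasite, host\}).
#'
#' @param path file path; format chosen by extension (`.yml`/`.yaml` vs TSV).
#' @return a `species_config`.
#' @export
read_species_config <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    return(species_config(unlist(y$roles), y$lineages))
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = character())
  need <- c("species_id", "role", "lineage_id")
  if (!all(need %in% names(d))) {
    stop("species config must have columns: ", paste(need, collapse = ", "))
  }
  roles <- stats::setNames(d$role, d$species_id)
  paired <- d[nzchar(d$lineage_id) & d$role %in% c("parasite", "host"), ]
  lineages <- lapply(split(paired, paired$lineage_id), function(g) {
    stats::setNames(g$species_id, g$role)[c("parasite", "host")]
  })
  species_config(roles, lineages)
}
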