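# Synthetic gene-family generator.
#
# Each family starts as a single ancestral copy at the root of the species
# tree and evolves by a linear birth-death process: every extant copy
# duplicates at rate lambda_dup and is lost at rate mu_loss per unit branch
# length. Loss is accelerated on parasite terminal branches by a multiplier
# (and further for designated convergent-target families), and switched off
# on the reference terminal branch so every family keeps an anchor. The
# recorded genealogy becomes the family's gene tree; tip counts and
# "ortholog-unit" counts (maximal single-species clades, the quantity the
# collapsing step recovers) go into the truth table.

#' Default species tree for simulations
#'
#' A unit-depth ultrametric tree with three parasite-host pairs (terminal
#' branches of length 0.2), two nonhost species and one reference outgroup
#' splitting at the root, echoing the three-independent-origins study design.
#'
#' @return newick string with branch lengths.
#' @export
default_sim_species_tree <- function() {
  paste0("(((PAR1:0.2,HOS1:0.2):0.7,",
         "(((PAR2:0.2,HOS2:0.2):0.3,NON1:0.5):0.1,",
         "((PAR3:0.2,HOS3:0.2):0.3,NON2:0.5):0.1):0.3):0.1,REF:1.0);")
}

#' Default species roles matching [default_sim_species_tree()]
#'
#' @return a [species_config()] with three parasite-host lineage pairs, two
#'   nonhosts and one reference species.
#' @export
default_sim_roles <- function() {
  species_config(
    roles = c(PAR1 = "parasite", PAR2 = "parasite", PAR3 = "parasite",
              HOS1 = "host", HOS2 = "host", HOS3 = "host",
              NON1 = "nonhost", NON2 = "nonhost", REF = "reference"),
    lineages = list(L1 = c(parasite = "PAR1", host = "HOS1"),
                    L2 = c(parasite = "PAR2", host = "HOS2"),
                    L3 = c(parasite = "PAR3", host = "HOS3"))
  )
}

#' Simulation configuration
#'
#' Rates are per gene copy per unit branch length of the species tree. The
#' defaults emulate the study conditions the package is calibrated against:
#' three independent parasite-host pairs, baseline turnover giving host
#' marginal loss probabilities of a few percent, a terminal-branch loss
#' multiplier lifting parasite marginals to roughly a quarter, and a tenth of
#' families designated convergent targets whose parasite copies are lost
#' almost surely.
#'
#' @param n_families number of independent gene families.
#' @param lambda_dup duplication rate per copy per unit length.
#' @param mu_loss baseline loss rate per copy per unit length.
#' @param parasite_multiplier loss-rate multiplier on parasite terminal
#'   branches (>= 1).
#' @param convergent_fraction fraction of families designated convergent
#'   targets (the first `round(f * n_families)` family indices).
#' @param convergent_multiplier loss-rate multiplier on parasite terminal
#'   branches for target families (>= `parasite_multiplier`).
#' @param support_noise `NULL` for fixed supports of 1.0, or `c(a, b)` to
#'   draw internal supports from Beta(a, b).
#' @param seed integer master seed; family `i` is simulated from a stream
#'   derived deterministically from `(seed, i)`.
#' @param species_tree newick with branch lengths; defaults to
#'   [default_sim_species_tree()].
#' @param roles a [species_config()]; defaults to [default_sim_roles()].
#' @param n_subfamilies number of ancestral subfamily labels cycled over
#'   families for the anchor table.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_families = 300, lambda_dup = 0.1, mu_loss = 0.15,
                       parasite_multiplier = 10, convergent_fraction = 0.1,
                       convergent_multiplier = 100, support_noise = NULL,
                       seed = 1, species_tree = default_sim_species_tree(),
                       roles = default_sim_roles(), n_subfamilies = 10) {
  stopifnot(n_families >= 1, lambda_dup >= 0, mu_loss >= 0,
            parasite_multiplier >= 1,
            convergent_fraction >= 0, convergent_fraction <= 1,
            convergent_multiplier >= parasite_multiplier,
            inherits(roles, "species_config"))
  if (!is.null(support_noise)) {
    stopifnot(length(support_noise) == 2, all(support_noise > 0))
  }
  phy <- ape::read.tree(text = species_tree)
  if (is.null(phy$edge.length)) stop("species tree needs branch lengths")
  unknown <- setdiff(phy$tip.label, names(roles$roles))
  if (length(unknown)) {
    stop("species tree tips without roles: ", paste(unknown, collapse = ", "))
  }
  sp_node <- .phylo_to_node(phy, stats::setNames(phy$tip.label, phy$tip.label))
  structure(list(n_families = n_families, lambda_dup = lambda_dup,
                 mu_loss = mu_loss, parasite_multiplier = parasite_multiplier,
                 convergent_fraction = convergent_fraction,
                 convergent_multiplier = convergent_multiplier,
                 support_noise = support_noise, seed = seed,
                 species_tree = species_tree, sp_node = sp_node,
                 roles = roles, n_subfamilies = n_subfamilies),
            class = "sim_config")
}

# deterministic per-family seed stream (kept under 2^31)
.mix_seed <- function(seed, i) {
  as.integer(((seed %% 2147483647) * 48271 + i * 8191 + 1) %% 2147483647)
}

#' Simulate one gene family along the species tree
#'
#' @param config a [sim_config()].
#' @param family_index family number in `1:n_families`; together with the
#'   config seed it fully determines the outcome.
#' @param events record the event history (branch, time, type per
#'   duplication/loss); disable in large calibration loops.
#' @return list with `genealogy` (nested-node gene tree, `NULL` when every
#'   copy died), `counts` (raw tip copies per species), `collapsed_counts`
#'   (maximal single-species clades per species — what in-paralog collapsing
#'   recovers), `convergent_target` flag, `family_id` and `events` (data
#'   frame: branch, time, type; `NULL` when disabled).
#' @export
simulate_family <- function(config, family_index, events = TRUE) {
  stopifnot(inherits(config, "sim_config"),
            family_index >= 1, family_index <= config$n_families)
  set.seed(.mix_seed(config$seed, family_index))
  target <- family_index <= round(config$convergent_fraction * config$n_families)
  lam <- config$lambda_dup
  roles <- config$roles$roles
  pm <- if (target) config$convergent_multiplier else config$parasite_multiplier

  record <- isTRUE(events)
  evts <- list()
  note <- function(branch, time, type) {
    if (record) {
      evts[[length(evts) + 1L]] <<- list(branch = branch, time = time,
                                         type = type)
    }
  }
  mu_on <- function(sp) {
    if (!sp$leaf) return(config$mu_loss)
    switch(roles[[sp$name]],
           parasite = config$mu_loss * pm,
           reference = 0,
           config$mu_loss)
  }
  branch_id <- function(sp) if (sp$leaf) sp$name else "internal"

  gnode <- function(length, children = list(), species = NA_character_,
                    leaf = FALSE) {
    list(leaf = leaf, name = NULL, species = species, length = length,
         support = NA_real_, children = children)
  }
  # one copy part-way down the branch above sp, `rem` time units left
  cont <- function(sp, rem) {
    mu <- mu_on(sp)
    rate <- lam + mu
    repeat {
      dt <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (dt >= rem) break
      rem0 <- rem
      rem <- rem - dt
      if (stats::runif(1) < mu / rate) {
        note(branch_id(sp), sp$length - rem, "loss")
        return(NULL)
      }
      note(branch_id(sp), sp$length - rem, "duplication")
      a <- cont(sp, rem)
      b <- cont(sp, rem)
      consumed <- rem0 - rem
      if (is.null(a) && is.null(b)) return(NULL)
      if (is.null(a) || is.null(b)) {
        k <- if (is.null(a)) b else a
        k$length <- k$length + consumed
        return(k)
      }
      return(gnode(consumed, list(a, b)))
    }
    # copy survives to the end of the branch
    if (sp$leaf) return(gnode(rem, species = sp$name, leaf = TRUE))
    kids <- Filter(Negate(is.null),
                   lapply(sp$children, function(ch) cont(ch, ch$length)))
    if (!length(kids)) return(NULL)
    if (length(kids) == 1L) {
      k <- kids[[1]]
      k$length <- k$length + rem
      return(k)
    }
    gnode(rem, kids)
  }

  # the root copy speciates immediately into the root's child branches
  kids <- Filter(Negate(is.null),
                 lapply(config$sp_node$children, function(ch) cont(ch, ch$length)))
  genealogy <- if (!length(kids)) NULL
  else if (length(kids) == 1L) kids[[1]]
  else gnode(NA_real_, kids)

  fam_id <- sprintf("fam%04d", family_index)
  species_levels <- names(roles)
  if (is.null(genealogy)) {
    counts <- collapsed <- stats::setNames(integer(length(species_levels)),
                                           species_levels)
  } else {
    genealogy <- .name_copies(genealogy, fam_id)
    leaves <- .node_leaves(genealogy)
    sp <- vapply(leaves, `[[`, character(1), "species")
    counts <- stats::setNames(
      as.integer(table(factor(sp, levels = species_levels))), species_levels)
    collapsed <- .ortholog_units(genealogy, species_levels)
  }
  ev <- if (!record) NULL
  else if (length(evts)) {
    data.frame(branch = vapply(evts, `[[`, character(1), "branch"),
               time = vapply(evts, `[[`, numeric(1), "time"),
               type = vapply(evts, `[[`, character(1), "type"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(branch = character(), time = numeric(), type = character())
  }
  list(family_id = fam_id, genealogy = genealogy, counts = counts,
       collapsed_counts = collapsed, convergent_target = target, events = ev)
}

# leaf names SPECIES|famNN_copyMM, copies numbered per species in tree order
.name_copies <- function(node, fam_id) {
  idx <- new.env(parent = emptyenv())
  walk <- function(n) {
    if (n$leaf) {
      i <- (if (is.null(idx[[n$species]])) 0L else idx[[n$species]]) + 1L
      idx[[n$species]] <- i
      n$name <- sprintf("%s|%s_copy%02d", n$species, fam_id, i)
      return(n)
    }
    n$children <- lapply(n$children, walk)
    n
  }
  walk(node)
}

# number of maximal single-species clades per species: the truth-level
# counterpart of in-paralog collapsing, computed directly on the genealogy
# (independent of the clustering module)
.ortholog_units <- function(node, species_levels) {
  units <- stats::setNames(integer(length(species_levels)), species_levels)
  # returns the species if the subtree is pure, otherwise NA after crediting
  # one unit per maximal pure child clade
  pure <- function(n) {
    if (n$leaf) return(n$species)
    sp <- vapply(n$children, pure, character(1))
    u <- unique(sp)
    if (length(u) == 1L && !is.na(u)) return(u)
    for (s in sp[!is.na(sp)]) units[[s]] <<- units[[s]] + 1L
    NA_character_
  }
  top <- pure(node)
  if (!is.na(top)) units[[top]] <- units[[top]] + 1L
  units
}

#' Emit a simulated genealogy as a newick gene tree
#'
#' Internal nodes receive support values: fixed 1.0 when `support_noise` is
#' `NULL`, otherwise draws from Beta(a, b) rounded to four decimals. The same
#' seed yields a byte-identical string.
#'
#' @param genealogy a genealogy from [simulate_family()].
#' @param support_noise `NULL` or `c(a, b)` Beta parameters.
#' @param seed integer seed for the support draws.
#' @return newick text with leaves named `SPECIES|famNN_copyMM`.
#' @export
emit_gene_tree <- function(genealogy, support_noise = NULL, seed = 1) {
  if (is.null(genealogy)) stop("genealogy has no surviving copy")
  set.seed(seed)
  decorate <- function(n) {
    if (n$leaf) return(n)
    n$children <- lapply(n$children, decorate)
    n$support <- if (is.null(support_noise)) 1.0
    else round(stats::rbeta(1, support_noise[1], support_noise[2]), 4)
    n
  }
  .node_to_newick(decorate(genealogy))
}

#' Generate a complete synthetic input set
#'
#' Simulates all families and writes every file the pipeline consumes: gene
#' trees (newick, one family per line; families with no surviving focal copy
#' are skipped), gene-to-species mapping, species roles, a reference-anchor
#' subfamily table (subfamily labels cycled over families), and the truth
#' table.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if missing); `NULL` returns the
#'   in-memory objects without writing.
#' @return (invisibly when writing) list with `trees` (named newick vector),
#'   `mapping`, `truth` (data frame: family_id, species_id, count,
#'   collapsed_count, convergent_flag), `anchors`, `config` and, when `dir`
#'   is given, `paths`.
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  trees <- character(0)
  map_rows <- list()
  truth_rows <- list()
  anchor_rows <- list()
  focal <- config$roles$focal
  subfam_labels <- LETTERS[seq_len(config$n_subfamilies)]
  for (i in seq_len(config$n_families)) {
    fam <- simulate_family(config, i)
    truth_rows[[i]] <- data.frame(
      family_id = fam$family_id,
      species_id = names(fam$counts),
      count = unname(fam$counts),
      collapsed_count = unname(fam$collapsed_counts),
      convergent_flag = fam$convergent_target,
      stringsAsFactors = FALSE)
    if (is.null(fam$genealogy) || sum(fam$counts[focal]) == 0) next
    nwk <- emit_gene_tree(fam$genealogy, config$support_noise,
                          seed = .mix_seed(config$seed, config$n_families + i))
    trees[[fam$family_id]] <- nwk
    leaves <- .node_leaves(fam$genealogy)
    gene_ids <- vapply(leaves, `[[`, character(1), "name")
    gene_sp <- vapply(leaves, `[[`, character(1), "species")
    map_rows[[fam$family_id]] <- data.frame(gene_id = gene_ids,
                                            species_id = gene_sp,
                                            stringsAsFactors = FALSE)
    ref_ids <- gene_ids[gene_sp %in% config$roles$reference]
    lab <- subfam_labels[(i - 1L) %% length(subfam_labels) + 1L]
    anchor_rows[[fam$family_id]] <- data.frame(gene_id = ref_ids,
                                               subfamily = lab,
                                               stringsAsFactors = FALSE)
  }
  mapping <- do.call(rbind, unname(map_rows))
  truth <- do.call(rbind, unname(truth_rows))
  anchors <- do.call(rbind, unname(anchor_rows))
  out <- list(trees = trees, mapping = mapping, truth = truth,
              anchors = anchors, config = config)
  if (is.null(dir)) return(out)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(trees = file.path(dir, "gene_trees.nwk"),
                mapping = file.path(dir, "mapping.tsv"),
                roles = file.path(dir, "roles.tsv"),
                anchors = file.path(dir, "anchors.tsv"),
                truth = file.path(dir, "truth.tsv"))
  writeLines(unname(trees), paths$trees)
  utils::write.table(mapping, paths$mapping, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  roles_df <- .roles_as_table(config$roles)
  utils::write.table(roles_df, paths$roles, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(anchors, paths$anchors, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out$paths <- paths
  invisible(out)
}

.roles_as_table <- function(config) {
  lineage_of <- stats::setNames(rep("", length(config$roles)),
                                names(config$roles))
  for (ln in names(config$lineages)) {
    lineage_of[config$lineages[[ln]]] <- ln
  }
  data.frame(species_id = names(config$roles),
             role = unname(config$roles),
             lineage_id = unname(lineage_of[names(config$roles)]),
             stringsAsFactors = FALSE)
}

#' Build a call table directly from simulator truth counts
#'
#' Constructs one pseudo-cluster per family (with at least one surviving
#' focal copy) from the truth table's ortholog-unit counts and runs the
#' standard call logic on it. On clean data (supports fixed at 1.0) this is
#' exactly what the full emit-parse-cluster-collapse route produces — an
#' equality the test suite asserts — so calibration loops can use it without
#' re-running tree IO.
#'
#' @param truth truth data frame from [generate_dataset()] (or a list of
#'   [simulate_family()] results).
#' @param config the [species_config()] used for calling (e.g.
#'   `sim_config()$roles`).
#' @return a `call_table`.
#' @export
truth_call_table <- function(truth, config) {
  stopifnot(inherits(config, "species_config"))
  focal <- config$focal
  if (is.data.frame(truth)) {
    raw <- as.matrix(stats::xtabs(count ~ family_id + species_id,
                                  truth))[, focal, drop = FALSE]
    col <- as.matrix(stats::xtabs(collapsed_count ~ family_id + species_id,
                                  truth))[, focal, drop = FALSE]
  } else {
    nsp <- length(truth[[1]]$counts)
    raw <- t(vapply(truth, `[[`, numeric(nsp), "counts"))[, focal, drop = FALSE]
    col <- t(vapply(truth, `[[`, numeric(nsp),
                    "collapsed_counts"))[, focal, drop = FALSE]
    rownames(raw) <- rownames(col) <-
      vapply(truth, `[[`, character(1), "family_id")
  }
  keep <- which(rowSums(raw) > 0)
  if (!length(keep)) stop("no family retains a focal copy")
  clusters <- lapply(keep, function(i) {
    structure(list(cluster_id = rownames(raw)[i],
                   raw_counts = raw[i, ], counts = col[i, ],
                   gains = raw[i, ] > col[i, ],
                   anchors = character(0), anchor_depths = integer(0),
                   genes = NULL, subfamily = NA_character_),
              class = "ortholog_cluster")
  })
  build_call_table(structure(unname(clusters), class = "ortholog_clusters",
                             focal = focal),
                   config)
}
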