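# Shared fixtures and independent oracles used across test files.

# minimal two-lineage config: P1/P2 parasites, H1/H2 hosts, REF reference
toy_config <- function() {
  species_config(
    roles = c(P1 = "parasite", P2 = "parasite", H1 = "host", H2 = "host",
              N1 = "nonhost", REF = "reference"),
    lineages = list(L1 = c(parasite = "P1", host = "H1"),
                    L2 = c(parasite = "P2", host = "H2"))
  )
}

# build an ortholog_cluster directly from counts (unit-test scaffolding)
make_cluster <- function(id, raw, counts = raw, anchors = "REF|r1") {
  sp <- names(raw)
  structure(list(cluster_id = id,
                 raw_counts = stats::setNames(as.integer(raw), sp),
                 counts = stats::setNames(as.integer(counts), sp),
                 gains = raw > counts,
                 anchors = anchors,
                 anchor_depths = stats::setNames(rep(1L, length(anchors)),
                                                 anchors),
                 genes = NULL, subfamily = NA_character_),
            class = "ortholog_cluster")
}

clusters_of <- function(..., focal) {
  structure(list(...), class = "ortholog_clusters", focal = focal)
}

# random leaf-labelled binary tree over given tip names, all supports 1
random_gene_newick <- function(tips, lengths = TRUE) {
  phy <- ape::rtree(length(tips), tip.label = sample(tips))
  phy$node.label <- rep("1", phy$Nnode)
  if (!lengths) phy$edge.length <- NULL
  ape::write.tree(phy)
}

# rooted-topology equality: same multiset of clade leaf-sets
same_topology <- function(a, b) {
  clades <- function(phy) {
    ntip <- length(phy$tip.label)
    sort(vapply(ntip + seq_len(phy$Nnode), function(nd) {
      paste(sort(ape::extract.clade(phy, nd)$tip.label), collapse = ",")
    }, character(1)))
  }
  setequal(a$tip.label, b$tip.label) && identical(clades(a), clades(b))
}

# --- independent oracles ---------------------------------------------------

# canonical bipartition set of an unrooted topology: for every internal edge,
# the lexicographically smaller side of the split
bipartitions_brute <- function(phy) {
  un <- if (ape::is.rooted(phy)) ape::unroot(phy) else phy
  ntip <- length(un$tip.label)
  out <- character(0)
  for (i in seq_len(nrow(un$edge))) {
    child <- un$edge[i, 2]
    if (child <= ntip) next
    side <- sort(ape::extract.clade(un, child)$tip.label)
    other <- sort(setdiff(un$tip.label, side))
    if (length(side) < 2 || length(other) < 2) next
    key <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = ",") else paste(other, collapse = ",")
    out <- c(out, key)
  }
  sort(out)
}

# exhaustive maximal focal-only clade enumeration on a rooted phylo
maximal_focal_clades_brute <- function(phy, species, reference) {
  ntip <- length(phy$tip.label)
  nodes <- c(seq_len(ntip), ntip + seq_len(phy$Nnode))
  tipsets <- lapply(nodes, function(nd) {
    if (nd <= ntip) phy$tip.label[nd]
    else ape::extract.clade(phy, nd)$tip.label
  })
  focal_only <- vapply(tipsets, function(ts) {
    !any(species[ts] %in% reference)
  }, logical(1))
  keep <- which(focal_only)
  maximal <- vapply(keep, function(i) {
    !any(vapply(keep, function(j) {
      j != i && all(tipsets[[i]] %in% tipsets[[j]])
    }, logical(1)))
  }, logical(1))
  lapply(keep[maximal], function(i) sort(tipsets[[i]]))
}

# two-sided binomial p by enumeration of all 2^n success/failure sequences
binom_brute_p <- function(x, n, p0) {
  counts <- rowSums(expand.grid(rep(list(0:1), n)))
  seq_prob <- p0^counts * (1 - p0)^(n - counts)
  outcome_prob <- vapply(0:n, function(j) sum(seq_prob[counts == j]),
                         numeric(1))
  min(1, sum(outcome_prob[outcome_prob <= outcome_prob[x + 1] * (1 + 1e-7)]))
}

# Benjamini-Hochberg step-up computed from the definition
bh_brute <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- prev
  }
  adj
}

# exact two-sided rank-sum p by enumeration of all group labelings
wilcox_exact_brute <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  r <- rank(pool)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# simulate a batch of families and return the truth-level call table
sim_truth_table <- function(cfg) {
  fams <- lapply(seq_len(cfg$n_families),
                 function(i) simulate_family(cfg, i, events = FALSE))
  truth_call_table(fams, cfg$roles)
}
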