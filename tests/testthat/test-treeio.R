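# Tree parsing, rooting and support collapsing.

test_that("newick parsing annotates leaves and normalizes both support dialects", {
  tr <- parse_gene_tree("((A|g1:0.1,B|g2:0.1)0.95:0.05,REF|r1:0.2);")
  expect_equal(length(tr$phy$tip.label), 3L)
  expect_equal(unname(tr$species), c("A", "B", "REF"))
  expect_equal(supports(tr)[!is.na(supports(tr))], 0.95)

  expect_message(
    tr100 <- parse_gene_tree("((A|g1,B|g2)95,REF|r1);"),
    "0-100 scale"
  )
  expect_equal(supports(tr100)[!is.na(supports(tr100))], 0.95)
  # once normalized, no support exceeds 1
  expect_lte(max(supports(tr100), na.rm = TRUE), 1)
})

test_that("parse errors name the offending position or leaf", {
  expect_error(parse_gene_tree("((A|a,B|b);"), "character")
  expect_error(parse_gene_tree("(A|a,B|b))extra;"), "character 10")
  expect_error(parse_gene_tree("(A|a,B|b)"), ";")
  expect_error(parse_gene_tree("((Aa:0.1,B|b:0.1):0.1,C|c:0.1);"),
               "Aa")
  expect_error(
    parse_gene_tree("((A|a,B|b),C|c);",
                    mapping = c("A|a" = "A", "B|b" = "B")),
    "C\\|c"
  )
})

test_that("parse -> write -> parse round trip preserves topology, leaves, supports", {
  set.seed(11)
  for (rep in 1:5) {
    tips <- paste0("SP", 1:8, "|g", 1:8)
    txt <- random_gene_newick(tips)
    t1 <- parse_gene_tree(txt)
    t2 <- parse_gene_tree(write_gene_tree(t1))
    expect_setequal(t1$phy$tip.label, t2$phy$tip.label)
    expect_true(same_topology(t1$phy, t2$phy))
    expect_equal(supports(t1), supports(t2))
  }
})

test_that("outgroup rooting splits outgroup clade from the rest and is idempotent", {
  tr <- parse_gene_tree("((og|1:1,og|2:1)1:1,((x|1:1,y|1:1)1:1,z|1:1)1:1);")
  rooted <- root_by_outgroup(tr, c("og|1", "og|2"))
  phy <- rooted$phy
  expect_true(ape::is.rooted(phy))
  root_children <- phy$edge[phy$edge[, 1] == length(phy$tip.label) + 1L, 2]
  sides <- lapply(root_children, function(nd) {
    if (nd <= length(phy$tip.label)) phy$tip.label[nd]
    else ape::extract.clade(phy, nd)$tip.label
  })
  expect_true(any(vapply(sides, function(s) setequal(s, c("og|1", "og|2")),
                         logical(1))))
  # rooting the already correctly rooted tree changes nothing topological
  again <- root_by_outgroup(rooted, c("og|1", "og|2"))
  expect_true(same_topology(rooted$phy, again$phy))
})

test_that("rooting preserves the unrooted bipartition set (random 12-leaf trees)", {
  set.seed(42)
  for (rep in 1:10) {
    tips <- paste0("S", 1:12, "|g")
    tr <- parse_gene_tree(random_gene_newick(tips))
    og <- sample(tr$phy$tip.label, 1)
    rooted <- root_by_outgroup(tr, og)
    expect_identical(bipartitions_brute(rooted$phy),
                     bipartitions_brute(tr$phy))
    expect_setequal(rooted$phy$tip.label, tr$phy$tip.label)
  }
})

test_that("non-monophyletic outgroup errors report the conflicting leaves", {
  tr <- parse_gene_tree("((a|1:1,b|1:1)1:1,(a|2:1,c|1:1)1:1);")
  expect_error(root_by_outgroup(tr, c("a|1", "a|2")), "monophyletic")
  expect_error(root_by_outgroup(tr, character(0)), "empty")
  expect_error(root_by_outgroup(tr, "missing|x"), "not in tree")
})

test_that("support collapsing contracts weak edges, keeps threshold and unlabeled edges", {
  tr <- parse_gene_tree("((a|1:1,b|1:1)0.5:1,(c|1:1,d|1:1)0.9:1);")
  out <- collapse_low_support(tr, 0.7)
  expect_equal(out$phy$Nnode, 2L)  # root + the 0.9 node
  expect_setequal(out$phy$tip.label, tr$phy$tip.label)

  # exactly at the threshold: retained (strict <)
  at <- collapse_low_support(
    parse_gene_tree("((a|1:1,b|1:1)0.7:1,(c|1:1,d|1:1)0.9:1);"), 0.7)
  expect_equal(at$phy$Nnode, 3L)

  # all supports 1: unchanged
  full <- parse_gene_tree("((a|1:1,b|1:1)1:1,(c|1:1,d|1:1)1:1);")
  expect_true(same_topology(collapse_low_support(full, 0.7)$phy, full$phy))

  # absent supports are retained
  nolab <- parse_gene_tree("((a|1:1,b|1:1):1,(c|1:1,d|1:1)0.9:1);")
  expect_equal(collapse_low_support(nolab, 0.7)$phy$Nnode, 3L)

  # collapsing everything yields a star tree
  star <- collapse_low_support(
    parse_gene_tree("((a|1:1,b|1:1)0.1:1,(c|1:1,d|1:1)0.2:1);"), 0.7)
  expect_equal(star$phy$Nnode, 1L)
})

test_that("nested weak nodes contract in one pass, independent of traversal order", {
  # pre-order (top-down, repeated to fixed point) contraction as the oracle
  contract_preorder <- function(tr, thr) {
    repeat {
      node <- convloss:::.phylo_to_node(tr$phy)
      changed <- FALSE
      top <- function(n) {
        if (n$leaf) return(n)
        keep <- list()
        for (ch in n$children) {
          if (!changed && !ch$leaf && !is.na(ch$support) && ch$support < thr) {
            changed <<- TRUE
            keep <- c(keep, ch$children)
          } else keep <- c(keep, list(ch))
        }
        n$children <- lapply(keep, top)
        n
      }
      out <- top(node)
      tr <- gene_tree(ape::read.tree(text = convloss:::.node_to_newick(out)),
                      tr$species)
      if (!changed) return(tr)
    }
  }
  set.seed(7)
  sup_grid <- c(0.5, 0.6, 0.65, 0.7, 0.8, 1)
  for (rep in 1:20) {
    phy <- ape::rtree(6, tip.label = paste0("S", 1:6, "|g"))
    phy$node.label <- as.character(sample(sup_grid, phy$Nnode, replace = TRUE))
    tr <- parse_gene_tree(ape::write.tree(phy))
    a <- collapse_low_support(tr, 0.7)
    b <- contract_preorder(tr, 0.7)
    expect_true(same_topology(a$phy, b$phy))
    expect_setequal(a$phy$tip.label, tr$phy$tip.label)
    # idempotence
    again <- collapse_low_support(a, 0.7)
    expect_true(same_topology(a$phy, again$phy))
  }
})

test_that("species config validates roles, pairing and reference presence", {
  expect_error(species_config(c(A = "parasite", R = "reference"),
                              list(L1 = c(parasite = "A"))),
               "exactly one parasite and one host")
  expect_error(species_config(c(A = "parasite", B = "host"),
                              list(L1 = c(parasite = "A", host = "B"))),
               "reference")
  expect_error(species_config(c(A = "parasite", B = "host", A = "host",
                                R = "reference"),
                              list(L1 = c(parasite = "A", host = "B"))),
               "more than one role")
  cfg <- toy_config()
  expect_s3_class(cfg, "species_config")
  expect_equal(cfg$reference, "REF")
  expect_setequal(cfg$focal, c("P1", "P2", "H1", "H2", "N1"))
})

test_that("tabular readers round-trip mapping and config files", {
  d <- tempfile(fileext = ".tsv")
  write.table(data.frame(gene_id = c("g1", "g2"), species_id = c("A", "B")),
              d, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_mapping(d)
  expect_equal(m[["g1"]], "A")

  r <- tempfile(fileext = ".tsv")
  write.table(data.frame(species_id = c("P1", "H1", "REF"),
                         role = c("parasite", "host", "reference"),
                         lineage_id = c("L1", "L1", "")),
              r, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- read_species_config(r)
  expect_equal(cfg$lineages$L1[["parasite"]], "P1")

  y <- tempfile(fileext = ".yaml")
  writeLines(c("roles:", "  P1: parasite", "  H1: host", "  REF: reference",
               "lineages:", "  L1:", "    parasite: P1", "    host: H1"), y)
  cfg2 <- read_species_config(y)
  expect_equal(cfg2$lineages$L1[["host"]], "H1")
})
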