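test_that("NJ recovers additive four-taxon distances exactly", {
  tr <- ape::read.tree(text = "((A:0.1,B:0.3):0.05,(C:0.2,D:0.4):0.05);")
  d <- ape::cophenetic.phylo(tr)
  rec <- nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(tr), rec), structure(0, Nnames = "PH85"),
               ignore_attr = TRUE)
  drec <- ape::cophenetic.phylo(rec)
  expect_equal(drec[rownames(d), colnames(d)], d, tolerance = 1e-9)
})

test_that("NJ edge cases: tiny matrices and validation", {
  m <- matrix(c(0, 0.2, 0.2, 0), 2, dimnames = list(c("A", "B"),
                                                    c("A", "B")))
  tr <- nj_tree(m)
  expect_setequal(tr$tip.label, c("A", "B"))
  expect_error(nj_tree(matrix(1)), "two taxa")
  bad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("A", "B"),
                                                  c("A", "B")))
  expect_error(nj_tree(bad), "symmetric")
})

test_that("outgroup rooting isolates the outgroup, with midpoint fallback", {
  tr <- ape::read.tree(text = "(a.F1.1:1,(b.F1.1:1,o.F1.1:3):1);")
  r <- root_tree(ape::unroot(tr), "o")
  expect_equal(attr(r, "rooting"), "outgroup")
  # root separates the outgroup leaf from the ingroup
  lab <- label_overlap(r)
  sets <- attr(lab, "species_sets")
  root_children <- r$edge[r$edge[, 1] == length(r$tip.label) + 1L, 2]
  child_sets <- lapply(root_children, function(n) sets[[n]])
  expect_true(any(vapply(child_sets, function(s) identical(s, "o"),
                         logical(1))))
  r2 <- root_tree(ape::unroot(tr), "zz")
  expect_equal(attr(r2, "rooting"), "midpoint")
})

test_that("same-species cherries collapse per criterion, to a fixpoint", {
  # collapse when both branches are short
  tr <- ape::read.tree(text = "((x.F1.1:0.005,x.F1.2:0.003):0.1,y.F1.1:0.1);")
  out <- collapse_pairs(tr, "branch", 0.01)
  expect_setequal(out$tip.label, c("x.F1.1", "y.F1.1"))
  # both branches must qualify
  tr2 <- ape::read.tree(text = "((x.F1.1:0.005,x.F1.2:0.02):0.1,y.F1.1:0.1);")
  expect_equal(length(collapse_pairs(tr2, "branch", 0.01)$tip.label), 3)
  # different species never collapse
  tr3 <- ape::read.tree(text = "((x.F1.1:0.001,y.F1.1:0.001):0.1,y.F1.2:0.1);")
  expect_equal(length(collapse_pairs(tr3, "branch", 0.01)$tip.label), 3)
  # chain of three same-species leaves collapses via the fixpoint
  tr4 <- ape::read.tree(
    text = "(((x.F1.1:0.001,x.F1.2:0.001):0.001,x.F1.3:0.002):0.1,y.F1.1:0.1);")
  out4 <- collapse_pairs(tr4, "branch", 0.01)
  expect_equal(sum(gene_species(out4$tip.label) == "x"), 1)
  # Ks mode with a lookup
  ksl <- c(0.05)
  names(ksl) <- pair_key("x.F1.1", "x.F1.2")
  out5 <- collapse_pairs(tr, "ks", 0.2, ks_lookup = ksl)
  expect_equal(length(out5$tip.label), 2)
  expect_error(collapse_pairs(tr, "ks", 0.2), "lookup")
})

test_that("collapse leaves non-target subtrees untouched", {
  tr <- ape::read.tree(text = paste0(
    "(((x.F1.1:0.001,x.F1.2:0.001):0.1,(a.F1.1:0.2,b.F1.1:0.3):0.1):0.1,",
    "(c.F1.1:0.1,d.F1.1:0.2):0.3);"))
  out <- collapse_pairs(tr, "branch", 0.01)
  sub_before <- ape::extract.clade(tr, ape::getMRCA(tr, c("a.F1.1", "b.F1.1")))
  sub_after <- ape::extract.clade(out, ape::getMRCA(out, c("a.F1.1", "b.F1.1")))
  expect_equal(ape::write.tree(sub_before), ape::write.tree(sub_after))
})

test_that("species-overlap labels match the worked patterns", {
  t1 <- label_overlap(ape::read.tree(
    text = "((C.F1.1:1,B.F1.1:1):1,B.F1.2:1);"))
  expect_equal(t1$node.label[1], "D")   # root: {C,B} vs {B} overlap
  t2 <- label_overlap(ape::read.tree(
    text = "((B.F1.1:1,B.F1.2:1):1,C.F1.1:1);"))
  expect_equal(t2$node.label[1], "S")   # root: {B} vs {C} disjoint
  expect_equal(t2$node.label[2], "D")   # inner: {B} vs {B}
  # multifurcation: any pair of children overlapping makes a D
  t3 <- label_overlap(ape::read.tree(
    text = "(A.F1.1:1,B.F1.1:1,B.F1.2:1);"))
  expect_equal(t3$node.label[1], "D")
  t4 <- label_overlap(ape::read.tree(
    text = "(A.F1.1:1,B.F1.1:1,C.F1.1:1);"))
  expect_equal(t4$node.label[1], "S")
})

test_that("labels equal the set-intersection oracle for all shapes <= 6
           leaves over 3 species", {
  species <- c("C", "B", "P")
  for (n in 2:6) {
    shapes <- tree_shapes(n)
    assigns <- expand.grid(rep(list(species), n), stringsAsFactors = FALSE)
    for (sh in shapes) {
      for (row in seq_len(nrow(assigns))) {
        tr_nested <- assign_species(sh, unlist(assigns[row, ]))
        nwk <- nested_to_newick(tr_nested)
        oracle <- oracle_overlap_labels(tr_nested)
        tree <- label_overlap(ape::read.tree(text = nwk))
        ntip <- length(tree$tip.label)
        for (nd in seq_len(tree$Nnode)) {
          tips <- ape::extract.clade(tree, ntip + nd)$tip.label
          key <- paste(sort(tips), collapse = "|")
          expect_equal(tree$node.label[nd], oracle[[key]])
        }
      }
    }
  }
})

test_that("clade mining types, patterns, and totals are consistent", {
  trees <- list(
    f1 = ape::read.tree(text = "((C.F1.1:1,B.F1.1:1):1,(B.F1.2:1,P.F1.1:1):1);"),
    f2 = ape::read.tree(text = "(((B.F2.1:1,B.F2.2:1):1,C.F2.1:1):1,P.F2.1:1);"),
    f3 = ape::read.tree(text = "((C.F3.1:1,C.F3.2:1):1,(B.F3.1:1,P.F3.1:1):1);"))
  rec <- mine_clades(trees, "C", "B", collapse = FALSE)
  # f1: maximal pure clade is (C,B) -> type c=1,b=1
  expect_true(any(rec$family == "f1" & rec$type == "c=1,b=1"))
  # f2: ((B,B),C) -> c=1,b>=2 with speciation MRCA -> [(B,B),C]
  r2 <- rec[rec$family == "f2", ]
  expect_equal(r2$type, "c=1,b>=2")
  expect_equal(r2$mrca_label, "S")
  expect_equal(r2$pattern, "[(B,B),C]")
  # nested pattern totals: pattern defined exactly for type c=1,b>=2
  expect_equal(sum(!is.na(rec$pattern)), sum(rec$type == "c=1,b>=2"))
  # the [(C,B),B] side
  t5 <- list(f5 = ape::read.tree(
    text = "(((C.F5.1:1,B.F5.1:1):1,B.F5.2:1):1,P.F5.1:1);"))
  r5 <- mine_clades(t5, "C", "B", collapse = FALSE)
  expect_equal(r5$pattern, "[(C,B),B]")
  expect_equal(r5$mrca_label, "D")
  s <- summarize_clades(rbind(rec, r5))
  expect_equal(s$ratio_patterns, 1 / 1)
})

test_that("count tables reproduce the published worked ratios", {
  # size-class counts -> ratio percent (rounded)
  expect_equal(dup_ratio(10567, 1708 + 437 + 440), 24)
  expect_equal(dup_ratio(1933, 6531 + 1697 + 3995), 632)
  expect_equal(dup_ratio(10988, 1564 + 342 + 257), 20)
  expect_true(is.na(dup_ratio(0, 5)))
  # via count_table on membership
  mem <- data.frame(
    family = c("f1", "f1", "f2", "f2", "f2", "f3"),
    gene = paste0("g", 1:6),
    species = c("a", "a", "a", "b", "b", "b"))
  ct <- count_table(mem)
  expect_equal(ct$ratio_pct[ct$species == "a"], 100)  # 1 multi / 1 single
  expect_equal(ct$n0[ct$species == "b"], 1)
  # all families single-copy -> ratio 0
  mem2 <- data.frame(family = c("f1", "f2"), gene = c("g1", "g2"),
                     species = "a")
  expect_equal(count_table(mem2)$ratio_pct, 0)
})

test_that("the sister ratio statistic rises with retention, the relic's
           stays flat", {
  ratios <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(r) {
    h <- scenario_allopolyploid()
    cfg <- sim_config(n_families = 200, retention = r, local_dup_rate = 0,
                      seed = 91)
    fams <- simulate_families(h, cfg)
    mem <- do.call(rbind, lapply(fams, function(f)
      if (!f$empty) data.frame(family = f$id, gene = f$leaves$gene,
                               species = f$leaves$species) else NULL))
    ct <- count_table(mem)
    # raw ratio (Inf when no single-copy families remain, as at full
    # retention where both homoeologs always survive)
    raw <- function(sp) {
      r <- ct[ct$species == sp, ]
      (r$n2 + r$n3 + r$n4plus) / r$n1
    }
    c(sister = raw("tetra"), relic = raw("relic"))
  }, numeric(2))
  expect_gte(cor(1:5, ratios["sister", ], method = "spearman"), 0.9)
  expect_true(all(100 * ratios["relic", ] < 10))
})
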