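test_that("histories validate events and replay karyotypes correctly", {
  h <- scenario_no_wgd()
  expect_true(all(h$events$kind == "speciation"))
  expect_true(all(karyotypes(h) == 7))

  h2 <- scenario_allopolyploid()
  ev <- h2$events[h2$events$kind == "allopolyploidy", ]
  expect_equal(nrow(ev), 1)
  expect_setequal(c(ev$parent1, ev$parent2), c("relic", "donor"))
  # karyotype of the allotetraploid is the sum of its parents (7 + 7)
  expect_equal(unname(karyotypes(h2)["tetra"]), 14L)
  # event-replay oracle agrees for every scenario
  for (h_ in list(scenario_no_wgd(), scenario_allopolyploid(),
                  scenario_autopolyploid())) {
    orc <- oracle_karyotypes(h_$events, h_$base_n, h_$root)
    expect_equal(karyotypes(h_)[sort(names(orc))],
                 orc[sort(names(orc))])
  }
})

test_that("invalid histories are refused", {
  # hybridization older than the donor divergence
  ev <- data.frame(
    time = c(0.2, 0.1),
    kind = c("allopolyploidy", "speciation"),
    lineage = c("tet", "root"),
    child1 = c(NA, "a"), child2 = c(NA, "b"),
    parent1 = c("a", NA), parent2 = c("b", NA),
    stringsAsFactors = FALSE)
  expect_error(build_history(ev, rates = c(root = 1, a = 1, b = 1, tet = 1)),
               "not alive")
  # non-positive rates
  expect_error(scenario_no_wgd(rate_relic = 0), "positive")
  # non-decreasing times
  ev2 <- data.frame(time = c(0.1, 0.1), kind = "speciation",
                    lineage = c("root", "a"),
                    child1 = c("a", "c"), child2 = c("b", "d"),
                    stringsAsFactors = FALSE)
  expect_error(build_history(ev2, rates = c(b = 1, c = 1, d = 1)),
               "strictly decrease")
})

test_that("autopolyploidy doubles the lineage karyotype exactly once", {
  ev <- data.frame(time = c(0.3, 0.15), kind = c("speciation",
                                                 "autopolyploidy"),
                   lineage = c("root", "a"),
                   child1 = c("a", NA), child2 = c("b", NA),
                   stringsAsFactors = FALSE)
  h <- build_history(ev, rates = c(root = 1, a = 1, b = 1))
  expect_equal(unname(karyotypes(h)), c(14L, 7L))
  expect_equal(karyotypes(h), oracle_karyotypes(ev, 7L, "root"))
})

test_that("full retention yields deterministic [(C,B),B] topologies", {
  h <- scenario_allopolyploid()
  cfg <- sim_config(n_families = 30, retention = 1, local_dup_rate = 0,
                    seed = 3)
  fams <- simulate_families(h, cfg)
  for (f in fams) {
    cb <- ape::keep.tip(f$tree,
                        f$leaves$gene[f$leaves$species %in%
                                        c("relic", "tetra")])
    lab <- label_overlap(cb)
    # [(C,B),B]: species-overlap calls the clade MRCA a duplication and
    # the relic+homoeolog cherry a speciation
    expect_equal(lab$node.label[1], "D")
    expect_true("S" %in% lab$node.label[-1])
  }
  # and with identical seeds the replay is fully deterministic
  fams2 <- simulate_families(h, cfg)
  expect_equal(vapply(fams, function(f) ape::write.tree(f$tree),
                      character(1)),
               vapply(fams2, function(f) ape::write.tree(f$tree),
                      character(1)))
})

test_that("autopolyploidy after speciation yields [(B,B),C] topologies", {
  h <- scenario_autopolyploid()
  cfg <- sim_config("autopolyploid", n_families = 30, retention = 1,
                    local_dup_rate = 0, seed = 3)
  fams <- simulate_families(h, cfg)
  for (f in fams) {
    cb <- ape::keep.tip(f$tree,
                        f$leaves$gene[f$leaves$species %in%
                                        c("relic", "tetra")])
    lab <- label_overlap(cb)
    # root is a speciation (relic vs the two homoeologs), the inner node
    # a duplication
    expect_equal(lab$node.label[1], "S")
    expect_true("D" %in% lab$node.label[-1])
  }
})

test_that("zero retention of duplicates leaves one copy per speciation", {
  h <- scenario_allopolyploid()
  h$events$retention1 <- NA_real_
  h$events$retention2 <- NA_real_
  h$events$retention2[h$events$kind == "allopolyploidy"] <- 0
  cfg <- sim_config(n_families = 20, retention = 1, local_dup_rate = 0,
                    seed = 5, history = h)
  fams <- simulate_families(h, cfg)
  for (f in fams) {
    # donor subgenome fully fractionated: exactly one tetraploid leaf,
    # and it is sister to the relic gene (no [(C,B),B] clades survive)
    expect_equal(sum(f$leaves$species == "tetra"), 1L)
  }
})

test_that("copy counts are conserved against the truth log", {
  h <- scenario_allopolyploid()
  cfg <- sim_config(n_families = 50, seed = 13)
  fams <- simulate_families(h, cfg)
  for (f in fams) {
    if (f$empty) next
    # every leaf maps to exactly one extant species and tree leaves match
    # the leaf table exactly
    expect_true(all(f$leaves$species %in% h$extant))
    if (!is.null(f$tree)) {
      expect_setequal(f$tree$tip.label, f$leaves$gene)
      expect_true(all(f$tree$edge.length >= -1e-12))
      # node annotations cover every internal node
      expect_true(all(f$tree$node.label %in%
                        c("speciation", "wgd_duplication",
                          "local_duplication")))
    }
  }
})

test_that("rate scaling doubles expected terminal branch lengths", {
  mk <- function(rate, seed) {
    ev <- data.frame(time = 0.2, kind = "speciation", lineage = "root",
                     child1 = "a", child2 = "b", stringsAsFactors = FALSE)
    h <- build_history(ev, rates = c(root = 1, a = rate, b = 1))
    cfg <- sim_config(n_families = 150, local_dup_rate = 0, seed = seed,
                      history = h)
    fams <- simulate_families(h, cfg)
    mean(vapply(fams, function(f)
      f$leaves$total_len[f$leaves$species == "a"], numeric(1)))
  }
  b1 <- mk(1, 17)
  b2 <- mk(2, 18)
  expect_equal(b2 / b1, 2, tolerance = 0.1)
})

test_that("sequences at zero divergence are identical; Ks spread is right", {
  # (near-)zero branch lengths: identical sequences, Ks exactly 0
  ev <- data.frame(time = 1e-9, kind = "speciation", lineage = "root",
                   child1 = "a", child2 = "b", stringsAsFactors = FALSE)
  h <- build_history(ev, rates = c(root = 1, a = 1e-9, b = 1e-9))
  cfg <- sim_config(n_families = 5, local_dup_rate = 0, seed = 2,
                    history = h)
  em <- emit_sequences(simulate_families(h, cfg), cfg)
  for (f in em$families) {
    s <- em$sequences[f$leaves$gene]
    expect_equal(s[[1]], s[[2]])
    expect_equal(ng86(s[[1]], s[[2]])$Ks, 0)
  }

  # two leaves at total path 0.2, 300 codons: mean NG86 estimate within
  # 3 standard errors of 0.2 over 50 replicates
  ev2 <- data.frame(time = 0.1, kind = "speciation", lineage = "root",
                    child1 = "a", child2 = "b", stringsAsFactors = FALSE)
  h2 <- build_history(ev2, rates = c(root = 1, a = 1, b = 1))
  cfg2 <- sim_config(n_families = 50, local_dup_rate = 0, seed = 23,
                     history = h2)
  em2 <- emit_sequences(simulate_families(h2, cfg2), cfg2)
  ks <- vapply(em2$families, function(f) {
    s <- em2$sequences[f$leaves$gene]
    ng86(s[[1]], s[[2]])$Ks
  }, numeric(1))
  se <- sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 0.2), 3 * se)
})

test_that("positions are 0-based half-open with subgenome collinearity", {
  h <- scenario_allopolyploid()
  cfg <- sim_config(n_families = 40, retention = 1, local_dup_rate = 0,
                    seed = 8)
  em <- emit_sequences(simulate_families(h, cfg), cfg)
  pos <- em$positions
  expect_true(all(pos$end == pos$start + 1))
  for (ch in unique(pos$chrom)) {
    p <- pos$start[pos$chrom == ch]
    expect_equal(sort(p), seq_along(p) - 1L)
  }
  # tetraploid subgenome 2 mirrors subgenome 1 order: homoeologous
  # chromosomes carry the same families in the same order
  t1 <- pos[pos$chrom == "tetra_chr1", ]
  t8 <- pos[pos$chrom == "tetra_chr8", ]
  fam_of <- function(g) sub("^[^.]*\\.([^.]*)\\..*$", "\\1", g)
  expect_equal(fam_of(t1$gene[order(t1$start)]),
               fam_of(t8$gene[order(t8$start)]))
})

test_that("configuration validation catches bad inputs", {
  expect_error(sim_config(retention = 1.2), "probability")
  expect_error(sim_config(codon_length = 10), "30")
  expect_error(emit_sequences(list(), sim_config()), "no families")
})
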