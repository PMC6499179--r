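mk_est <- function(a, b, ks) {
  data.frame(gene_a = a, gene_b = b,
             species_a = gene_species(a), species_b = gene_species(b),
             Ks = ks, valid = !is.na(ks), stringsAsFactors = FALSE)
}

test_that("edges survive iff Ks is within the species-pair cutoff", {
  est <- mk_est(c("sp.F1.1", "sp.F1.2"), c("sp.F1.3", "sp.F1.4"),
                c(0.3, 0.95))
  g <- build_graph(est, c("sp|sp" = 0.9))
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::vcount(g), 4)
  w <- igraph::E(g)$weight
  expect_equal(w, 1 - 0.3 / 0.9, tolerance = 1e-12)
  # empty input
  g0 <- build_graph(mk_est(character(0), character(0), numeric(0)),
                    c("sp|sp" = 0.9), nodes = c("sp.F1.1"))
  expect_equal(igraph::ecount(g0), 0)
  expect_equal(igraph::vcount(g0), 1)
  # missing cutoff is an error naming the pair
  expect_error(build_graph(mk_est("a.F1.1", "b.F1.1", 0.2),
                           c("a|a" = 1)), "a\\|b")
})

test_that("random graphs match a brute-force filter oracle and cutoffs
           are monotone", {
  set.seed(31)
  sps <- c("x", "y", "z")
  for (rep_i in 1:10) {
    n <- 40
    a <- paste0(sample(sps, n, TRUE), ".F", sample(5, n, TRUE), ".1")
    b <- paste0(sample(sps, n, TRUE), ".F", sample(5, n, TRUE), ".2")
    ks <- round(runif(n, 0, 1.5), 3)
    est <- mk_est(a, b, ks)
    cuts <- setNames(runif(6, 0.2, 1.2),
                     c("x|x", "x|y", "x|z", "y|y", "y|z", "z|z"))
    g <- build_graph(est, cuts)
    keep <- ks <= cuts[species_pair_key(gene_species(a),
                                        gene_species(b))]
    oracle_edges <- unique(pair_key(a[keep], b[keep]))
    got <- apply(igraph::as_edgelist(g), 1, function(r)
      pair_key(r[1], r[2]))
    expect_setequal(got, oracle_edges)
    # lowering every cutoff never adds edges
    g2 <- build_graph(est, cuts * 0.6)
    got2 <- apply(igraph::as_edgelist(g2), 1, function(r)
      pair_key(r[1], r[2]))
    expect_true(all(got2 %in% got))
  }
})

test_that("MCL keeps disjoint cliques apart and partitions all nodes", {
  genes <- c(paste0("a.F1.", 1:4), paste0("a.F2.", 1:4))
  combs1 <- t(combn(genes[1:4], 2))
  combs2 <- t(combn(genes[5:8], 2))
  est <- mk_est(c(combs1[, 1], combs2[, 1]), c(combs1[, 2], combs2[, 2]),
                rep(0.2, 12))
  g <- build_graph(est, c("a|a" = 1))
  for (infl in c(1.2, 1.5, 2)) {
    cl <- mcl_cluster(g, inflation = infl)
    expect_equal(length(cl$clusters), 2)
    expect_setequal(unlist(cl$clusters), genes)
    expect_equal(anyDuplicated(unlist(cl$clusters)), 0)
  }
})

test_that("MCL on a weighted path agrees with a naive reference run", {
  genes <- paste0("p.F1.", 1:6)
  est <- mk_est(genes[1:5], genes[2:6], rep(0.1, 5))
  g <- build_graph(est, c("p|p" = 1))
  cl <- mcl_cluster(g, inflation = 1.2)
  adj <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight"))
  comp <- oracle_mcl(adj, inflation = 1.2)
  # same partition up to label permutation
  mine <- cl$membership[rownames(adj)]
  expect_equal(length(unique(mine)), length(unique(comp)))
  # cross-tabulation is a permutation matrix: identical partitions
  ct <- table(mine, comp)
  expect_true(all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1))
})

test_that("simulated families are recovered with high adjusted Rand index", {
  skip_if_not_installed("mclust")
  h <- scenario_allopolyploid()
  cfg <- sim_config(n_families = 40, retention = 0.8, seed = 19)
  em <- emit_sequences(simulate_families(h, cfg), cfg)
  pairs <- top_pairs(sim_match_table(em), per_species = TRUE)
  est <- ng86_pairs(pairs, em$sequences)
  key <- species_pair_key(est$species_a, est$species_b)
  cuts <- vapply(sort(unique(key)), function(k)
    ks_cutoff(modal_peak(ks_histogram(est[key == k, , drop = FALSE]))),
    numeric(1))
  g <- build_graph(est, cuts, nodes = names(em$sequences))
  cl <- mcl_cluster(g)
  truth <- vapply(strsplit(names(cl$membership), ".", fixed = TRUE),
                  `[`, character(1), 2)
  ari <- mclust::adjustedRandIndex(cl$membership, truth)
  expect_gte(ari, 0.9)
})

test_that("profile refinement drops a random interloper, keeps clones", {
  set.seed(41)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L")
  clone <- paste(sample(aa, 60, TRUE), collapse = "")
  rand <- paste(sample(aa, 60, TRUE), collapse = "")
  prots <- setNames(c(rep(clone, 4), rand),
                    c(paste0("s.F1.", 1:4), "s.F9.1"))
  out <- refine_families(list(names(prots)), prots)
  expect_equal(sort(out$families[[1]]), paste0("s.F1.", 1:4))
  expect_true("s.F9.1" %in% out$unassigned)
  expect_true("removed_round1" %in% out$log$action)
  # identical members only: no removals
  out2 <- refine_families(list(paste0("s.F1.", 1:4)), prots)
  expect_equal(sort(out2$families[[1]]), paste0("s.F1.", 1:4))
  expect_false(any(grepl("removed", out2$log$action)))
})

test_that("members excluded upstream are recaptured by the rescan", {
  set.seed(43)
  recaptured <- 0
  for (case_i in 1:10) {
    h <- scenario_no_wgd()
    cfg <- sim_config("no_wgd", n_families = 6, retention = 1,
                      local_dup_rate = 0, seed = 100 + case_i)
    em <- emit_sequences(simulate_families(h, cfg), cfg)
    prots <- translate_cds(em$sequences)
    fams <- lapply(em$families, function(f) f$leaves$gene)
    # drop one member of family 1 from the clustering (as an over-strict
    # Ks cutoff would); it stays in the proteome
    victim <- fams[[1]][1]
    fams[[1]] <- setdiff(fams[[1]], victim)
    out <- refine_families(fams, prots)
    hit <- any(vapply(out$families, function(m) victim %in% m, logical(1)))
    if (hit) recaptured <- recaptured + 1
  }
  expect_gte(recaptured, 9)
})

test_that("refinement is idempotent on stable assignments", {
  set.seed(47)
  h <- scenario_no_wgd()
  cfg <- sim_config("no_wgd", n_families = 8, retention = 1,
                    local_dup_rate = 0, seed = 77)
  em <- emit_sequences(simulate_families(h, cfg), cfg)
  prots <- translate_cds(em$sequences)
  fams <- lapply(em$families, function(f) f$leaves$gene)
  once <- refine_families(fams, prots)
  twice <- refine_families(once$families, prots)
  expect_equal(unname(lapply(twice$families, sort)),
               unname(lapply(once$families, sort)))
})
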