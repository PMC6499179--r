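mk_anchors <- function(x, y, chrom_x = "cx", chrom_y = "cy", ks = NULL) {
  df <- data.frame(gene_x = sprintf("gx%d", seq_along(x)),
                   gene_y = sprintf("gy%d", seq_along(y)),
                   chrom_x = rep_len(chrom_x, length(x)), pos_x = x,
                   chrom_y = rep_len(chrom_y, length(y)), pos_y = y,
                   stringsAsFactors = FALSE)
  if (!is.null(ks)) df$ks <- ks
  df[order(df$chrom_x, df$pos_x), ]
}

test_that("collinear anchors chain into one block; large gaps split", {
  a <- mk_anchors(0:19, 0:19)
  b <- chain_anchors(a)
  expect_equal(nrow(b), 1)
  expect_equal(b$n_anchors, 20)
  expect_equal(c(b$x_start, b$x_end), c(0, 20))
  # a 15-rank gap with max_gap 10 splits the run
  a2 <- mk_anchors(c(0:9, 25:34), c(0:9, 25:34))
  b2 <- chain_anchors(a2, max_gap = 10)
  expect_equal(nrow(b2), 2)
  # inversions chain as decreasing-Y blocks
  a3 <- mk_anchors(0:9, 9:0)
  b3 <- chain_anchors(a3)
  expect_equal(b3$orientation, "-")
  expect_equal(b3$n_anchors, 10)
  # blocks below min_anchors are discarded; empty input tolerated
  expect_equal(nrow(chain_anchors(mk_anchors(0:2, 0:2))), 0)
  expect_equal(nrow(chain_anchors(mk_anchors(integer(0), integer(0)))), 0)
})

test_that("chain DP matches the exhaustive oracle on small anchor sets", {
  set.seed(53)
  for (rep_i in 1:30) {
    n <- sample(4:12, 1)
    x <- sample(0:30, n)
    y <- sample(0:30, n)
    a <- mk_anchors(x, y)
    best <- wgdetect:::best_chain(a, max_gap = 10)
    oracle <- oracle_best_chain_score(a$pos_x, a$pos_y, max_gap = 10)
    expect_equal(best$score, oracle)
  }
})

test_that("quota selection enforces depth and reports coverage", {
  # identical single-copy genomes: full coverage at 1:1
  a <- mk_anchors(0:49, 0:49)
  b <- chain_anchors(a)
  q <- quota_select(b, c(cx = 50L), c(cy = 50L), 1, 1)
  expect_gte(q$coverage_x, 99)
  expect_gte(q$coverage_y, 99)
  expect_true(q$depth_ok)

  # X duplicated into Y twice: 2:1 on the Y axis only via qy = 2
  a2 <- rbind(mk_anchors(0:49, 0:49, "cx", "cy1"),
              mk_anchors(0:49, 0:49, "cx", "cy2"))
  b2 <- chain_anchors(a2)
  gx <- c(cx = 50L)
  gy <- c(cy1 = 50L, cy2 = 50L)
  q11 <- quota_select(b2, gx, gy, 1, 1)
  q21 <- quota_select(b2, gx, gy, 2, 1)
  expect_lte(q11$coverage_y, 65)
  expect_gte(q21$coverage_y, 95)
  expect_gte(q21$coverage_x, 95)
  # coverage is monotone in quota depth
  expect_gte(q21$coverage_y, q11$coverage_y)
  q22 <- quota_select(b2, gx, gy, 2, 2)
  expect_gte(q22$coverage_y, q21$coverage_y)
})

test_that("quota screening flags the smallest sufficient quota BEST", {
  a2 <- rbind(mk_anchors(0:49, 0:49, "cx", "cy1"),
              mk_anchors(0:49, 0:49, "cx", "cy2"))
  b2 <- chain_anchors(a2)
  scr <- quota_screen(b2, c(cx = 50L), c(cy1 = 50L, cy2 = 50L))
  expect_equal(scr$flag[scr$quota == "2:1"], "BEST")
  expect_equal(scr$flag[scr$quota == "1:1"], "insufficient")
  # 2:2 also reaches coverage but is deeper than necessary
  expect_equal(scr$flag[scr$quota == "2:2"], "OK")
  expect_error(quota_screen(b2, c(cx = 50L), c(cy1 = 50L), quotas = list()),
               "at least one")
})

test_that("simulated tetraploid self-comparison behaves like one WGD", {
  h <- scenario_allopolyploid()
  cfg <- sim_config(n_families = 60, retention = 1, local_dup_rate = 0,
                    seed = 61)
  em <- emit_sequences(simulate_families(h, cfg), cfg)
  mem <- do.call(rbind, lapply(em$families, function(f)
    data.frame(family = f$id, gene = f$leaves$gene,
               species = f$leaves$species)))
  anc <- anchor_set(mem, em$positions, "tetra", "tetra")
  expect_true(attr(anc, "self"))
  expect_false(any(anc$gene_x == anc$gene_y))
  blocks <- chain_anchors(anc)
  gs <- genome_sizes(em$positions, "tetra")
  q11 <- quota_select(blocks, gs, gs, 1, 1)
  # one WGD, trivial diagonal suppressed: quota 1:1 suffices
  expect_gte(q11$coverage_x, 90)
  # relic self-comparison has no homoeologous blocks at all
  anc_r <- anchor_set(mem, em$positions, "relic", "relic")
  expect_equal(nrow(chain_anchors(anc_r)), 0)
})

test_that("synteny-restricted Ks histograms isolate the WGD signal", {
  h <- scenario_allopolyploid()
  cfg <- sim_config(n_families = 80, retention = 1, seed = 67)
  em <- emit_sequences(simulate_families(h, cfg), cfg)
  mem <- do.call(rbind, lapply(em$families, function(f)
    data.frame(family = f$id, gene = f$leaves$gene,
               species = f$leaves$species)))
  # Ks on all within-species pairs of the outgroup
  ks <- list()
  cods <- lapply(em$sequences, seq_to_codons)
  for (f in em$families) {
    g <- f$leaves$gene[f$leaves$species == "outgrp"]
    if (length(g) < 2) next
    for (i in seq_len(length(g) - 1)) for (j in (i + 1):length(g))
      ks[[pair_key(g[i], g[j])]] <- ng86_codons(cods[[g[i]]],
                                                cods[[g[j]]])$Ks
  }
  ks <- unlist(ks)
  anc <- anchor_set(mem, em$positions, "outgrp", "outgrp", ks = ks)
  blocks <- chain_anchors(anc)
  hist <- synteny_ks(anc, blocks, label = "outgrp|outgrp")
  p <- modal_peak(hist)
  expect_true(p$found)
  # homoeolog pairs were calibrated to Ks 0.6: peak within one bin
  expect_lte(abs(p$mode - 0.6), 0.05 + 0.025)
  expect_error(synteny_ks(anc[, setdiff(names(anc), "ks")], blocks),
               "no Ks")
  # empty block list gives an empty, flagged histogram
  h0 <- synteny_ks(anc, chain_anchors(anc[0, ]), label = "x")
  expect_true(h0$empty)
})
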