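# Synteny-block chaining on gene-rank anchor coordinates, quota-based
# block selection with per-position depth auditing, and quota screening
# (the synteny-depth line of evidence for WGD status).

#' Build an anchor set from family membership and gene positions
#'
#' Anchors are homologous gene pairs (same family) between genome X and
#' genome Y with their ordinal gene-rank coordinates. In self-comparisons
#' the trivial diagonal (a gene matched with itself) is excluded, and so
#' is a near-diagonal band of width `tandem_window` gene ranks: local
#' tandem pairs sit just off the diagonal and would otherwise chain into
#' spurious "duplicated" self-synteny. Both orientations of every
#' self-comparison pair are kept so both axes can be covered.
#'
#' @param membership data.frame with columns `family`, `gene`, `species`.
#' @param positions data.frame from [gene_positions()] (columns `species`,
#'   `chrom`, `start`, `gene`).
#' @param species_x,species_y genome labels (equal for self-comparison).
#' @param ks optional named numeric of pair Ks keyed by [pair_key()],
#'   carried onto anchors.
#' @param tandem_window self-comparison diagonal exclusion half-width in
#'   gene ranks (default 10).
#' @return data.frame: gene_x, gene_y, chrom_x, pos_x, chrom_y, pos_y
#'   (ordinal ranks), and ks if supplied; attribute `self` flags
#'   self-comparison.
#' @export
anchor_set <- function(membership, positions, species_x, species_y,
                       ks = NULL, tandem_window = 10L) {
  px <- positions[positions$species == species_x, , drop = FALSE]
  py <- positions[positions$species == species_y, , drop = FALSE]
  mx <- membership[membership$species == species_x, , drop = FALSE]
  my <- membership[membership$species == species_y, , drop = FALSE]
  self <- species_x == species_y
  rows <- list()
  fams <- intersect(unique(mx$family), unique(my$family))
  gx_by_fam <- split(mx$gene, mx$family)
  gy_by_fam <- split(my$gene, my$family)
  posx <- stats::setNames(px$start, px$gene)
  chrx <- stats::setNames(px$chrom, px$gene)
  posy <- stats::setNames(py$start, py$gene)
  chry <- stats::setNames(py$chrom, py$gene)
  for (f in fams) {
    gx <- gx_by_fam[[f]]
    gy <- gy_by_fam[[f]]
    pairs <- expand.grid(gene_x = gx, gene_y = gy,
                         stringsAsFactors = FALSE)
    if (self) pairs <- pairs[pairs$gene_x != pairs$gene_y, , drop = FALSE]
    if (nrow(pairs) == 0L) next
    rows[[f]] <- pairs
  }
  if (length(rows) == 0L) {
    out <- data.frame(gene_x = character(0), gene_y = character(0),
                      chrom_x = character(0), pos_x = integer(0),
                      chrom_y = character(0), pos_y = integer(0))
  } else {
    p <- do.call(rbind, rows)
    out <- data.frame(gene_x = p$gene_x, gene_y = p$gene_y,
                      chrom_x = unname(chrx[p$gene_x]),
                      pos_x = unname(posx[p$gene_x]),
                      chrom_y = unname(chry[p$gene_y]),
                      pos_y = unname(posy[p$gene_y]),
                      stringsAsFactors = FALSE)
    out <- out[!is.na(out$pos_x) & !is.na(out$pos_y), , drop = FALSE]
    if (self && tandem_window > 0) {
      near_diag <- out$chrom_x == out$chrom_y &
        abs(out$pos_x - out$pos_y) <= tandem_window
      out <- out[!near_diag, , drop = FALSE]
    }
    if (!is.null(ks)) out$ks <- unname(ks[pair_key(out$gene_x, out$gene_y)])
    out <- out[order(out$chrom_x, out$pos_x, out$chrom_y, out$pos_y,
                     method = "radix"), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "self") <- self
  out
}

#' Chain anchors into synteny blocks
#'
#' Within each chromosome pair, finds maximal-scoring chains of anchors
#' strictly increasing in X and monotone (increasing or decreasing,
#' allowing inversions) in Y, with consecutive anchors at most `max_gap`
#' gene ranks apart on both axes (sparse dynamic programming, score =
#' anchor count). Chains are extracted greedily best-first; chains shorter
#' than `min_anchors` are discarded.
#'
#' @param anchors data.frame from [anchor_set()].
#' @param max_gap adjacency limit in gene ranks (default 10).
#' @param min_anchors minimum anchors per block (default 4).
#' @return data.frame of blocks: block id, chrom_x, chrom_y, x_start,
#'   x_end, y_start, y_end (half-open rank spans), n_anchors, orientation;
#'   with attribute `anchor_blocks` (list of anchor-row indices).
#' @export
chain_anchors <- function(anchors, max_gap = 10L, min_anchors = 4L) {
  empty <- data.frame(block = integer(0), chrom_x = character(0),
                      chrom_y = character(0), x_start = integer(0),
                      x_end = integer(0), y_start = integer(0),
                      y_end = integer(0), n_anchors = integer(0),
                      orientation = character(0))
  if (nrow(anchors) == 0L) {
    attr(empty, "anchor_blocks") <- list()
    return(empty)
  }
  blocks <- list()
  anchor_rows <- list()
  cp <- paste(anchors$chrom_x, anchors$chrom_y, sep = "\r")
  for (key in sort(unique(cp), method = "radix")) {
    idx <- which(cp == key)
    sub <- anchors[idx, , drop = FALSE]
    avail <- rep(TRUE, nrow(sub))
    repeat {
      best <- best_chain(sub[avail, , drop = FALSE], max_gap)
      if (is.null(best) || length(best$chain) < min_anchors) break
      rows_local <- which(avail)[best$chain]
      avail[rows_local] <- FALSE
      b <- sub[rows_local, , drop = FALSE]
      blocks[[length(blocks) + 1L]] <- data.frame(
        chrom_x = b$chrom_x[1], chrom_y = b$chrom_y[1],
        x_start = min(b$pos_x), x_end = max(b$pos_x) + 1L,
        y_start = min(b$pos_y), y_end = max(b$pos_y) + 1L,
        n_anchors = nrow(b), orientation = best$orientation,
        stringsAsFactors = FALSE)
      anchor_rows[[length(anchor_rows) + 1L]] <- idx[rows_local]
    }
  }
  if (length(blocks) == 0L) {
    attr(empty, "anchor_blocks") <- list()
    return(empty)
  }
  out <- do.call(rbind, blocks)
  o <- order(-out$n_anchors, out$chrom_x, out$x_start, out$chrom_y,
             out$y_start, method = "radix")
  out <- out[o, , drop = FALSE]
  out <- cbind(block = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  attr(out, "anchor_blocks") <- anchor_rows[o]
  out
}

# best monotone chain (either orientation) among the given anchors;
# O(n^2) DP, fine at gene-rank anchor densities
best_chain <- function(sub, max_gap) {
  n <- nrow(sub)
  if (n == 0L) return(NULL)
  o <- order(sub$pos_x, sub$pos_y, method = "radix")
  x <- sub$pos_x[o]
  y <- sub$pos_y[o]
  run <- function(dir) {
    f <- rep(1L, n)
    pred <- rep(0L, n)
    for (i in seq_len(n)) {
      for (j in seq_len(i - 1L)) {
        if (x[j] >= x[i]) next
        if (x[i] - x[j] > max_gap) next
        dy <- if (dir > 0) y[i] - y[j] else y[j] - y[i]
        if (dy <= 0 || dy > max_gap) next
        if (f[j] + 1L > f[i]) {
          f[i] <- f[j] + 1L
          pred[i] <- j
        }
      }
    }
    best <- which.max(f)
    chain <- integer(0)
    k <- best
    while (k != 0L) {
      chain <- c(k, chain)
      k <- pred[k]
    }
    list(score = f[best], chain = chain)
  }
  up <- run(1L)
  dn <- run(-1L)
  pick <- if (up$score >= dn$score) up else dn
  list(chain = o[pick$chain], score = pick$score,
       orientation = if (up$score >= dn$score) "+" else "-")
}

#' Select blocks under a synteny quota and measure coverage
#'
#' Admits blocks greedily in decreasing score (anchor count) order,
#' rejecting any block whose admission would push the coverage depth of
#' any gene position past `qx` on genome X or `qy` on genome Y. Coverage
#' is the percentage of gene positions covered by at least one selected
#' block span.
#'
#' @param blocks data.frame from [chain_anchors()].
#' @param genome_x,genome_y named integer vectors: chromosome -> number of
#'   gene positions (see [genome_sizes()]).
#' @param qx,qy quota depths (>= 1).
#' @return list with `quota` ("qx:qy"), `selected` (block ids),
#'   `coverage_x`, `coverage_y` (percent), and `depth_ok` (audit flag).
#' @export
quota_select <- function(blocks, genome_x, genome_y, qx = 1L, qy = 1L) {
  stopifnot(qx >= 1L, qy >= 1L)
  depth_x <- lapply(genome_x, function(n) integer(n))
  depth_y <- lapply(genome_y, function(n) integer(n))
  selected <- integer(0)
  if (nrow(blocks)) {
    for (i in seq_len(nrow(blocks))) {        # already score-ordered
      b <- blocks[i, ]
      sx <- (b$x_start + 1L):b$x_end
      sy <- (b$y_start + 1L):b$y_end
      if (max(depth_x[[b$chrom_x]][sx]) + 1L > qx) next
      if (max(depth_y[[b$chrom_y]][sy]) + 1L > qy) next
      depth_x[[b$chrom_x]][sx] <- depth_x[[b$chrom_x]][sx] + 1L
      depth_y[[b$chrom_y]][sy] <- depth_y[[b$chrom_y]][sy] + 1L
      selected <- c(selected, b$block)
    }
  }
  cov <- function(depth) {
    tot <- sum(lengths(depth))
    if (tot == 0L) return(0)
    100 * sum(vapply(depth, function(d) sum(d > 0L), integer(1))) / tot
  }
  ok_x <- all(vapply(depth_x, function(d) all(d <= qx), logical(1)))
  ok_y <- all(vapply(depth_y, function(d) all(d <= qy), logical(1)))
  list(quota = paste0(qx, ":", qy), selected = selected,
       coverage_x = cov(depth_x), coverage_y = cov(depth_y),
       depth_ok = ok_x && ok_y)
}

#' Chromosome sizes (gene counts) of a genome
#' @param positions data.frame from [gene_positions()].
#' @param species species id.
#' @return named integer vector: chromosome -> gene count.
#' @export
genome_sizes <- function(positions, species) {
  p <- positions[positions$species == species, , drop = FALSE]
  tapply(p$gene, p$chrom, length)[sort(unique(p$chrom), method = "radix")]
}

#' Screen a ladder of synteny quotas
#'
#' Evaluates every quota and marks as `BEST` the smallest-total-depth
#' quota reaching at least `threshold` percent coverage on both axes
#' (mirroring the decision rule used when a duplicated genome shows poor
#' coverage at quota 1:1 but full coverage at 2:1). If none qualifies,
#' all rows are flagged insufficient.
#'
#' @param blocks data.frame from [chain_anchors()].
#' @param genome_x,genome_y as in [quota_select()].
#' @param quotas list of `c(qx, qy)` pairs (default 1:1, 2:1, 1:2, 2:2).
#' @param threshold BEST coverage threshold in percent (default 90).
#' @return data.frame: quota, coverage_x, coverage_y, flag
#'   (`BEST` / `OK` / `insufficient`).
#' @export
quota_screen <- function(blocks, genome_x, genome_y,
                         quotas = list(c(1L, 1L), c(2L, 1L), c(1L, 2L),
                                       c(2L, 2L)),
                         threshold = 90) {
  if (length(quotas) == 0L) stop("need at least one quota")
  res <- lapply(quotas, function(q)
    quota_select(blocks, genome_x, genome_y, q[1], q[2]))
  df <- data.frame(
    quota = vapply(res, `[[`, character(1), "quota"),
    qx = vapply(quotas, `[`, integer(1), 1),
    qy = vapply(quotas, `[`, integer(1), 2),
    coverage_x = vapply(res, `[[`, numeric(1), "coverage_x"),
    coverage_y = vapply(res, `[[`, numeric(1), "coverage_y"),
    stringsAsFactors = FALSE)
  ok <- df$coverage_x >= threshold & df$coverage_y >= threshold
  df$flag <- ifelse(ok, "OK", "insufficient")
  if (any(ok)) {
    depth <- df$qx + df$qy
    cand <- which(ok)
    best <- cand[order(depth[cand], df$qx[cand])][1]
    df$flag[best] <- "BEST"
  }
  df[, c("quota", "coverage_x", "coverage_y", "flag")]
}

#' Ks histogram of anchors inside selected synteny blocks
#'
#' Restricting Ks histograms to syntenic anchor pairs removes local
#' (tandem) duplicates and recent paralogous noise, which is what makes
#' the self-comparison WGD peak (or its absence) unambiguous.
#'
#' @param anchors data.frame from [anchor_set()] with a `ks` column.
#' @param blocks data.frame from [chain_anchors()] on those anchors.
#' @param bin_width histogram bin width (default 0.05).
#' @param label species-pair label.
#' @return a [ks_histogram()] with provenance `"synteny-pairs"`.
#' @export
synteny_ks <- function(anchors, blocks, bin_width = 0.05,
                       label = NA_character_) {
  if (is.null(anchors$ks))
    stop("anchors carry no Ks values")
  rows <- unlist(attr(blocks, "anchor_blocks"), use.names = FALSE)
  ks <- anchors$ks[rows]
  ks_histogram(ks[!is.na(ks)], bin_width = bin_width,
               provenance = "synteny-pairs", label = label)
}
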