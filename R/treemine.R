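# Gene-tree construction, rooting, terminal-pair collapsing,
# duplication/speciation labeling by species overlap, clade-pattern
# mining, and gene-family copy-number statistics.

#' Neighbor-joining tree from a synonymous-distance matrix
#'
#' Thin wrapper around `ape::nj` with negative branch estimates clamped to
#' zero; fewer than three taxa yield a trivial tree.
#'
#' @param d symmetric non-negative distance matrix (or `dist`).
#' @return unrooted `ape::phylo`.
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (!isSymmetric(unname(m), tol = 1e-8))
    stop("distance matrix must be symmetric")
  if (any(m < 0, na.rm = TRUE)) stop("distances must be non-negative")
  n <- nrow(m)
  if (n < 2L) stop("need at least two taxa")
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%.10f,%s:%.10f);",
                                        rownames(m)[1], m[1, 2] / 2,
                                        rownames(m)[2], m[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(m)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Pairwise NG86 Ks matrix for a set of genes
#'
#' @param genes character vector of gene ids.
#' @param seqs named list/vector of sequences (or codon-index vectors).
#' @param fill value used for invalid/saturated estimates (default 3,
#'   beyond the informative Ks range, keeping the matrix usable by NJ).
#' @return symmetric matrix of Ks values with zero diagonal.
#' @export
ks_matrix <- function(genes, seqs, fill = 3) {
  n <- length(genes)
  cods <- lapply(genes, function(g) {
    s <- seqs[[g]]
    if (is.character(s)) seq_to_codons(s) else s
  })
  m <- matrix(0, n, n, dimnames = list(genes, genes))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      e <- ng86_codons(cods[[i]], cods[[j]])
      m[i, j] <- m[j, i] <- if (e$valid) e$Ks else fill
    }
  }
  m
}

#' Root a gene tree with an outgroup species set
#'
#' Places the root on the edge separating the outgroup (single leaf, or
#' the smallest clade containing all outgroup leaves) from the rest. When
#' no outgroup species is present the tree is midpoint-rooted and flagged.
#'
#' @param tree unrooted (or rooted) `ape::phylo`; leaf names
#'   `<species>.<gene>`.
#' @param outgroup_species character vector of outgroup species ids.
#' @return rooted `ape::phylo` with attribute `rooting` set to
#'   `"outgroup"` or `"midpoint"`.
#' @export
root_tree <- function(tree, outgroup_species) {
  sp <- gene_species(tree$tip.label)
  og <- tree$tip.label[sp %in% outgroup_species]
  if (length(og) == 0L) {
    r <- phangorn::midpoint(tree)
    attr(r, "rooting") <- "midpoint"
    return(r)
  }
  r <- tryCatch(
    ape::root(tree, outgroup = og, resolve.root = TRUE),
    error = function(e) NULL)
  if (is.null(r)) {
    # outgroup not monophyletic in the unrooted tree: fall back to the
    # single outgroup leaf with the longest path (deepest representative)
    r <- ape::root(tree, outgroup = og[1], resolve.root = TRUE)
  }
  attr(r, "rooting") <- "outgroup"
  r
}

#' Collapse recent same-species terminal pairs
#'
#' Repeatedly replaces any cherry whose two leaves belong to the same
#' species and meet the collapse criterion with a single representative
#' (the lexicographically smaller gene id), until no such cherry remains.
#' Two criteria exist and are never mixed in one run: `"branch"` collapses
#' when both terminal branch lengths are below `threshold` (0.01 controls
#' for private local duplications before clade mining); `"ks"` collapses
#' when the pair's Ks is below `threshold` (0.2 for the reduced
#' copy-number tables).
#'
#' @param tree rooted `ape::phylo` with leaf names `<species>.<gene>`.
#' @param mode `"branch"` or `"ks"`.
#' @param threshold collapse threshold (default 0.01 for branch mode).
#' @param ks_lookup for `"ks"` mode: function of two gene ids returning the
#'   pair Ks, or a named numeric vector keyed by [pair_key()].
#' @return collapsed `ape::phylo` (possibly the input, unchanged).
#' @export
collapse_pairs <- function(tree, mode = c("branch", "ks"), threshold = 0.01,
                           ks_lookup = NULL) {
  mode <- match.arg(mode)
  if (mode == "ks" && is.null(ks_lookup))
    stop("ks mode needs a ks_lookup")
  lookup <- if (is.function(ks_lookup)) ks_lookup else
    function(a, b) unname(ks_lookup[[pair_key(a, b)]])
  repeat {
    if (length(tree$tip.label) < 3L) break
    ntip <- length(tree$tip.label)
    tab <- tabulate(tree$edge[, 1], nbins = ntip + tree$Nnode)
    done <- TRUE
    # deterministic scan order: internal nodes ascending
    for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
      ch <- tree$edge[tree$edge[, 1] == nd, 2]
      if (length(ch) != 2L || any(ch > ntip)) next
      l1 <- tree$tip.label[ch[1]]
      l2 <- tree$tip.label[ch[2]]
      if (gene_species(l1) != gene_species(l2)) next
      meets <- if (mode == "branch") {
        b <- tree$edge.length[match(ch, tree$edge[, 2])]
        all(b < threshold)
      } else {
        k <- lookup(l1, l2)
        !is.null(k) && !is.na(k) && k < threshold
      }
      if (!meets) next
      drop <- if (l1 <= l2) l2 else l1
      tree <- ape::drop.tip(tree, drop)
      done <- FALSE
      break
    }
    if (done) break
  }
  tree
}

#' Canonical unordered pair key
#' @param a,b gene id vectors.
#' @export
pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")

#' Label internal nodes duplication/speciation by species overlap
#'
#' A node is a duplication (`D`) iff the species sets of (any pair of) its
#' child subtrees intersect, otherwise a speciation (`S`). Works on
#' multifurcating trees (any-pair intersection).
#'
#' @param tree rooted `ape::phylo`, leaf names `<species>.<gene>`.
#' @return the tree with `node.label` set to `"D"`/`"S"` and an attribute
#'   `species_sets` (list, per internal node) attached.
#' @export
label_overlap <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sp <- gene_species(tree$tip.label)
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- sp[i]
  labels <- character(nnode)
  # postorder: children before parents
  ord <- rev(ape::reorder.phylo(tree, "cladewise")$edge[, 2])
  ord <- unique(c(ord, ntip + 1L))
  for (nd in ord) {
    if (nd <= ntip) next
    ch <- tree$edge[tree$edge[, 1] == nd, 2]
    child_sets <- lapply(ch, function(c_) sets[[c_]])
    overlap <- FALSE
    if (length(child_sets) >= 2L) {
      for (i in seq_len(length(child_sets) - 1L)) {
        for (j in (i + 1L):length(child_sets)) {
          if (length(intersect(child_sets[[i]], child_sets[[j]]))) {
            overlap <- TRUE
            break
          }
        }
        if (overlap) break
      }
    }
    sets[[nd]] <- sort(unique(unlist(child_sets)))
    labels[nd - ntip] <- if (overlap) "D" else "S"
  }
  tree$node.label <- labels
  attr(tree, "species_sets") <- sets
  tree
}

#' Mine relic/sister clade patterns from labeled gene trees
#'
#' Extracts, from each tree, the maximal clades whose leaves all belong to
#' the relic or sister species and that contain at least one leaf of each.
#' Each clade is typed by its leaf counts (`c` relic, `b` sister):
#' `"c>=2,b>=2"`, `"c>=2,b=1"`, `"c=1,b>=2"`, or `"c=1,b=1"`. For the
#' `c=1,b>=2` type the nested pattern is read off the MRCA label:
#' a duplication MRCA means the relic leaf is nested among sister leaves
#' (`[(C,B),B]`, the allopolyploidy signature), a speciation MRCA means
#' the sister leaves form their own clade (`[(B,B),C]`, the
#' WGD-after-speciation signature).
#'
#' @param trees list of rooted `ape::phylo` (labels applied internally via
#'   [label_overlap()]; trees are first collapsed with the branch
#'   criterion unless `collapse = FALSE`).
#' @param relic_species,sister_species species ids.
#' @param collapse collapse same-species terminal pairs (branch mode,
#'   threshold 0.01) before mining (default TRUE).
#' @return data.frame of clade records: family (list index or name), type,
#'   c, b, mrca_label, pattern.
#' @export
mine_clades <- function(trees, relic_species, sister_species,
                        collapse = TRUE) {
  nm <- names(trees)
  if (is.null(nm)) nm <- as.character(seq_along(trees))
  rows <- list()
  for (t_ in seq_along(trees)) {
    tree <- trees[[t_]]
    if (is.null(tree) || length(tree$tip.label) < 2L) next
    if (collapse) tree <- collapse_pairs(tree, "branch", 0.01)
    if (length(tree$tip.label) < 2L) next
    tree <- label_overlap(tree)
    sets <- attr(tree, "species_sets")
    ntip <- length(tree$tip.label)
    target <- c(relic_species, sister_species)
    pure <- vapply(seq_len(ntip + tree$Nnode), function(nd)
      all(sets[[nd]] %in% target), logical(1))
    parent <- integer(ntip + tree$Nnode)
    parent[tree$edge[, 2]] <- tree$edge[, 1]
    # maximal pure nodes: pure, with non-pure (or absent) parent
    maximal <- which(pure & (parent == 0L | !pure[pmax(parent, 1L)]))
    for (nd in maximal) {
      leaves <- if (nd <= ntip) tree$tip.label[nd] else
        ape::extract.clade(tree, nd)$tip.label
      spl <- gene_species(leaves)
      cc <- sum(spl %in% relic_species)
      bb <- sum(spl %in% sister_species)
      if (cc < 1L || bb < 1L) next
      type <- paste0(if (cc >= 2L) "c>=2" else "c=1", ",",
                     if (bb >= 2L) "b>=2" else "b=1")
      mrca <- if (nd <= ntip) NA_character_ else
        tree$node.label[nd - ntip]
      pattern <- if (cc == 1L && bb >= 2L) {
        if (identical(mrca, "D")) "[(C,B),B]" else "[(B,B),C]"
      } else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        family = nm[t_], type = type, c = cc, b = bb,
        mrca_label = mrca, pattern = pattern, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(family = character(0), type = character(0), c = integer(0),
               b = integer(0), mrca_label = character(0),
               pattern = character(0))
  rownames(out) <- NULL
  out
}

#' Summaries and ratios of mined clade types
#'
#' @param records data.frame from [mine_clades()] (or equivalent counts).
#' @return list with `type_counts` (named integer), `pattern_counts`
#'   (named integer over `[(C,B),B]` / `[(B,B),C]`), `ratio_types`
#'   (count of `c=1,b>=2` over `c>=2,b=1` clades) and `ratio_patterns`
#'   (`[(C,B),B]` over `[(B,B),C]`).
#' @export
summarize_clades <- function(records) {
  tc <- table(records$type)
  pc <- table(records$pattern[!is.na(records$pattern)])
  n12 <- if ("c=1,b>=2" %in% names(tc)) as.integer(tc[["c=1,b>=2"]]) else 0L
  n21 <- if ("c>=2,b=1" %in% names(tc)) as.integer(tc[["c>=2,b=1"]]) else 0L
  ncb <- if ("[(C,B),B]" %in% names(pc)) as.integer(pc[["[(C,B),B]"]]) else 0L
  nbc <- if ("[(B,B),C]" %in% names(pc)) as.integer(pc[["[(B,B),C]"]]) else 0L
  list(type_counts = tc, pattern_counts = pc,
       ratio_types = if (n21 > 0) n12 / n21 else NA_real_,
       ratio_patterns = if (nbc > 0) ncb / nbc else NA_real_)
}

#' Per-species gene-family copy-number table and duplication ratio
#'
#' Tabulates, for every species, the number of families with 0, 1, 2, 3,
#' and >= 4 members, and the duplication-ratio statistic
#' `100 * (families with >= 2 members) / (families with exactly 1)`,
#' rounded to the nearest integer percent. A ratio well above ~50%
#' indicates a WGD within the window the families span; single-digit to
#' ~25% values indicate tandem duplications only.
#'
#' @param membership data.frame with columns `family`, `gene`, `species`.
#' @param species optional character vector fixing the species set/order.
#' @return data.frame: species, n0, n1, n2, n3, n4plus, ratio_pct
#'   (NA when no single-copy families exist).
#' @export
count_table <- function(membership, species = NULL) {
  if (is.null(species))
    species <- sort(unique(membership$species), method = "radix")
  fams <- sort(unique(membership$family), method = "radix")
  out <- lapply(species, function(sp) {
    cnt <- table(factor(membership$family[membership$species == sp],
                        levels = fams))
    size_class <- c(sum(cnt == 0), sum(cnt == 1), sum(cnt == 2),
                    sum(cnt == 3), sum(cnt >= 4))
    data.frame(species = sp, n0 = size_class[1], n1 = size_class[2],
               n2 = size_class[3], n3 = size_class[4],
               n4plus = size_class[5],
               ratio_pct = dup_ratio(size_class[2], size_class[3] +
                                       size_class[4] + size_class[5]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Duplication-ratio statistic from size-class counts
#'
#' @param n1 number of families with exactly one member for the species.
#' @param n2plus number of families with two or more members.
#' @return `round(100 * n2plus / n1)`; NA (undefined) when `n1` is 0.
#' @export
dup_ratio <- function(n1, n2plus) {
  if (n1 == 0) return(NA_real_)
  round(100 * n2plus / n1)
}
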