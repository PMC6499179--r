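# Modal chromosome-count analysis per genus and per clade, and the
# picogram-to-megabase genome-size conversion.

#' Modal gametic chromosome number per genus
#'
#' Pools species-level count records per genus and reports the modal n.
#' All co-modes are returned; the smallest co-mode is designated primary
#' (deterministic and conservative) with an explicit tie flag. The mode
#' fraction is the share of records at the primary mode.
#'
#' @param records data.frame with columns `genus`, `species`, `n`
#'   (gametic counts, integers >= 2).
#' @return data.frame: genus, mode (primary), co_modes
#'   (comma-separated), tie (logical), n_records, mode_fraction_pct
#'   (rounded percent).
#' @export
genus_mode <- function(records) {
  stopifnot(all(c("genus", "n") %in% names(records)))
  if (any(records$n < 2)) stop("gametic counts must be >= 2")
  if (any(!nzchar(records$genus))) stop("genus must be nonempty")
  gen <- sort(unique(records$genus), method = "radix")
  out <- lapply(gen, function(g) {
    n <- records$n[records$genus == g]
    tab <- table(n)
    modes <- sort(as.integer(names(tab)[tab == max(tab)]))
    data.frame(genus = g, mode = modes[1],
               co_modes = paste(modes, collapse = ","),
               tie = length(modes) > 1L,
               n_records = length(n),
               mode_fraction_pct = round(100 * max(tab) / length(n)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Tally genus modal counts per clade
#'
#' Builds the clade-by-count summary table: one row per clade, one column
#' per count value 6..16 plus `gt16`, each cell the number of genera in
#' that clade whose modal n equals the column value. Genera absent from
#' the clade map land in an `unplaced` row rather than being dropped.
#'
#' @param modes data.frame from [genus_mode()] (columns `genus`, `mode`).
#' @param clade_map data.frame with columns `genus`, `clade`.
#' @param counts integer count columns (default 6:16; values above the
#'   maximum pool into `gt16`, values below the minimum into the minimum
#'   column's left neighbor `lt` column only if they occur).
#' @return data.frame: clade, one column per count (`n6`..`n16`, `gt16`),
#'   `total`.
#' @export
clade_summary <- function(modes, clade_map, counts = 6:16) {
  clade <- clade_map$clade[match(modes$genus, clade_map$genus)]
  clade[is.na(clade)] <- "unplaced"
  clades <- unique(clade_map$clade)
  clades <- c(clades, if (any(clade == "unplaced")) "unplaced")
  rows <- lapply(clades, function(cl) {
    m <- modes$mode[clade == cl]
    cells <- vapply(counts, function(k) sum(m == k), integer(1))
    df <- data.frame(clade = cl, stringsAsFactors = FALSE)
    df[paste0("n", counts)] <- as.list(cells)
    df$gt16 <- sum(m > max(counts))
    df$lt_min <- sum(m < min(counts))
    df$total <- length(m)
    df
  })
  do.call(rbind, rows)
}

#' Genome size in Mbp from a 2C value in picograms
#'
#' Uses the conversion 1 pg = 978 Mbp and halves the 2C mass to obtain
#' the 1C (haploid) genome size, rounded to the nearest Mbp.
#'
#' @param two_c_pg 2C DNA amount in picograms (> 0).
#' @return 1C genome size in Mbp (integer-valued numeric).
#' @export
pg_to_mbp <- function(two_c_pg) {
  if (any(two_c_pg <= 0)) stop("2C values must be positive")
  round(two_c_pg * 978 / 2)
}

#' Annotate a species tree with genus modal counts
#'
#' Each leaf is annotated with the modal n of its genus (leaf names are
#' matched to genera by their first `_`-separated token, or exactly).
#' Internal nodes receive a clade-modal annotation: the mode over the
#' descendant leaves' modes (smallest on ties). Leaves without data are
#' flagged, never silently pruned.
#'
#' @param tree `ape::phylo` or newick string.
#' @param modes data.frame from [genus_mode()].
#' @return list with `tree` (node labels set to clade modes), `leaf_modes`
#'   (named integer, NA when unknown), `no_data` (leaf names lacking
#'   counts).
#' @export
annotate_tree <- function(tree, modes) {
  if (!inherits(tree, "phylo")) tree <- ape::read.tree(text = tree)
  genus_of <- sub("_.*$", "", tree$tip.label)
  lm <- modes$mode[match(genus_of, modes$genus)]
  exact <- modes$mode[match(tree$tip.label, modes$genus)]
  lm[is.na(lm)] <- exact[is.na(lm)]
  names(lm) <- tree$tip.label
  ntip <- length(tree$tip.label)
  node_mode <- character(tree$Nnode)
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    tips <- ape::extract.clade(tree, nd)$tip.label
    vals <- lm[tips]
    vals <- vals[!is.na(vals)]
    node_mode[nd - ntip] <- if (length(vals)) {
      tab <- table(vals)
      as.character(min(as.integer(names(tab)[tab == max(tab)])))
    } else "no_data"
  }
  tree$node.label <- node_mode
  list(tree = tree, leaf_modes = lm,
       no_data = tree$tip.label[is.na(lm)])
}
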