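# Codon sequence generation along simulated family trees. The root codon
# sequence is drawn uniformly from sense codons; along each branch,
# synonymous substitutions arrive as a Poisson process with expectation
# branch-length x synonymous sites, choosing uniformly among synonymous
# single-nucleotide neighbors (so the expected Ks of a branch equals its
# length); nonsynonymous substitutions arrive at ka_ratio times the
# synonymous per-site rate among non-stop nonsynonymous neighbors. Branches
# are processed in segments so that site counts track the evolving
# sequence.

# apply substitutions for one branch of length d (Ks units)
mutate_codons <- function(cod, d, ka_ratio, seg = 0.05) {
  if (d <= 0) return(cod)
  tab <- ng86_tables()
  syn_cnt <- lengths(tab$syn_neighbors)
  non_cnt <- lengths(tab$nonsyn_neighbors)
  remaining <- d
  while (remaining > 1e-12) {
    step <- min(seg, remaining)
    remaining <- remaining - step
    # synonymous hits: expectation step * S, S = sum(syn neighbors)/3
    w <- syn_cnt[cod]
    S <- sum(w) / 3
    nsub <- stats::rpois(1L, step * S)
    for (k in seq_len(nsub)) {
      w <- syn_cnt[cod]
      pos <- sample.int(length(cod), 1L, prob = w)
      nb <- tab$syn_neighbors[[cod[pos]]]
      cod[pos] <- nb[sample.int(length(nb), 1L)]
    }
    # nonsynonymous hits at the reduced rate
    if (ka_ratio > 0) {
      wn <- non_cnt[cod]
      N <- sum(wn) / 3
      nsub <- stats::rpois(1L, step * ka_ratio * N)
      for (k in seq_len(nsub)) {
        wn <- non_cnt[cod]
        pos <- sample.int(length(cod), 1L, prob = wn)
        nb <- tab$nonsyn_neighbors[[cod[pos]]]
        cod[pos] <- nb[sample.int(length(nb), 1L)]
      }
    }
  }
  cod
}

#' Emit codon sequences and gene positions for simulated families
#'
#' @param families list of `true_family` objects from [simulate_families()].
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, per-species CDS FASTA
#'   (`<species>.cds.fna`), a BED-like gene position table
#'   (`gene_positions.tsv`: chrom, start, end, gene, strand; 0-based
#'   half-open gene-rank coordinates), true trees
#'   (`true_trees.nwk`) and a truth log (`truth_families.tsv`) are written.
#' @return list with `sequences` (named character vector, gene id ->
#'   nucleotide string), `positions` (data.frame: species, chrom, start,
#'   end, gene, strand), and `families` (the input, unchanged).
#' @export
emit_sequences <- function(families, config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (length(families) == 0L) stop("no families to emit")
  if (config$codon_length < 30L)
    stop("codon_length must be at least 30 codons")
  tab <- ng86_tables()
  seqs <- list()
  for (i in seq_along(families)) {
    fam <- families[[i]]
    if (fam$empty || nrow(fam$leaves) == 0L) next
    set.seed(fam_seed(config$seed, i, 1L))
    root_cod <- tab$sense[sample.int(length(tab$sense), config$codon_length,
                                     replace = TRUE)]
    if (max(fam$leaves$total_len) > 3)
      warning("family ", fam$id, " has expected Ks > 3 on a root-to-leaf ",
              "path; the estimator will be saturated")
    if (is.null(fam$tree)) {
      # single gene: evolve straight down its recorded path length
      g <- fam$leaves$gene[1]
      seqs[[g]] <- mutate_codons(root_cod, fam$leaves$total_len[1],
                                 config$ka_ratio)
    } else {
      tr <- fam$tree
      ntip <- length(tr$tip.label)
      root <- ntip + 1L
      node_seq <- vector("list", ntip + tr$Nnode)
      node_seq[[root]] <- root_cod
      # preorder over edges
      eo <- ape::reorder.phylo(tr, "cladewise")
      for (k in seq_len(nrow(eo$edge))) {
        par <- eo$edge[k, 1]
        ch <- eo$edge[k, 2]
        node_seq[[ch]] <- mutate_codons(node_seq[[par]],
                                        eo$edge.length[k], config$ka_ratio)
      }
      for (t_ in seq_len(ntip))
        seqs[[tr$tip.label[t_]]] <- node_seq[[t_]]
    }
  }
  sequences <- vapply(seqs, codons_to_seq, character(1))

  positions <- gene_positions(families)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (sp in sort(unique(positions$species))) {
      g <- positions$gene[positions$species == sp]
      write_fasta(sequences[g], file.path(outdir,
                                          paste0(sp, ".cds.fna")))
    }
    write_tsv(positions[, c("chrom", "start", "end", "gene", "strand")],
              file.path(outdir, "gene_positions.tsv"))
    write_truth(families, outdir)
  }
  list(sequences = sequences, positions = positions, families = families)
}

#' Gene-rank positions of all simulated genes
#'
#' Families occupy chromosomes in index order; polyploid subgenomes sit on
#' homoeologous chromosomes preserving order, and tandem copies are
#' adjacent to their source, so synteny blocks exist by construction.
#' Coordinates are 0-based half-open ordinal gene ranks per chromosome.
#'
#' @param families list of `true_family` objects.
#' @return data.frame: species, chrom, start, end, gene, strand.
#' @export
gene_positions <- function(families) {
  lv <- do.call(rbind, lapply(families, function(f)
    if (!f$empty && nrow(f$leaves)) f$leaves else NULL))
  o <- order(lv$species, lv$chrom, lv$pos_key, lv$gene, method = "radix")
  lv <- lv[o, , drop = FALSE]
  rank0 <- stats::ave(seq_len(nrow(lv)),
                      paste(lv$species, lv$chrom, sep = "\r"),
                      FUN = function(x) seq_along(x) - 1L)
  data.frame(species = lv$species,
             chrom = paste0(lv$species, "_chr", lv$chrom),
             start = as.integer(rank0), end = as.integer(rank0) + 1L,
             gene = lv$gene, strand = "+", stringsAsFactors = FALSE)
}

# truth log + true trees, for ground-truth-aware tests and reports
write_truth <- function(families, outdir) {
  rows <- do.call(rbind, lapply(families, function(f) {
    if (f$empty || nrow(f$leaves) == 0L)
      return(data.frame(family = f$id, gene = NA_character_,
                        species = NA_character_, empty = TRUE))
    data.frame(family = f$id, gene = f$leaves$gene,
               species = f$leaves$species, empty = FALSE)
  }))
  write_tsv(rows, file.path(outdir, "truth_families.tsv"))
  trees <- vapply(families, function(f) {
    if (is.null(f$tree)) "" else ape::write.tree(f$tree)
  }, character(1))
  writeLines(paste(vapply(families, `[[`, character(1), "id"), trees,
                   sep = "\t"),
             file.path(outdir, "true_trees.nwk"))
  invisible(outdir)
}

#' Within-family similarity match table
#'
#' Stands in for an all-by-all protein search in simulation mode: for every
#' ordered pair of genes within a family, reports percent nucleotide
#' identity, full query coverage (the simulator generates no indels), and
#' an identity-weighted score. Downstream filtering ([top_pairs()]) treats
#' it exactly like an external match table.
#'
#' @param emitted result of [emit_sequences()].
#' @return data.frame: query, subject, identity, coverage, score.
#' @export
sim_match_table <- function(emitted) {
  seqs <- emitted$sequences
  raws <- lapply(seqs, charToRaw)
  rows <- vector("list", length(emitted$families))
  for (i in seq_along(emitted$families)) {
    fam <- emitted$families[[i]]
    if (fam$empty || nrow(fam$leaves) < 2L) next
    g <- fam$leaves$gene
    g <- g[g %in% names(seqs)]
    n <- length(g)
    if (n < 2L) next
    qq <- ss <- character(0)
    id <- numeric(0)
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        pid <- 100 * mean(raws[[g[a]]] == raws[[g[b]]])
        qq <- c(qq, g[a], g[b])
        ss <- c(ss, g[b], g[a])
        id <- c(id, pid, pid)
      }
    }
    rows[[i]] <- data.frame(query = qq, subject = ss, identity = id,
                            coverage = 100, score = id,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(query = character(0), subject = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      score = numeric(0))
  rownames(out) <- NULL
  out
}
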