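# Ks-filtered homology graphs, Markov clustering, and profile-score
# refinement of gene families.

#' Build a Ks-filtered homology graph
#'
#' Keeps a gene pair as an edge iff its Ks does not exceed the cutoff for
#' its species pair; edge weight is the linear decay `1 - Ks/cutoff`,
#' floored at `eps` so surviving edges always carry positive weight.
#'
#' @param estimates data.frame from [ng86_pairs()] (columns `gene_a`,
#'   `gene_b`, `species_a`, `species_b`, `Ks`, `valid`).
#' @param cutoffs named numeric vector of per-species-pair cutoffs; names
#'   are `"<spA>|<spB>"` with species sorted alphabetically (see
#'   [species_pair_key()]).
#' @param nodes optional character vector of all gene ids (isolated genes
#'   are kept as vertices so the later rescan can see them).
#' @param eps weight floor (default 1e-3).
#' @return an `igraph` undirected graph with vertex attribute `species`
#'   and edge attributes `weight` and `Ks`.
#' @export
build_graph <- function(estimates, cutoffs, nodes = NULL, eps = 1e-3) {
  est <- estimates[estimates$valid & !is.na(estimates$Ks), , drop = FALSE]
  key <- species_pair_key(est$species_a, est$species_b)
  missing_pairs <- setdiff(unique(key), names(cutoffs))
  if (length(missing_pairs))
    stop("no Ks cutoff supplied for species pair(s): ",
         paste(missing_pairs, collapse = ", "))
  cut <- unname(cutoffs[key])
  keep <- est$Ks <= cut
  est <- est[keep, , drop = FALSE]
  w <- pmax(eps, 1 - est$Ks / cut[keep])
  verts <- unique(c(nodes, estimates$gene_a, estimates$gene_b))
  verts <- sort(verts, method = "radix")
  g <- igraph::graph_from_data_frame(
    data.frame(from = est$gene_a, to = est$gene_b, weight = w, Ks = est$Ks,
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, species = gene_species(verts),
                          stringsAsFactors = FALSE))
  igraph::simplify(g, edge.attr.comb = list(weight = "max", Ks = "min"))
}

#' Canonical species-pair key
#' @param a,b species id vectors.
#' @return `"<spA>|<spB>"` with the two species sorted.
#' @export
species_pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Markov clustering of a weighted homology graph
#'
#' Classic MCL on the column-stochastic transition matrix with self-loops
#' (self-loop weight = maximum incident edge weight): alternate expansion
#' (matrix squaring) and inflation (entrywise power, column
#' renormalization), pruning entries below `prune` for sparsity, until the
#' maximum entrywise change drops below `tol` or `max_iter` is reached.
#' Clusters are the connected components of the converged matrix's
#' non-zero structure; every vertex lands in exactly one cluster.
#'
#' @param graph an `igraph` graph from [build_graph()].
#' @param inflation inflation exponent (> 1; default 1.2, the value used
#'   for legume-scale family construction).
#' @param tol convergence threshold on the max entry change (default 1e-6).
#' @param max_iter iteration cap (default 200).
#' @param prune drop matrix entries below this during iteration.
#' @return list with `membership` (named integer vector, gene -> cluster),
#'   `clusters` (list of character vectors), `iterations`, `converged`.
#' @export
mcl_cluster <- function(graph, inflation = 1.2, tol = 1e-6, max_iter = 200L,
                        prune = 1e-5) {
  if (inflation <= 1) stop("inflation must exceed 1")
  n <- igraph::vcount(graph)
  if (n == 0L) stop("empty graph")
  nm <- igraph::V(graph)$name
  A <- igraph::as_adjacency_matrix(graph, attr = "weight", sparse = TRUE)
  A <- methods::as(A, "CsparseMatrix")
  # self loops: max incident weight (1 for isolated vertices)
  mx <- apply_max_col(A)
  mx[mx <= 0] <- 1
  diag(A) <- mx
  M <- normalize_cols(A)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M                       # expansion
    M2@x <- M2@x^inflation              # inflation
    M2 <- Matrix::drop0(M2)
    M2@x[M2@x < prune] <- 0
    M2 <- Matrix::drop0(M2)
    M2 <- normalize_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; returning current interpretation")
  # components of the non-zero structure
  gM <- igraph::graph_from_adjacency_matrix(M != 0, mode = "max",
                                            diag = FALSE)
  comp <- igraph::components(gM)$membership
  names(comp) <- nm
  # renumber clusters deterministically by smallest member name
  first <- vapply(split(nm, comp), min, character(1))
  relabel <- match(names(sort(first)), names(first))
  new_id <- match(comp, as.integer(names(first))[relabel])
  membership <- stats::setNames(new_id, nm)
  clusters <- lapply(split(nm, membership), sort)
  list(membership = membership, clusters = unname(clusters),
       iterations = it, converged = converged)
}

normalize_cols <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(x = 1 / cs)
}

apply_max_col <- function(A) {
  # max per column of a sparse nonneg matrix (0 for empty columns)
  out <- numeric(ncol(A))
  A <- methods::as(A, "CsparseMatrix")
  p <- A@p
  for (j in seq_len(ncol(A))) {
    if (p[j + 1L] > p[j]) out[j] <- max(A@x[(p[j] + 1L):p[j + 1L]])
  }
  out
}

#' Positional log-odds profile of a gene family
#'
#' Families produced by the simulator (and real-data families with supplied
#' alignments) are positionally aligned, so the profile is a per-column
#' amino-acid log-odds matrix against a uniform background with
#' pseudocount `alpha`. It stands behind the same 40%-of-median scoring
#' architecture that profile HMMs provide in large-scale family pipelines.
#'
#' @param aa_seqs character vector of equal-length amino-acid sequences.
#' @param alpha Laplace pseudocount (default 1; keeps one stray member in
#'   a small family from dominating its own columns).
#' @return matrix (20 + 1 rows: amino acids and `X`) x columns, log2 odds.
#' @export
family_profile <- function(aa_seqs, alpha = 1) {
  if (length(aa_seqs) < 1L) stop("need at least one sequence")
  L <- unique(nchar(aa_seqs))
  if (length(L) != 1L)
    stop("family sequences must be positionally aligned (equal length)")
  alph <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
            "P", "Q", "R", "S", "T", "V", "W", "Y", "X")
  m <- do.call(rbind, strsplit(aa_seqs, ""))
  m[!m %in% alph] <- "X"
  prof <- matrix(0, nrow = length(alph), ncol = L, dimnames = list(alph))
  for (j in seq_len(L)) {
    cnt <- table(factor(m[, j], levels = alph))
    p <- (as.numeric(cnt) + alpha) / (length(aa_seqs) + alpha * length(alph))
    prof[, j] <- log2(p / (1 / 20))
  }
  prof
}

#' Score a protein against a family profile
#'
#' Sum of per-column log-odds over the aligned prefix, with an affine
#' penalty (`gap_open` + `gap_extend` per extra column) for any length
#' difference.
#'
#' @param aa_seq amino-acid string.
#' @param profile matrix from [family_profile()].
#' @param gap_open,gap_extend affine length-mismatch penalty
#'   (defaults -2 and -0.5).
#' @return numeric score (bits).
#' @export
profile_score <- function(aa_seq, profile, gap_open = -2, gap_extend = -0.5) {
  L <- ncol(profile)
  chars <- strsplit(aa_seq, "")[[1]]
  n <- length(chars)
  k <- min(n, L)
  idx <- match(chars[seq_len(k)], rownames(profile))
  idx[is.na(idx)] <- match("X", rownames(profile))
  s <- sum(profile[cbind(idx, seq_len(k))])
  d <- abs(n - L)
  if (d > 0) s <- s + gap_open + gap_extend * (d - 1)
  s
}

#' Translate CDS strings to amino acids
#' @param seqs named character vector of nucleotide strings.
#' @return named character vector of amino-acid strings.
#' @export
translate_cds <- function(seqs) {
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(seqs), if.fuzzy.codon = "solve"))
  stats::setNames(aa, names(seqs))
}

#' Refine families by profile-score outliers and whole-proteome rescan
#'
#' Round 1 scores every member against its family profile and removes
#' members scoring below `threshold` (default 40%) of the family's median
#' member score. Round 2 rebuilds the profiles from the survivors, scores
#' every protein in the proteome (including genes never clustered, e.g.
#' those dropped by the Ks filter), assigns each protein to its
#' best-scoring family when that score reaches the threshold fraction of
#' the family's median, and finally drops sub-threshold members once more.
#' A protein joins at most one family; families reduced below two members
#' are dissolved and their genes returned to the unassigned pool.
#'
#' @param families list of character vectors of gene ids (or the
#'   `clusters` element of [mcl_cluster()]).
#' @param proteins named character vector of amino-acid sequences for the
#'   whole proteome.
#' @param threshold fraction of the median score (default 0.4).
#' @return list with `families` (refined list, named F0001-style in input
#'   order), `unassigned` (character vector), `log` (data.frame of removal
#'   and recapture events).
#' @export
refine_families <- function(families, proteins, threshold = 0.4) {
  stopifnot(is.list(families), !is.null(names(proteins)))
  log_rows <- list()
  note <- function(gene, family, action)
    log_rows[[length(log_rows) + 1L]] <<-
      data.frame(gene = gene, family = family, action = action,
                 stringsAsFactors = FALSE)

  fam_ids <- sprintf("FAM%04d", seq_along(families))
  fams <- stats::setNames(families, fam_ids)

  # round 1: score members, drop < threshold * median
  for (fid in names(fams)) {
    mem <- intersect(fams[[fid]], names(proteins))
    if (length(mem) < 2L) { fams[[fid]] <- mem; next }
    prof <- family_profile(unname(proteins[mem]))
    sc <- vapply(proteins[mem], profile_score, numeric(1), profile = prof)
    med <- stats::median(sc)
    drop <- mem[sc < threshold * med]
    if (length(drop)) {
      for (g in drop) note(g, fid, "removed_round1")
      fams[[fid]] <- setdiff(mem, drop)
    } else fams[[fid]] <- mem
  }
  alive <- names(fams)[lengths(fams) >= 2L]

  # round 2: rebuild profiles, rescan the whole proteome
  profs <- lapply(fams[alive], function(mem)
    family_profile(unname(proteins[mem])))
  meds <- vapply(alive, function(fid) {
    sc <- vapply(proteins[fams[[fid]]], profile_score, numeric(1),
                 profile = profs[[fid]])
    stats::median(sc)
  }, numeric(1))

  prot_ids <- sort(names(proteins), method = "radix")
  scores <- score_matrix(proteins[prot_ids], profs)
  # best family per protein, subject to the per-family threshold
  assign <- rep(NA_character_, length(prot_ids))
  names(assign) <- prot_ids
  if (length(alive)) {
    ok <- sweep(scores, 2, threshold * meds, ">=")
    for (i in seq_along(prot_ids)) {
      cand <- which(ok[i, ])
      if (length(cand)) {
        best <- cand[which.max(scores[i, cand])]
        assign[i] <- alive[best]
      }
    }
  }
  old_assign <- rep(NA_character_, length(prot_ids))
  names(old_assign) <- prot_ids
  for (fid in alive) old_assign[fams[[fid]]] <- fid

  new_fams <- lapply(alive, function(fid)
    sort(prot_ids[!is.na(assign) & assign == fid], method = "radix"))
  names(new_fams) <- alive
  for (i in seq_along(prot_ids)) {
    g <- prot_ids[i]
    if (!identical(assign[[g]], old_assign[[g]])) {
      if (is.na(old_assign[[g]]) && !is.na(assign[[g]]))
        note(g, assign[[g]], "recaptured_round2")
      else if (!is.na(old_assign[[g]]) && is.na(assign[[g]]))
        note(g, old_assign[[g]], "removed_round2")
      else if (!is.na(assign[[g]]))
        note(g, assign[[g]], "reassigned_round2")
    }
  }
  keep <- lengths(new_fams) >= 2L
  for (fid in names(new_fams)[!keep])
    for (g in new_fams[[fid]]) note(g, fid, "dissolved")
  new_fams <- new_fams[keep]
  unassigned <- setdiff(prot_ids, unlist(new_fams, use.names = FALSE))
  lg <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(gene = character(0), family = character(0),
               action = character(0))
  list(families = new_fams, unassigned = sort(unassigned, method = "radix"),
       log = lg)
}

# score all proteins against all profiles via one sparse matrix product;
# profiles are padded to a common length and the affine length penalty is
# added afterwards
score_matrix <- function(proteins, profs) {
  if (length(profs) == 0L)
    return(matrix(numeric(0), nrow = length(proteins), ncol = 0))
  alph_n <- nrow(profs[[1]])
  Ls <- vapply(profs, ncol, integer(1))
  Lmax <- max(Ls, vapply(proteins, nchar, integer(1)))
  P <- matrix(0, nrow = length(profs), ncol = alph_n * Lmax)
  for (f in seq_along(profs)) {
    pr <- profs[[f]]
    P[f, seq_len(alph_n * ncol(pr))] <- as.numeric(pr)
  }
  rn <- rownames(profs[[1]])
  xi <- match("X", rn)
  jlist <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    chars <- strsplit(proteins[[i]], "")[[1]]
    idx <- match(chars, rn)
    idx[is.na(idx)] <- xi
    jlist[[i]] <- (seq_along(chars) - 1L) * alph_n + idx
  }
  ii <- rep.int(seq_along(proteins), lengths(jlist))
  jj <- unlist(jlist, use.names = FALSE)
  X <- Matrix::sparseMatrix(i = ii, j = jj, x = 1,
                            dims = c(length(proteins), alph_n * Lmax))
  S <- as.matrix(X %*% t(P))
  # affine penalty for length differences
  n_i <- vapply(proteins, nchar, integer(1))
  for (f in seq_along(profs)) {
    d <- abs(n_i - Ls[f])
    pen <- ifelse(d > 0, -2 + -0.5 * (d - 1), 0)
    # truncate scoring to the aligned prefix: subtract profile columns
    # beyond the protein length is already handled because X has no
    # entries there; extra protein columns beyond the profile have zero
    # profile weight. Only the penalty is added.
    S[, f] <- S[, f] + pen
  }
  dimnames(S) <- list(names(proteins), names(profs))
  S
}
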