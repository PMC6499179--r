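# Codon-level lookup tables shared by the NG86 estimator and the sequence
# simulator. Built once per session from the standard genetic code and cached.

.wgd_cache <- new.env(parent = emptyenv())

.NT <- c("A", "C", "G", "T")

#' @keywords internal
codon_index <- function(codon) {
  # 1-based index in the 64-codon table, ordered A,C,G,T at each position
  m <- match(strsplit(codon, "")[[1]], .NT)
  if (anyNA(m)) return(NA_integer_)
  (m[1] - 1L) * 16L + (m[2] - 1L) * 4L + m[3]
}

all_codons <- function() {
  g <- expand.grid(p3 = .NT, p2 = .NT, p1 = .NT, stringsAsFactors = FALSE)
  paste0(g$p1, g$p2, g$p3)
}

# Single-nucleotide neighbors of a codon (9 per codon)
.codon_neighbors <- function(codon) {
  nts <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (nt in setdiff(.NT, nts[pos])) {
      x <- nts
      x[pos] <- nt
      out <- c(out, paste(x, collapse = ""))
    }
  }
  out
}

#' NG86 codon tables
#'
#' Builds (and caches) the per-codon synonymous site counts and the 64 x 64
#' matrices of pathway-averaged synonymous/nonsynonymous difference counts
#' used by [ng86()]. Synonymous sites per codon follow the Nei-Gojobori
#' counting rule: at each codon position, the fraction of the three possible
#' single-nucleotide changes that preserve the encoded amino acid (changes
#' producing a stop codon count as nonsynonymous). Multi-position codon
#' differences are averaged with equal weight over all minimal mutational
#' pathways that do not pass through a stop codon; if every pathway is
#' blocked by stops, all pathways are used with stop-passing steps counted
#' as nonsynonymous.
#'
#' @return A list with elements `codons` (character 64), `aa` (amino acids,
#'   `*` for stop), `syn_sites` (numeric 64), `sd` and `nd` (64 x 64
#'   matrices), `syn_neighbors` and `nonsyn_neighbors` (lists of integer
#'   vectors of codon indices, sense codons only).
#' @keywords internal
ng86_tables <- function() {
  if (!is.null(.wgd_cache$ng86)) return(.wgd_cache$ng86)

  codons <- all_codons()
  gc_map <- Biostrings::GENETIC_CODE
  aa <- unname(gc_map[codons])
  is_stop <- aa == "*"

  # per-codon synonymous sites
  syn_sites <- numeric(64)
  syn_nb <- vector("list", 64)
  nonsyn_nb <- vector("list", 64)
  for (i in seq_len(64)) {
    if (is_stop[i]) {
      syn_sites[i] <- NA_real_
      next
    }
    nb <- .codon_neighbors(codons[i])
    nb_idx <- vapply(nb, codon_index, integer(1))
    nb_aa <- aa[nb_idx]
    syn <- nb_aa == aa[i]              # stop neighbors are not synonymous
    syn_sites[i] <- sum(syn) / 3
    syn_nb[[i]] <- nb_idx[syn]
    nonsyn_nb[[i]] <- nb_idx[!syn & nb_aa != "*"]
  }

  # pathway-averaged difference counts for every sense-codon pair
  sd <- matrix(NA_real_, 64, 64)
  nd <- matrix(NA_real_, 64, 64)
  step_counts <- function(path_codons) {
    # path_codons: integer codon indices visited in order
    s <- 0
    n <- 0
    for (k in seq_len(length(path_codons) - 1L)) {
      a1 <- aa[path_codons[k]]
      a2 <- aa[path_codons[k + 1L]]
      if (a1 == a2 && a1 != "*") s <- s + 1 else n <- n + 1
    }
    c(s, n)
  }
  perms2 <- list(1:2, 2:1)
  perms3 <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                 c(3, 1, 2), c(3, 2, 1))
  split3 <- function(codon) strsplit(codon, "")[[1]]
  for (i in seq_len(64)) {
    if (is_stop[i]) next
    ci <- split3(codons[i])
    for (j in seq_len(64)) {
      if (is_stop[j]) next
      if (j < i) { sd[i, j] <- sd[j, i]; nd[i, j] <- nd[j, i]; next }
      cj <- split3(codons[j])
      diff_pos <- which(ci != cj)
      ndiff <- length(diff_pos)
      if (ndiff == 0L) { sd[i, j] <- 0; nd[i, j] <- 0; next }
      perms <- switch(ndiff, list(1L), perms2, perms3)
      paths <- lapply(perms, function(ord) {
        cur <- ci
        idx <- integer(ndiff + 1L)
        idx[1] <- i
        for (k in seq_len(ndiff)) {
          p <- diff_pos[ord[k]]
          cur[p] <- cj[p]
          idx[k + 1L] <- codon_index(paste(cur, collapse = ""))
        }
        idx
      })
      through_stop <- vapply(paths, function(p) any(aa[p] == "*"), logical(1))
      use <- if (all(through_stop)) paths else paths[!through_stop]
      cnt <- vapply(use, step_counts, numeric(2))
      sd[i, j] <- mean(cnt[1, ])
      nd[i, j] <- mean(cnt[2, ])
    }
  }

  sense <- which(!is_stop)
  .wgd_cache$ng86 <- list(codons = codons, aa = aa, is_stop = is_stop,
                          sense = sense, syn_sites = syn_sites,
                          sd = sd, nd = nd,
                          syn_neighbors = syn_nb,
                          nonsyn_neighbors = nonsyn_nb)
  .wgd_cache$ng86
}

#' Convert a nucleotide string to codon indices
#'
#' Codons containing characters outside A/C/G/T, and stop codons, map to
#' `NA` and are skipped by the estimator.
#'
#' @param seq single nucleotide string, length a multiple of 3.
#' @return integer vector of codon indices (NA for ambiguous/stop codons).
#' @keywords internal
seq_to_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("sequence length ", n, " is not a multiple of 3")
  tab <- ng86_tables()
  nts <- match(strsplit(toupper(seq), "")[[1]], .NT)
  ncod <- n %/% 3L
  dim(nts) <- c(3L, ncod)
  idx <- (nts[1, ] - 1L) * 16L + (nts[2, ] - 1L) * 4L + nts[3, ]
  st <- tab$is_stop[idx]
  st[is.na(st)] <- FALSE
  idx[st] <- NA_integer_
  idx
}

#' @keywords internal
codons_to_seq <- function(idx) {
  tab <- ng86_tables()
  paste(tab$codons[idx], collapse = "")
}
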