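#' Nei-Gojobori (1986) synonymous and nonsynonymous distances
#'
#' Estimates Ks and Ka for one pair of aligned in-frame coding sequences by
#' the unweighted-pathway counting method: synonymous sites are counted per
#' codon as the fraction of single-nucleotide changes that preserve the
#' amino acid (averaged between the two sequences), observed differences in
#' codons differing at several positions are averaged with equal weight over
#' all minimal mutational pathways avoiding stop codons, and the resulting
#' proportions are corrected for multiple hits with the Jukes-Cantor
#' formula, Ks = -(3/4) log(1 - 4 ps / 3).
#'
#' Codons containing non-ACGT characters (or stop codons) in either sequence
#' are excluded from all counts. The estimate is flagged invalid when the
#' correction is undefined (1 - 4 ps / 3 <= 0, saturation) or when no
#' synonymous sites remain.
#'
#' @param seq_a,seq_b aligned nucleotide strings of equal length, divisible
#'   by 3. Alternatively pre-computed codon index vectors from
#'   [seq_to_codons()].
#' @return A one-row data.frame with columns `S`, `N` (site counts), `Sd`,
#'   `Nd` (pathway-averaged difference counts), `ps`, `pn`, `Ks`, `Ka`, and
#'   `valid`.
#' @examples
#' ng86("TTTGATAAA", "TTTGATAAG")
#' @export
ng86 <- function(seq_a, seq_b) {
  a <- if (is.character(seq_a)) seq_to_codons(seq_a) else as.integer(seq_a)
  b <- if (is.character(seq_b)) seq_to_codons(seq_b) else as.integer(seq_b)
  if (length(a) != length(b))
    stop("sequences differ in length (", length(a), " vs ", length(b),
         " codons); an aligned in-frame pair is required")
  ng86_codons(a, b)
}

#' @keywords internal
ng86_codons <- function(a, b) {
  tab <- ng86_tables()
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]
  b <- b[keep]
  ncod <- length(a)
  if (ncod == 0L) {
    return(data.frame(S = 0, N = 0, Sd = 0, Nd = 0, ps = NA_real_,
                      pn = NA_real_, Ks = NA_real_, Ka = NA_real_,
                      valid = FALSE))
  }
  S <- (sum(tab$syn_sites[a]) + sum(tab$syn_sites[b])) / 2
  N <- 3 * ncod - S
  Sd <- sum(tab$sd[cbind(a, b)])
  Nd <- sum(tab$nd[cbind(a, b)])
  ps <- if (S > 0) Sd / S else NA_real_
  pn <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    arg <- 1 - 4 * p / 3
    if (arg <= 0) return(NA_real_)
    -0.75 * log(arg)
  }
  Ks <- jc(ps)
  Ka <- jc(pn)
  data.frame(S = S, N = N, Sd = Sd, Nd = Nd, ps = ps, pn = pn,
             Ks = Ks, Ka = Ka, valid = !is.na(Ks) && S > 0)
}

#' NG86 estimates for a table of gene pairs
#'
#' @param pairs data.frame with columns `gene_a`, `gene_b` (ids present in
#'   `seqs`).
#' @param seqs named character vector or list of nucleotide strings, or a
#'   named list of codon-index vectors.
#' @return `pairs` with the [ng86()] columns appended, plus `species_a` and
#'   `species_b` parsed from the gene ids (`<species>.<rest>`).
#' @export
ng86_pairs <- function(pairs, seqs) {
  if (nrow(pairs) == 0L) {
    est0 <- ng86_codons(integer(0), integer(0))[0, ]
    return(cbind(pairs, species_a = character(0), species_b = character(0),
                 est0))
  }
  codons <- if (is.list(seqs) && !is.character(seqs[[1]])) {
    seqs
  } else {
    lapply(as.list(seqs), seq_to_codons)
  }
  est <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    ng86_codons(codons[[pairs$gene_a[i]]], codons[[pairs$gene_b[i]]])
  }))
  out <- cbind(pairs,
               species_a = gene_species(pairs$gene_a),
               species_b = gene_species(pairs$gene_b),
               est)
  rownames(out) <- NULL
  out
}

#' Species component of a gene identifier
#'
#' Gene ids follow `<species>.<family>.<copy>`; the species is everything
#' before the first dot.
#' @param ids character vector of gene ids.
#' @return character vector of species ids.
#' @export
gene_species <- function(ids) {
  sub("\\..*$", "", ids)
}
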