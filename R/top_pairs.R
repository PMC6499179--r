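#' Filter a homology match table to top candidate pairs
#'
#' Reproduces the standard homolog-pair screen applied to all-by-all
#' protein search results before Ks estimation: per query, keep the best
#' two non-self subjects by score among matches with query coverage of at
#' least `min_coverage` percent and identity of at least `min_identity`
#' percent, then deduplicate unordered pairs. With `per_species = TRUE`
#' the top-two rule is applied separately within each subject species, so
#' that every species pair retains its best matches (required when
#' per-species-pair histograms are the goal).
#'
#' @param matches data.frame with columns `query`, `subject`, `identity`,
#'   `coverage`, `score` (identity/coverage in percent).
#' @param min_identity identity threshold in percent (default 60).
#' @param min_coverage query-coverage threshold in percent (default 50).
#' @param top number of subjects kept per query (default 2).
#' @param per_species apply the `top` rule per subject species
#'   (default FALSE).
#' @return data.frame with columns `gene_a`, `gene_b` (unordered,
#'   `gene_a < gene_b`), deduplicated and sorted.
#' @export
top_pairs <- function(matches, min_identity = 60, min_coverage = 50,
                      top = 2L, per_species = FALSE) {
  req <- c("query", "subject", "identity", "coverage", "score")
  miss <- setdiff(req, names(matches))
  if (length(miss))
    stop("match table is missing required column(s): ",
         paste(miss, collapse = ", "))
  empty <- data.frame(gene_a = character(0), gene_b = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(matches) == 0L) return(empty)
  m <- matches[matches$query != matches$subject &
                 matches$coverage >= min_coverage &
                 matches$identity >= min_identity, , drop = FALSE]
  if (nrow(m) == 0L) return(empty)
  grp <- if (per_species) {
    paste(m$query, gene_species(m$subject), sep = "\r")
  } else {
    m$query
  }
  # stable deterministic order: by group, decreasing score, subject id
  o <- order(grp, -m$score, m$subject, method = "radix")
  m <- m[o, , drop = FALSE]
  grp <- grp[o]
  # a subject listed several times for one query counts once (best score)
  dup <- duplicated(paste(m$query, m$subject, sep = "\r"))
  m <- m[!dup, , drop = FALSE]
  grp <- grp[!dup]
  rank <- stats::ave(seq_len(nrow(m)), grp, FUN = seq_along)
  m <- m[rank <= top, , drop = FALSE]
  a <- pmin(m$query, m$subject)
  b <- pmax(m$query, m$subject)
  key <- !duplicated(paste(a, b, sep = "\r"))
  out <- data.frame(gene_a = a[key], gene_b = b[key],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
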