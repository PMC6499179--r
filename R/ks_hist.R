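#' Ks histogram over [0, 2]
#'
#' Bins valid Ks estimates into uniform left-closed, right-open bins over
#' the interval \\[0, 2\\] (the last bin is closed). Values outside \\[0, 2\\]
#' and invalid estimates are excluded, mirroring the standard practice of
#' restricting Ks analyses to the range where the estimator is informative.
#'
#' @param ks numeric vector of Ks values, or a data.frame with columns `Ks`
#'   and `valid` as returned by [ng86_pairs()].
#' @param bin_width bin width; must divide 2 evenly (default 0.05, 40 bins).
#' @param provenance tag recording how the pairs were obtained
#'   (`"blast-pairs"`, `"synteny-pairs"`, `"truth-pairs"`).
#' @param label species-pair label carried into downstream reports.
#' @return An object of class `ks_histogram`: list with `breaks`, `mids`,
#'   `counts`, `bin_width`, `provenance`, `label`, and `empty` flag.
#' @export
ks_histogram <- function(ks, bin_width = 0.05, provenance = "blast-pairs",
                         label = NA_character_) {
  if (is.data.frame(ks)) {
    ks <- ks$Ks[ks$valid]
  }
  nb <- 2 / bin_width
  if (abs(nb - round(nb)) > 1e-9)
    stop("bin_width must divide the interval [0, 2] evenly")
  nb <- as.integer(round(nb))
  ks <- ks[!is.na(ks) & ks >= 0 & ks <= 2]
  breaks <- seq(0, 2, length.out = nb + 1L)
  idx <- pmin(findInterval(ks, breaks, rightmost.closed = TRUE), nb)
  counts <- tabulate(idx, nbins = nb)
  structure(list(breaks = breaks,
                 mids = (breaks[-1] + breaks[-(nb + 1L)]) / 2,
                 counts = counts,
                 bin_width = bin_width,
                 provenance = provenance,
                 label = label,
                 empty = length(ks) == 0L),
            class = "ks_histogram")
}

#' @export
print.ks_histogram <- function(x, ...) {
  cat("Ks histogram (", x$provenance, ") ",
      if (!is.na(x$label)) paste0("[", x$label, "] ") else "",
      sum(x$counts), " values in ", length(x$counts), " bins of width ",
      x$bin_width, "\n", sep = "")
  invisible(x)
}

#' Modal Ks peak of a histogram
#'
#' Returns the bin center with the highest count at or above
#' `exclude_below`. The exclusion floor (default 0.05) skips the near-zero
#' shoulder produced by recent tandem duplications, which otherwise
#' dominates self-comparison histograms. The candidate mode is accepted as
#' a peak only under amplitude dominance: its count must strictly exceed
#' every bin count below the exclusion floor. A decaying tandem shoulder
#' therefore yields a "no peak" result rather than a spurious mode on its
#' flank, while a genuine WGD/speciation burst (which outnumbers the
#' shoulder at its mode) is retained. Ties between bins of equal count are
#' broken toward the smaller Ks.
#'
#' @param hist a [ks_histogram()].
#' @param exclude_below lower bound of the search window (default 0.05).
#' @param upper upper bound of the search window (default 2).
#' @return An object of class `ks_peak`: list with `mode` (bin center, NA
#'   if no peak), `amplitude`, `bin_width`, and `found` flag.
#' @export
modal_peak <- function(hist, exclude_below = 0.05, upper = 2) {
  stopifnot(inherits(hist, "ks_histogram"))
  in_win <- hist$mids >= exclude_below & hist$mids <= upper
  no_peak <- structure(list(mode = NA_real_, amplitude = NA_real_,
                            bin_width = hist$bin_width, found = FALSE),
                       class = "ks_peak")
  if (!any(in_win) || all(hist$counts[in_win] == 0L)) return(no_peak)
  cand <- which(in_win)[which.max(hist$counts[in_win])]  # ties -> smaller Ks
  below <- hist$mids < exclude_below
  shoulder_max <- if (any(below)) max(hist$counts[below]) else 0L
  if (hist$counts[cand] <= shoulder_max) return(no_peak)
  structure(list(mode = hist$mids[cand],
                 amplitude = hist$counts[cand],
                 bin_width = hist$bin_width,
                 found = TRUE),
            class = "ks_peak")
}

#' @export
print.ks_peak <- function(x, ...) {
  if (x$found) {
    cat("Ks peak at ", x$mode, " (amplitude ", x$amplitude, ")\n", sep = "")
  } else {
    cat("no Ks peak\n")
  }
  invisible(x)
}

#' Per-species-pair Ks cutoff from a modal peak
#'
#' The homology-graph cutoff for a species pair is 1.5 times the modal Ks
#' of that pair's histogram; pairs older than the cutoff are discarded
#' before clustering so that families span the most recent shared peak
#' (WGD or speciation) but not older duplications. When no peak was found
#' the configurable fallback (default 2, the histogram ceiling) is used.
#'
#' @param peak a [modal_peak()] result.
#' @param multiplier cutoff multiplier (default 1.5).
#' @param fallback cutoff used when `peak` is a no-peak result.
#' @return numeric cutoff.
#' @export
ks_cutoff <- function(peak, multiplier = 1.5, fallback = 2) {
  stopifnot(inherits(peak, "ks_peak"))
  if (!peak$found) return(fallback)
  multiplier * peak$mode
}

#' Write a Ks histogram as TSV
#' @param hist a [ks_histogram()].
#' @param path output file.
#' @export
write_ks_histogram <- function(hist, path) {
  df <- data.frame(bin_start = hist$breaks[-length(hist$breaks)],
                   bin_end = hist$breaks[-1],
                   count = hist$counts)
  write_tsv(df, path)
  invisible(path)
}
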