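# Synthetic species histories: timed speciation / polyploidy / extinction
# events with per-lineage substitution-rate multipliers and karyotype
# bookkeeping. Times are ages before the present, in units such that a
# branch of age t on a rate-1 lineage accumulates an expected Ks of t.

#' Build and validate a species history
#'
#' Events are replayed from the oldest to the newest while tracking which
#' lineages are alive and their haploid chromosome numbers. A speciation
#' replaces a lineage by two daughters; an autopolyploidy doubles a
#' lineage's karyotype in place; an allopolyploidy creates a new lineage
#' from two parents alive at that time (karyotype = sum of the parents');
#' an extinction removes a lineage.
#'
#' @param events data.frame with columns `time` (age, strictly decreasing),
#'   `kind` (`speciation`, `autopolyploidy`, `allopolyploidy`,
#'   `extinction`), `lineage` (the lineage acted on or, for allopolyploidy,
#'   created), `child1`, `child2` (speciation daughters), `parent1`,
#'   `parent2` (allopolyploidy parents), and optional `retention1`,
#'   `retention2` overriding the global duplicate-retention probability
#'   per subgenome.
#' @param rates named numeric vector of positive rate multipliers, one per
#'   lineage (expected synonymous substitutions per unit time, relative to
#'   a rate-1 reference).
#' @param base_n haploid chromosome number of the root lineage (default 7).
#' @param root root lineage id (default `"root"`).
#' @return An object of class `species_history`: list with `events`,
#'   `rates`, `base_n`, `root`, `extant` (lineages alive at the present)
#'   and `karyotypes` (haploid n per lineage, final state).
#' @export
build_history <- function(events, rates, base_n = 7L, root = "root") {
  need <- c("time", "kind", "lineage")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("events table is missing column(s): ", paste(miss, collapse = ", "))
  for (cl in c("child1", "child2", "parent1", "parent2"))
    if (is.null(events[[cl]])) events[[cl]] <- NA_character_
  for (cl in c("retention1", "retention2"))
    if (is.null(events[[cl]])) events[[cl]] <- NA_real_
  if (any(diff(events$time) >= 0))
    stop("event times must strictly decrease toward the present")
  if (any(events$time <= 0))
    stop("event ages must be positive (the present is age 0)")
  if (any(rates <= 0))
    stop("rate multipliers must be positive; offending lineage(s): ",
         paste(names(rates)[rates <= 0], collapse = ", "))

  alive <- root
  karyo <- stats::setNames(as.integer(base_n), root)
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    switch(ev$kind,
      speciation = {
        if (!ev$lineage %in% alive)
          stop("speciation of lineage '", ev$lineage,
               "' which is not alive at age ", ev$time)
        if (is.na(ev$child1) || is.na(ev$child2))
          stop("speciation events need child1 and child2")
        alive <- c(setdiff(alive, ev$lineage), ev$child1, ev$child2)
        karyo[c(ev$child1, ev$child2)] <- karyo[[ev$lineage]]
      },
      autopolyploidy = {
        if (!ev$lineage %in% alive)
          stop("autopolyploidy on lineage '", ev$lineage,
               "' which is not alive at age ", ev$time)
        karyo[[ev$lineage]] <- 2L * karyo[[ev$lineage]]
      },
      allopolyploidy = {
        if (is.na(ev$parent1) || is.na(ev$parent2))
          stop("allopolyploidy events need parent1 and parent2")
        bad <- setdiff(c(ev$parent1, ev$parent2), alive)
        if (length(bad))
          stop("allopolyploidy at age ", ev$time, " references lineage(s) ",
               paste(bad, collapse = ", "),
               " not alive at that time (hybridization must postdate the ",
               "donor divergence)")
        alive <- c(alive, ev$lineage)
        karyo[[ev$lineage]] <- karyo[[ev$parent1]] + karyo[[ev$parent2]]
      },
      extinction = {
        if (!ev$lineage %in% alive)
          stop("extinction of lineage '", ev$lineage,
               "' which is not alive at age ", ev$time)
        alive <- setdiff(alive, ev$lineage)
      },
      stop("unknown event kind: ", ev$kind)
    )
  }
  missing_rates <- setdiff(alive, names(rates))
  if (length(missing_rates))
    stop("extant lineage(s) without a rate multiplier: ",
         paste(missing_rates, collapse = ", "))
  structure(list(events = events, rates = rates, base_n = as.integer(base_n),
                 root = root, extant = sort(alive), karyotypes = karyo),
            class = "species_history")
}

#' @export
print.species_history <- function(x, ...) {
  cat("species history:", nrow(x$events), "events;",
      length(x$extant), "extant lineage(s):",
      paste(x$extant, collapse = ", "), "\n")
  cat("karyotypes (n):",
      paste(names(x$karyotypes), x$karyotypes, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Simulation configuration
#'
#' Bundles the generator parameters. Defaults describe the study
#' conditions of the default allopolyploid scenario: 200 base families of
#' 300 codons, duplicate retention 0.8 after polyploidy (i.i.d. per-gene
#' fractionation), tandem duplication rate 2 per gene per unit time with
#' duplicate half-life governed by loss rate 10 (so surviving tandem pairs
#' concentrate near Ks 0), and a nonsynonymous rate 0.05 times the
#' synonymous rate.
#'
#' @param scenario one of `"allopolyploid"`, `"autopolyploid"`,
#'   `"no_wgd"`; ignored when `history` is supplied.
#' @param n_families number of base gene families.
#' @param codon_length family coding length in codons (>= 30).
#' @param retention probability that a polyploidy-derived duplicate copy
#'   survives fractionation.
#' @param local_dup_rate tandem duplication rate per gene per unit time.
#' @param local_dup_loss exponential loss rate of tandem duplicates per
#'   unit time (survival to the present = exp(-rate * age)).
#' @param ka_ratio nonsynonymous substitutions per nonsynonymous site as a
#'   fraction of the synonymous rate.
#' @param seed integer random seed.
#' @param history optional pre-built [build_history()] object.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(scenario = c("allopolyploid", "autopolyploid",
                                    "no_wgd"),
                       n_families = 200L, codon_length = 300L,
                       retention = 0.8, local_dup_rate = 2,
                       local_dup_loss = 10, ka_ratio = 0.05, seed = 1L,
                       history = NULL) {
  scenario <- match.arg(scenario)
  if (retention < 0 || retention > 1)
    stop("retention must be a probability in [0, 1]")
  if (ka_ratio < 0) stop("ka_ratio must be non-negative")
  if (codon_length < 30L)
    stop("codon_length must be at least 30 codons")
  if (n_families < 1L) stop("n_families must be positive")
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  if (is.null(history)) {
    history <- switch(scenario,
                      allopolyploid = scenario_allopolyploid(),
                      autopolyploid = scenario_autopolyploid(),
                      no_wgd = scenario_no_wgd())
  }
  structure(list(scenario = scenario, n_families = as.integer(n_families),
                 codon_length = as.integer(codon_length),
                 retention = retention, local_dup_rate = local_dup_rate,
                 local_dup_loss = local_dup_loss, ka_ratio = ka_ratio,
                 seed = seed, history = history),
            class = "sim_config")
}

#' Default allopolyploid ("relic + tetraploid sister") scenario
#'
#' A slow diploid relic lineage (rate 0.25) whose ancestor hybridized with
#' a now-extinct diploid donor to found an allotetraploid sister lineage,
#' plus a fast outgroup (rate 2.5) carrying an independent autopolyploidy.
#' Event ages are calibrated so that expected pairwise Ks values are
#' approximately 0.15 (relic vs tetraploid), 0.25 (tetraploid homoeolog
#' pair), 0.55 (relic vs outgroup), and 0.6 (outgroup homoeolog pair).
#' Karyotype starts at n = 7 and doubles to 14 at each polyploidy.
#'
#' @param t_outgroup,t_split,t_outgroup_wgd,t_hybrid,t_extinct event ages.
#' @param rate_relic,rate_donor,rate_tetra,rate_outgroup rate multipliers.
#' @return a `species_history`.
#' @export
scenario_allopolyploid <- function(t_outgroup = 0.2, t_split = 0.128,
                                   t_outgroup_wgd = 0.12, t_hybrid = 0.1195,
                                   t_extinct = 0.05,
                                   rate_relic = 0.25, rate_donor = 1,
                                   rate_tetra = 1, rate_outgroup = 2.5) {
  events <- data.frame(
    time = c(t_outgroup, t_split, t_outgroup_wgd, t_hybrid, t_extinct),
    kind = c("speciation", "speciation", "autopolyploidy",
             "allopolyploidy", "extinction"),
    lineage = c("root", "cercid_anc", "outgrp", "tetra", "donor"),
    child1 = c("cercid_anc", "relic", NA, NA, NA),
    child2 = c("outgrp", "donor", NA, NA, NA),
    parent1 = c(NA, NA, NA, "relic", NA),
    parent2 = c(NA, NA, NA, "donor", NA),
    stringsAsFactors = FALSE)
  build_history(events,
                rates = c(root = 1, cercid_anc = rate_relic,
                          relic = rate_relic, donor = rate_donor,
                          tetra = rate_tetra, outgrp = rate_outgroup))
}

#' Autopolyploidy-after-speciation scenario
#'
#' The discriminating contrast to [scenario_allopolyploid()]: the sister
#' lineage's genome doubling happens after its split from the relic, so
#' homoeolog divergence dates to the WGD itself and mined clade patterns
#' should be dominated by `[(B,B),C]` rather than `[(C,B),B]`.
#'
#' @param t_outgroup,t_split,t_outgroup_wgd,t_wgd event ages.
#' @param rate_relic,rate_tetra,rate_outgroup rate multipliers.
#' @return a `species_history`.
#' @export
scenario_autopolyploid <- function(t_outgroup = 0.2, t_split = 0.128,
                                   t_outgroup_wgd = 0.12, t_wgd = 0.07,
                                   rate_relic = 0.25, rate_tetra = 1,
                                   rate_outgroup = 2.5) {
  events <- data.frame(
    time = c(t_outgroup, t_split, t_outgroup_wgd, t_wgd),
    kind = c("speciation", "speciation", "autopolyploidy", "autopolyploidy"),
    lineage = c("root", "cercid_anc", "outgrp", "tetra"),
    child1 = c("cercid_anc", "relic", NA, NA),
    child2 = c("outgrp", "tetra", NA, NA),
    parent1 = NA_character_, parent2 = NA_character_,
    stringsAsFactors = FALSE)
  build_history(events,
                rates = c(root = 1, cercid_anc = rate_relic,
                          relic = rate_relic, tetra = rate_tetra,
                          outgrp = rate_outgroup))
}

#' Polyploidy-free two-diploid scenario (plus outgroup)
#'
#' @param t_outgroup,t_split event ages.
#' @param rate_relic,rate_sister,rate_outgroup rate multipliers.
#' @return a `species_history`.
#' @export
scenario_no_wgd <- function(t_outgroup = 0.2, t_split = 0.128,
                            rate_relic = 0.25, rate_sister = 1,
                            rate_outgroup = 2.5) {
  events <- data.frame(
    time = c(t_outgroup, t_split),
    kind = c("speciation", "speciation"),
    lineage = c("root", "cercid_anc"),
    child1 = c("cercid_anc", "relic"),
    child2 = c("outgrp", "sister"),
    parent1 = NA_character_, parent2 = NA_character_,
    stringsAsFactors = FALSE)
  build_history(events,
                rates = c(root = 1, cercid_anc = rate_relic,
                          relic = rate_relic, sister = rate_sister,
                          outgrp = rate_outgroup))
}

#' Haploid chromosome numbers of extant lineages
#' @param history a `species_history`.
#' @return named integer vector over extant lineages.
#' @export
karyotypes <- function(history) {
  stopifnot(inherits(history, "species_history"))
  history$karyotypes[history$extant]
}

# deterministic per-family seed derivation; kept below 2^31
fam_seed <- function(seed, fam, stream = 0L) {
  as.integer((as.double(seed) * 1000003 + fam * 97 + stream * 7919) %%
               2147483647)
}
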