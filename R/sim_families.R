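# Gene-family replay along a species history. Each family starts as one
# gene in the root lineage at the oldest event age; speciations copy the
# gene into both daughters, polyploidies duplicate it (duplicates survive
# fractionation with the retention probability), allopolyploidy joins one
# surviving copy from each parent lineage into the tetraploid, and tandem
# duplications arise as a Poisson process along every gene branch. Branch
# lengths accumulate as elapsed time x lineage rate multiplier, i.e. in
# expected-Ks units.

#' Simulate gene families along a species history
#'
#' @param history a [build_history()] object.
#' @param config a [sim_config()].
#' @return list of `true_family` objects: each has `id`, `tree`
#'   (`ape::phylo` with event labels `speciation`, `wgd_duplication`,
#'   `local_duplication` on internal nodes; `NULL` for families with < 2
#'   leaves), `leaves` (data.frame: gene, species, chrom, pos_key,
#'   total_len), and `empty` flag. Gene ids are `<species>.<family>.<copy>`
#'   with copies numbered along the chromosome.
#' @export
simulate_families <- function(history, config) {
  stopifnot(inherits(history, "species_history"),
            inherits(config, "sim_config"))
  lapply(seq_len(config$n_families), function(i) {
    set.seed(fam_seed(config$seed, i, 0L))
    replay_family(history, config, i)
  })
}

# one family; RNG state assumed set by the caller
replay_family <- function(history, config, fam_idx) {
  ev <- history$events
  rates <- history$rates
  fam_id <- sprintf("F%04d", fam_idx)
  base_chrom <- ((fam_idx - 1L) %% history$base_n) + 1L
  base_slot <- (fam_idx - 1L) %/% history$base_n

  # mutable family state
  nodes <- list()        # label per node
  children <- list()     # per node: list of (kind = "node"/"leaf", id, len)
  copies <- list(list(lineage = history$root, chrom = base_chrom,
                      pos_key = base_slot, parent = 0L, blen = 0,
                      total = 0))
  tandem_counter <- 0L
  karyo <- stats::setNames(history$base_n, history$root)

  new_node <- function(label) {
    nodes[[length(nodes) + 1L]] <<- label
    children[[length(nodes)]] <<- list()
    length(nodes)
  }
  attach_node <- function(parent, child, len) {
    if (parent > 0L)
      children[[parent]][[length(children[[parent]]) + 1L]] <<-
        list(kind = "node", id = child, len = len)
  }

  # advance all copies from age t_hi to t_lo, sprinkling tandem
  # duplications; a surviving tandem twin evolves independently from its
  # creation age (nested tandems within one interval are second-order at
  # these rates and are not generated)
  advance2 <- function(t_hi, t_lo) {
    lam <- config$local_dup_rate
    mu <- config$local_dup_loss
    out <- list()
    for (cp in copies) {
      r <- rates[[cp$lineage]]
      ndup <- if (lam > 0) stats::rpois(1L, lam * (t_hi - t_lo)) else 0L
      if (ndup > 0L) {
        ages <- sort(stats::runif(ndup, t_lo, t_hi), decreasing = TRUE)
        cur_age <- t_hi
        live <- cp
        for (u in ages) {
          if (stats::runif(1L) >= exp(-mu * u)) next
          live$blen <- live$blen + (cur_age - u) * r
          live$total <- live$total + (cur_age - u) * r
          nd <- new_node("local_duplication")
          attach_node(live$parent, nd, live$blen)
          tandem_counter <<- tandem_counter + 1L
          twin <- live
          twin$pos_key <- live$pos_key + 0.001 * tandem_counter
          twin$parent <- nd
          twin$blen <- 0
          live$parent <- nd
          live$blen <- 0
          # the twin evolves independently from age u to t_lo (no nested
          # tandems within the same interval: second-order at these rates)
          twin$blen <- (u - t_lo) * r
          twin$total <- twin$total + (u - t_lo) * r
          out[[length(out) + 1L]] <- twin
          cur_age <- u
        }
        live$blen <- live$blen + (cur_age - t_lo) * r
        live$total <- live$total + (cur_age - t_lo) * r
        out[[length(out) + 1L]] <- live
      } else {
        cp$blen <- cp$blen + (t_hi - t_lo) * r
        cp$total <- cp$total + (t_hi - t_lo) * r
        out[[length(out) + 1L]] <- cp
      }
    }
    copies <<- out
  }

  split_copy <- function(cp, lin1, lin2, chrom2_offset, label,
                         keep2_prob = 1) {
    # close the incoming branch with a node; emit copy in lin1 and, with
    # probability keep2_prob, a second copy in lin2 (chromosome offset for
    # subgenome-2 placement)
    keep2 <- stats::runif(1L) < keep2_prob
    if (!keep2) {
      cp$lineage <- lin1
      return(list(cp))
    }
    nd <- new_node(label)
    attach_node(cp$parent, nd, cp$blen)
    c1 <- cp; c1$lineage <- lin1; c1$parent <- nd; c1$blen <- 0
    c2 <- cp; c2$lineage <- lin2; c2$parent <- nd; c2$blen <- 0
    c2$chrom <- cp$chrom + chrom2_offset
    list(c1, c2)
  }

  ages <- ev$time
  for (i in seq_len(nrow(ev))) {
    if (i > 1L) advance2(ages[i - 1L], ages[i])
    e <- ev[i, ]
    ret1 <- if (!is.na(e$retention1)) e$retention1 else config$retention
    ret2 <- if (!is.na(e$retention2)) e$retention2 else config$retention
    out <- list()
    for (cp in copies) {
      res <- switch(e$kind,
        speciation = {
          if (cp$lineage == e$lineage) {
            nd <- new_node("speciation")
            attach_node(cp$parent, nd, cp$blen)
            c1 <- cp; c1$lineage <- e$child1; c1$parent <- nd; c1$blen <- 0
            c2 <- cp; c2$lineage <- e$child2; c2$parent <- nd; c2$blen <- 0
            list(c1, c2)
          } else list(cp)
        },
        autopolyploidy = {
          if (cp$lineage == e$lineage) {
            split_copy(cp, e$lineage, e$lineage, karyo[[e$lineage]],
                       "wgd_duplication", keep2_prob = ret2)
          } else list(cp)
        },
        allopolyploidy = {
          if (cp$lineage == e$parent1) {
            split_copy(cp, e$parent1, e$lineage, 0L, "speciation",
                       keep2_prob = ret1)
          } else if (cp$lineage == e$parent2) {
            split_copy(cp, e$parent2, e$lineage, karyo[[e$parent1]],
                       "speciation", keep2_prob = ret2)
          } else list(cp)
        },
        extinction = {
          if (cp$lineage == e$lineage) list() else list(cp)
        })
      out <- c(out, res)
    }
    copies <- out
    # karyotype bookkeeping (mirrors build_history)
    if (e$kind == "speciation") {
      karyo[c(e$child1, e$child2)] <- karyo[[e$lineage]]
    } else if (e$kind == "autopolyploidy") {
      karyo[[e$lineage]] <- 2L * karyo[[e$lineage]]
    } else if (e$kind == "allopolyploidy") {
      karyo[[e$lineage]] <- karyo[[e$parent1]] + karyo[[e$parent2]]
    }
  }
  if (length(copies) && nrow(ev))
    advance2(ages[nrow(ev)], 0)

  # keep only extant lineages (guards against lingering non-extant copies)
  copies <- Filter(function(cp) cp$lineage %in% history$extant, copies)

  if (length(copies) == 0L) {
    return(structure(list(id = fam_id, tree = NULL,
                          leaves = data.frame(), empty = TRUE),
                     class = "true_family"))
  }

  # deterministic leaf naming: per species, copies ordered along the genome
  df <- data.frame(
    species = vapply(copies, `[[`, character(1), "lineage"),
    chrom = vapply(copies, `[[`, numeric(1), "chrom"),
    pos_key = vapply(copies, `[[`, numeric(1), "pos_key"),
    parent = vapply(copies, `[[`, numeric(1), "parent"),
    blen = vapply(copies, `[[`, numeric(1), "blen"),
    total = vapply(copies, `[[`, numeric(1), "total"),
    stringsAsFactors = FALSE)
  o <- order(df$species, df$chrom, df$pos_key, method = "radix")
  df <- df[o, , drop = FALSE]
  copy_no <- stats::ave(seq_len(nrow(df)), df$species, FUN = seq_along)
  df$gene <- paste(df$species, fam_id, copy_no, sep = ".")

  tree <- if (nrow(df) >= 2L) {
    build_family_tree(nodes, children, df)
  } else NULL

  leaves <- data.frame(gene = df$gene, species = df$species,
                       chrom = as.integer(df$chrom), pos_key = df$pos_key,
                       total_len = df$total, stringsAsFactors = FALSE)
  structure(list(id = fam_id, tree = tree, leaves = leaves, empty = FALSE),
            class = "true_family")
}

# assemble a phylo from the replay's node/edge records, pruning internal
# nodes that lost one or both descendant lines
build_family_tree <- function(nodes, children, leaf_df) {
  for (i in seq_len(nrow(leaf_df))) {
    p <- leaf_df$parent[i]
    if (p > 0L)
      children[[p]][[length(children[[p]]) + 1L]] <-
        list(kind = "leaf", id = leaf_df$gene[i], len = leaf_df$blen[i])
  }
  # which nodes actually lead to >= 1 leaf? build newick by recursion with
  # single-child suppression (child edge length absorbed)
  render <- function(kind, id, len) {
    if (kind == "leaf")
      return(list(txt = id, len = len, nleaf = 1L))
    ch <- children[[id]]
    parts <- list()
    for (c_ in ch) {
      r <- render(c_$kind, c_$id, c_$len)
      if (!is.null(r)) parts[[length(parts) + 1L]] <- r
    }
    if (length(parts) == 0L) return(NULL)
    if (length(parts) == 1L) {
      parts[[1L]]$len <- parts[[1L]]$len + len
      return(parts[[1L]])
    }
    inner <- paste(vapply(parts, function(p)
      sprintf("%s:%.10f", p$txt, p$len), character(1)), collapse = ",")
    list(txt = sprintf("(%s)%s", inner, nodes[[id]]), len = len,
         nleaf = sum(vapply(parts, `[[`, integer(1), "nleaf")))
  }
  # find root node: a node never appearing as a child
  child_nodes <- unlist(lapply(children, function(ch)
    vapply(Filter(function(c_) c_$kind == "node", ch), `[[`, numeric(1),
           "id")), use.names = FALSE)
  root_candidates <- setdiff(seq_along(nodes), child_nodes)
  rendered <- list()
  for (rt in root_candidates) {
    r <- render("node", rt, 0)
    if (!is.null(r)) rendered[[length(rendered) + 1L]] <- r
  }
  if (length(rendered) == 0L) return(NULL)
  if (length(rendered) > 1L) {
    inner <- paste(vapply(rendered, function(p)
      sprintf("%s:%.10f", p$txt, p$len), character(1)), collapse = ",")
    txt <- sprintf("(%s)speciation;", inner)
  } else {
    if (rendered[[1L]]$nleaf < 2L) return(NULL)
    txt <- paste0(rendered[[1L]]$txt, ";")
  }
  ape::read.tree(text = txt)
}
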