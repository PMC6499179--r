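# Independent oracles used to validate the package implementations.
# Each is written from the operation's definition, not by calling the
# implementation under test.

# ---- NG86 site-enumeration oracle -----------------------------------------
# Direct per-codon computation from the genetic code: synonymous site
# fractions by neighbor enumeration, difference counts by explicit
# enumeration of mutational pathways (stop-avoiding, equal weights).
oracle_ng86 <- function(seq_a, seq_b) {
  gc_map <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  split_codons <- function(s) {
    v <- strsplit(s, "")[[1]]
    apply(matrix(v, nrow = 3), 2, paste, collapse = "")
  }
  ca <- split_codons(seq_a)
  cb <- split_codons(seq_b)
  ok <- function(cd) all(strsplit(cd, "")[[1]] %in% nts) &&
    !is.na(gc_map[cd]) && gc_map[cd] != "*"
  keep <- vapply(seq_along(ca), function(i) ok(ca[i]) && ok(cb[i]),
                 logical(1))
  ca <- ca[keep]; cb <- cb[keep]
  syn_sites_of <- function(cd) {
    v <- strsplit(cd, "")[[1]]
    s <- 0
    for (p in 1:3) for (x in setdiff(nts, v[p])) {
      w <- v; w[p] <- x
      if (gc_map[paste(w, collapse = "")] == gc_map[cd]) s <- s + 1 / 3
    }
    s
  }
  path_counts <- function(c1, c2) {
    v1 <- strsplit(c1, "")[[1]]; v2 <- strsplit(c2, "")[[1]]
    dif <- which(v1 != v2)
    if (!length(dif)) return(c(0, 0))
    perms <- if (length(dif) == 1) list(dif) else {
      pm <- list()
      rec <- function(rem, acc) {
        if (!length(rem)) { pm[[length(pm) + 1]] <<- acc; return() }
        for (r in rem) rec(setdiff(rem, r), c(acc, r))
      }
      rec(dif, integer(0)); pm
    }
    res <- list()
    for (ordp in perms) {
      cur <- v1; sdn <- c(0, 0); blocked <- FALSE
      for (p in ordp) {
        nxt <- cur; nxt[p] <- v2[p]
        aa1 <- gc_map[paste(cur, collapse = "")]
        aa2 <- gc_map[paste(nxt, collapse = "")]
        if (aa2 == "*") { blocked <- TRUE; break }
        if (aa1 == aa2) sdn[1] <- sdn[1] + 1 else sdn[2] <- sdn[2] + 1
        cur <- nxt
      }
      if (!blocked) res[[length(res) + 1]] <- sdn
    }
    if (!length(res)) {  # all paths blocked: count stop steps nonsyn
      for (ordp in perms) {
        cur <- v1; sdn <- c(0, 0)
        for (p in ordp) {
          nxt <- cur; nxt[p] <- v2[p]
          aa1 <- gc_map[paste(cur, collapse = "")]
          aa2 <- gc_map[paste(nxt, collapse = "")]
          if (aa1 == aa2 && aa1 != "*") sdn[1] <- sdn[1] + 1
          else sdn[2] <- sdn[2] + 1
          cur <- nxt
        }
        res[[length(res) + 1]] <- sdn
      }
    }
    Reduce(`+`, res) / length(res)
  }
  S <- (sum(vapply(ca, syn_sites_of, numeric(1))) +
          sum(vapply(cb, syn_sites_of, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  sdnd <- Reduce(`+`, lapply(seq_along(ca), function(i)
    path_counts(ca[i], cb[i])), accumulate = FALSE)
  if (is.null(sdnd)) sdnd <- c(0, 0)
  ps <- sdnd[1] / S; pn <- sdnd[2] / N
  jc <- function(p) if (1 - 4 * p / 3 <= 0) NA_real_ else
    -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = sdnd[1], Nd = sdnd[2], Ks = jc(ps), Ka = jc(pn))
}

# random sense-codon sequence and mutated partner for oracle comparisons
random_cds <- function(ncod, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gc_map <- Biostrings::GENETIC_CODE
  sense <- names(gc_map)[gc_map != "*"]
  paste(sample(sense, ncod, replace = TRUE), collapse = "")
}

perturb_cds <- function(seq, n_changes) {
  v <- strsplit(seq, "")[[1]]
  gc_map <- Biostrings::GENETIC_CODE
  nts <- c("A", "C", "G", "T")
  changed <- 0L
  while (changed < n_changes) {
    p <- sample(length(v), 1)
    x <- sample(setdiff(nts, v[p]), 1)
    w <- v; w[p] <- x
    cod_i <- (p - 1) %/% 3
    cd <- paste(w[(cod_i * 3 + 1):(cod_i * 3 + 3)], collapse = "")
    if (gc_map[cd] == "*") next
    v <- w
    changed <- changed + 1L
  }
  paste(v, collapse = "")
}

# ---- exact-JC pair generator ----------------------------------------------
# Codons drawn from four-fold degenerate boxes whose first two positions
# admit no synonymous change; third positions are literal 4-state JC sites,
# so the pair's true synonymous divergence is exactly d.
jc_fourfold_pair <- function(d, ncod) {
  boxes <- c("GC", "GG", "CC", "AC", "GT")
  nts <- c("A", "C", "G", "T")
  pre <- sample(boxes, ncod, replace = TRUE)
  third_a <- sample(nts, ncod, replace = TRUE)
  p_diff <- 0.75 * (1 - exp(-4 * d / 3))
  flip <- runif(ncod) < p_diff
  third_b <- third_a
  third_b[flip] <- vapply(third_a[flip], function(x)
    sample(setdiff(nts, x), 1), character(1))
  list(a = paste0(pre, third_a, collapse = ""),
       b = paste0(pre, third_b, collapse = ""))
}

# ---- naive dense MCL ------------------------------------------------------
oracle_mcl <- function(adj, inflation, tol = 1e-6, max_iter = 200) {
  n <- nrow(adj)
  for (j in 1:n) {
    inc <- adj[, j]
    adj[j, j] <- if (any(inc > 0)) max(inc) else 1
  }
  M <- sweep(adj, 2, colSums(adj), "/")
  for (it in 1:max_iter) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, pmax(colSums(M2), 1e-300), "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; break }
    M <- M2
  }
  # connected components of the support, by hand (BFS)
  sup <- (M > 1e-8) | t(M > 1e-8)
  comp <- rep(0L, n)
  cur <- 0L
  for (s in 1:n) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] != 0L) next
      comp[v] <- cur
      queue <- c(queue, which(sup[v, ] & comp == 0L))
    }
  }
  comp
}

# ---- exhaustive best chain ------------------------------------------------
oracle_best_chain_score <- function(x, y, max_gap) {
  n <- length(x)
  best <- 0L
  for (dir in c(1L, -1L)) {
    rec <- function(last, count) {
      best <<- max(best, count)
      for (i in seq_len(n)) {
        if (last > 0L) {
          if (x[i] <= x[last]) next
          if (x[i] - x[last] > max_gap) next
          dy <- if (dir > 0) y[i] - y[last] else y[last] - y[i]
          if (dy <= 0 || dy > max_gap) next
        }
        rec(i, count + 1L)
      }
    }
    rec(0L, 0L)
  }
  best
}

# ---- rooted tree shape enumeration + species-overlap oracle ----------------
# all rooted binary shapes with n leaves, as nested lists
tree_shapes <- function(n) {
  if (n == 1) return(list("leaf"))
  out <- list()
  for (k in 1:(n %/% 2)) {
    left <- tree_shapes(k)
    right <- tree_shapes(n - k)
    for (l in left) for (r in right)
      out[[length(out) + 1]] <- list(l, r)
  }
  out
}

# assign species (by index) to the leaves of a shape, in left-to-right order
assign_species <- function(shape, species) {
  i <- 0L
  walk <- function(s) {
    if (identical(s, "leaf")) {
      i <<- i + 1L
      return(species[i])
    }
    list(walk(s[[1]]), walk(s[[2]]))
  }
  walk(shape)
}

count_leaves <- function(shape) {
  if (identical(shape, "leaf")) 1L else
    count_leaves(shape[[1]]) + count_leaves(shape[[2]])
}

# newick for a species-assigned nested tree, leaves named sp.g<k>
nested_to_newick <- function(tr) {
  i <- 0L
  walk <- function(s) {
    if (!is.list(s)) {
      i <<- i + 1L
      return(paste0(s, ".g", i))
    }
    paste0("(", walk(s[[1]]), ":1,", walk(s[[2]]), ":1):1")
  }
  paste0(sub(":1$", "", walk(tr)), ";")
}

# oracle labels: map from sorted-leafset key to D/S, by set intersection
oracle_overlap_labels <- function(tr) {
  i <- 0L
  labels <- list()
  walk <- function(s) {
    if (!is.list(s)) {
      i <<- i + 1L
      return(list(leaves = paste0(s, ".g", i), species = s))
    }
    l <- walk(s[[1]]); r <- walk(s[[2]])
    leaves <- c(l$leaves, r$leaves)
    species <- unique(c(l$species, r$species))
    lab <- if (length(intersect(l$species, r$species))) "D" else "S"
    labels[[paste(sort(leaves), collapse = "|")]] <<- lab
    list(leaves = leaves, species = species)
  }
  walk(tr)
  labels
}

# ---- karyotype replay oracle ----------------------------------------------
oracle_karyotypes <- function(events, base_n, root) {
  k <- c()
  k[root] <- base_n
  alive <- root
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$kind == "speciation") {
      k[e$child1] <- k[[e$lineage]]
      k[e$child2] <- k[[e$lineage]]
      alive <- c(setdiff(alive, e$lineage), e$child1, e$child2)
    } else if (e$kind == "autopolyploidy") {
      k[e$lineage] <- 2 * k[[e$lineage]]
    } else if (e$kind == "allopolyploidy") {
      k[e$lineage] <- k[[e$parent1]] + k[[e$parent2]]
      alive <- c(alive, e$lineage)
    } else if (e$kind == "extinction") {
      alive <- setdiff(alive, e$lineage)
    }
  }
  k[alive]
}
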