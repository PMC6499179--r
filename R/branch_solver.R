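#' Name the edges of a rooted topology
#'
#' Each edge is named after the node it leads to: tip labels for terminal
#' edges, node labels (or `node<k>` when absent) for internal edges.
#' @param tree an `ape::phylo` object.
#' @return character vector of edge names, in `tree$edge` row order.
#' @export
edge_names <- function(tree) {
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  nl <- tree$node.label
  nm <- character(nrow(tree$edge))
  for (i in seq_along(child)) {
    ch <- child[i]
    if (ch <= ntip) {
      nm[i] <- tree$tip.label[ch]
    } else {
      lab <- if (!is.null(nl)) nl[ch - ntip] else ""
      nm[i] <- if (!is.na(lab) && nzchar(lab)) lab else paste0("node", ch)
    }
  }
  nm
}

.path_edges <- function(tree, tip_a, tip_b) {
  ia <- match(tip_a, tree$tip.label)
  ib <- match(tip_b, tree$tip.label)
  if (is.na(ia) || is.na(ib))
    stop("constraint references unknown tip(s): ",
         paste(c(tip_a, tip_b)[c(is.na(ia), is.na(ib))], collapse = ", "))
  nodes <- ape::nodepath(tree, ia, ib)
  key_edge <- paste(tree$edge[, 1], tree$edge[, 2])
  idx <- integer(length(nodes) - 1L)
  for (k in seq_len(length(nodes) - 1L)) {
    hit <- match(paste(nodes[k], nodes[k + 1L]), key_edge)
    if (is.na(hit)) hit <- match(paste(nodes[k + 1L], nodes[k]), key_edge)
    idx[k] <- hit
  }
  idx
}

#' Solve branch lengths from modal Ks path constraints
#'
#' Given a fixed rooted species/homoeolog topology and observed modal Ks
#' values between terminal pairs, solves the linear system
#' `sum of branch lengths along the path = observed Ks` for the free
#' branches. Branches listed in `fixed` are substituted at a constant
#' (conventionally 0.01 for short internal branches that the path data
#' cannot determine). Branches named together in an `equal_groups` entry
#' share one variable, which resolves the symmetric homoeolog-terminal
#' ambiguity. Overdetermined systems are solved by least squares; exactly
#' determined systems reproduce the constraints to machine precision.
#' Underdetermined systems are refused with the list of unresolvable
#' branches rather than silently guessed.
#'
#' @param topology newick string or `ape::phylo`; rooted, tips named.
#' @param constraints data.frame with columns `tip_a`, `tip_b`, `ks`.
#' @param fixed named numeric vector: edge name -> fixed length (edges are
#'   named by [edge_names()]).
#' @param equal_groups list of character vectors of edge names tied to a
#'   common length.
#' @param clamp clamp negative solutions to zero (default TRUE).
#' @return list with `edge_lengths` (named, all edges), `tree` (phylo with
#'   solved lengths), `residuals` (per constraint), `clamped` (names of
#'   clamped edges), `rank`, `n_free`.
#' @export
solve_branches <- function(topology, constraints, fixed = numeric(0),
                           equal_groups = list(), clamp = TRUE) {
  tree <- if (inherits(topology, "phylo")) topology else
    ape::read.tree(text = topology)
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0, nrow(tree$edge))
  enames <- edge_names(tree)
  stopifnot(all(c("tip_a", "tip_b", "ks") %in% names(constraints)))
  if (length(fixed) && !all(names(fixed) %in% enames))
    stop("fixed edge(s) not in topology: ",
         paste(setdiff(names(fixed), enames), collapse = ", "))

  # variable id per edge: fixed -> 0; grouped edges share an id
  var_of <- seq_along(enames)
  names(var_of) <- enames
  for (g in equal_groups) {
    if (!all(g %in% enames))
      stop("equal_groups edge(s) not in topology: ",
           paste(setdiff(g, enames), collapse = ", "))
    var_of[g] <- var_of[g[1]]
  }
  var_of[names(fixed)] <- 0L
  free_ids <- sort(unique(var_of[var_of > 0L]))
  nfree <- length(free_ids)

  ncon <- nrow(constraints)
  A <- matrix(0, ncon, nfree)
  bvec <- numeric(ncon)
  for (i in seq_len(ncon)) {
    eidx <- .path_edges(tree, constraints$tip_a[i], constraints$tip_b[i])
    b_i <- constraints$ks[i]
    for (e in eidx) {
      v <- var_of[e]
      if (v == 0L) {
        b_i <- b_i - fixed[[enames[e]]]
      } else {
        A[i, match(v, free_ids)] <- A[i, match(v, free_ids)] + 1
      }
    }
    bvec[i] <- b_i
  }

  qr_a <- qr(A)
  if (qr_a$rank < nfree) {
    free_names <- vapply(free_ids, function(v) {
      paste(enames[var_of == v], collapse = "=")
    }, character(1))
    stop("underdetermined branch system: ", nfree, " free branch variable(s) [",
         paste(free_names, collapse = ", "), "] but rank ", qr_a$rank,
         "; fix or tie additional branches")
  }
  sol <- qr.coef(qr_a, bvec)

  lens <- numeric(length(enames))
  names(lens) <- enames
  for (e in seq_along(enames)) {
    v <- var_of[e]
    lens[e] <- if (v == 0L) fixed[[enames[e]]] else sol[match(v, free_ids)]
  }
  clamped <- character(0)
  if (clamp && any(lens < 0)) {
    clamped <- enames[lens < 0]
    lens[lens < 0] <- 0
  }
  resid <- as.numeric(A %*% sol - bvec)
  tree$edge.length <- unname(lens)
  list(edge_lengths = lens, tree = tree, residuals = resid,
       clamped = clamped, rank = qr_a$rank, n_free = nfree)
}
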