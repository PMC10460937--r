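#' Counting semantics for case flags
#'
#' Controls how the uppercase/lowercase species semantics are applied when
#' matching a pattern against the interaction map.  An uppercase species
#' must have *exactly* the contacts its role in the pattern shows; the
#' degree it is judged against is taken from the full graph
#' (`case_scope = "global"`, the default: any other contact breaks
#' isolation) or from the pattern's macro-class subgraph
#' (`case_scope = "macro"`).  A lowercase species imposes no constraint
#' under `lowercase_mode = "superset"` (the default: isolated instances are
#' also counted) or must have at least one contact beyond the pattern under
#' `"exclusive"`.
#'
#' @param case_scope `"global"` or `"macro"`.
#' @param lowercase_mode `"superset"` or `"exclusive"`.
#' @return a `semantics_config` list.
#' @export
semantics_config <- function(case_scope = c("global", "macro"),
                             lowercase_mode = c("superset", "exclusive")) {
  structure(list(case_scope = match.arg(case_scope),
                 lowercase_mode = match.arg(lowercase_mode)),
            class = "semantics_config")
}

# adjacency list (sorted integer vectors) of a contact graph
.adj <- function(g) {
  n <- nrow(g$nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  e <- g$edges
  if (nrow(e)) {
    ends <- c(e[, 1L], e[, 2L])
    nbrs <- c(e[, 2L], e[, 1L])
    sp <- split(nbrs, ends)
    for (nm in names(sp)) adj[[as.integer(nm)]] <- sort(sp[[nm]])
  }
  adj
}

#' Restrict a contact graph to one macro class
#'
#' Keeps every node but only the edges whose species pair belongs to macro
#' class `m`.  The three macro edge sets partition the edge set.  The
#' original full-graph degree is retained in `$full_degree` so case
#' semantics can still be judged against the unrestricted map.
#'
#' @param g a [contact_graph()].
#' @param m macro class label, e.g. `"ID_182_182"`.
#' @return a `contact_graph` whose `$degree` refers to the restricted
#'   edge set and `$full_degree` to the original one.
#' @export
macro_subgraph <- function(g, m) {
  stopifnot(inherits(g, "contact_graph"))
  tags <- unique(g$nodes$species)
  e <- g$edges
  keep <- if (nrow(e))
    macro_edge_class(g$nodes$species[e[, 1L]], g$nodes$species[e[, 2L]],
                     tags = tags) == m
  else logical(0)
  sub <- contact_graph(g$nodes, e[keep, , drop = FALSE],
                       cutoff = g$cutoff, cl = g$cell)
  sub$full_degree <- if (is.null(g$full_degree)) g$degree else g$full_degree
  sub
}

# per-node match vector for one pattern position
.match_nodes <- function(g, sdeg, species, upper, roledeg, lowercase_mode) {
  ok <- g$nodes$species == species
  if (upper) ok & sdeg == roledeg
  else if (lowercase_mode == "exclusive") ok & sdeg > roledeg
  else ok
}

# scope degree per node for case judging
.scope_degree <- function(g, p, s) {
  if (s$case_scope == "global") {
    if (is.null(g$full_degree)) g$degree else g$full_degree
  } else macro_subgraph(g, p$macro)$degree
}

.perms <- function(k) {
  if (k == 1L) return(matrix(1L, 1L, 1L))
  sub <- .perms(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    rest <- seq_len(k)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), k - 1L), deparse.level = 0L)
  }))
}

# star view of a J pattern: center position adjacent to all others
.as_star <- function(pg) {
  ctr <- which(pg$roledeg == pg$k - 1L)
  if (length(ctr) != 1L || any(pg$roledeg[-ctr] != 1L)) return(NULL)
  list(center = ctr, leaves = seq_len(pg$k)[-ctr])
}

#' Count one micro-pattern in a contact graph
#'
#' Subgraph-census counting: the count is the number of distinct instances
#' (node set plus role assignment, up to the pattern's automorphisms) whose
#' pattern edges are all present in the map and whose species and case
#' constraints hold.  Extra graph edges among the instance's nodes are not
#' excluded for lowercase species — a triangle therefore also contains
#' three linear chains.  Supported topologies: `L2`, `L3`, `R3` and the
#' star junctions `J4`, `J5`.
#'
#' @param g a [contact_graph()].
#' @param p a `danai_pattern`.
#' @param s a [semantics_config()].
#' @return non-negative integer count.
#' @export
count_pattern <- function(g, p, s = semantics_config()) {
  stopifnot(inherits(g, "contact_graph"), inherits(p, "danai_pattern"))
  if (!inherits(s, "semantics_config")) stop("s must be a semantics_config")
  pg <- .pattern_graph(p)
  fam <- paste0(p$topology, p$order)
  star <- if (p$topology == "J") .as_star(pg) else NULL
  if (!(fam %in% c("L2", "L3", "R3") ||
        (fam %in% c("J4", "J5") && !is.null(star))))
    stop("unsupported pattern: only the L2/L3/R3/J4/J5 star family is counted")
  sdeg <- .scope_degree(g, p, s)
  mvec <- lapply(seq_len(pg$k), function(i)
    .match_nodes(g, sdeg, pg$labels$species[i], pg$labels$upper[i],
                 pg$roledeg[i], s$lowercase_mode))
  key <- .elem_key(pg$labels$species, pg$labels$upper)
  e <- g$edges
  adj <- NULL

  if (fam == "L2") {
    emb <- 0L
    if (nrow(e)) {
      m1 <- mvec[[1L]]; m2 <- mvec[[2L]]
      emb <- sum(m1[e[, 1L]] & m2[e[, 2L]]) + sum(m1[e[, 2L]] & m2[e[, 1L]])
    }
    aut <- if (key[1L] == key[2L]) 2L else 1L
  } else if (fam == "L3") {
    adj <- .adj(g)
    mC <- mvec[[2L]]; mA <- mvec[[1L]]; mB <- mvec[[3L]]
    emb <- 0
    for (v in which(mC)) {
      nb <- adj[[v]]
      if (length(nb) < 2L) next
      na <- sum(mA[nb]); nbk <- sum(mB[nb]); both <- sum(mA[nb] & mB[nb])
      emb <- emb + na * nbk - both
    }
    aut <- if (key[1L] == key[3L]) 2L else 1L
  } else if (fam == "R3") {
    adj <- .adj(g)
    perm3 <- .perms(3L)
    aut <- sum(apply(perm3, 1L, function(pp) all(key == key[pp])))
    emb <- 0
    if (nrow(e)) for (r in seq_len(nrow(e))) {
      u <- e[r, 1L]; v <- e[r, 2L]
      ws <- adj[[u]][adj[[u]] %in% adj[[v]] & adj[[u]] > v]
      for (w in ws) {
        t3 <- c(u, v, w)
        for (q in seq_len(nrow(perm3))) {
          pp <- perm3[q, ]
          if (mvec[[1L]][t3[pp[1L]]] && mvec[[2L]][t3[pp[2L]]] &&
              mvec[[3L]][t3[pp[3L]]]) emb <- emb + 1
        }
      }
    }
  } else {  # J4 / J5 star
    adj <- .adj(g)
    k <- length(star$leaves)
    mC <- mvec[[star$center]]
    leafm <- mvec[star$leaves]
    leafkey <- key[star$leaves]
    permk <- .perms(k)
    aut <- sum(apply(permk, 1L, function(pp) all(leafkey == leafkey[pp])))
    emb <- 0
    uniform <- length(unique(leafkey)) == 1L
    for (v in which(mC)) {
      nb <- adj[[v]]
      if (length(nb) < k) next
      if (uniform) {
        m <- sum(leafm[[1L]][nb])
        if (m >= k) emb <- emb + choose(m, k) * factorial(k)
      } else {
        cand <- nb[Reduce(`|`, lapply(leafm, function(mm) mm[nb]))]
        if (length(cand) < k) next
        combos <- utils::combn(cand, k)
        for (cc in seq_len(ncol(combos))) {
          nodes <- combos[, cc]
          for (q in seq_len(nrow(permk))) {
            pp <- permk[q, ]
            ok <- TRUE
            for (t in seq_len(k))
              if (!leafm[[pp[t]]][nodes[t]]) { ok <- FALSE; break }
            if (ok) emb <- emb + 1
          }
        }
      }
    }
  }
  if (emb %% aut != 0)
    stop("internal error: embedding count not divisible by automorphism count")
  as.integer(emb / aut)
}

#' Closed-form census for lowercase single-species patterns
#'
#' On the macro-class subgraph with degrees `deg`: `L2 = |E|`,
#' `L3 = sum(choose(deg, 2))`, `J4 = sum(choose(deg, 3))`,
#' `J5 = sum(choose(deg, 4))`.  Only defined for lowercase, single-species
#' patterns under superset semantics; agrees exactly with
#' [count_pattern()].
#'
#' @inheritParams count_pattern
#' @return non-negative integer count.
#' @export
closed_form_count <- function(g, p) {
  stopifnot(inherits(g, "contact_graph"), inherits(p, "danai_pattern"))
  pg <- .pattern_graph(p)
  if (any(pg$labels$upper) || length(unique(pg$labels$species)) != 1L)
    stop("unsupported pattern: closed form needs a lowercase single-species pattern")
  fam <- paste0(p$topology, p$order)
  if (!fam %in% c("L2", "L3", "J4", "J5"))
    stop("unsupported pattern: closed form covers L2, L3, J4, J5")
  if (fam %in% c("J4", "J5") && is.null(.as_star(pg)))
    stop("unsupported pattern: junction is not a star")
  sub <- macro_subgraph(g, p$macro)
  switch(fam,
         L2 = nrow(sub$edges),
         L3 = sum(choose(sub$degree, 2L)),
         J4 = sum(choose(sub$degree, 3L)),
         J5 = sum(choose(sub$degree, 4L)))
}

#' Count every mode of a mode set in one frame's graph
#'
#' @param g a [contact_graph()].
#' @param modes a [builtin_modes()]-style mode set.
#' @param s a [semantics_config()].
#' @param step,time frame metadata attached to the result.
#' @return named integer vector (one count per canonical statement) with
#'   attributes `step` and `time`.
#' @export
count_modes <- function(g, modes = builtin_modes(), s = semantics_config(),
                        step = NA_integer_, time = NA_real_) {
  counts <- vapply(modes, function(p) count_pattern(g, p, s), integer(1))
  attr(counts, "step") <- as.integer(step)
  attr(counts, "time") <- as.numeric(time)
  counts
}
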