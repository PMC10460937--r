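#' Brute-force motif census (testing oracle)
#'
#' Independent ground-truth census: enumerates ordered assignments of graph
#' nodes to pattern positions by exhaustive depth-first search, checking the
#' species, case-degree and edge constraints literally, and collapses the
#' embeddings onto instances through the pattern's automorphism group
#' (computed here by enumerating all position permutations).  Shares no
#' counting code with [count_pattern()]; it exists to cross-validate it.
#' Intended for small graphs only (refuses more than 200 nodes).
#'
#' @param g a [contact_graph()].
#' @param p a `danai_pattern` (any topology the parser accepts).
#' @param s a [semantics_config()].
#' @return list with `count`, and `instances` (a list of node tuples, one
#'   canonical representative per automorphism orbit, positions in pattern
#'   order).
#' @export
brute_force_count <- function(g, p, s = semantics_config()) {
  stopifnot(inherits(g, "contact_graph"), inherits(p, "danai_pattern"))
  n <- nrow(g$nodes)
  if (n > 200L)
    stop("oracle refusal: brute-force census is limited to 200 nodes")
  pg <- .pattern_graph(p)
  k <- pg$k

  # adjacency as a dense logical matrix, built directly from the edge list
  A <- matrix(FALSE, n, n)
  if (nrow(g$edges)) {
    A[g$edges] <- TRUE
    A[g$edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  }

  # scope degree, computed independently of .scope_degree()
  species <- g$nodes$species
  if (s$case_scope == "global") {
    full <- if (is.null(g$full_degree)) rowSums(A) else g$full_degree
    sdeg <- as.numeric(full)
  } else {
    in_macro <- function(u, v) {
      cls <- paste0("ID_", paste(sort(as.numeric(.species_code_num(
        c(species[u], species[v])))), collapse = "_"))
      cls == p$macro
    }
    sdeg <- vapply(seq_len(n), function(u)
      sum(vapply(which(A[u, ]), function(v) in_macro(u, v), logical(1))),
      numeric(1))
  }

  ok_node <- function(v, pos) {
    if (species[v] != pg$labels$species[pos]) return(FALSE)
    rd <- pg$roledeg[pos]
    if (pg$labels$upper[pos]) sdeg[v] == rd
    else if (s$lowercase_mode == "exclusive") sdeg[v] > rd
    else TRUE
  }

  # pattern edges incident to each position from earlier positions
  back_edges <- lapply(seq_len(k), function(pos) {
    e <- pg$edges
    prev <- c(e[e[, 2L] == pos & e[, 1L] < pos, 1L],
              e[e[, 1L] == pos & e[, 2L] < pos, 2L])
    prev
  })

  embeddings <- list()
  assign_pos <- integer(k)
  used <- logical(n)
  recurse <- function(pos) {
    if (pos > k) {
      embeddings[[length(embeddings) + 1L]] <<- assign_pos
      return(invisible(NULL))
    }
    for (v in seq_len(n)) {
      if (used[v] || !ok_node(v, pos)) next
      fits <- TRUE
      for (u in back_edges[[pos]])
        if (!A[assign_pos[u], v]) { fits <- FALSE; break }
      if (!fits) next
      used[v] <<- TRUE
      assign_pos[pos] <<- v
      recurse(pos + 1L)
      used[v] <<- FALSE
    }
    invisible(NULL)
  }
  if (n >= k) recurse(1L)

  # automorphisms: label- and adjacency-preserving position permutations
  em <- matrix(FALSE, k, k)
  if (nrow(pg$edges)) {
    em[pg$edges] <- TRUE
    em[pg$edges[, c(2L, 1L), drop = FALSE]] <- TRUE
  }
  lab <- paste0(pg$labels$species, ifelse(pg$labels$upper, "^", "_"))
  perms <- .perms(k)
  auto <- perms[apply(perms, 1L, function(pp)
    all(lab == lab[pp]) && all(em == em[pp, pp])), , drop = FALSE]

  canonical <- vapply(embeddings, function(emb) {
    reps <- apply(auto, 1L, function(pp) paste(emb[pp], collapse = ","))
    min(reps)
  }, character(1))
  keep <- !duplicated(canonical)
  instances <- embeddings[keep]
  if (length(embeddings) %% nrow(auto) != 0L)
    stop("oracle internal error: orbit sizes are inconsistent")
  list(count = length(instances), instances = instances)
}
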