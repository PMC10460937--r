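#' Interaction centers and contact graphs
#'
#' The interaction map of a frame is an undirected graph whose nodes are
#' chemically tagged carbon centers (DL_F-style species codes, e.g. `C180`
#' for a monohaloalkane carbon, `C182` for a trihaloalkane carbon) and whose
#' edges join centers of *different* molecules whose minimum-image distance
#' does not exceed the cutoff (5 Angstrom by default; the boundary is
#' inclusive).
#'
#' @name contact_graph
NULL

# numeric part of a species code ("C182" -> "182")
.species_code_num <- function(code) sub("^[A-Za-z]+", "", code)

#' Extract tagged interaction centers from a frame
#'
#' @param fr an [frame()] object.
#' @param tags character vector of species codes to keep (default
#'   `c("C180", "C182")`); matching is exact on the atom label.
#' @return data.frame with columns `node`, `species`, `molecule`, `x`, `y`,
#'   `z`, one row per matching atom in atom order.
#' @export
extract_centers <- function(fr, tags = c("C180", "C182")) {
  stopifnot(inherits(fr, "md_frame"), length(tags) >= 1L)
  keep <- fr$atoms$label %in% tags
  if (!any(keep))
    warning("no atoms match the requested species tags; empty center list")
  a <- fr$atoms[keep, , drop = FALSE]
  data.frame(node = seq_len(nrow(a)), species = a$label,
             molecule = a$molecule, x = a$x, y = a$y, z = a$z)
}

#' Construct a contact graph object
#'
#' Low-level constructor used by [build_contact_graph()] and by tests that
#' work with abstract graphs; validates the structural invariants (no self
#' edges, no intramolecular edges).
#'
#' @param nodes data.frame as returned by [extract_centers()]; positions may
#'   be absent for abstract graphs.
#' @param edges two-column integer matrix of node indices (unordered pairs).
#' @param cutoff the distance criterion used, Angstrom (`NA` for abstract
#'   graphs).
#' @param cl the [cell()] (optional).
#' @return object of class `contact_graph` with fields `nodes`, `edges`
#'   (each row `i < j`), `cutoff`, `cell`, and `degree` (full-graph degree).
#' @export
contact_graph <- function(nodes, edges, cutoff = NA_real_, cl = NULL) {
  stopifnot(is.data.frame(nodes),
            all(c("species", "molecule") %in% names(nodes)))
  n <- nrow(nodes)
  if (is.null(dim(edges))) edges <- matrix(as.integer(edges), ncol = 2L)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    if (any(edges < 1L | edges > n)) stop("edge endpoint out of range")
    if (any(edges[, 1L] == edges[, 2L])) stop("self edges are not allowed")
    if (any(nodes$molecule[edges[, 1L]] == nodes$molecule[edges[, 2L]]))
      stop("intramolecular edges are not allowed")
    edges <- t(apply(edges, 1L, sort))
    edges <- edges[!duplicated(edges), , drop = FALSE]
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)
  structure(list(nodes = nodes, edges = edges, cutoff = cutoff, cell = cl,
                 degree = deg),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat(sprintf("<contact_graph> %d nodes, %d edges, cutoff %s A\n",
              nrow(x$nodes), nrow(x$edges), format(x$cutoff)))
  invisible(x)
}

#' Build the intermolecular interaction map of a frame
#'
#' An edge joins two centers iff they belong to different molecules and
#' their minimum-image distance is `<= cutoff`.  For more than 500 centers a
#' cell-list (spatial binning) search is used; both search paths produce
#' identical graphs.
#'
#' @param centers data.frame from [extract_centers()].
#' @param cl the periodic [cell()].
#' @param cutoff distance criterion, Angstrom (default 5); must be below half
#'   the smallest cell width so the nearest image is unambiguous.
#' @param method `"auto"` (default), `"brute"` (all pairs) or `"cell"`.
#' @return a [contact_graph()] object.
#' @export
build_contact_graph <- function(centers, cl, cutoff = 5.0,
                                method = c("auto", "brute", "cell")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(centers), inherits(cl, "md_cell"), cutoff > 0)
  if (is_periodic(cl) && cutoff >= min_cell_width(cl) / 2)
    stop(sprintf(
      "geometry error: cutoff %.3f A must be below half the smallest cell width (%.3f A)",
      cutoff, min_cell_width(cl) / 2))
  n <- nrow(centers)
  pos <- as.matrix(centers[, c("x", "y", "z")])
  if (method == "auto")
    method <- if (n > 500L &&
                  cl$periodic %in% c("cubic", "orthorhombic")) "cell"
              else "brute"
  if (method == "cell" && !cl$periodic %in% c("cubic", "orthorhombic"))
    stop("cell-list search supports cubic/orthorhombic cells only")
  pairs <- if (method == "brute") .pairs_brute(n)
           else .pairs_cell_list(pos, cl, cutoff)
  edges <- matrix(integer(0), 0L, 2L)
  if (nrow(pairs)) {
    keep <- centers$molecule[pairs[, 1L]] != centers$molecule[pairs[, 2L]]
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs)) {
      d2 <- .min_image_dist2(pos[pairs[, 1L], , drop = FALSE] -
                               pos[pairs[, 2L], , drop = FALSE], cl)
      edges <- pairs[d2 <= cutoff^2, , drop = FALSE]
    }
  }
  contact_graph(centers, edges, cutoff = cutoff, cl = cl)
}

.pairs_brute <- function(n) {
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  cbind(i, j, deparse.level = 0L)
}

# candidate pairs from periodic spatial binning; bins are >= cutoff wide so
# only the 27 surrounding bins need scanning.
.pairs_cell_list <- function(pos, cl, cutoff) {
  L <- diag(cl$matrix)
  nb <- pmax(1L, floor(L / cutoff))
  if (any(nb < 3L)) return(.pairs_brute(nrow(pos)))  # wrap duplicates: bail out
  frac <- sweep(pos, 2L, L, "/")
  frac <- frac - floor(frac)
  bi <- pmin(floor(frac[, 1L] * nb[1L]), nb[1L] - 1L)
  bj <- pmin(floor(frac[, 2L] * nb[2L]), nb[2L] - 1L)
  bk <- pmin(floor(frac[, 3L] * nb[3L]), nb[3L] - 1L)
  bin <- bi + nb[1L] * (bj + nb[2L] * bk)
  members <- split(seq_len(nrow(pos)), bin)
  # half-space of neighbor offsets so each bin pair is visited once
  offs <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  offs <- offs[offs[, 3L] > 0L | (offs[, 3L] == 0L & offs[, 2L] > 0L) |
                 (offs[, 3L] == 0L & offs[, 2L] == 0L & offs[, 1L] > 0L), ,
               drop = FALSE]
  out <- vector("list", length(members) * (nrow(offs) + 1L))
  nout <- 0L
  for (nm in names(members)) {
    b <- as.integer(nm)
    k0 <- b %/% (nb[1L] * nb[2L])
    j0 <- (b %/% nb[1L]) %% nb[2L]
    i0 <- b %% nb[1L]
    m <- members[[nm]]
    if (length(m) > 1L) {
      nout <- nout + 1L
      p0 <- .pairs_brute(length(m))
      out[[nout]] <- cbind(m[p0[, 1L]], m[p0[, 2L]], deparse.level = 0L)
    }
    for (r in seq_len(nrow(offs))) {
      ii <- (i0 + offs[r, 1L]) %% nb[1L]
      jj <- (j0 + offs[r, 2L]) %% nb[2L]
      kk <- (k0 + offs[r, 3L]) %% nb[3L]
      m2 <- members[[as.character(ii + nb[1L] * (jj + nb[2L] * kk))]]
      if (is.null(m2)) next
      nout <- nout + 1L
      out[[nout]] <- cbind(rep(m, each = length(m2)), rep(m2, length(m)),
                           deparse.level = 0L)
    }
  }
  if (!nout) return(matrix(integer(0), 0L, 2L))
  pr <- do.call(rbind, out[seq_len(nout)])
  # orient and drop duplicates that arise when two bins are periodic images
  pr <- cbind(pmin(pr[, 1L], pr[, 2L]), pmax(pr[, 1L], pr[, 2L]))
  pr <- pr[pr[, 1L] != pr[, 2L], , drop = FALSE]
  pr[!duplicated(pr), , drop = FALSE]
}

#' Macro-interaction class of a species pair
#'
#' Contacts are grouped by the unordered pair of participating species:
#' `ID_182_182`, `ID_180_180` or `ID_180_182` for the fluoroalkane system
#' (generalized as `ID_<a>_<b>` with numeric codes in increasing order).
#'
#' @param species_a,species_b species codes (e.g. `"C182"`).
#' @param tags the configured tag set; species outside it are an error.
#' @return the class label, e.g. `"ID_180_182"`.
#' @examples
#' macro_edge_class("C180", "C182") # "ID_180_182"
#' @export
macro_edge_class <- function(species_a, species_b, tags = c("C180", "C182")) {
  bad <- setdiff(unique(c(species_a, species_b)), tags)
  if (length(bad))
    stop("species outside the configured tag set: ", paste(bad, collapse = ", "))
  a <- .species_code_num(species_a)
  b <- .species_code_num(species_b)
  lo <- ifelse(suppressWarnings(as.numeric(a)) <= suppressWarnings(as.numeric(b)), a, b)
  hi <- ifelse(lo == a, b, a)
  paste0("ID_", lo, "_", hi)
}
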