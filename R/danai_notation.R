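#' DANAI micro-interaction notation
#'
#' A DANAI statement encodes one local pattern of non-bonded contacts:
#' `"[" topology order "]"` followed by the participating species.  The
#' topology letter is `L` (linear chain), `R` (ring) or `J` (junction); the
#' digit is the number of participating species.  A colon denotes a contact
#' between the two adjacent species.  In a ring the first and last species
#' are written twice to mark the closure.  A bracketed species is a branch:
#' `"(X:)"` attaches to the species that follows the bracket, `"(:X)"` to
#' the species that precedes it.  An uppercase species letter means the
#' species has *only* the contacts shown in the statement (isolation); a
#' lowercase letter allows further contacts not shown.
#'
#' Examples: `[L2]C182:C180` is an isolated pair; `[R3]c182:c182:c182:c182`
#' a three-membered ring; `[J5]c182:(c182:)c182(:c182):c182` a four-fold
#' junction (star) on the middle species.
#'
#' @name danai_notation
NULL

.danai_err <- function(text, offset, msg) {
  stop(sprintf("DANAI syntax error at character %d of \"%s\": %s",
               offset, text, msg), call. = FALSE)
}

# one species token -> list(species = canonical code, upper = flag)
.parse_species_token <- function(tok, text, offset) {
  m <- regexec("^([A-Za-z]+)([0-9]+)$", tok)[[1L]]
  if (m[1L] == -1L) .danai_err(text, offset, paste0("invalid species token '", tok, "'"))
  letters_part <- regmatches(tok, regexec("^([A-Za-z]+)", tok))[[1L]][2L]
  digits_part <- sub("^[A-Za-z]+", "", tok)
  if (letters_part != toupper(letters_part) &&
      letters_part != tolower(letters_part))
    .danai_err(text, offset, "species letters must be uniformly upper or lower case")
  list(species = paste0(toupper(letters_part), digits_part),
       upper = letters_part == toupper(letters_part))
}

.macro_of_species <- function(species) {
  codes <- unique(.species_code_num(species))
  num <- suppressWarnings(as.numeric(codes))
  codes <- codes[order(num, codes)]
  if (length(codes) == 1L) paste0("ID_", codes, "_", codes)
  else if (length(codes) == 2L) paste0("ID_", codes[1L], "_", codes[2L])
  else NA_character_
}

.new_pattern <- function(topology, order, backbone, branches) {
  species <- c(backbone$species, branches$species)
  structure(list(topology = topology, order = as.integer(order),
                 backbone = backbone, branches = branches,
                 macro = .macro_of_species(species)),
            class = "danai_pattern")
}

#' Parse a DANAI statement
#'
#' @param text a single statement, e.g. `"[J4]c182:c182(:c182):c182"`.
#' @return an object of class `danai_pattern` with fields `topology`
#'   (`"L"`, `"R"` or `"J"`), `order`, `backbone` (data.frame `species`,
#'   `upper`), `branches` (data.frame `attach`, `species`, `upper`; `attach`
#'   indexes the backbone) and `macro`.  For rings the backbone includes the
#'   repeated closure species; the distinct ring members are rows
#'   `1:order`.
#' @examples
#' parse_danai("[L2]C182:C180")
#' @export
parse_danai <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- trimws(text)
  hm <- regexec("^\\[([A-Za-z])([0-9]+)\\]", s)[[1L]]
  if (hm[1L] == -1L)
    .danai_err(text, 1L, "statement must open with a [<topology><order>] header")
  hdr <- regmatches(s, regexec("^\\[([A-Za-z])([0-9]+)\\]", s))[[1L]]
  topo <- toupper(hdr[2L])
  order <- as.integer(hdr[3L])
  if (!topo %in% c("L", "R", "J"))
    .danai_err(text, 2L, paste0("unknown topology letter '", hdr[2L], "'"))
  pos <- nchar(hdr[1L]) + 1L
  n <- nchar(s)

  backbone <- list()
  branches <- list()
  pending_fwd <- list()
  prev <- "start"   # start | species | colon | fwd | back
  while (pos <= n) {
    ch <- substr(s, pos, pos)
    rest <- substr(s, pos, n)
    if (ch == ":") {
      if (!prev %in% c("species", "back"))
        .danai_err(text, pos, "misplaced ':' (dangling or doubled colon)")
      prev <- "colon"
      pos <- pos + 1L
    } else if (ch == "(") {
      bm <- regexec("^\\(([A-Za-z]+[0-9]+):\\)", rest)[[1L]]
      if (bm[1L] != -1L) {  # (X:) binds forward
        tok <- regmatches(rest, regexec("^\\(([A-Za-z]+[0-9]+):\\)", rest))[[1L]][2L]
        if (!prev %in% c("colon", "fwd"))
          .danai_err(text, pos, "forward branch '(X:)' must follow a ':'")
        pending_fwd[[length(pending_fwd) + 1L]] <-
          .parse_species_token(tok, text, pos + 1L)
        prev <- "fwd"
        pos <- pos + nchar(tok) + 3L
      } else {
        bm <- regexec("^\\(:([A-Za-z]+[0-9]+)\\)", rest)[[1L]]
        if (bm[1L] == -1L)
          .danai_err(text, pos, "malformed branch group (expected '(X:)' or '(:X)')")
        tok <- regmatches(rest, regexec("^\\(:([A-Za-z]+[0-9]+)\\)", rest))[[1L]][2L]
        if (!prev %in% c("species", "back"))
          .danai_err(text, pos, "backward branch '(:X)' must follow a species")
        sp <- .parse_species_token(tok, text, pos + 2L)
        branches[[length(branches) + 1L]] <-
          c(list(attach = length(backbone)), sp)
        prev <- "back"
        pos <- pos + nchar(tok) + 3L
      }
    } else {
      tm <- regexec("^[A-Za-z]+[0-9]+", rest)[[1L]]
      if (tm[1L] == -1L)
        .danai_err(text, pos, paste0("unexpected character '", ch, "'"))
      tok <- substr(rest, 1L, attr(tm, "match.length"))
      if (!prev %in% c("start", "colon", "fwd"))
        .danai_err(text, pos, "missing ':' between species")
      sp <- .parse_species_token(tok, text, pos)
      backbone[[length(backbone) + 1L]] <- sp
      for (b in pending_fwd)
        branches[[length(branches) + 1L]] <-
          c(list(attach = length(backbone)), b)
      pending_fwd <- list()
      prev <- "species"
      pos <- pos + nchar(tok)
    }
  }
  if (prev == "colon") .danai_err(text, n, "dangling trailing ':'")
  if (length(pending_fwd))
    .danai_err(text, n, "forward branch '(X:)' has no following species")
  if (!length(backbone)) .danai_err(text, pos, "statement has no species")

  bb <- data.frame(species = vapply(backbone, `[[`, character(1), "species"),
                   upper = vapply(backbone, `[[`, logical(1), "upper"))
  br <- if (length(branches))
    data.frame(attach = vapply(branches, `[[`, integer(1), "attach"),
               species = vapply(branches, `[[`, character(1), "species"),
               upper = vapply(branches, `[[`, logical(1), "upper"))
  else data.frame(attach = integer(0), species = character(0),
                  upper = logical(0))

  len <- nrow(bb)
  if (topo == "L") {
    if (nrow(br)) .danai_err(text, 1L, "linear (L) patterns take no branches")
    if (len != order)
      .danai_err(text, 1L, sprintf("L%d statement must list %d species, found %d",
                                   order, order, len))
    if (order < 2L) .danai_err(text, 1L, "linear order must be at least 2")
  } else if (topo == "R") {
    if (nrow(br)) .danai_err(text, 1L, "ring (R) patterns take no branches")
    if (len != order + 1L)
      .danai_err(text, 1L,
                 sprintf("R%d statement must list %d species (closure repeated), found %d",
                         order, order + 1L, len))
    if (order < 3L) .danai_err(text, 1L, "ring order must be at least 3")
    if (bb$species[1L] != bb$species[len] || bb$upper[1L] != bb$upper[len])
      .danai_err(text, 1L, "ring closure: first and last species must be identical")
  } else {  # J
    if (!nrow(br))
      .danai_err(text, 1L, "junction (J) patterns need at least one branch")
    if (len + nrow(br) != order)
      .danai_err(text, 1L,
                 sprintf("J%d statement must involve %d species, found %d",
                         order, order, len + nrow(br)))
    if (any(br$attach <= 1L | br$attach >= len))
      .danai_err(text, 1L, "branches must attach to an interior backbone species")
  }
  .new_pattern(topo, order, bb, br)
}

.species_text <- function(species, upper) {
  letters_part <- sub("[0-9]+$", "", species)
  digits_part <- sub("^[A-Za-z]+", "", species)
  paste0(ifelse(upper, toupper(letters_part), tolower(letters_part)),
         digits_part)
}

#' Serialize a pattern to its DANAI statement
#'
#' Inverse of [parse_danai()]: `parse_danai(format_danai(p))` reproduces `p`,
#' and formatting is byte-identical on all canonical built-in statements.
#' Branches at one attachment point are emitted half before the species (as
#' `"(X:)"`) and half after (as `"(:X)"`), matching the published writing of
#' the junction modes.
#'
#' @param p a `danai_pattern`.
#' @return the statement text.
#' @export
format_danai <- function(p) {
  stopifnot(inherits(p, "danai_pattern"))
  groups <- character(nrow(p$backbone))
  for (i in seq_len(nrow(p$backbone))) {
    here <- which(p$branches$attach == i)
    npre <- length(here) %/% 2L
    pre <- here[seq_len(npre)]
    post <- setdiff(here, pre)
    groups[i] <- paste0(
      paste0(vapply(pre, function(b) paste0(
        "(", .species_text(p$branches$species[b], p$branches$upper[b]), ":)"),
        character(1)), collapse = ""),
      .species_text(p$backbone$species[i], p$backbone$upper[i]),
      paste0(vapply(post, function(b) paste0(
        "(:", .species_text(p$branches$species[b], p$branches$upper[b]), ")"),
        character(1)), collapse = ""))
  }
  paste0("[", p$topology, p$order, "]", paste(groups, collapse = ":"))
}

#' @export
print.danai_pattern <- function(x, ...) {
  cat("<danai_pattern>", format_danai(x), "\n")
  cat("  topology:", x$topology, " order:", x$order, " macro:", x$macro, "\n")
  invisible(x)
}

#' @export
format.danai_pattern <- function(x, ...) format_danai(x)

# sort key of one (species, upper) element.  The published statements write
# the higher species code first ([L2]c182:c180), so the element order ranks
# species by DESCENDING numeric code, then code text, then uppercase before
# lowercase.
.elem_key <- function(species, upper) {
  num <- suppressWarnings(as.numeric(.species_code_num(species)))
  num[is.na(num)] <- 0
  paste0(sprintf("%08.0f", 1e8 - num), species, ifelse(upper, "0", "1"))
}

# TRUE if key sequence a < b lexicographically (element-wise)
.seq_less <- function(a, b) {
  for (i in seq_len(min(length(a), length(b)))) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  length(a) < length(b)
}

#' Canonicalize a pattern
#'
#' Collapses the symmetric rewritings of one abstract motif onto a single
#' representative: linear backbones take the lexicographically smaller of
#' the two reading directions; junction backbones likewise, with branches
#' sorted; rings open at the majority species (the published writing
#' convention), with the remaining members ordered so that minority species
#' come first.  Case flags are never changed.  Idempotent.
#'
#' @param p a `danai_pattern`.
#' @return the canonical `danai_pattern`.
#' @export
canonicalize_danai <- function(p) {
  stopifnot(inherits(p, "danai_pattern"))
  bb <- p$backbone
  keys <- .elem_key(bb$species, bb$upper)
  if (p$topology == "L") {
    if (.seq_less(rev(keys), keys)) bb <- bb[rev(seq_len(nrow(bb))), ]
    rownames(bb) <- NULL
    return(.new_pattern("L", p$order, bb, p$branches))
  }
  if (p$topology == "R") {
    memb <- bb[seq_len(p$order), , drop = FALSE]
    mk <- .elem_key(memb$species, memb$upper)
    k <- length(mk)
    cands <- list()
    for (r in 0:(k - 1L)) {
      rot <- c((r + 1L):k, seq_len(r))[seq_len(k)]
      cands[[length(cands) + 1L]] <- rot
      cands[[length(cands) + 1L]] <- rev(rot)
    }
    # closure = majority element (ties: smallest key)
    tab <- table(mk)
    closure <- min(names(tab)[tab == max(tab)])
    cands <- Filter(function(ix) mk[ix[1L]] == closure, cands)
    # among openings at the closure species, minimize the remainder under an
    # order that ranks non-closure species first (puts the minority early)
    rank_key <- function(ix) paste0(ifelse(mk[ix] == closure, "1", "0"), mk[ix])
    best <- cands[[1L]]
    for (cand in cands[-1L])
      if (.seq_less(rank_key(cand), rank_key(best))) best <- cand
    memb <- memb[best, , drop = FALSE]
    bb2 <- rbind(memb, memb[1L, ])
    rownames(bb2) <- NULL
    return(.new_pattern("R", p$order, bb2, p$branches))
  }
  # J: minimal backbone orientation, then branches sorted by (attach, key)
  len <- nrow(bb)
  br <- p$branches
  orient <- function(bbo, bro) {
    bro <- bro[order(bro$attach, .elem_key(bro$species, bro$upper)), ,
               drop = FALSE]
    rownames(bbo) <- NULL; rownames(bro) <- NULL
    list(bb = bbo, br = bro)
  }
  fwd <- orient(bb, br)
  rbr <- br; rbr$attach <- len + 1L - br$attach
  rv <- orient(bb[rev(seq_len(len)), , drop = FALSE], rbr)
  keyed <- function(o) c(.elem_key(o$bb$species, o$bb$upper),
                         sprintf("%03d%s", o$br$attach,
                                 .elem_key(o$br$species, o$br$upper)))
  pick <- if (.seq_less(keyed(rv), keyed(fwd))) rv else fwd
  .new_pattern("J", p$order, pick$bb, pick$br)
}

.builtin_statements <- list(
  ID_182_182 = c("[L2]C182:C182",
                 "[L2]c182:c182",
                 "[L3]c182:c182:c182",
                 "[R3]c182:c182:c182:c182",
                 "[J4]c182:c182(:c182):c182",
                 "[J4]C182:C182(:C182):C182",
                 "[J5]c182:(c182:)c182(:c182):c182"),
  ID_180_180 = c("[L2]C180:C180",
                 "[L2]c180:c180",
                 "[L3]c180:c180:c180",
                 "[R3]c180:c180:c180:c180",
                 "[J4]c180:c180(:c180):c180",
                 "[J4]C180:C180(:C180):C180",
                 "[J5]c180:(c180:)c180(:c180):c180"),
  ID_180_182 = c("[L2]C182:C180",
                 "[L2]c182:c180",
                 "[L3]c182:c180:c182",
                 "[R3]c182:c180:c182:c182",
                 "[L3]c180:c182:c180",
                 "[R3]c180:c182:c180:c180"))

#' The built-in mode set
#'
#' The 20 micro-interaction modes analyzed for the two-center fluoroalkane
#' system, grouped by macro class (7 + 7 + 6) in the published listing
#' order.
#'
#' @return an object of class `danai_modes`: a named list of
#'   `danai_pattern`s (names are the canonical statements) with a `macro`
#'   attribute giving each mode's macro class.
#' @export
builtin_modes <- function() {
  stmts <- unlist(.builtin_statements, use.names = FALSE)
  macros <- rep(names(.builtin_statements),
                vapply(.builtin_statements, length, integer(1)))
  pats <- lapply(stmts, parse_danai)
  names(pats) <- stmts
  structure(pats, macro = macros, class = "danai_modes")
}

#' @export
print.danai_modes <- function(x, ...) {
  cat(sprintf("<danai_modes> %d modes\n", length(x)))
  macro <- attr(x, "macro")
  for (m in unique(macro))
    cat(" ", m, ":", paste(names(x)[macro == m], collapse = "  "), "\n")
  invisible(x)
}

# positions/edges view of a pattern: backbone positions first, then branch
# positions; returns labels, edge matrix and per-position role degree.
.pattern_graph <- function(p) {
  bb <- p$backbone
  br <- p$branches
  if (p$topology == "R") {
    k <- p$order
    labels <- data.frame(species = bb$species[seq_len(k)],
                         upper = bb$upper[seq_len(k)])
    e <- cbind(seq_len(k), c(seq_len(k)[-1L], 1L))
  } else {
    labels <- data.frame(species = c(bb$species, br$species),
                         upper = c(bb$upper, br$upper))
    e <- NULL
    if (nrow(bb) > 1L)
      e <- cbind(seq_len(nrow(bb) - 1L), seq_len(nrow(bb) - 1L) + 1L)
    if (nrow(br))
      e <- rbind(e, cbind(br$attach, nrow(bb) + seq_len(nrow(br))))
  }
  e <- matrix(as.integer(e), ncol = 2L)
  deg <- tabulate(c(e[, 1L], e[, 2L]), nbins = nrow(labels))
  list(k = nrow(labels), labels = labels, edges = e, roledeg = deg)
}
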