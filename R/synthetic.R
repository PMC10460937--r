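#' Synthetic dimer liquid generator
#'
#' Generates trajectories of a reduced two-center model of the study liquid:
#' each molecule is a bonded C180-C182 site pair ("dimer") at a fixed bond
#' length, placed at a uniformly random position and orientation in a
#' periodic cubic box, rejection-sampled so that no intermolecular site pair
#' comes closer than `min_separation` under the minimum image convention.
#' Defaults mirror the published system scale: 1000 molecules in a 53 A
#' cubic box.  Successive frames are independent redraws — the generator
#' emulates the static packing statistics of the liquid, not its dynamics.
#' Frames are stamped every 4 ps (2000 MD steps), the write-out cadence of
#' the source simulations.
#'
#' @param n_molecules number of dimer molecules (default 1000).
#' @param box_length cubic box edge, Angstrom (default 53).
#' @param bond_length intramolecular C-C site distance, Angstrom
#'   (default 1.5).
#' @param min_separation smallest allowed intermolecular site distance,
#'   Angstrom (default 2.0, a hard-sphere clash criterion).
#' @param n_frames number of independent frames (default 1).
#' @param seed RNG seed; the same spec and seed give a bit-identical
#'   trajectory.
#' @param max_attempts placement attempts per molecule before the generator
#'   gives up (density too high).
#' @return an [trajectory()] object with `2 * n_molecules` atoms per frame
#'   (per molecule: one `C180` then one `C182` site; `molecule_size = 2`).
#' @export
generate_liquid <- function(n_molecules = 1000L, box_length = 53,
                            bond_length = 1.5, min_separation = 2.0,
                            n_frames = 1L, seed = 1L,
                            max_attempts = 200L) {
  stopifnot(n_molecules >= 1L, box_length > 0, bond_length > 0,
            n_frames >= 1L)
  if (min_separation >= box_length / 2)
    stop("min_separation must be below half the box length")
  set.seed(as.integer(seed))
  cl <- cubic_cell(box_length)
  L <- box_length
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    pos <- matrix(NA_real_, 2L * n_molecules, 3L)
    placed <- 0L
    for (m in seq_len(n_molecules)) {
      ok <- FALSE
      for (try in seq_len(max_attempts)) {
        ctr <- stats::runif(3L, 0, L)
        ax <- stats::rnorm(3L)
        ax <- ax / sqrt(sum(ax * ax))
        s1 <- (ctr - ax * bond_length / 2) %% L
        s2 <- (ctr + ax * bond_length / 2) %% L
        if (placed > 0L) {
          prev <- pos[seq_len(2L * placed), , drop = FALSE]
          d2 <- c(.min_image_dist2(sweep(prev, 2L, s1), cl),
                  .min_image_dist2(sweep(prev, 2L, s2), cl))
          if (min(d2) < min_separation^2) next
        }
        pos[2L * m - 1L, ] <- s1
        pos[2L * m, ] <- s2
        placed <- placed + 1L
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf(
          "generation error: could not place molecule %d of %d (placed %d); density too high",
          m, n_molecules, placed))
    }
    atoms <- data.frame(
      label = rep(c("C180", "C182"), n_molecules),
      index = seq_len(2L * n_molecules),
      molecule = rep(seq_len(n_molecules) - 1L, each = 2L),
      x = pos[, 1L], y = pos[, 2L], z = pos[, 3L],
      mass = 12.011, charge = 0)
    frames[[f]] <- frame(step = (f - 1L) * 2000L, time = (f - 1L) * 4,
                         cl = cl, atoms = atoms)
  }
  trajectory(frames, source = sprintf("generate_liquid(n=%d, L=%g, seed=%d)",
                                      n_molecules, box_length, seed))
}

# unit directions for the motif-site layout of each supported topology
.motif_directions <- list(
  planar3 = t(vapply(0:2, function(i)
    c(cos(2 * pi * i / 3), sin(2 * pi * i / 3), 0), numeric(3))),
  tetra4 = matrix(c(1, 1, 1,  1, -1, -1,  -1, 1, -1,  -1, -1, 1) / sqrt(3),
                  4L, 3L, byrow = TRUE))

#' Plant a single motif instance in an otherwise empty frame
#'
#' Builds a frame of two-site dimer molecules whose contact graph at the
#' given cutoff contains *exactly* one instance of the pattern and no other
#' intermolecular edge: each pattern node becomes one site of its own
#' molecule, motif edges are realized at `0.96 * cutoff`, non-adjacent motif
#' sites are kept beyond `1.1 * cutoff`, and every companion (bonded
#' partner) site is parked on a wide ring far outside the cutoff of
#' everything else.  The whole construction is rigidly rotated at random
#' (seeded) and centered in the box.
#'
#' @param p a `danai_pattern` from the supported family (L2, L3, R3, J4,
#'   J5; species `C180`/`C182`, any case).
#' @param cutoff intended analysis cutoff, Angstrom (default 5).
#' @param box_length cubic box edge, Angstrom (default 53; must exceed
#'   7 x cutoff so the parked companions stay clear across images).
#' @param seed RNG seed for the rigid rotation.
#' @return an [frame()] object (`molecule_size = 2`).
#' @export
plant_pattern <- function(p, cutoff = 5, box_length = 53, seed = 1L) {
  stopifnot(inherits(p, "danai_pattern"), cutoff > 0)
  if (box_length <= 7 * cutoff)
    stop("box_length must exceed 7 * cutoff for a clean planted frame")
  pg <- .pattern_graph(p)
  fam <- paste0(p$topology, p$order)
  star <- if (p$topology == "J") .as_star(pg) else NULL
  r <- 0.96 * cutoff
  k <- pg$k
  site <- matrix(0, k, 3L)
  if (fam == "L2") {
    site[2L, ] <- c(r, 0, 0)
  } else if (fam == "L3") {
    site[1L, ] <- c(-r, 0, 0)
    site[3L, ] <- c(r, 0, 0)
  } else if (fam == "R3") {
    site <- r * rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  } else if (fam %in% c("J4", "J5") && !is.null(star)) {
    dirs <- if (fam == "J4") .motif_directions$planar3
            else .motif_directions$tetra4
    site[star$leaves, ] <- r * dirs
  } else {
    stop("unsupported pattern: plant_pattern covers the L2/L3/R3/J4/J5 star family")
  }
  if (!all(pg$labels$species %in% c("C180", "C182")))
    stop("unsupported species: planted dimers carry C180/C182 sites only")

  # companions parked on a wide ring around the motif centroid
  centroid <- colMeans(site)
  Rc <- 2.5 * cutoff
  comp <- t(vapply(seq_len(k), function(j) {
    th <- 2 * pi * (j - 1L) / k
    centroid + Rc * c(cos(th), sin(th), 0)
  }, numeric(3)))

  set.seed(as.integer(seed))
  rot <- qr.Q(qr(matrix(stats::rnorm(9L), 3L)))
  if (det(rot) < 0) rot[, 1L] <- -rot[, 1L]
  shift <- rep(box_length / 2, 3L)
  site <- sweep(site %*% rot, 2L, shift, "+")
  comp <- sweep(comp %*% rot, 2L, shift, "+")

  other <- function(sp) if (sp == "C182") "C180" else "C182"
  lab <- character(2L * k); posm <- matrix(0, 2L * k, 3L)
  for (j in seq_len(k)) {
    sp <- pg$labels$species[j]
    pair_lab <- c("C180", "C182")
    rows <- c(2L * j - 1L, 2L * j)
    if (sp == "C180") {
      posm[rows[1L], ] <- site[j, ]; posm[rows[2L], ] <- comp[j, ]
    } else {
      posm[rows[1L], ] <- comp[j, ]; posm[rows[2L], ] <- site[j, ]
    }
    lab[rows] <- pair_lab
  }
  atoms <- data.frame(label = lab, index = seq_len(2L * k),
                      molecule = rep(seq_len(k) - 1L, each = 2L),
                      x = posm[, 1L], y = posm[, 2L], z = posm[, 3L],
                      mass = 12.011, charge = 0)
  frame(step = 0L, time = 0, cl = cubic_cell(box_length), atoms = atoms)
}
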