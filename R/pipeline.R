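#' Analyze a frame or trajectory end to end
#'
#' Convenience drivers tying the pipeline together: extract tagged centers,
#' build the intermolecular contact graph at the cutoff, and count every
#' mode of the mode set.
#'
#' @param fr an [frame()] object.
#' @param cutoff contact distance criterion, Angstrom (default 5).
#' @param tags species codes of the interaction centers.
#' @param modes mode set (default [builtin_modes()]).
#' @param s a [semantics_config()].
#' @return `analyze_frame`: a named count vector (see [count_modes()]);
#'   `analyze_trajectory`: a [build_series()] object.
#' @export
analyze_frame <- function(fr, cutoff = 5, tags = c("C180", "C182"),
                          modes = builtin_modes(), s = semantics_config()) {
  centers <- extract_centers(fr, tags)
  g <- build_contact_graph(centers, fr$cell, cutoff = cutoff)
  count_modes(g, modes, s, step = fr$step, time = fr$time)
}

#' @rdname analyze_frame
#' @param traj an [trajectory()] object.
#' @param verbose log per-frame progress to standard error.
#' @export
analyze_trajectory <- function(traj, cutoff = 5, tags = c("C180", "C182"),
                               modes = builtin_modes(),
                               s = semantics_config(), verbose = FALSE) {
  stopifnot(inherits(traj, "md_trajectory"))
  per_frame <- vector("list", length(traj$frames))
  for (i in seq_along(traj$frames)) {
    per_frame[[i]] <- analyze_frame(traj$frames[[i]], cutoff, tags, modes, s)
    if (verbose)
      message(sprintf("frame %d/%d (t = %g ps) processed",
                      i, length(traj$frames), traj$frames[[i]]$time))
  }
  build_series(per_frame)
}
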