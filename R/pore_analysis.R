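# Pore envelope definition, hydration counting, crystallographic-water
# matching and positional RMSD.

#' Define the pore envelope
#'
#' The primary envelope is a capped cylinder around the segment between two
#' endpoint atoms (default: the carboxylate carbons CD of Glu908 and Glu918),
#' extended axially by `axis_padding` at both ends; a water oxygen is inside
#' when its axial projection lies within the padded segment and its radial
#' distance is at most `cylinder_radius` (closed boundaries). The
#' alternative `"lining"` mode instead counts waters within `lining_cutoff`
#' of any polar (O/N) atom of the lining residues.
#'
#' @param lining_residues residue ids lining the pore (used by `"lining"`
#'   mode); defaults to the seven pathway residues.
#' @param axis_endpoints list of two selectors, each
#'   `list(residue_id=, atom_name=)`.
#' @param cylinder_radius cylinder radius (Angstrom, > 0).
#' @param axis_padding axial extension beyond the endpoints (Angstrom).
#' @param mode `"cylinder"` (default) or `"lining"`.
#' @param lining_cutoff distance cutoff for `"lining"` mode (Angstrom).
#' @param chain_id optional chain restriction for all selections.
#' @return Object of class `pore_definition`.
#' @export
pore_definition <- function(lining_residues = c(767, 836, 837, 908, 911, 914, 918),
                            axis_endpoints = list(
                              list(residue_id = 908, atom_name = "CD"),
                              list(residue_id = 918, atom_name = "CD")),
                            cylinder_radius = 5.0, axis_padding = 2.0,
                            mode = c("cylinder", "lining"),
                            lining_cutoff = 4.5, chain_id = NULL) {
  mode <- match.arg(mode)
  stopifnot(cylinder_radius > 0, axis_padding >= 0, lining_cutoff > 0,
            length(axis_endpoints) == 2)
  structure(list(lining_residues = as.integer(lining_residues),
                 axis_endpoints = axis_endpoints,
                 cylinder_radius = cylinder_radius,
                 axis_padding = axis_padding, mode = mode,
                 lining_cutoff = lining_cutoff, chain_id = chain_id),
            class = "pore_definition")
}

resolve_pore_endpoints <- function(topology, pore) {
  vapply(pore$axis_endpoints, function(s) {
    hit <- atom_select(topology, residue_id = s$residue_id,
                       atom_name = s$atom_name, chain_id = pore$chain_id)
    if (length(hit) != 1) {
      stop("pore axis endpoint (residue ", s$residue_id, ", atom ",
           s$atom_name, ") resolves to ", length(hit), " atoms")
    }
    hit
  }, integer(1))
}

#' Water oxygens inside the pore in one frame
#'
#' @param frame a [frame()].
#' @param topology the matching [topology()].
#' @param pore a [pore_definition()].
#' @return Sorted integer vector of water-oxygen ordinals inside the
#'   envelope.
#' @export
waters_in_pore <- function(frame, topology, pore) {
  stopifnot(inherits(frame, "frame"), inherits(pore, "pore_definition"))
  wo <- water_oxygens(topology)
  if (length(wo) == 0) return(integer(0))
  xyz <- frame$xyz
  if (pore$mode == "lining") {
    lin <- atom_select(topology, residue_id = pore$lining_residues,
                       chain_id = pore$chain_id, element = c("O", "N"))
    if (length(lin) == 0) stop("lining residues resolve to zero polar atoms")
    keep <- vapply(wo, function(w) {
      any(pair_dist(xyz, rep(w, length(lin)), lin, frame$box) <=
            pore$lining_cutoff)
    }, logical(1))
    return(wo[keep])
  }
  ep <- resolve_pore_endpoints(topology, pore)
  a <- xyz[ep[1], ]
  ab <- as.vector(min_image(matrix(xyz[ep[2], ] - a, 1), frame$box))
  L <- sqrt(sum(ab^2))
  u <- ab / L
  rel <- min_image(sweep(xyz[wo, , drop = FALSE], 2, a), frame$box)
  t_ax <- as.vector(rel %*% u)
  radial <- sqrt(pmax(0, rowSums(rel^2) - t_ax^2))
  inside <- t_ax >= -pore$axis_padding & t_ax <= L + pore$axis_padding &
    radial <= pore$cylinder_radius
  sort(wo[inside])
}

#' Pore-hydration time series
#'
#' Counts pore waters in each sampled frame; frames are sampled at
#' `interval_ps` (which must be an integer multiple of, and at least, the
#' frame spacing), mirroring the convention of reporting pore water counts
#' at fixed intervals.
#'
#' @param frames list of [frame()] objects with uniformly spaced times.
#' @param topology the matching [topology()].
#' @param pore a [pore_definition()].
#' @param interval_ps sampling interval (ps); default every frame.
#' @param windows optional list of `c(start, end)` time windows (ps, closed)
#'   over which mean counts are reported.
#' @return list of class `hydration_series`: `series` (data.frame `time`,
#'   `count`), `interval`, `window_means` (data.frame `start`, `end`,
#'   `mean_count`; `NULL` when no windows), `pore_ids` (per sampled frame,
#'   the ordinals counted).
#' @export
hydration_timeseries <- function(frames, topology, pore, interval_ps = NULL,
                                 windows = NULL) {
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (length(frames) > 1) {
    dt <- diff(times)
    spacing <- dt[1]
    if (any(dt <= 0)) stop("frame times must be strictly increasing")
  } else {
    spacing <- NA_real_
  }
  if (is.null(interval_ps)) {
    keep <- seq_along(frames)
    interval_ps <- spacing
  } else {
    if (!is.na(spacing)) {
      if (interval_ps < spacing) {
        stop("interval_ps (", interval_ps, ") is smaller than the frame ",
             "spacing (", spacing, ")")
      }
      k <- interval_ps / spacing
      if (abs(k - round(k)) > 1e-9) {
        stop("interval_ps must be an integer multiple of the frame spacing")
      }
      keep <- seq(1, length(frames), by = as.integer(round(k)))
    } else {
      keep <- 1L
    }
  }
  ids <- lapply(frames[keep], waters_in_pore, topology = topology, pore = pore)
  series <- data.frame(time = times[keep],
                       count = vapply(ids, length, integer(1)))
  wm <- NULL
  if (!is.null(windows)) {
    wm <- do.call(rbind, lapply(windows, function(w) {
      sel <- series$time >= w[1] & series$time <= w[2]
      data.frame(start = w[1], end = w[2],
                 mean_count = if (any(sel)) mean(series$count[sel]) else NA_real_)
    }))
  }
  structure(list(series = series, interval = interval_ps,
                 window_means = wm, pore_ids = ids),
            class = "hydration_series")
}

#' @export
print.hydration_series <- function(x, ...) {
  cat("hydration series:", nrow(x$series), "samples, interval",
      x$interval, "ps, mean count", round(mean(x$series$count), 2), "\n")
  if (!is.null(x$window_means)) {
    for (i in seq_len(nrow(x$window_means))) {
      cat(sprintf("  window [%g, %g] ps: mean %.2f waters\n",
                  x$window_means$start[i], x$window_means$end[i],
                  x$window_means$mean_count[i]))
    }
  }
  invisible(x)
}

#' Match simulation waters to crystallographic waters
#'
#' Greedy nearest-neighbour matching in ascending displacement order among
#' all pairs closer than `cutoff_A` (strict, matching the "RMSD < 2 A"
#' convention for single waters); each crystal water and each simulation
#' water is matched at most once. Both frames must already be superposed
#' (see [superpose()]).
#'
#' @param sim_frame,crystal_frame [frame()] objects in a common reference
#'   frame.
#' @param sim_waters,crystal_waters ordinals of the water oxygens to match
#'   (into their respective frames).
#' @param cutoff_A matching cutoff (Angstrom, > 0).
#' @return list of class `overlap_result`: `matches` (data.frame
#'   `sim_ordinal`, `crystal_ordinal`, `displacement`), `unmatched_crystal`,
#'   `unmatched_sim`, `cutoff`.
#' @export
match_crystal_waters <- function(sim_frame, sim_waters, crystal_frame,
                                 crystal_waters, cutoff_A = 2.0) {
  stopifnot(cutoff_A > 0)
  empty <- data.frame(sim_ordinal = integer(0), crystal_ordinal = integer(0),
                      displacement = numeric(0))
  if (length(sim_waters) == 0 || length(crystal_waters) == 0) {
    return(structure(list(matches = empty,
                          unmatched_crystal = crystal_waters,
                          unmatched_sim = sim_waters, cutoff = cutoff_A),
                     class = "overlap_result"))
  }
  sx <- sim_frame$xyz[sim_waters, , drop = FALSE]
  cx <- crystal_frame$xyz[crystal_waters, , drop = FALSE]
  d <- outer(seq_len(nrow(sx)), seq_len(nrow(cx)), function(i, j) {
    sqrt(rowSums((sx[i, , drop = FALSE] - cx[j, , drop = FALSE])^2))
  })
  cand <- which(d < cutoff_A, arr.ind = TRUE)
  if (nrow(cand) > 0) {
    # ascending displacement; deterministic tie-break by ordinals
    o <- order(d[cand], sim_waters[cand[, 1]], crystal_waters[cand[, 2]])
    cand <- cand[o, , drop = FALSE]
  }
  used_s <- logical(nrow(sx)); used_c <- logical(nrow(cx))
  rows <- list()
  for (r in seq_len(nrow(cand))) {
    i <- cand[r, 1]; j <- cand[r, 2]
    if (used_s[i] || used_c[j]) next
    used_s[i] <- TRUE; used_c[j] <- TRUE
    rows[[length(rows) + 1]] <- data.frame(
      sim_ordinal = sim_waters[i], crystal_ordinal = crystal_waters[j],
      displacement = d[i, j])
  }
  matches <- if (length(rows) > 0) do.call(rbind, rows) else empty
  structure(list(matches = matches,
                 unmatched_crystal = crystal_waters[!used_c],
                 unmatched_sim = sim_waters[!used_s],
                 cutoff = cutoff_A),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("crystal-water overlap:", nrow(x$matches), "matched,",
      length(x$unmatched_crystal), "crystal waters unmatched (cutoff",
      x$cutoff, "A)\n")
  invisible(x)
}

#' Least-squares rigid-body superposition
#'
#' Superposes `mobile_frame` onto `reference_frame` using the fit atoms
#' (Kabsch least squares via `bio3d::fit.xyz()`), and reports the RMSD over
#' the fit atoms after superposition.
#'
#' @param mobile_frame,reference_frame [frame()] objects.
#' @param fit_atoms ordinals of the fit atoms in the mobile frame
#'   (>= 3, non-collinear).
#' @param fit_atoms_ref ordinals in the reference frame (default: same).
#' @return list: `frame` (transformed mobile frame; periodic box dropped,
#'   the transform breaks lattice alignment) and `rmsd` (Angstrom).
#' @export
superpose <- function(mobile_frame, reference_frame, fit_atoms,
                      fit_atoms_ref = fit_atoms) {
  stopifnot(length(fit_atoms) == length(fit_atoms_ref))
  if (length(fit_atoms) < 3) {
    stop("superposition needs at least 3 fit atoms")
  }
  m <- mobile_frame$xyz[fit_atoms, , drop = FALSE]
  sv <- svd(sweep(m, 2, colMeans(m)))
  if (sum(sv$d > 1e-8 * max(sv$d)) < 2) {
    stop("fit atoms are collinear; superposition is ill-determined")
  }
  moved <- bio3d::fit.xyz(
    fixed = as.vector(t(reference_frame$xyz)),
    mobile = as.vector(t(mobile_frame$xyz)),
    fixed.inds = bio3d::atom2xyz(fit_atoms_ref),
    mobile.inds = bio3d::atom2xyz(fit_atoms))
  new_xyz <- matrix(moved, ncol = 3, byrow = TRUE)
  dev <- new_xyz[fit_atoms, , drop = FALSE] -
    reference_frame$xyz[fit_atoms_ref, , drop = FALSE]
  list(frame = frame(new_xyz, time = mobile_frame$time),
       rmsd = sqrt(mean(rowSums(dev^2))))
}

#' Per-residue positional RMSD along a trajectory
#'
#' Each frame is globally superposed onto the reference on `fit_atoms`; the
#' residue's heavy atoms are then compared position-by-position against the
#' reference (no refitting on the residue). Reports mean and standard
#' deviation over frames — the convention behind per-residue stability
#' figures such as "0.9 +/- 0.1 A".
#'
#' @param frames list of [frame()] objects.
#' @param topology the matching [topology()].
#' @param residue_id residue to monitor.
#' @param reference_frame reference [frame()].
#' @param fit_atoms ordinals used for the global superposition.
#' @param chain_id optional chain restriction.
#' @return list: `per_frame` (data.frame `time`, `rmsd`), `mean`, `sd`.
#' @export
residue_rmsd_series <- function(frames, topology, residue_id, reference_frame,
                                fit_atoms, chain_id = NULL) {
  res <- atom_select(topology, residue_id = residue_id, chain_id = chain_id)
  res <- res[topology$atoms$element[res] != "H"]
  if (length(res) == 0) {
    stop("residue ", residue_id, " resolves to zero heavy atoms")
  }
  ref <- reference_frame$xyz[res, , drop = FALSE]
  vals <- vapply(frames, function(f) {
    fitted <- superpose(f, reference_frame, fit_atoms)$frame
    dev <- fitted$xyz[res, , drop = FALSE] - ref
    sqrt(mean(rowSums(dev^2)))
  }, numeric(1))
  per_frame <- data.frame(time = vapply(frames, `[[`, numeric(1), "time"),
                          rmsd = vals)
  list(per_frame = per_frame, mean = mean(vals),
       sd = if (length(vals) > 1) sd(vals) else 0)
}
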