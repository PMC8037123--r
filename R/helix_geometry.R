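# Helix hinge-bend angle, backbone i -> i+4 hydrogen bond, and gating-contact
# distances.
#
# The bend angle is computed as the angle between the principal axes of the
# two helix flanks on either side of the hinge, each axis fitted by least
# squares through the flank's C-alpha positions and oriented N-terminal to
# C-terminal. The literature this mirrors never states how its bending angle
# was computed, so flank ranges and the C-alpha-only fit are explicit,
# overridable choices here.

#' Helix hinge-bend specification
#'
#' Defaults target the M5 hinge at residues 761-765, with flanks 748-760 and
#' 766-778 (13 residues each) fitted through their C-alpha atoms.
#'
#' @param pre_hinge_range,post_hinge_range `c(first, last)` residue-id
#'   intervals of the flanks; each must span at least 6 residues and be
#'   disjoint from the hinge.
#' @param hinge_range `c(first, last)` hinge interval.
#' @param axis_atoms atom name(s) used for axis fitting.
#' @param chain_id optional chain restriction.
#' @return Object of class `helix_bend_spec`.
#' @export
helix_bend_spec <- function(pre_hinge_range = c(748, 760),
                            post_hinge_range = c(766, 778),
                            hinge_range = c(761, 765),
                            axis_atoms = "CA", chain_id = NULL) {
  span <- function(r) r[2] - r[1] + 1
  stopifnot(length(pre_hinge_range) == 2, length(post_hinge_range) == 2,
            length(hinge_range) == 2)
  if (span(pre_hinge_range) < 6 || span(post_hinge_range) < 6) {
    stop("each flank must span at least 6 residues for a stable axis fit")
  }
  ranges <- list(pre_hinge_range, hinge_range, post_hinge_range)
  ids <- lapply(ranges, function(r) seq(r[1], r[2]))
  if (length(unique(unlist(ids))) != length(unlist(ids))) {
    stop("flank and hinge residue ranges must be disjoint")
  }
  structure(list(pre_hinge_range = pre_hinge_range,
                 post_hinge_range = post_hinge_range,
                 hinge_range = hinge_range, axis_atoms = axis_atoms,
                 chain_id = chain_id),
            class = "helix_bend_spec")
}

#' Fit a helix axis through a set of points
#'
#' Least-squares cylinder axis: starting from the principal axis of the
#' centred coordinates, the axis direction and its lateral offset are
#' refined (Levenberg-Marquardt) to minimise the spread of squared radial
#' distances about the axis. The refinement matters because the raw
#' principal axis of a short helix is biased by 1-2 degrees towards the
#' first residues of an incomplete turn, whereas helix points lie exactly
#' on a circular cylinder, making the cylinder axis exact for ideal
#' geometry. The axis is oriented from the first point toward the last
#' (N-terminal to C-terminal when points come in chain order).
#'
#' @param coords m x 3 matrix of points, in chain order (m >= 3; the
#'   cylinder refinement engages for m >= 5, below that the principal axis
#'   is returned).
#' @return list: `axis` (unit 3-vector), `centroid`.
#' @export
fit_helix_axis <- function(coords) {
  coords <- as_xyz_matrix(coords)
  m <- nrow(coords)
  if (m < 3) stop("axis fitting needs at least 3 points")
  ctr <- colMeans(coords)
  pc <- sweep(coords, 2, ctr)
  sv <- svd(pc)
  u0 <- sv$v[, 1]
  ax <- u0
  if (m >= 5 && sv$d[2] > 1e-8 * sv$d[1]) {
    b1 <- sv$v[, 2]; b2 <- sv$v[, 3]
    # Kasa circle fit in the plane normal to the initial axis seeds the
    # lateral offset of the cylinder axis
    q <- cbind(pc %*% b1, pc %*% b2)
    kasa <- tryCatch({
      beta <- qr.solve(cbind(2 * q, 1), rowSums(q^2))
      beta[1:2]
    }, error = function(e) c(0, 0))
    resid <- function(th) {
      u <- u0 + th[1] * b1 + th[2] * b2
      u <- u / sqrt(sum(u^2))
      qq <- pc - tcrossprod(rep(1, m), th[3] * b1 + th[4] * b2)
      r2 <- rowSums(qq^2) - as.vector(qq %*% u)^2
      r2 - mean(r2)
    }
    o <- minpack.lm::nls.lm(
      par = c(0, 0, kasa[1], kasa[2]), fn = resid,
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                           maxiter = 100))
    ax <- u0 + o$par[1] * b1 + o$par[2] * b2
    ax <- ax / sqrt(sum(ax^2))
  }
  if (sum(ax * (coords[m, ] - coords[1, ])) < 0) ax <- -ax
  list(axis = ax, centroid = ctr)
}

flank_coords <- function(frame, topology, spec, range) {
  ids <- seq(range[1], range[2])
  ords <- unlist(lapply(ids, function(rid) {
    atom_select(topology, residue_id = rid, atom_name = spec$axis_atoms,
                chain_id = spec$chain_id)
  }))
  if (length(ords) < 3) {
    stop("helix flank ", range[1], "-", range[2],
         " resolves to fewer than 3 axis atoms")
  }
  frame$xyz[ords, , drop = FALSE]
}

#' Hinge-bend angle of a kinked helix
#'
#' Angle between the fitted axes of the two flanks, in `[0, 180]` degrees
#' (0 for a straight helix).
#'
#' @param frame a [frame()].
#' @param topology the matching [topology()].
#' @param spec a [helix_bend_spec()].
#' @return Bend angle in degrees.
#' @export
bend_angle <- function(frame, topology, spec = helix_bend_spec()) {
  a1 <- fit_helix_axis(flank_coords(frame, topology, spec,
                                    spec$pre_hinge_range))$axis
  a2 <- fit_helix_axis(flank_coords(frame, topology, spec,
                                    spec$post_hinge_range))$axis
  acos(pmin(1, pmax(-1, sum(a1 * a2)))) * 180 / pi
}

#' Backbone O(i) to N(i+4) hydrogen-bond distance
#'
#' Distance between the carbonyl oxygen of the donor residue and the
#' backbone amide nitrogen of the acceptor residue — the canonical
#' alpha-helical i -> i+4 hydrogen bond (about 3.0 A when intact). The bond
#' is flagged broken when the distance exceeds `cutoff` (a distance exactly
#' at the cutoff counts as intact).
#'
#' @param frame a [frame()].
#' @param topology the matching [topology()].
#' @param donor_residue_id residue providing the backbone O (default 761).
#' @param acceptor_residue_id residue providing the backbone N
#'   (default 765).
#' @param cutoff broken-bond threshold (Angstrom).
#' @param chain_id optional chain restriction.
#' @return list: `distance` (Angstrom), `broken` (logical), `cutoff`.
#' @export
backbone_hbond_distance <- function(frame, topology, donor_residue_id = 761,
                                    acceptor_residue_id = 765, cutoff = 3.5,
                                    chain_id = NULL) {
  o <- atom_select(topology, residue_id = donor_residue_id, atom_name = "O",
                   chain_id = chain_id)
  n <- atom_select(topology, residue_id = acceptor_residue_id,
                   atom_name = "N", chain_id = chain_id)
  if (length(o) != 1 || length(n) != 1) {
    stop("backbone atoms missing: need exactly one O in residue ",
         donor_residue_id, " and one N in residue ", acceptor_residue_id)
  }
  d <- pair_dist(frame$xyz, o, n, frame$box)
  list(distance = d, broken = d > cutoff, cutoff = cutoff)
}

#' Distance between two atom groups
#'
#' Minimum (default) or centroid-to-centroid distance, with a contact flag
#' under the `R < 5` Angstrom clustering criterion.
#'
#' @param frame a [frame()].
#' @param topology the matching [topology()] (unused beyond validation;
#'   kept for interface symmetry).
#' @param group_a,group_b ordinals of the two groups (non-empty).
#' @param mode `"min"` or `"centroid"`.
#' @param contact_cutoff contact threshold (Angstrom, strict `<`).
#' @return list: `distance`, `contact`, `mode`, `contact_cutoff`.
#' @export
contact_distance <- function(frame, topology, group_a, group_b,
                             mode = c("min", "centroid"),
                             contact_cutoff = 5.0) {
  mode <- match.arg(mode)
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("empty atom group in contact_distance")
  }
  xyz <- frame$xyz
  if (mode == "min") {
    ii <- rep(group_a, each = length(group_b))
    jj <- rep(group_b, length(group_a))
    d <- min(pair_dist(xyz, ii, jj, frame$box))
  } else {
    ca <- colMeans(xyz[group_a, , drop = FALSE])
    cb <- colMeans(xyz[group_b, , drop = FALSE])
    d <- sqrt(sum(as.vector(min_image(matrix(cb - ca, 1), frame$box))^2))
  }
  list(distance = d, contact = d < contact_cutoff, mode = mode,
       contact_cutoff = contact_cutoff)
}

#' Helix-geometry time series
#'
#' Per sampled frame: the hinge-bend angle, the Arg762-Ser915 gating
#' distance (minimum over the Arg762 guanidine nitrogens NE/NH1/NH2 to the
#' Ser915 backbone oxygen; one figure label in the source literature reads
#' "Arg762-Arg915", which is taken as Arg762-Ser915 per the body text), and
#' the Ile761 O to Ile765 N backbone hydrogen-bond distance.
#'
#' @param frames list of [frame()] objects.
#' @param topology the matching [topology()].
#' @param spec a [helix_bend_spec()].
#' @param contact_a_residue,contact_a_atoms guanidine group selector
#'   (default Arg762 NE/NH1/NH2).
#' @param contact_b_residue,contact_b_atoms partner selector (default
#'   Ser915 backbone O).
#' @param bb_donor,bb_acceptor backbone hydrogen-bond residue pair
#'   (default 761 -> 765).
#' @param windows optional list of `c(start, end)` time windows (ps) over
#'   which means of all three observables are reported.
#' @return list of class `geometry_series`: `series` (data.frame `time`,
#'   `bend_angle`, `contact_distance`, `backbone_on_distance`),
#'   `window_means` (or `NULL`).
#' @export
geometry_timeseries <- function(frames, topology, spec = helix_bend_spec(),
                                contact_a_residue = 762,
                                contact_a_atoms = c("NE", "NH1", "NH2"),
                                contact_b_residue = 915,
                                contact_b_atoms = "O",
                                bb_donor = 761, bb_acceptor = 765,
                                windows = NULL) {
  ga <- atom_select(topology, residue_id = contact_a_residue,
                    atom_name = contact_a_atoms, chain_id = spec$chain_id,
                    must_resolve = TRUE)
  gb <- atom_select(topology, residue_id = contact_b_residue,
                    atom_name = contact_b_atoms, chain_id = spec$chain_id,
                    must_resolve = TRUE)
  # axis fits are cached across frames with unchanged flank coordinates
  # (static phases of a trajectory), which the cylinder refinement makes
  # worthwhile
  last <- list(pre = NULL, post = NULL, pre_ax = NULL, post_ax = NULL)
  bend_cached <- function(f) {
    cp <- flank_coords(f, topology, spec, spec$pre_hinge_range)
    cq <- flank_coords(f, topology, spec, spec$post_hinge_range)
    if (!identical(cp, last$pre)) {
      last$pre <<- cp; last$pre_ax <<- fit_helix_axis(cp)$axis
    }
    if (!identical(cq, last$post)) {
      last$post <<- cq; last$post_ax <<- fit_helix_axis(cq)$axis
    }
    acos(pmin(1, pmax(-1, sum(last$pre_ax * last$post_ax)))) * 180 / pi
  }
  rows <- lapply(frames, function(f) {
    data.frame(
      time = f$time,
      bend_angle = bend_cached(f),
      contact_distance = contact_distance(f, topology, ga, gb)$distance,
      backbone_on_distance = backbone_hbond_distance(
        f, topology, bb_donor, bb_acceptor, chain_id = spec$chain_id)$distance)
  })
  series <- do.call(rbind, rows)
  wm <- NULL
  if (!is.null(windows)) {
    wm <- do.call(rbind, lapply(windows, function(w) {
      sel <- series$time >= w[1] & series$time <= w[2]
      data.frame(start = w[1], end = w[2],
                 mean_bend_angle = mean(series$bend_angle[sel]),
                 mean_contact_distance = mean(series$contact_distance[sel]),
                 mean_backbone_on_distance = mean(series$backbone_on_distance[sel]))
    }))
  }
  structure(list(series = series, window_means = wm),
            class = "geometry_series")
}

#' @export
print.geometry_series <- function(x, ...) {
  cat("geometry series:", nrow(x$series), "frames; bend",
      sprintf("%.1f-%.1f deg", min(x$series$bend_angle),
              max(x$series$bend_angle)),
      "; contact", sprintf("%.1f-%.1f A", min(x$series$contact_distance),
                           max(x$series$contact_distance)), "\n")
  invisible(x)
}
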