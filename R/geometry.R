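# Shared distance/geometry helpers. All distances in Angstrom, angles in
# degrees. When a periodic box is present the minimum-image convention is
# applied (orthorhombic boxes only).

min_image <- function(d, box) {
  if (is.null(box)) return(d)
  d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
}

# displacement vectors xyz[j,] - xyz[i,] under minimum image
disp_vec <- function(xyz, i, j, box = NULL) {
  d <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  min_image(d, box)
}

pair_dist <- function(xyz, i, j, box = NULL) {
  sqrt(rowSums(disp_vec(xyz, i, j, box)^2))
}

# All unordered pairs among `idx` with distance <= cutoff.
# Brute force is the reference; the cell-list path is used for large periodic
# systems and must give identical results (tested).
neighbor_pairs <- function(xyz, idx, cutoff, box = NULL,
                           method = c("auto", "brute", "cells")) {
  method <- match.arg(method)
  n <- length(idx)
  empty <- data.frame(i = integer(0), j = integer(0), dist = numeric(0))
  if (n < 2) return(empty)
  if (method == "auto") {
    method <- if (!is.null(box) && n > 400) "cells" else "brute"
  }
  if (method == "brute") {
    sub <- xyz[idx, , drop = FALSE]
    if (is.null(box)) {
      dm <- as.matrix(stats::dist(sub))
      hit <- which(upper.tri(dm) & dm <= cutoff, arr.ind = TRUE)
      if (nrow(hit) == 0) return(empty)
      return(data.frame(i = idx[hit[, 1]], j = idx[hit[, 2]],
                        dist = dm[hit]))
    }
    ii <- rep(seq_len(n - 1), times = (n - 1):1)
    jj <- unlist(lapply(seq_len(n - 1), function(a) (a + 1):n))
    d <- sqrt(rowSums(min_image(sub[jj, , drop = FALSE] -
                                  sub[ii, , drop = FALSE], box)^2))
    keep <- d <= cutoff
    return(data.frame(i = idx[ii[keep]], j = idx[jj[keep]], dist = d[keep]))
  }
  # cell lists over a periodic orthorhombic box
  stopifnot(!is.null(box))
  sub <- xyz[idx, , drop = FALSE]
  wrapped <- sub - sweep(floor(sweep(sub, 2, box, "/")), 2, box, "*")
  ncell <- pmax(1L, floor(box / cutoff))
  cell_of <- function(p) {
    c3 <- pmin(floor(p / rep(box / ncell, each = nrow(p))),
               matrix(ncell - 1, nrow(p), 3, byrow = TRUE))
    c3[, 1] + ncell[1] * (c3[, 2] + ncell[2] * c3[, 3]) + 1
  }
  cid <- cell_of(wrapped)
  members <- split(seq_len(n), cid)
  key <- function(cx, cy, cz) {
    cx %% ncell[1] + ncell[1] * ((cy %% ncell[2]) + ncell[2] * (cz %% ncell[3])) + 1
  }
  res_i <- integer(0); res_j <- integer(0); res_d <- numeric(0)
  seen <- new.env(hash = TRUE)
  for (nm in names(members)) {
    c1 <- as.integer(nm) - 1L
    cz <- c1 %/% (ncell[1] * ncell[2])
    cy <- (c1 %% (ncell[1] * ncell[2])) %/% ncell[1]
    cx <- c1 %% ncell[1]
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      k2 <- key(cx + dx, cy + dy, cz + dz)
      other <- members[[as.character(k2)]]
      if (is.null(other)) next
      pk <- paste(min(as.integer(nm), k2), max(as.integer(nm), k2))
      if (!is.null(seen[[pk]])) next
      seen[[pk]] <- TRUE
      a <- members[[nm]]
      if (k2 == as.integer(nm)) {
        if (length(a) < 2) next
        cmb <- utils::combn(a, 2)
        ii <- cmb[1, ]; jj <- cmb[2, ]
      } else {
        ii <- rep(a, each = length(other)); jj <- rep(other, length(a))
      }
      d <- sqrt(rowSums(min_image(wrapped[jj, , drop = FALSE] -
                                    wrapped[ii, , drop = FALSE], box)^2))
      keep <- d <= cutoff
      res_i <- c(res_i, ii[keep]); res_j <- c(res_j, jj[keep])
      res_d <- c(res_d, d[keep])
    }
  }
  if (length(res_i) == 0) return(empty)
  a <- pmin(res_i, res_j); b <- pmax(res_i, res_j)
  o <- order(a, b)
  dup <- duplicated(paste(a[o], b[o]))
  data.frame(i = idx[a[o][!dup]], j = idx[b[o][!dup]], dist = res_d[o][!dup])
}

# angle at vertex `h` between directions h->a and h->b, degrees
vertex_angle <- function(xyz, a, h, b, box = NULL) {
  v1 <- min_image(xyz[a, , drop = FALSE] - xyz[h, , drop = FALSE], box)
  v2 <- min_image(xyz[b, , drop = FALSE] - xyz[h, , drop = FALSE], box)
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

unit <- function(v) v / sqrt(sum(v^2))

# rotation matrix about unit axis by angle (degrees), Rodrigues form
rotation_matrix <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

apply_rigid <- function(xyz, R, pivot = c(0, 0, 0), shift = c(0, 0, 0)) {
  sweep(sweep(xyz, 2, pivot) %*% t(R), 2, pivot + shift, "+")
}
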