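# Fixture builders and independent oracles shared across the test files.
# Oracles are deliberately written as naive scalar loops so they share no
# code path with the package implementation.

# ---- fixture builders -------------------------------------------------------

# water system: oxygens at o_pos (n x 3); with_h adds two hydrogens per
# water with orientations drawn from the current RNG stream
make_water_system <- function(o_pos, with_h = TRUE, box = NULL,
                              extra_atoms = NULL, extra_xyz = NULL) {
  o_pos <- matrix(o_pos, ncol = 3)
  n <- nrow(o_pos)
  rows <- list(); xyz <- list()
  for (i in seq_len(n)) {
    if (with_h) {
      d1 <- rnorm(3); d1 <- d1 / sqrt(sum(d1^2))
      p <- rnorm(3); p <- p - sum(p * d1) * d1; p <- p / sqrt(sum(p^2))
      d2 <- cos(104.5 * pi / 180) * d1 + sin(104.5 * pi / 180) * p
      rows[[i]] <- data.frame(
        atom_name = c("OH2", "H1", "H2"), residue_name = "TIP3",
        residue_id = 1000L + i, chain_id = "W", element = c("O", "H", "H"))
      xyz[[i]] <- rbind(o_pos[i, ], o_pos[i, ] + 0.957 * d1,
                        o_pos[i, ] + 0.957 * d2)
    } else {
      rows[[i]] <- data.frame(
        atom_name = "O", residue_name = "HOH", residue_id = 1000L + i,
        chain_id = "W", element = "O")
      xyz[[i]] <- o_pos[i, , drop = FALSE]
    }
  }
  atoms <- do.call(rbind, rows)
  coords <- do.call(rbind, xyz)
  if (!is.null(extra_atoms)) {
    atoms <- rbind(extra_atoms, atoms)
    coords <- rbind(extra_xyz, coords)
  }
  top <- topology(atoms, coords)
  list(topology = top, frame = frame(coords, box = box))
}

# two glutamate-like carboxylate endpoints for wire fixtures
carboxylate_endpoints <- function(src = c(0, 0, 0), snk = c(0, 0, 19.6)) {
  atoms <- data.frame(
    atom_name = c("CD", "OE1", "CD", "OE1"),
    residue_name = "GLU", residue_id = c(908L, 908L, 918L, 918L),
    chain_id = "A", element = c("C", "O", "C", "O"))
  xyz <- rbind(src + c(0, 0, -1.25), src, snk + c(0, 0, 1.25), snk)
  list(atoms = atoms, xyz = xyz)
}

# ideal helix C-alpha coordinates: radius 2.3 A, 100 deg/residue, 1.5 A rise
helix_points <- function(n, base = c(0, 0, 0), axis_z = TRUE) {
  k <- seq_len(n) - 1
  phi <- k * 100 * pi / 180
  cbind(base[1] + 2.3 * cos(phi), base[2] + 2.3 * sin(phi),
        base[3] + 1.5 * k)
}

rotation_matrix_test <- function(axis, angle_deg) {
  porewire:::rotation_matrix(axis, angle_deg)
}

random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

rigid_frame <- function(f, R = random_rotation(), shift = rnorm(3, sd = 5)) {
  frame(sweep(f$xyz %*% t(R), 2, shift, "+"), time = f$time)
}

# minimal CHARMM-flavoured DCD writer (test-only, to exercise the reader)
write_mini_dcd <- function(path, xyz_list) {
  con <- file(path, "wb")
  on.exit(close(con))
  natom <- nrow(xyz_list[[1]])
  nf <- length(xyz_list)
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L
  icntrl[4] <- nf; icntrl[20] <- 24L
  writeBin(84L, con, size = 4)
  writeChar("CORD", con, nchars = 4, eos = NULL)
  writeBin(as.integer(icntrl), con, size = 4)
  writeBin(84L, con, size = 4)
  writeBin(84L, con, size = 4); writeBin(1L, con, size = 4)
  writeChar(sprintf("%-80s", "porewire test fixture"), con, nchars = 80,
            eos = NULL)
  writeBin(84L, con, size = 4)
  writeBin(4L, con, size = 4)
  writeBin(as.integer(natom), con, size = 4)
  writeBin(4L, con, size = 4)
  for (xyz in xyz_list) {
    for (k in 1:3) {
      writeBin(as.integer(4 * natom), con, size = 4)
      writeBin(as.numeric(xyz[, k]), con, size = 4)
      writeBin(as.integer(4 * natom), con, size = 4)
    }
  }
  invisible(path)
}

# ---- independent oracles ----------------------------------------------------

# all-pairs scalar-loop hydrogen-bond oracle; returns sorted "i-j" pair keys
oracle_hbond_pairs <- function(frame, top, criteria, nodes) {
  xyz <- frame$xyz
  box <- frame$box
  mi <- function(v) {
    if (is.null(box)) v else v - box * round(v / box)
  }
  ang_at_h <- function(d, h, a) {
    v1 <- mi(xyz[d, ] - xyz[h, ]); v2 <- mi(xyz[a, ] - xyz[h, ])
    acos(max(-1, min(1, sum(v1 * v2) /
                       sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
  }
  keys <- character(0)
  nodes <- sort(nodes)
  for (x in seq_along(nodes)) {
    for (y in seq_len(x - 1)) {
      i <- nodes[y]; j <- nodes[x]
      d <- sqrt(sum(mi(xyz[j, ] - xyz[i, ])^2))
      if (d > criteria$max_heavy_distance) next
      ok <- FALSE
      if (criteria$heavy_only) {
        ok <- TRUE
      } else {
        hi <- bonded_hydrogens(top, i)
        hj <- bonded_hydrogens(top, j)
        for (h in hi) if (ang_at_h(i, h, j) >= criteria$min_dha_angle) ok <- TRUE
        for (h in hj) if (ang_at_h(j, h, i) >= criteria$min_dha_angle) ok <- TRUE
        if (length(hi) == 0 && length(hj) == 0) ok <- TRUE
      }
      if (ok) keys <- c(keys, paste(i, j, sep = "-"))
    }
  }
  sort(keys)
}

graph_edge_keys <- function(g) {
  if (igraph::ecount(g) == 0) return(character(0))
  el <- igraph::as_edgelist(g)
  el <- matrix(as.integer(el), ncol = 2)
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "-"))
}

# exhaustive path oracle through igraph::all_simple_paths
oracle_wire_sets <- function(g, endpoints) {
  ords <- igraph::V(g)$ordinal
  is_w <- igraph::V(g)$is_water
  src <- which(ords %in% endpoints$source)
  snk <- which(ords %in% endpoints$sink)
  sets <- character(0)
  for (s in src) {
    paths <- igraph::all_simple_paths(g, from = s, to = snk,
                                      cutoff = endpoints$max_waters + 1)
    for (p in paths) {
      v <- as.integer(p)
      if (length(v) < 3) next
      internal <- v[-c(1, length(v))]
      if (any(ords[internal] %in% c(endpoints$source, endpoints$sink))) next
      if (!all(is_w[internal])) next
      sets <- c(sets, paste(sort(ords[internal]), collapse = ","))
    }
  }
  sort(unique(sets))
}

# exact maximum-cardinality (then minimum total displacement) matching
oracle_assignment <- function(D, cutoff) {
  nS <- nrow(D); nC <- ncol(D)
  best <- list(n = -1L, total = Inf)
  rec <- function(si, used_c, n, total) {
    if (n + (nS - si + 1) < best$n) return()
    if (si > nS) {
      if (n > best$n || (n == best$n && total < best$total)) {
        best <<- list(n = n, total = total)
      }
      return()
    }
    for (cc in seq_len(nC)) {
      if (!used_c[cc] && D[si, cc] < cutoff) {
        used_c[cc] <- TRUE
        rec(si + 1L, used_c, n + 1L, total + D[si, cc])
        used_c[cc] <- FALSE
      }
    }
    rec(si + 1L, used_c, n, total)
  }
  rec(1L, rep(FALSE, nC), 0L, 0)
  best
}

# mean/sd of the RMSD of m atoms jittered iid N(0, sigma^2) per coordinate:
# RMSD = sigma/sqrt(m) * chi_{3m}
rmsd_chi_moments <- function(sigma, m) {
  k <- 3 * m
  mean_chi <- sqrt(2) * exp(lgamma((k + 1) / 2) - lgamma(k / 2))
  mu <- sigma / sqrt(m) * mean_chi
  v <- sigma^2 / m * (k - mean_chi^2)
  list(mean = mu, sd = sqrt(v))
}
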