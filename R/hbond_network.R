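# Geometric hydrogen-bond detection and per-frame hydrogen-bond graphs.
#
# The detection criterion is purely geometric: donor-acceptor heavy-atom
# distance plus the D-H...A angle at the hydrogen. Crystallographic waters
# that carry no hydrogens are accepted on the distance criterion alone, so
# hydrogen-free structures remain analysable.

#' Hydrogen-bond acceptance criteria
#'
#' Default geometric criterion: donor-acceptor heavy-atom distance <= 3.5 A
#' and D-H...A angle >= 150 degrees, the standard definition used in
#' trajectory analysis. `heavy_only = TRUE` drops the angle test entirely
#' (used for structures without hydrogens, e.g. crystal waters).
#'
#' @param max_heavy_distance donor-acceptor heavy-atom cutoff (Angstrom, > 0).
#' @param min_dha_angle minimum donor-hydrogen-acceptor angle (degrees,
#'   0..180).
#' @param heavy_only accept on heavy-atom distance alone.
#' @return Object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(max_heavy_distance = 3.5, min_dha_angle = 150,
                           heavy_only = FALSE) {
  stopifnot(max_heavy_distance > 0,
            min_dha_angle >= 0, min_dha_angle <= 180,
            is.logical(heavy_only))
  structure(list(max_heavy_distance = max_heavy_distance,
                 min_dha_angle = min_dha_angle,
                 heavy_only = heavy_only),
            class = "hbond_criteria")
}

#' Default polar side-chain node atoms of the proton-release pathway
#'
#' Resolves the polar side-chain atoms of the pathway residues to ordinals:
#' Glu908/Glu918 carboxylate oxygens, Ser767 hydroxyl oxygen, Asn911
#' carboxamide O/N, Arg836 guanidine nitrogens and Tyr837 hydroxyl oxygen.
#' (One passage of the source literature credits a "Tyr377"; that residue
#' appears nowhere else while Tyr837 recurs throughout, so it is read as
#' Tyr837 here.)
#'
#' @param topology a [topology()].
#' @param chain_id chain to search.
#' @return Integer vector of ordinals (only those that resolve).
#' @export
pathway_node_atoms <- function(topology, chain_id = NULL) {
  sel <- list(
    list(residue_id = 908, atom_name = c("OE1", "OE2")),
    list(residue_id = 918, atom_name = c("OE1", "OE2")),
    list(residue_id = 767, atom_name = "OG"),
    list(residue_id = 911, atom_name = c("OD1", "ND2")),
    list(residue_id = 836, atom_name = c("NE", "NH1", "NH2")),
    list(residue_id = 837, atom_name = "OH")
  )
  sort(unique(unlist(lapply(sel, function(s) {
    atom_select(topology, residue_id = s$residue_id,
                atom_name = s$atom_name, chain_id = chain_id)
  }))))
}

#' Detect hydrogen bonds in one frame
#'
#' Evaluates every pair of `node_atoms` within the heavy-atom cutoff. A pair
#' is accepted as a hydrogen bond when some hydrogen covalently bonded to one
#' of the two heavy atoms makes a D-H...A angle of at least
#' `criteria$min_dha_angle`, or — for hydrogen-less heavy atoms such as
#' crystallographic water oxygens, or under `heavy_only` mode — on distance
#' alone. The unordered heavy-pair set is independent of atom enumeration
#' order.
#'
#' @param frame a [frame()].
#' @param topology the matching [topology()].
#' @param criteria an [hbond_criteria()].
#' @param node_atoms ordinals of the heavy atoms forming the graph nodes
#'   (water oxygens plus polar side-chain atoms).
#' @return data.frame with columns `donor`, `hydrogen` (`NA` for
#'   distance-only acceptances), `acceptor`, `heavy_distance`, `dha_angle`.
#' @export
detect_hbonds <- function(frame, topology, criteria = hbond_criteria(),
                          node_atoms) {
  stopifnot(inherits(frame, "frame"), inherits(topology, "topology"),
            inherits(criteria, "hbond_criteria"))
  if (length(node_atoms) == 0) stop("empty selection: no node atoms")
  xyz <- frame$xyz
  box <- frame$box
  pairs <- neighbor_pairs(xyz, sort(unique(as.integer(node_atoms))),
                          criteria$max_heavy_distance, box)
  np <- nrow(pairs)
  h_ids <- which(!is.na(topology$h_parent))
  h_map <- split(h_ids, topology$h_parent[h_ids])
  hydrogens_of <- function(i) {
    h <- h_map[[as.character(i)]]
    if (is.null(h)) integer(0) else h
  }
  cap <- 2L * np + 1L
  v_don <- integer(cap); v_hyd <- integer(cap); v_acc <- integer(cap)
  v_d <- numeric(cap); v_a <- numeric(cap)
  n_out <- 0L
  emit <- function(donor, hydrogen, acceptor, d, ang) {
    n_out <<- n_out + 1L
    v_don[n_out] <<- donor; v_hyd[n_out] <<- hydrogen
    v_acc[n_out] <<- acceptor; v_d[n_out] <<- d; v_a[n_out] <<- ang
  }
  for (r in seq_len(np)) {
    i <- pairs$i[r]; j <- pairs$j[r]; d <- pairs$dist[r]
    if (criteria$heavy_only) {
      emit(i, NA_integer_, j, d, NA_real_)
      next
    }
    hi <- hydrogens_of(i)
    hj <- hydrogens_of(j)
    found <- FALSE
    if (length(hi) > 0) {
      ang <- vertex_angle(xyz, rep(i, length(hi)), hi, rep(j, length(hi)), box)
      k <- which(ang >= criteria$min_dha_angle)
      if (length(k) > 0) {
        b <- k[which.max(ang[k])]
        emit(i, hi[b], j, d, ang[b]); found <- TRUE
      }
    }
    if (length(hj) > 0) {
      ang <- vertex_angle(xyz, rep(j, length(hj)), hj, rep(i, length(hj)), box)
      k <- which(ang >= criteria$min_dha_angle)
      if (length(k) > 0) {
        b <- k[which.max(ang[k])]
        emit(j, hj[b], i, d, ang[b]); found <- TRUE
      }
    }
    if (!found && length(hi) == 0 && length(hj) == 0) {
      # neither partner carries hydrogens (e.g. crystal waters, protein
      # carbonyls in an H-free structure): accept on distance alone
      emit(i, NA_integer_, j, d, NA_real_)
    }
  }
  keep <- seq_len(n_out)
  data.frame(donor = v_don[keep], hydrogen = v_hyd[keep],
             acceptor = v_acc[keep], heavy_distance = v_d[keep],
             dha_angle = v_a[keep])
}

#' Assemble the hydrogen-bond graph
#'
#' Reduces a hydrogen-bond list to a simple undirected graph over the node
#' atoms: both donation directions of the same heavy pair collapse to one
#' edge; no self loops.
#'
#' @param hbonds data.frame as returned by [detect_hbonds()].
#' @param node_atoms ordinals of all graph nodes (isolated nodes are kept).
#' @param topology the matching [topology()]; used to tag water nodes.
#' @return An `igraph` undirected graph; vertex attributes `ordinal` and
#'   `is_water`, edge attribute `heavy_distance`.
#' @export
build_hbond_graph <- function(hbonds, node_atoms, topology) {
  node_atoms <- sort(unique(as.integer(node_atoms)))
  if (nrow(hbonds) > 0) {
    bad <- setdiff(unique(c(hbonds$donor, hbonds$acceptor)), node_atoms)
    if (length(bad) > 0) {
      stop("hydrogen-bond endpoint(s) not in node set: ",
           paste(head(bad), collapse = ", "))
    }
  }
  g <- igraph::make_empty_graph(n = length(node_atoms), directed = FALSE)
  igraph::V(g)$name <- as.character(node_atoms)
  igraph::V(g)$ordinal <- node_atoms
  igraph::V(g)$is_water <- topology$atoms$is_water[node_atoms]
  if (nrow(hbonds) > 0) {
    a <- pmin(hbonds$donor, hbonds$acceptor)
    b <- pmax(hbonds$donor, hbonds$acceptor)
    keep <- !duplicated(paste(a, b)) & a != b
    g <- igraph::add_edges(
      g, rbind(as.character(a[keep]), as.character(b[keep])),
      heavy_distance = hbonds$heavy_distance[keep])
  }
  g
}

#' Hydrogen-bond graph for one frame (convenience wrapper)
#'
#' @inheritParams detect_hbonds
#' @return igraph graph, as [build_hbond_graph()].
#' @export
hbond_graph <- function(frame, topology, criteria = hbond_criteria(),
                        node_atoms) {
  build_hbond_graph(detect_hbonds(frame, topology, criteria, node_atoms),
                    node_atoms, topology)
}

#' Export a hydrogen-bond list with atom annotations as TSV
#'
#' @param hbonds data.frame from [detect_hbonds()].
#' @param topology the matching [topology()].
#' @param time frame time (ps) stamped on every row.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_hbonds <- function(hbonds, topology, time, path) {
  at <- topology$atoms
  lab <- function(i) ifelse(is.na(i), NA_character_,
                            paste0(at$residue_name[i], at$residue_id[i], ":",
                                   at$atom_name[i]))
  write_table(data.frame(
    time_ps = time,
    donor = lab(hbonds$donor), acceptor = lab(hbonds$acceptor),
    heavy_distance_A = round(hbonds$heavy_distance, 3),
    dha_angle_deg = round(hbonds$dha_angle, 2)), path)
}
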