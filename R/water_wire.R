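# Water-wire enumeration, temporal tracking and lifetime statistics.
#
# A water wire is a simple path in the per-frame hydrogen-bond graph from a
# source endpoint atom to a sink endpoint atom whose internal nodes are
# exclusively water oxygens. Wires are tracked through time into events; an
# event's lifetime is (number of contiguous frames) x frame spacing, so a
# single-frame observation has a lifetime of one sampling interval.

#' Wire endpoint definition
#'
#' Defaults are the carboxylate oxygens of Glu908 (source, transport-site
#' side) and Glu918 (sink, cytosolic side).
#'
#' @param topology a [topology()].
#' @param source_residue,source_atoms residue id and atom names of the source
#'   group.
#' @param sink_residue,sink_atoms residue id and atom names of the sink group.
#' @param chain_id optional chain restriction.
#' @param max_waters maximum number of internal waters per wire (>= 1).
#' @return Object of class `wire_endpoints` with resolved ordinals.
#' @export
wire_endpoints <- function(topology, source_residue = 908,
                           source_atoms = c("OE1", "OE2"),
                           sink_residue = 918,
                           sink_atoms = c("OE1", "OE2"),
                           chain_id = NULL, max_waters = 8) {
  stopifnot(inherits(topology, "topology"), max_waters >= 1)
  src <- atom_select(topology, residue_id = source_residue,
                     atom_name = source_atoms, chain_id = chain_id)
  snk <- atom_select(topology, residue_id = sink_residue,
                     atom_name = sink_atoms, chain_id = chain_id)
  if (length(src) == 0) stop("source endpoint selection resolves to zero atoms")
  if (length(snk) == 0) stop("sink endpoint selection resolves to zero atoms")
  if (length(intersect(src, snk)) > 0) {
    stop("source and sink endpoint atoms must be disjoint")
  }
  structure(list(source = sort(src), sink = sort(snk),
                 max_waters = as.integer(max_waters)),
            class = "wire_endpoints")
}

#' Enumerate water wires in a hydrogen-bond graph
#'
#' Depth-first enumeration of all simple source-to-sink paths whose internal
#' nodes are water oxygens, with at most `endpoints$max_waters` waters.
#' Wires are deduplicated by their internal water set (two paths over the
#' same waters count once) and ordered deterministically by water count and
#' then lexicographically by internal ordinals. A direct source-sink contact
#' with no intervening water is not a wire.
#'
#' @param graph igraph graph from [build_hbond_graph()].
#' @param topology the matching [topology()].
#' @param endpoints a [wire_endpoints()].
#' @param frame_time time stamp (ps) attached to the returned wires.
#' @return list of wires; each is a list with `path` (atom ordinals,
#'   source to sink), `waters` (internal ordinals in path order),
#'   `water_count` and `frame_time`.
#' @export
find_wires <- function(graph, topology, endpoints, frame_time = NA_real_) {
  stopifnot(inherits(endpoints, "wire_endpoints"))
  ords <- igraph::V(graph)$ordinal
  present <- function(x) x[x %in% ords]
  src <- present(endpoints$source)
  snk <- present(endpoints$sink)
  if (length(src) == 0 || length(snk) == 0) return(list())

  idx_of <- setNames(seq_along(ords), as.character(ords))
  adj <- igraph::as_adj_list(graph)
  # neighbor ordinals, sorted for deterministic traversal
  nbr <- lapply(adj, function(v) sort(ords[as.integer(v)]))
  is_water_node <- setNames(igraph::V(graph)$is_water, as.character(ords))
  sink_set <- snk

  paths <- list()
  dfs <- function(u, path, visited) {
    for (v in nbr[[idx_of[[as.character(u)]]]]) {
      if (v %in% sink_set) {
        if (length(path) >= 2) {        # at least one internal water
          paths[[length(paths) + 1]] <<- c(path, v)
        }
        next
      }
      if (!isTRUE(is_water_node[[as.character(v)]])) next
      if (v %in% visited) next
      if (length(path) - 1 >= endpoints$max_waters) next
      dfs(v, c(path, v), c(visited, v))
    }
  }
  for (s in sort(src)) dfs(s, s, s)
  if (length(paths) == 0) return(list())

  wires <- lapply(paths, function(p) {
    internal <- p[-c(1, length(p))]
    list(path = p, waters = internal, water_count = length(internal),
         frame_time = frame_time)
  })
  # deterministic order: water_count, then lexicographic internal ordinals
  keyord <- order(
    vapply(wires, `[[`, integer(1), "water_count"),
    vapply(wires, function(w) paste(sprintf("%08d", sort(w$waters)),
                                    collapse = ","), character(1))
  )
  wires <- wires[keyord]
  setkey <- vapply(wires, function(w) paste(sort(w$waters), collapse = ","),
                   character(1))
  wires[!duplicated(setkey)]
}

#' Enumerate wires for every frame of a trajectory
#'
#' @param frames list of [frame()] objects.
#' @param topology the matching [topology()].
#' @param criteria an [hbond_criteria()].
#' @param endpoints a [wire_endpoints()].
#' @param node_atoms graph nodes; default water oxygens plus the endpoint
#'   atoms plus [pathway_node_atoms()].
#' @return list (one element per frame) of wire lists, as [find_wires()].
#' @export
wires_per_frame <- function(frames, topology, criteria = hbond_criteria(),
                            endpoints, node_atoms = NULL) {
  if (is.null(node_atoms)) {
    node_atoms <- sort(unique(c(water_oxygens(topology),
                                endpoints$source, endpoints$sink,
                                pathway_node_atoms(topology))))
  }
  lapply(frames, function(f) {
    g <- hbond_graph(f, topology, criteria, node_atoms)
    find_wires(g, topology, endpoints, frame_time = f$time)
  })
}

wire_identity_key <- function(wire, identity_mode) {
  if (identity_mode == "path") {
    paste(wire$path, collapse = ",")
  } else {
    paste(sort(wire$waters), collapse = ",")
  }
}

#' Track per-frame wires into temporal events
#'
#' Wires observed in consecutive frames are merged into one event when their
#' identity matches. The default identity is the exact unordered internal
#' water set; `"path"` additionally requires the same node order, and
#' `"jaccard"` accepts a Jaccard similarity of the water sets of at least
#' `jaccard_threshold`. There is no gap tolerance: a wire absent for one
#' sampled frame ends its event. Lifetime is
#' `n_contiguous_frames * frame_spacing`, so a single-frame observation has
#' lifetime equal to the sampling resolution.
#'
#' @param per_frame_wires list of per-frame wire lists
#'   (see [wires_per_frame()]).
#' @param times frame times (ps), uniformly spaced; alternatively give
#'   `frame_spacing` and times are inferred as `0, h, 2h, ...`.
#' @param frame_spacing spacing in ps (required if `times` is `NULL`).
#' @param identity_mode `"set"` (default), `"path"` or `"jaccard"`.
#' @param jaccard_threshold similarity threshold for `"jaccard"` mode.
#' @return data.frame of events: `start_time`, `end_time`, `lifetime`
#'   (all ps), `n_frames`, `water_count`, plus list-columns `water_set`
#'   (unordered internal ordinals) and `representative_path` (node path at
#'   first observation).
#' @export
track_wires <- function(per_frame_wires, times = NULL, frame_spacing = NULL,
                        identity_mode = c("set", "path", "jaccard"),
                        jaccard_threshold = 0.8) {
  identity_mode <- match.arg(identity_mode)
  n <- length(per_frame_wires)
  if (is.null(times)) {
    if (is.null(frame_spacing)) stop("give either times or frame_spacing")
    times <- (seq_len(n) - 1) * frame_spacing
  }
  stopifnot(length(times) == n)
  if (n > 1) {
    dt <- diff(times)
    if (any(abs(dt - dt[1]) > 1e-6 * max(dt[1], 1))) {
      stop("frames are not uniformly spaced; wire tracking requires a ",
           "constant sampling interval")
    }
    frame_spacing <- dt[1]
  } else if (is.null(frame_spacing)) {
    frame_spacing <- NA_real_
  }

  events <- list()
  close_event <- function(ev) events[[length(events) + 1]] <<- ev
  active <- list()   # key -> list(start_idx, last_idx, wire)

  for (f in seq_len(n)) {
    wires <- per_frame_wires[[f]]
    if (identity_mode %in% c("set", "path")) {
      keys <- vapply(wires, wire_identity_key, character(1),
                     identity_mode = identity_mode)
      new_active <- list()
      for (w in seq_along(wires)) {
        k <- keys[w]
        if (!is.null(active[[k]]) && active[[k]]$last_idx == f - 1) {
          ev <- active[[k]]
          ev$last_idx <- f
          new_active[[k]] <- ev
        } else {
          new_active[[k]] <- list(start_idx = f, last_idx = f,
                                  wire = wires[[w]])
        }
      }
      for (k in names(active)) {
        if (is.null(new_active[[k]])) close_event(active[[k]])
      }
      active <- new_active
    } else {
      # jaccard: greedily match this frame's wires to active events
      new_active <- list()
      used <- rep(FALSE, length(active))
      akeys <- names(active)
      for (w in seq_along(wires)) {
        ws <- sort(wires[[w]]$waters)
        best <- 0; best_k <- NA
        for (ai in seq_along(akeys)) {
          if (used[ai]) next
          aset <- sort(active[[akeys[ai]]]$wire$waters)
          jac <- length(intersect(ws, aset)) / length(union(ws, aset))
          if (jac > best) { best <- jac; best_k <- ai }
        }
        if (!is.na(best_k) && best >= jaccard_threshold &&
            active[[akeys[best_k]]]$last_idx == f - 1) {
          ev <- active[[akeys[best_k]]]
          ev$last_idx <- f
          ev$wire <- wires[[w]]
          used[best_k] <- TRUE
          new_active[[paste0("e", length(new_active) + 1)]] <- ev
        } else {
          new_active[[paste0("e", length(new_active) + 1)]] <-
            list(start_idx = f, last_idx = f, wire = wires[[w]])
        }
      }
      for (ai in seq_along(akeys)) {
        if (!used[ai]) close_event(active[[akeys[ai]]])
      }
      active <- new_active
    }
  }
  for (k in names(active)) close_event(active[[k]])

  if (length(events) == 0) {
    return(data.frame(start_time = numeric(0), end_time = numeric(0),
                      lifetime = numeric(0), n_frames = integer(0),
                      water_count = integer(0),
                      water_set = I(list()), representative_path = I(list())))
  }
  out <- data.frame(
    start_time = vapply(events, function(e) times[e$start_idx], numeric(1)),
    end_time = vapply(events, function(e) times[e$last_idx], numeric(1)),
    n_frames = vapply(events, function(e) e$last_idx - e$start_idx + 1L,
                      integer(1)),
    water_count = vapply(events, function(e) e$wire$water_count, integer(1))
  )
  out$lifetime <- out$n_frames * frame_spacing
  out$water_set <- I(lapply(events, function(e) sort(e$wire$waters)))
  out$representative_path <- I(lapply(events, function(e) e$wire$path))
  out <- out[order(out$start_time, out$water_count), ]
  rownames(out) <- NULL
  out[, c("start_time", "end_time", "lifetime", "n_frames", "water_count",
          "water_set", "representative_path")]
}

#' Summary statistics over wire events
#'
#' @param events data.frame from [track_wires()].
#' @param lifetime_threshold events with lifetime >= this value (ps) are
#'   counted as "stable".
#' @return list: `n_events`, `length_histogram` (named integer vector over
#'   water counts), `dominant_length` (most frequent water count; smaller one
#'   on ties; `NA` when empty), `lifetime_quantiles` (0/25/50/75/100%),
#'   `lifetime_mean`, `n_stable`.
#' @export
wire_statistics <- function(events, lifetime_threshold = 0) {
  if (nrow(events) == 0) {
    return(list(n_events = 0L, length_histogram = integer(0),
                dominant_length = NA_integer_,
                lifetime_quantiles = setNames(rep(NA_real_, 5),
                                              c("0%", "25%", "50%", "75%", "100%")),
                lifetime_mean = NA_real_, n_stable = 0L))
  }
  hist <- table(events$water_count)
  hist_v <- as.integer(hist)
  names(hist_v) <- names(hist)
  dom <- as.integer(names(hist)[which.max(hist_v)])  # ties: first = smallest
  list(
    n_events = nrow(events),
    length_histogram = hist_v,
    dominant_length = dom,
    lifetime_quantiles = quantile(events$lifetime,
                                  c(0, 0.25, 0.5, 0.75, 1), names = TRUE),
    lifetime_mean = mean(events$lifetime),
    n_stable = sum(events$lifetime >= lifetime_threshold)
  )
}

#' Binary wire-presence time series
#'
#' @param per_frame_wires list of per-frame wire lists.
#' @param times frame times (ps).
#' @return list: `series` (data.frame `time`, `n_wires`, `present`) and
#'   `first_passage_time` (time of the first frame with a wire; `NA` when no
#'   wire ever forms).
#' @export
wire_presence_series <- function(per_frame_wires, times) {
  stopifnot(length(per_frame_wires) == length(times))
  n_wires <- vapply(per_frame_wires, length, integer(1))
  series <- data.frame(time = times, n_wires = n_wires,
                       present = as.integer(n_wires > 0))
  fp <- if (any(n_wires > 0)) times[which(n_wires > 0)[1]] else NA_real_
  list(series = series, first_passage_time = fp)
}

#' Export wire events as TSV
#'
#' @param events data.frame from [track_wires()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_wire_events <- function(events, path) {
  flat <- events
  flat$water_set <- vapply(events$water_set, paste, character(1),
                           collapse = ",")
  flat$representative_path <- vapply(events$representative_path, paste,
                                     character(1), collapse = ",")
  write_table(flat, path)
}
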