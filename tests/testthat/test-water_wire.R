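# Wire enumeration, temporal tracking, and statistics.

# small helper: graph + endpoints from an explicit water chain between the
# two carboxylates, with optional extra waters
chain_system <- function(chain_z, extra_o = NULL, o_pos = NULL) {
  ep <- carboxylate_endpoints()
  o <- if (!is.null(o_pos)) o_pos else cbind(0, 0, chain_z)
  if (!is.null(extra_o)) o <- rbind(o, extra_o)
  sys <- make_water_system(o, with_h = FALSE, extra_atoms = ep$atoms,
                           extra_xyz = ep$xyz)
  ends <- wire_endpoints(sys$topology, source_atoms = "OE1",
                         sink_atoms = "OE1")
  nodes <- sort(c(water_oxygens(sys$topology), ends$source, ends$sink))
  g <- hbond_graph(sys$frame, sys$topology, hbond_criteria(), nodes)
  list(sys = sys, ends = ends, graph = g)
}

test_that("wire enumeration honours the water-only path definition", {
  # no source-sink connectivity: empty result
  cs <- chain_system(c(5, 12))
  expect_length(find_wires(cs$graph, cs$sys$topology, cs$ends), 0)

  # planted 6-water chain: exactly one wire of six waters
  cs <- chain_system(2.8 * (1:6))
  wires <- find_wires(cs$graph, cs$sys$topology, cs$ends, frame_time = 3)
  expect_length(wires, 1)
  expect_equal(wires[[1]]$water_count, 6)
  expect_equal(wires[[1]]$frame_time, 3)
  # path runs source -> waters -> sink and revalidates edge by edge
  p <- wires[[1]]$path
  expect_true(p[1] %in% cs$ends$source)
  expect_true(p[length(p)] %in% cs$ends$sink)
  for (k in seq_len(length(p) - 1)) {
    expect_true(igraph::are_adjacent(cs$graph, as.character(p[k]),
                                     as.character(p[k + 1])))
  }

  # a chain routed through a protein heteroatom mid-path is not a wire:
  # replace the middle water by a side-chain-like oxygen node
  ep <- carboxylate_endpoints()
  mid <- data.frame(atom_name = "OG", residue_name = "SER",
                    residue_id = 767L, chain_id = "A", element = "O")
  o <- cbind(0, 0, 2.8 * c(1, 2, 4, 5, 6))
  sys <- make_water_system(o, with_h = FALSE,
                           extra_atoms = rbind(ep$atoms, mid),
                           extra_xyz = rbind(ep$xyz, c(0, 0, 2.8 * 3)))
  ends <- wire_endpoints(sys$topology, source_atoms = "OE1",
                         sink_atoms = "OE1")
  nodes <- sort(c(water_oxygens(sys$topology), ends$source, ends$sink,
                  atom_select(sys$topology, atom_name = "OG")))
  g <- hbond_graph(sys$frame, sys$topology, hbond_criteria(), nodes)
  expect_gt(igraph::ecount(g), 5)   # the bridged chain is connected
  expect_length(find_wires(g, sys$topology, ends), 0)
})

test_that("enumeration matches the exhaustive path oracle on random graphs", {
  # a spanning chain plus random branch waters gives connected, branched
  # graphs without a combinatorial path explosion
  set.seed(17)
  for (rep in 1:100) {
    chain <- cbind(runif(7, -0.5, 0.5), runif(7, -0.5, 0.5),
                   2.45 * (1:7) + runif(7, -0.3, 0.3))
    n_x <- sample(2:10, 1)
    extras <- cbind(runif(n_x, -3.5, 3.5), runif(n_x, -3.5, 3.5),
                    runif(n_x, 0.5, 19))
    cs <- chain_system(NULL, o_pos = rbind(chain, extras))
    ends <- cs$ends
    ends$max_waters <- sample(4:8, 1)
    wires <- find_wires(cs$graph, cs$sys$topology, ends)
    got <- sort(vapply(wires, function(w) paste(sort(w$waters), collapse = ","),
                       character(1)))
    expect_identical(got, oracle_wire_sets(cs$graph, ends))
  }
})

test_that("raising max_waters never reduces the number of wires", {
  set.seed(23)
  for (rep in 1:10) {
    chain <- cbind(0, 0, 2.45 * (1:7) + runif(7, -0.3, 0.3))
    extras <- cbind(runif(4, -3.5, 3.5), runif(4, -3.5, 3.5),
                    runif(4, 0.5, 19))
    cs <- chain_system(NULL, o_pos = rbind(chain, extras))
    prev <- -1
    for (mw in c(3, 5, 8)) {
      ends <- cs$ends
      ends$max_waters <- mw
      n <- length(find_wires(cs$graph, cs$sys$topology, ends))
      expect_gte(n, prev)
      prev <- n
    }
  }
})

test_that("tracking applies the lifetime and no-gap conventions", {
  # fw(waters): a frame observing one wire; none: a wire-free frame
  fw <- function(waters) list(list(path = c(100L, waters, 200L),
                                   waters = as.integer(waters),
                                   water_count = length(waters),
                                   frame_time = NA_real_))
  none <- list()

  # single-frame wire at 10 ps spacing: lifetime 10 ps
  ev <- track_wires(list(none, fw(1:6), none), frame_spacing = 10)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$lifetime, 10)

  # persistence over frames 5..24 inclusive at 10 ps: lifetime 200 ps
  pf <- c(rep(list(none), 4), rep(list(fw(1:6)), 20), rep(list(none), 3))
  ev <- track_wires(pf, frame_spacing = 10)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$lifetime, 200)
  expect_equal(ev$start_time, 40)
  expect_equal(ev$end_time, 230)

  # same water set at frames 3 and 5 but absent at 4: two events
  ev <- track_wires(list(none, none, fw(1:6), none, fw(1:6)),
                    frame_spacing = 10)
  expect_equal(nrow(ev), 2)
  expect_equal(ev$lifetime, c(10, 10))

  # a changed water set ends the event under the default identity
  pf <- list(fw(1:6), fw(2:7))
  ev <- track_wires(pf, frame_spacing = 10)
  expect_equal(nrow(ev), 2)
  # ... but is bridged under jaccard identity below 5/7 similarity
  ev <- track_wires(pf, frame_spacing = 10, identity_mode = "jaccard",
                    jaccard_threshold = 0.6)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$lifetime, 20)

  expect_error(track_wires(list(fw(1:6), fw(2:7), fw(1:6)),
                           times = c(0, 10, 25)), "uniformly spaced")
})

test_that("statistics summarise events and handle the empty case", {
  empty <- track_wires(list(list(), list()), frame_spacing = 10)
  st <- wire_statistics(empty)
  expect_equal(st$n_events, 0)
  expect_true(is.na(st$dominant_length))
  expect_equal(st$n_stable, 0)

  one <- data.frame(start_time = 0, end_time = 90, lifetime = 100,
                    n_frames = 10L, water_count = 6L)
  st <- wire_statistics(one, lifetime_threshold = 100)
  expect_true(all(st$lifetime_quantiles == 100))
  expect_equal(st$n_stable, 1)
  expect_equal(st$dominant_length, 6)
})

test_that("presence series reports first passage and planted absence", {
  w6 <- list(list(path = c(100L, 1:6, 200L), waters = 1:6,
                  water_count = 6L, frame_time = NA_real_))
  pf <- c(rep(list(list()), 3), list(w6), list(w6))
  ps <- wire_presence_series(pf, times = seq(0, 40, by = 10))
  expect_equal(ps$series$present, c(0, 0, 0, 1, 1))
  expect_equal(ps$first_passage_time, 30)

  ps0 <- wire_presence_series(rep(list(list()), 4), times = seq(0, 30, 10))
  expect_true(all(ps0$series$present == 0))
  expect_true(is.na(ps0$first_passage_time))
})

test_that("event frame counts conserve per-frame wire counts", {
  ws <- data.frame(start_frame = c(3, 9, 15), duration = c(4, 4, 3),
                   length = c(6, 7, 6))
  tr <- generate_trajectory(scenario_spec("wire_formation", wire_script = ws,
                                          n_frames = 20, seed = 9))
  pfw <- wires_per_frame(tr$frames, tr$topology, hbond_criteria(),
                         wire_endpoints(tr$topology))
  ev <- track_wires(pfw, times = tr$ground_truth$times)
  expect_equal(sum(ev$n_frames), sum(lengths(pfw)))
  expect_equal(nrow(ev), 3)
  expect_equal(sort(ev$water_count), c(6, 6, 7))
})
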