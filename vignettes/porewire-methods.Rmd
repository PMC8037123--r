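---
title: "Detecting water wires, pore hydration and helix gating with porewire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting water wires, pore hydration and helix gating with porewire}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

P-type ATPases such as the sarco/endoplasmic-reticulum Ca²⁺ pump (SERCA)
countertransport protons while they move metal ions. In the protonated E2
state, a residue-lined pore at the C-terminal transmembrane region — running
from transport-site residue Glu908 to Glu918 near the cytosol, past Ser767,
Arg836, Tyr837, Asn911 and Asn914 — is believed to conduct those protons.
Protons travel along *water wires*: chains of hydrogen-bonded water
molecules bridging a donor and an acceptor group. Whether such wires form,
how many waters they contain, how long they live, and whether deprotonation
of Glu908 closes the pore (via bending of transmembrane helix M5 at the
Ile761–Ile765 hinge and formation of an Arg762–Ser915 contact) are the
questions this package turns into reproducible trajectory analyses.

`porewire` implements the full chain of those analyses for structures and
trajectories in standard formats (PDB, DCD), and ships a synthetic-data
generator that plants each phenotype with known ground truth so that every
stage is testable end to end without multi-microsecond simulation data.

## The hydrogen-bond graph

Each frame is reduced to an undirected graph whose nodes are water oxygens
plus configured polar side-chain atoms (by default the carboxylate oxygens
of Glu908/Glu918, Ser767 OG, Asn911 OD1/ND2, Arg836 NE/NH1/NH2 and Tyr837
OH), and whose edges are geometrically detected hydrogen bonds.

The detection criterion is the standard geometric one: donor–acceptor
heavy-atom distance ≤ 3.5 Å **and** D–H···A angle ≥ 150°. The study this
package operationalises never states its hydrogen-bond definition, so both
thresholds are explicit configuration (`hbond_criteria()`), with the common
3.5 Å / 150° convention as default. Two special cases:

* **Hydrogen-free atoms** (crystallographic waters, protein heteroatoms in
  structures without hydrogens) are accepted on the distance criterion
  alone, so hydration analyses of crystal structures remain possible.
* **Periodic boxes**: when a frame carries orthorhombic box lengths, all
  distances use the minimum-image convention; fixture data without a box
  use plain Euclidean distances.

Neighbour search is brute force for the small node sets typical here, with
a periodic cell-list path for large systems; the two are tested to give
identical pair sets. Both donation directions of one heavy-atom pair
collapse to a single undirected edge.

One residue-naming note: one passage of the source literature attributes
wire stabilisation to "Tyr377", a residue that appears nowhere else, while
Tyr837 recurs throughout. The package treats this as a typographical slip
and uses Tyr837, flagged here rather than silently.

## Water wires and their lifetimes

A *wire* is a simple path in the hydrogen-bond graph from any source
endpoint atom (default: Glu908 carboxylate oxygens) to any sink endpoint
atom (Glu918 carboxylate oxygens) whose internal nodes are exclusively
water oxygens — a chain routed through a protein heteroatom is not a wire,
and a direct carboxylate–carboxylate contact (zero waters) is not either.
Enumeration is a depth-first search bounded by `max_waters` (default 8:
the observed wires carry 6–7 waters, plus one of headroom); results are
deduplicated by their internal water set and ordered deterministically.
The enumeration is cross-checked in the test suite against exhaustive
simple-path search (`igraph::all_simple_paths`) on hundreds of random
graphs. The same passage of the source text once names the endpoints
"Glu309 and Glu318" where every other mention and all figure captions say
Glu908/Glu918; endpoints are configuration, so either reading is runnable,
and Glu908/Glu918 is the default.

Wires are tracked through time into *events*. The default identity of a
wire across frames is its exact unordered water set — the strictest
deterministic rule, chosen because the literature defines "stable" only
through a lifetime range; a stricter ordered-path mode and a looser
Jaccard ≥ 0.8 mode are options. There is no gap tolerance: a wire absent in
one sampled frame ends its event. An event's lifetime is
`n_contiguous_frames × frame_spacing`, so a single-frame observation has a
lifetime of one sampling interval; since reported lifetimes (150–250 ps)
sit far above any reasonable sampling interval, the convention is
immaterial to comparisons but fixed for reproducibility. Tracking
conserves observations exactly: summed event frame counts equal summed
per-frame wire counts.

## The pore envelope and hydration counting

The pore is pictured in the source literature but never given an explicit
geometry, so the package defines it as a **capped cylinder** between the
carboxylate carbons of Glu908 and Glu918 — the wire endpoints — with
default radius 5 Å and 2 Å axial padding at both ends; boundaries are
closed (a water exactly on the boundary counts). An alternative
`"lining"` mode counts waters within 4.5 Å of any polar atom of the seven
lining residues; when the two modes disagree materially, both can be
reported, and both are configuration. Hydration time series are counted at
a configurable interval (the reported counts were taken at fixed 1 ns
intervals; the sampling interval here must be a multiple of the frame
spacing), with means over user-specified time windows for phase
comparisons such as "partially hydrated, ~4 waters" versus "fully
hydrated, 7–11 waters".

## Crystallographic-water overlap

The source compares simulation waters with crystal waters using an
"overlap (RMSD < 2 Å)" rule; applied to single waters, RMSD reduces to a
displacement. After rigid-body superposition (Kabsch least squares, via
`bio3d::fit.xyz`) of the crystal structure onto the chosen simulation
frame on shared Cα atoms, waters are matched greedily in ascending
displacement order under a strict 2 Å cutoff, each water used at most
once. Greedy matching was chosen for determinism; the tests verify it
equals an exact maximum-cardinality assignment on jittered instances of
the sizes that occur here (waters cannot physically approach each other
closer than ~2.8 Å, so the bipartite candidate graph is essentially a
matching already). Per-residue positional stability is reported as the
mean ± sd over frames of the residue's heavy-atom RMSD after global
superposition; the superposition atom set is unstated in the source, so
it is a configuration choice (transmembrane Cα fitting by default in the
pipeline).

## Helix hinge-bending and gating contacts

The M5 bend angle is the angle between the axes of the two helix flanks on
either side of the Ile761–Ile765 hinge. How the source computed its
bending angle is unstated; here the flanks default to residues 748–760 and
766–778 (13 residues each), fitted through Cα positions, all
configuration-exposed. The axis of each flank is fitted as a
**least-squares cylinder axis**: the principal axis of the centred
coordinates seeds a Levenberg–Marquardt refinement of the axis direction
and lateral offset that minimises the spread of squared radial distances.
The refinement matters: the raw principal axis of a short helix segment
with an incomplete final turn is biased by 1–2°, while helix points lie
exactly on a circular cylinder, making the cylinder axis exact for ideal
geometry (the tests assert < 1° on straight fixtures and ≤ 1° recovery of
planted 10–30° kinks). Under 0.3 Å coordinate noise the fitted axis stays
within ~2° of the construction axis in expectation.

The gating observables follow the source's criteria: the Arg762–Ser915
distance is the minimum over the three guanidine nitrogens to the Ser915
backbone oxygen, with a contact flagged under R < 5 Å (one figure label
reads "Arg762–Arg915"; the body text's Ser915 is used); the backbone
O(i)→N–H(i+4) bond between Ile761 and Ile765 is monitored as the O···N
distance, flagged broken above 3.5 Å — the same threshold as the
hydrogen-bond criterion — with a distance exactly at the cutoff counting
as intact. Note that the minimum-distance and centroid contact modes are
not ordered in general (two atoms straddling the contact axis can make the
minimum exceed the centroid distance); for the compact, facing groups of
the gating contact the minimum mode is the smaller, and the tests check
exactly that.

## The synthetic-data generator

`build_scaffold()` emits a deterministic ~250-atom stand-in protein — not
a homology model — carrying the real residue names and numbers so that
production configurations resolve verbatim: an ideal-helix M5 (748–778)
with the Arg762 guanidine, the seven pore-lining residues around an
explicit pore axis with the Glu908/Glu918 carboxylates 19.6 Å apart at its
ends, and Ser915 across from Arg762. `generate_trajectory()` adds a
24-water pool and animates three scenarios:

* **hydration_onset** — stepwise pore filling 0 → 2 → 4 → 5 waters
  (emulating water binding events early in the hydration run), with a
  crystal-style reference (`make_crystal_reference()`) in which a chosen
  number of waters sits within a set jitter of planted positions and the
  rest far away.
* **wire_formation** — a partially hydrated burn-in (4 waters), then a
  fully hydrated phase (9 waters, the midpoint of the reported 7–11
  band) carrying 130 planted wire events, 100 six-water and 30
  seven-water, lifetimes uniform over 150–250 ps at 10 ps sampling,
  scheduled back-to-back with one wire-free frame between events.
* **pore_closure** — 4–5 waters occupying the two pore ends with two brief
  complete-dewetting episodes, no bridging chain anywhere, and a scripted
  closure window in which the hinge kinks to 20°, the Arg762–Ser915
  distance ramps 8 → 4.2 Å and the Ile761–Ile765 O···N distance ramps
  ~3.0 → 5.2 Å concomitantly.

Geometry guarantees detection margins rather than hoping for them: wire
waters sit at 2.8 Å O–O spacing with hydrogens aligned along the chain
(well inside 3.5 Å/150°), while all non-wire in-pore positions come from a
library of ring positions that are mutually ≥ 4.6 Å apart — beyond the
hydrogen-bond cutoff — so scripted absence of wires is geometrically
certain, not statistical. Positional noise (`noise_sigma`, default 0 Å so
that planted counts and window means are recovered exactly) jitters
everything *except* the atoms that scripts pin (in-pore waters, the
endpoint carboxylates, the gating atoms): the ground truth always
describes the emitted coordinates exactly. The generator's single RNG
stream is fully determined by the scenario seed, and fixtures round-trip
through multi-MODEL PDB at the format's 10⁻³ Å precision.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: physically realistic water dynamics and exchange
with bulk, membrane lipids, thermal protein motion beyond isotropic
jitter, wires that rearrange gradually rather than appearing and
disappearing, and crystallographic coordinate error models. The planted
phenotypes make recovery *exactly* checkable; they say nothing about
detection sensitivity at marginal hydrogen-bond geometries, which is why
the oracle-equivalence tests (brute-force pair evaluation, exhaustive path
search, exact assignment) cover randomised geometry separately.

## Numerical choices and degenerate inputs

* Boundary ties are closed everywhere (≤, ≥) except the two criteria the
  source states as strict inequalities: crystal-water matching (< 2 Å)
  and the contact flag (R < 5 Å).
* Atom ordinals are 1-based row indices into the topology — idiomatic for
  R — while residue identifiers are kept verbatim from the source file so
  that literature residue numbers work unchanged in configurations.
* Superposition requires ≥ 3 non-collinear fit atoms and fails loudly
  otherwise; axis fitting requires ≥ 3 points and engages the cylinder
  refinement from 5 points (flanks must span ≥ 6 residues).
* Tracking requires uniformly spaced frames and rejects anything else
  rather than guessing; hydration sampling intervals must be integer
  multiples of the frame spacing.
* `find_wires` ties are broken by water count and then lexicographic
  ordinal order, making every output list deterministic.
* In `geometry_timeseries`, axis fits are cached across frames whose
  flank coordinates are bit-identical (common in scripted fixtures);
  results are unaffected.

## Problem sizes used in the checks

The shipped test and acceptance fixtures use a ~250-atom scaffold with a
24-water pool; the wire-formation fixture spans ~2,800 frames at 10 ps
spacing (130 events), and oracle comparisons run on hundreds of random
systems of up to ~50 atoms or 30 graph nodes. These sizes exercise every
code path while keeping a full run in minutes on one core; all scale
linearly in frames for larger real trajectories.

## Known limitations

XTC trajectories are not read (no installed R reader; convert to DCD or
multi-MODEL PDB). Hydrogen-bond definitions are purely geometric — no
energetic or electronic criteria. Pore-radius profiling along the axis
(HOLE-style) is out of scope, as are proton-hopping simulation and wire
free-energy estimates. The command-line surface is intentionally thin: the
documented R functions, the `run_pipeline()` configuration file, and the
scripts shipped with the package are the supported interface.
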