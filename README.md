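# porewire

Trajectory analysis of proton-release pathways in membrane proteins:
hydrogen-bond graphs, water wires, pore hydration, crystallographic-water
overlap, and helix-gating geometry — with a synthetic-trajectory generator
that makes every stage testable against planted ground truth.

## The problem

The sarco/endoplasmic-reticulum Ca²⁺ pump (SERCA) countertransports protons
while it moves Ca²⁺. In its protonated E2 state, a residue-lined pore at
the C-terminal transmembrane region — from transport-site residue Glu908
past Ser767, Arg836, Tyr837, Asn911 and Asn914 to Glu918 near the
cytosol — is thought to conduct those protons along *water wires*: chains
of hydrogen-bonded waters bridging the two carboxylates. Deprotonation of
Glu908 is proposed to close the pore through bending of transmembrane
helix M5 at the Ile761–Ile765 hinge and an Arg762–Ser915 gating contact.

`porewire` turns each of those claims into a computation over a structure
plus trajectory:

* **Hydrogen-bond graphs** per frame over water oxygens and polar
  side-chain atoms (geometric criterion, default ≤ 3.5 Å and ≥ 150°;
  minimum-image under periodic boxes; distance-only fallback for
  hydrogen-free crystal waters).
* **Water wires**: all simple source→sink paths whose internal nodes are
  waters, deduplicated and bounded (`max_waters`, default 8); temporal
  tracking into events by exact water-set identity, with lifetimes
  `n_frames × spacing`; statistics (count, length histogram, dominant
  length, lifetime quantiles) and a wire-presence/first-passage series.
* **Pore hydration**: waters inside a capped cylinder between the Glu908
  and Glu918 carboxylate carbons (radius 5 Å, padding 2 Å, closed
  boundaries; lining-proximity mode as an alternative), counted per frame
  with windowed means.
* **Crystal-water overlap**: greedy nearest-first matching under a strict
  2 Å displacement cutoff after Cα superposition, verified against exact
  assignment; per-residue positional RMSD (mean ± sd) after global
  superposition.
* **Helix gating**: hinge-bend angle between least-squares cylinder axes
  of the flanks around Ile761–Ile765, the Arg762(NE/NH1/NH2)–Ser915(O)
  minimum distance with the R < 5 Å contact flag, and the
  Ile761 O···N Ile765 backbone bond with a 3.5 Å broken flag.
* **Synthetic data**: a deterministic scaffold carrying the real residue
  numbering plus three scripted scenarios (hydration onset, wire
  formation with 130 planted events, pore closure) whose ground truth is
  exact by construction.

I/O rides on `bio3d` (PDB, multi-MODEL PDB, DCD); graphs on `igraph`;
everything else is base R. See the methods vignette
(`vignettes/porewire-methods.Rmd`) for the model, parameter rationale and
limitations.

## Worked example

Generate the wire-formation fixture (130 planted events, 100 six-water and
30 seven-water, lifetimes uniform in 150–250 ps at 10 ps sampling, pore
occupancy 4 then 9 waters) and run the full pipeline:

```r
library(porewire)

tr  <- generate_trajectory(scenario_spec("wire_formation", seed = 101))
rep <- run_pipeline(list(lifetime_threshold = 150,
                         windows = list(c(0, 490), c(500, 28800))),
                    topology = tr$topology, frames = tr$frames)
rep
#> porewire analysis report
#>   hydration: mean 8.91 waters in pore
#>   wires: 130 events, dominant length 6 waters, median lifetime 200 ps
#>   helix bend: 0 - 0 deg
rep$wires$length_histogram
#>   6   7
#> 100  30
range(rep$wires$events$lifetime)
#> [1] 150 250
```

The report says: 130 wire events were recovered (one per planted event),
six-water wires dominate (100 of 130), every lifetime lies inside the
planted 150–250 ps band, the pore holds ~9 waters on average once wires
form (4 during the burn-in — see `rep$hydration$window_means`), and the
helix stays straight, as scripted for this scenario. The same
`run_pipeline()` call accepts `structure`/`trajectory` file paths or a
YAML configuration for real data, and writes TSV tables plus a JSON report
when given an `outdir`.

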