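Package: porewire
Title: Water Wires, Pore Hydration and Helix Gating in Membrane-Protein Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Trajectory analysis of proton-release pathways in P-type ATPases
    and related membrane proteins. Builds per-frame hydrogen-bond graphs over
    water oxygens and polar side-chain atoms, enumerates hydrogen-bonded water
    wires connecting two carboxylate endpoints, tracks wires through time into
    events with lifetimes, counts waters inside a residue-defined pore
    envelope, matches simulation waters against crystallographic waters, and
    quantifies helix hinge-bending together with the gating contacts that
    accompany pore closure. Ships a synthetic-trajectory generator with
    planted ground truth so every analysis stage is testable end to end
    without external simulation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
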