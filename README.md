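# betafold

Folding and self-association analytics for β-peptide foldamers.

β-peptides — oligomers of β-amino acids, the closest homologues of natural
peptides — fold into characteristic secondary structures (the 3₁₄-helix with
its NH(i)···O=C(i+2) hydrogen-bond ladder, the 2.5₁₂-helix with i → i−3
bonds, hairpins) and self-assemble into transient hydrogen-bonded oligomers.
Molecular-dynamics studies of these systems all need the same analysis
stack, and that stack is what this package provides, for anyone working with
structural ensembles of β-peptides:

* **Continuous fold scores.** The presence of a backbone hydrogen bond is
  graded by the rational switching function of the hydrogen–acceptor-oxygen
  distance,

  s(d) = (1 − (d/d₀)ⁿ) / (1 − (d/d₀)ᵐ),

  with d₀ = 0.25 nm and exponents calibrated so the score crosses 50% at
  0.27 nm and 10% at 0.44 nm. The **helicity** of an N-residue chain is the
  mean of s over the N−2 possible H(i)···O(i+2) distances; **hairpin
  likeness** is the mean over the fold's designated bonds (3 → 4, 2 → 5,
  1 → 6 for a six-residue hairpin).
* **Discrete hydrogen bonds and occupancy fingerprints.** The classical
  geometric criterion (donor–acceptor < 0.3 nm, D–H–A angle > 150°,
  donor–H < 0.12 nm) drives per-frame detection and residue–residue
  occupancy maps pooled over independent reruns.
* **Associate lifetimes.** Chains are sorted into associates per frame by
  Hoshen–Kopelman labeling of the interchain hydrogen-bond graph; dimer,
  trimer, … events are tracked through time with the rule that an
  underlying smaller associate stays *alive* while part of a larger one,
  and summarized as median/longest lifetime, trajectory percentage and
  events per 1000 ns.
* **NOE violations.** Effective interproton distances ⟨r⁻⁶⟩⁻¹/⁶ (per-frame
  minimum over chemical-equivalence groups) against experimental upper
  bounds.
* **Conformational classification.** Kabsch least-squares superposition
  RMSD, Daura clustering (0.1 nm cutoff on central-residue Cα atoms by
  default) and cumulative cluster-count convergence curves.
* **Synthetic structure generator.** An internal-coordinate (NeRF) backbone
  builder with torsion presets for ideal extended, 3₁₄-helix, 2.5₁₂-helix
  and hairpin conformations, noisy fold↔unfold pseudo-trajectories, and
  scripted eight-chain association boxes — so every stage above is testable
  in seconds without running MD.

Structures and trajectories are read/written as PDB (multi-model, CRYST1
boxes), GRO and XYZ text files; all coordinates are nm, times ps, angles
degrees, residue numbering 1-based.

## Worked example

```r
library(betafold)

## an ideal six-residue 14-helix, jiggled with 0.005 nm of positional noise
hel  <- presetConformation("helix314", 6)
stab <- synthesizeTrajectory(hel, hel,
          synthesisPlan(200, dt = 100, noiseSigma = 0.005, seed = 1))

mean(scoreValues(helicitySeries(stab)))      # 0.951  -> 95.1% helicity
occupancyPercent(occupancyMap(stab))         # 100% at (1,3) (2,4) (3,5) (4,6)

## an unfolding run: helix -> extended
ext <- presetConformation("extended", 6)
unf <- synthesizeTrajectory(hel, ext,
         synthesisPlan(200, dt = 100, noiseSigma = 0.005, seed = 2))
mean(scoreValues(helicitySeries(unf)))       # 0.164  -> 16.4%
dauraCluster(unf)                            # 4 clusters at 0.1 nm cutoff

## eight extended chains forming and breaking scripted associates
atrj <- synthesizeAssociation(presetConformation("extended", 6), 8, 3,
          synthesisPlan(120, dt = 100, noiseSigma = 0.002, seed = 1))
ev <- associateEvents(atrj)
lifetimeStatistics(ev, spanPs = 120 * 100, dtPs = 100)
```

The lifetime table for the scripted box reads:

```
  order n_events median_lifetime_ns longest_lifetime_ns trajectory_percent per_1000ns
      2        2                3.4                 4.9               56.7      166.7
      3        1                1.9                 1.9               15.8       83.3
```

Two dimers lived (median 3.4 ns, longest 4.9 ns, at least one alive in 57%
of frames) and one trimer, whose host dimer outlives it — the nested
sub-associate rule in action. `runPipeline()` chains all stages (trajectory,
helicity, hydrogen bonds, occupancy, clustering, association) into one
deterministic run with a CSV manifest.

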