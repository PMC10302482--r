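Package: betafold
Title: Folding and Self-Association Analytics for Beta-Peptide Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics style trajectories of
    beta-peptide foldamers. Provides continuous hydrogen-bond switching-function
    scores for 14-helix and hairpin propensity, discrete geometric hydrogen-bond
    detection with residue-residue occupancy fingerprints, Hoshen-Kopelman
    labeling of multichain associates with lifetime bookkeeping and summary
    statistics, NOE upper-bound violation analysis with r^-6 time averaging,
    least-squares superposition RMSD, Daura conformational clustering with
    cumulative cluster-count convergence curves, and a synthetic beta-peptide
    structure and trajectory generator (internal-coordinate backbone builder,
    torsion-preset secondary structures, multichain box assembly) so that every
    analysis stage can be exercised at desk scale. Structures and trajectories
    are read and written as PDB, GRO and XYZ text formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'templates.R'
    'geometry.R'
    'build.R'
    'synthesize.R'
    'trajio.R'
    'hbonds.R'
    'foldscores.R'
    'association.R'
    'conformers.R'
    'pipeline.R'
    'betafold-package.R'
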