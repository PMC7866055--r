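Package: poreflow
Title: Water Permeability and Interaction-Network Analysis of Membrane-Protein MD Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing toolkit for molecular-dynamics trajectories of
    membrane-protein pores. Implements the collective-diffusion estimate of
    single-channel osmotic water permeability (pore region from alpha-carbon
    rings, boundary-clipped collective displacement, diffusion-coefficient fit
    over subtrajectories, viscosity rescaling), salt-bridge network distance and
    occupancy analysis, water number-density profiles, occupancy volume maps
    with channel-continuity testing, water crossing counts, conformational
    stability metrics (mass-weighted superposition, RMSD, RMSF, common PCA and
    principal-component span area), and ligand-binding contact and distance
    analyses over replica ensembles. Ships a Brownian-dynamics synthetic
    trajectory generator with analytic ground truth so every stage is testable
    without an MD engine, plus structure/trajectory readers and writers (GRO,
    PDB, DCD) and a declarative analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
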