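---
title: "Graph-embedded relative coordinates: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-embedded relative coordinates: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The representation problem

A conformer is an N x 3 coordinate matrix, but its chemistry is unchanged by
translation, rotation, and relabeling of atoms.  Models that learn directly
on Cartesian coordinates inherit all three nuisances; internal coordinates
(Z-matrices) remove the rigid motions but are brittle under noise, because a
single perturbed torsion in the middle of a chain swings everything built on
top of it.  `gierc` implements a representation that is invariant to all
three operations *and* decodes back to 3D losslessly: each atom describes its
topological neighborhood in its own local frame, and the decoder reassembles
the molecule by averaging redundant internal-coordinate estimates across
overlapping neighborhoods.

## Encoding

For a molecule with bonds and bond orders known, the encoder works purely
from topology plus one conformer:

1. **Weighted graph distances.**  Every bond gets a reference length from an
   embedded force-field-style table (`standard_bond_length()`; covalent-radii
   sum as fallback).  `weighted_graph_distances()` runs Dijkstra on those
   weights, giving a topology-only distance `r2d` for every atom pair.
   Encoder and decoder share the table, so round-trip exactness never
   depends on its chemical accuracy.
2. **Canonical atom order.**  A Coulomb matrix is built from `r2d`
   (`0.5 * Z^2.4` diagonal, `Z_i Z_j / r2d` off-diagonal) and atoms are
   ranked by descending row norm, with ties refined iteratively over sorted
   neighbor keys (a Weisfeiler–Lehman-style sharpening).  Atoms that remain
   tied after refinement are genuine graph automorphisms (e.g. the three
   hydrogens of a methyl group); their relative order falls back to input
   position.  Because automorphic atoms have *different* 3D environments in
   any particular conformer, no graph-derived order can make the encoding
   literally identical under relabelings that swap them — the encoding is
   exchange-invariant up to automorphism, exactly invariant for molecules
   whose atoms are all topologically distinguishable.
3. **Local structure features.**  For each atom `i`, all atoms within three
   bonds are listed, sorted by `r2d` (canonical rank breaks ties).  The two
   closest define a right-handed frame (x toward the first, z along the
   cross product with the second; a collinear second neighbor is replaced by
   the next one in order, tolerance `|sin| > 1e-3`).  Each neighbor `j`
   contributes its local coordinates scaled by `S2D(r2d)/r2d`, where `S2D`
   is a smooth 1/r attenuation that tapers to zero between the cutoffs
   `rcs = 5.0` and `rc = 6.0` Angstrom.  Rows are zero-padded to the
   dataset-wide maximum neighborhood size `m`, and atom slabs are stacked in
   canonical order, giving the N x m x 3 feature tensor.

Because every ingredient except the local coordinates is graph-determined,
the tensor is translation/rotation-invariant, and mirror images flip the
sign of the z-components only — chirality is retained.

## Decoding

Scaling by `r2d/S2D` inverts each feature row back to a neighbor position in
the atom's local frame.  A neighbor whose graph distance exceeds `rc` has
been multiplied by zero; it is unrecoverable and excluded (with a warning).
Every spanning-tree internal coordinate — bond, angle, dihedral — is then
*estimated once per local structure that contains all of its atoms*: a bond
deep inside a molecule is typically seen by six or more neighborhoods.  Per
coordinate the estimates are filtered with one-dimensional DBSCAN
(`min_samples = 1`, radii 0.1 Angstrom / 20 degrees / 20 degrees; circular
distance for dihedrals), only the biggest cluster is kept, and its mean
(circular mean for angles and dihedrals) becomes the consensus value.  At
zero noise all estimates coincide and the filter is a no-op; under noise the
redundancy averages the error down and the filter drops wild outliers.

Cartesian coordinates are rebuilt by sequential natural-extension-reference-
frame placement over a spanning tree (breadth-first from the first canonical
atom, children in canonical order; reference atoms prefer tree ancestors and
fall back to the earliest-placed graph neighbor, so every tuple spans at
most three bonds and is guaranteed at least one estimate).  Rings rely on
the spanning tree: closure bonds are never enforced, only reported by a
diagnostic (`ring_closure_diagnostic()`).  At zero noise the spanning-tree
internal coordinates determine the geometry completely, so ring closure is
exact anyway and `decode(encode(x))` reproduces `x` to numerical precision
(~1e-15 Angstrom in the tests).  Degenerate placements (a collinear
reference triple) abort with an error; the synthetic templates keep ideal
angles away from 180 degrees.

## Noise benchmark

`run_noise_benchmark()` compares three flattenings of the same conformer —
the feature tensor, the spanning-tree Z-matrix, and centroid-centered
Cartesian coordinates — under elementwise multiplicative Gaussian noise
`x -> x (1 + p e)`.  Exact zeros (padding) stay zero, so the tensor
structure survives.  The "percentage of noise" is a modeling choice: a
multiplicative model is the only unit-consistent way to perturb a vector
that mixes Angstroms and degrees, and Cartesian coordinates are centered
first so the perturbation does not depend on an arbitrary origin.  All
three representations decode through the same rebuild routine, isolating
the representation as the experimental variable.

Two behaviors follow from the model and are reproduced by the tests: the
graph-embedded encoding beats the internal-coordinate baseline on both
metrics at every noise level (consensus averaging vs. single-value
torsions), and it beats the Cartesian baseline on torsion error by an order
of magnitude.  One behavior differs from what a reader of the original
noise table might expect: centered multiplicative Cartesian noise produces a
coordinate RMSD of roughly `p` times the radius of gyration, which for a
compact 150-atom peptide (about 0.2 Angstrom at 5 percent) is *smaller*
than the accumulated rebuild error of any torsion-based representation.
A noise model applied to uncentered coordinates — whose error scales with
the arbitrary distance from the origin — would reverse that comparison;
we consider the centered model the defensible one and report the asymmetric
dominance claim (coordinates vs. internal baseline, torsions vs. Cartesian
baseline) as the package's tested guarantee.

## Synthetic conformers

No external data ships with the package; `make_template()` builds four
molecular families deterministically (carbon/heteroatom chains, branched
skeletons, an aromatic ring with a phosphate-ester-like tail, and capped
peptide-like chains of alanine/glycine/serine-like residues), assigns ideal
geometry (tabulated bond lengths, tetrahedral/trigonal angles, staggered or
planar torsions, flat rings), and fills valences with explicit hydrogens.
The two benchmark systems are sized to the published atom counts: the
ring-plus-tail molecule has 24 atoms and the 14-residue peptide
(12 alanine-like, 1 glycine-like, 1 serine-like) exactly 150.

`sample_ensemble()` draws each rotatable-bond torsion from an explicit
mixture (modes, spreads, weights), jitters bonds (default sd 0.01 Angstrom)
and angles (default sd 2 degrees), and rebuilds coordinates through the same
spanning-tree machinery as the decoder.  Setting a torsion exactly requires
knowing the sign relating a placement-record offset to the measured
canonical torsion; the template probes each bond once numerically and caches
the sign.  Default mixtures are anti/gauche (180/60, weights 0.7/0.3) for
small molecules and, for peptide-like templates, trans amides (sd 3 degrees)
with helix-leaning backbone mixtures — a statistical stand-in for folded MD
ensembles.  What the generator deliberately does *not* emulate: Boltzmann
weighting, steric exclusion between non-bonded atoms, solvent, or correlated
backbone torsions.  Tests passing on these ensembles demonstrate the
representation's algebraic and statistical properties, not force-field
realism.

## Autoencoders

The graph-conditioned autoencoder treats conformer generation as per-node
feature generation.  Node features one-hot encode atomic number, degree,
formal charge, chirality and hybridization; edges one-hot the bond order.
Three rounds of communicative node/edge message passing produce per-node
embeddings `h_v` whose receptive field (three bonds) matches the local
structure features.  The encoder MLP (three tanh layers, 256 wide) maps each
atom's m x 3 feature slab to a 128-dimensional latent `z_v`; during training
`z_v` is perturbed multiplicatively with 5 percent Gaussian noise; the
decoder MLP receives `concat(h_v, z_v)` and reconstructs the slab.  The loss
is masked MSE — padding rows never contribute.  Optimization is Adam
(initial 1e-3) with a halve-on-plateau schedule (patience 10), stopping
below 1e-8 or after 30 non-improving epochs; the returned model carries the
best-validation parameters, and every random element (9:1 split,
initialization, latent noise, batch order) derives from one seed.

Two deliberate simplifications, both consequences of the single-molecule
training setting:

* the message-passing weights are fixed (seeded) rather than trained.  For
  a fixed molecule `h_v` is a constant per-node vector, so any trainable
  transform of it is absorbed by the decoder's first dense layer; freezing
  it changes nothing that the in-scope experiments can observe, while
  removing two-thirds of the backpropagation graph.  The embedding width
  defaults to 64 for the same reason — it only needs to separate node
  environments, not to generalize across molecules.
* the naive baseline (no graph conditioning, one global 128-dimensional
  latent for the whole flattened tensor) uses dense layers rather than a
  convolutional stack.  Its defining property — whole-tensor compression
  without graph information — is what the comparison tests exercise.

The expected phenomenology reproduces at desk scale: on the 24-atom system
both models reconstruct held-out conformers well, while on the 150-atom
peptide the naive model's global 128-d bottleneck fails badly (held-out
torsion RMSD an order of magnitude above the graph model's few degrees).
Latent-space interpolation decodes convex combinations of the endpoint
latents under the fixed graph embedding; at `t = 0, 1` it is bitwise the
direct reconstruction, and with the transition region excluded from
training, interior interpolants still traverse the excluded torsion range —
the latent space is continuous across the gap.

## Numerical choices and problem sizes

* Angles live in degrees at every API boundary; radians only inside kernels.
* Dihedral estimates are averaged with the circular mean and clustered with
  circular (period-360) distance; bond lengths with the plain mean.
* Ties for "biggest cluster" resolve to the cluster appearing first in the
  sort order; encoding is bitwise reproducible for a fixed input.
* Mode detection in `exclude_transition_region()` uses a circular kernel
  density estimate (default bandwidth 15 degrees) and takes the two tallest
  peaks; density clustering by eps-chaining was rejected because a
  populated transition valley chains the modes together.
* Test and benchmark problem sizes: ten structures per benchmark cell with
  30 noise repeats; 2,000-conformer training ensemble for the 24-atom
  system and 330 for the 150-atom system at reduced epoch counts (25 and
  20).  These sizes give stable means (repeat-to-repeat variation of the
  noise cells is a few percent) while keeping the whole suite desk-scale.

## Known limitations

* Exchange invariance is exact only up to graph automorphism (see above).
* Decoded rings are as good as their spanning-tree torsions under noise;
  closure error is reported, not repaired.
* The generator's ensembles are statistically, not physically, realistic.
* The autoencoder is trained per molecule; conditioning on `h_v` makes
  cross-molecule generalization possible in principle, but nothing here
  validates it.
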