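---
title: "Dynamic contact network analysis of multi-state conformational ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic contact network analysis of multi-state conformational ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdcna)
```

## The problem

Molecular machines such as the Pol II–Rad26 (CSB) transcription-coupled
repair complex convert nucleotide binding and hydrolysis into directed
conformational change. Molecular-dynamics ensembles of the same complex in
different functional states (nucleotide-free apo, ATP-bound, ADP-bound)
encode how residue–residue interactions rearrange around the ATPase cycle,
but the raw trajectories are far too high-dimensional to compare directly.
`mdcna` implements a residue-level network reduction of such ensembles:

1. **Contact maps.** Each state's ensemble is reduced to a symmetric matrix
   of contact probabilities: the fraction of frames in which two residues
   have at least one heavy-atom pair within a distance cutoff (4.5 Å by
   default, inclusive). Contacts present in more than half the frames are
   *persistent*; persistent contacts can be classified chemically
   (salt bridge, hydrogen bond, hydrophobic) by per-frame geometric
   criteria.
2. **Consensus network and dynamic communities.** Contacts stable in
   *every* state (probability ≥ 0.9 in each map, by default) form an
   unweighted consensus graph. Divisive Girvan–Newman clustering —
   repeatedly deleting the edge of maximal edge betweenness, recomputed
   exactly after every deletion — partitions the graph into dynamic
   communities: groups of residues that stay persistently connected across
   the whole cycle. Division stops when the modularity change between
   successive partitions falls below a tolerance (0.001 by default) and the
   best-modularity partition on the divisive trace is returned.
3. **Difference contact analysis.** For a state transition, residue-level
   contact-probability differences d(i,j) = p_to(i,j) − p_from(i,j) are
   summed over pairs of distinct communities, giving a community-pair
   matrix ΔP whose sign marks net gain or loss of interface contacts. The
   three transitions of the hydrolysis cycle (apo→ATP, ATP→ADP, ADP→apo)
   telescope: their ΔP matrices sum to zero exactly, a built-in consistency
   check.
4. **Allosteric paths.** Within one state, persistent contacts (probability
   > 0.75) are weighted by the cross-correlation of residue positional
   fluctuations, w = −ln|c|, so strongly coupled contacts are short edges.
   The bundle of lowest-weight simple paths between two residues (e.g. an
   active-site residue and a DNA-binding element) traces the dominant
   allosteric routes; per-node path counts show which residues carry the
   communication, and a query set of positions (such as disease-mutation
   sites) can be scored by the fraction that lies on the bundle.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| contact cutoff | 4.5 Å | heavy-atom distance defining a contact (inclusive) |
| persistence (paths) | 0.75 | minimum contact probability for a network edge |
| persistence (classification) | 0.5 | "persistent contact" threshold, strict |
| consensus threshold | 0.90 | per-state probability required of consensus edges (≥) |
| modularity tolerance | 0.001 | stopping rule of the divisive clustering |
| k | 5000 | number of suboptimal paths enumerated |
| hop radius | 2 | graph reduction radius around the optimal path |
| sequence exclusion | 1 | same-chain neighbours excluded from contact maps |

All thresholds are arguments with these defaults; the pipeline records the
values used in its JSON manifest.

Node positions for correlations and B-factors use Cα for amino acids and P
for nucleotides (the same convention as heavy-atom RMSD fitting of
protein–DNA complexes), with a residue-centroid alternative. Frames are
least-squares superposed onto the ensemble mean (two fit–remean iterations)
before fluctuations are measured; superposition can be disabled for
ensembles known to carry no rigid-body drift.

## Suboptimal path enumeration

The optimal path is the minimum-total-weight simple path under nonnegative
weights; ties resolve to the lexicographically smallest node sequence, so
results are reproducible across platforms. Suboptimal enumeration follows
the reduce-then-enumerate scheme: the graph is restricted to nodes within a
small hop radius of the optimal path, and the k lowest-weight simple paths
are enumerated inside the reduction with a deviation (Yen-style) algorithm.
Enumeration continues past k until the weight strictly exceeds the k-th
weight, then the list is sorted by (weight, lexicographic order) and
truncated, so boundary ties cannot make the output order depend on
exploration order. The reduction is an efficiency device and is visible in
the output: a low-weight detour through nodes outside the radius is absent
from the reduced enumeration although exhaustive enumeration would list it.
The test suite checks equivalence with brute-force enumeration whenever the
radius covers the graph, and checks the pruning artifact deliberately.

Zero-weight edges (perfect correlation) are legal; the simple-path
constraint keeps enumeration finite, but lexicographic tie-breaking among
equal-weight paths through zero-weight cycles is then best-effort.

## Community detection: scope and limitations

Girvan–Newman is divisive and greedy: it can only return partitions whose
communities are connected components of some edge-deletion state reached by
always removing the current maximal-betweenness edge. On graphs with clear
modules (dense blocks, sparse bridges — the regime consensus networks of
folded macromolecular complexes occupy) the divisive trace passes through
the modularity optimum and the returned partition achieves it; the test
suite verifies this on planted block graphs (3 blocks × 10 nodes, intra
density 0.9, inter 0.05: exact recovery in 100/100 seeds) and on the
two-clique reference graph, whose optimum (K = 2, Q = 12/13 − 1/2) is
confirmed by exhaustive search over all partitions. On unstructured sparse
random graphs, however, pendant edges carry maximal betweenness, the trace
descends through singleton splits, and the modularity optimum — although it
has connected communities — is often never visited. This is an inherent
property of the algorithm, shared by every faithful implementation; the
acceptance checks therefore compare against exhaustive search conditionally
on the optimum appearing on the divisive trace, and report the
unconditional agreement rate alongside.

The stopping tolerance interacts with the same behaviour: on small graphs
the modularity of the first few accepted partitions can decrease before it
rises, and the default rule (stop when the gain drops below 0.001) then
stops at the initial partition. `modularity_tol = -Inf` explores the full
dendrogram and returns the best partition seen; validation uses that mode.

## The synthetic-data generator

Real multi-microsecond trajectories of a megadalton complex cannot ship
with a package, so every stage is validated against generated ensembles
with planted ground truth.

The generator plants K communities of m residues in three (or more)
functional states. Each residue contributes a *body* atom — a Cα bead that
carries the residue's displacement and serves as the network node — plus
one dedicated *probe* atom per designated contact pair. A designated pair's
probes sit at a private contact site, 2.8 Å apart when the pair is "in
contact" and 10 Å apart otherwise, and every frame draws the state
independently with the planted probability. A single bead per residue
cannot realize independent Bernoulli contacts for the many pairs a residue
participates in; dedicating one probe per pair makes the planted
probability exact by construction. Contact sites are placed
deterministically on grids away from the residue bodies (intra-community
sites on a shelf below each community, inter-community sites between
community pairs), and the layout is verified: for every residue pair, all
atoms other than the pair's own probes stay at least 2.5 Å clear of the
contact cutoff, so only the designated probes ever decide a contact. A
layout that cannot be placed cleanly is rejected with an error rather than
generated approximately.

Designated pairs comprise: all intra-community pairs at sequence distance
2–4 (probability `p_intra` = 0.95 in every state; distance-1 pairs are
covalent neighbours and excluded from contact maps), `n_inter_pairs` = 3
toggling pairs per community pair whose probabilities follow a cyclic
gain/loss pattern over the states (0.10/0.85/0.45 rotated per community
pair — a caricature of an ATPase cycle in which each interface gains
contacts in one state and relaxes through the others), and one stable
bridge pair per community pair (probability 0.98 everywhere) so the
consensus network is connected and community detection has real work to do.
The distance-2–4 band gives each community 21 internal edges; splitting a
band costs about 0.08 in modularity, so the planted partition is the
modularity optimum of the expected consensus graph.

Displacements are d_i(t) = √ρ·s_k(t) + √(1−ρ)·ε_i(t) with a shared
Gaussian s_k per community and independent ε_i, per-coordinate standard
deviation σ = 0.4 Å — small enough that displacement noise flips a planted
contact state in well under 1% of frames. Raw intra-community correlation
is ρ and inter-community correlation is 0 by construction, and generated
frames contain no rigid-body drift. Note that *fitted* correlations differ:
least-squares superposition removes the common-mode average of the
independently moving communities, which deterministically lowers
intra-community correlation (to (K−1)ρ/((K−1)ρ + K(1−ρ)) for K equal
communities) and makes inter-community correlations negative. Ground-truth
recovery checks therefore measure correlations with `fit = FALSE`, which is
exact for these drift-free ensembles; analysis of real trajectories keeps
the default `fit = TRUE`.

What the generator does *not* emulate: force-field energetics, anisotropic
or time-correlated dynamics, cooperative (non-independent) contact
formation, solvent, or the actual Pol II–Rad26 geometry. Passing the
recovery tests shows the pipeline measures what was planted at realistic
sample sizes (T = 1000 frames, 30 residues); it does not show that 4.5 Å /
75% / 0.9 are optimal choices for any particular real system.

## Numerical choices

- Contact cutoffs are inclusive (≤); persistence thresholds are strict (>)
  and the consensus threshold inclusive (≥), matching the conventions
  "within 4.5 Å", "more than 75%", "≥ 90%".
- Betweenness ties during division remove the lexicographically smallest
  (from, to) pair; path-weight ties resolve lexicographically by node
  sequence, compared bytewise so results do not depend on the locale.
- Correlations of zero-fluctuation residues are undefined and set to 0 with
  a warning; |c| values marginally above 1 from rounding clamp to weight 0.
  A fully rigid ensemble yields an edgeless network, reported as such.
- Contact-map computation prunes atom pairs by per-atom bounding boxes over
  all frames before any distance is computed, making cost proportional to
  near-contact pairs.
- Buried surface area is reported unhalved, BSA = SASA(A) + SASA(B) −
  SASA(A∪B), with a `halved` flag; sub-group contributions use the same
  formula with the sub-group in place of A, so the whole-group
  decomposition reproduces the total. Van der Waals radii follow the Bondi
  set (documented in `atom_radii`); unknown elements fall back to 2.0 Å
  with a warning. Sphere sampling uses a deterministic Fibonacci lattice
  (960 points by default; the isolated-sphere error is < 0.01% and
  converges with point count).
- Density simulation uses atom-centred Gaussians with σ = 0.225 × the
  nominal resolution and amplitudes proportional to atomic number; the
  correlation domain is the simulated envelope (> 1% of the simulated
  maximum) because whole-box correlations are dominated by empty voxels. An
  "about-mean" whole-box variant is available. These kernel conventions
  approximate, but are not guaranteed to match, those of external
  visualization packages, so absolute correlation values carry that caveat.
- The 22-community / modularity-0.91 scale of the published Pol II–Rad26
  consensus network derives from ~11 μs of trajectories that are not
  deposited; validation here is property-based at desk scale (problem sizes:
  30-residue planted ensembles × 1000 frames, ≤ 10-node graphs against
  exhaustive search, 10⁴-frame analytic ensembles), chosen so the full
  suite runs in minutes on one CPU.

## Design choices on open points

- **Consensus construction.** The dCNA literature describes both "stable
  in all states" and subtraction-based constructions. The default here is
  the intersection rule (probability ≥ threshold in every state), which is
  what "persistence across all functional states" means operationally; a
  `mode = "subtraction"` flag keeps contacts persistent in the reference
  state whose probability changes by at most 1 − threshold in every other
  state.
- **Waters and ions** are excluded from network nodes by default (scope is
  polymer residues); ligands can be opted in through selections.
- **ΔP summation** runs over unordered residue pairs, so ΔP(A,B) =
  ΔP(B,A); a factor-of-two convention difference is possible against
  implementations that sum ordered pairs.
- **XTC input** is not supported (no reader available to this package);
  multi-model PDB and DCD are, plus an explicit nm→Å conversion switch for
  nm-based sources re-exported to supported containers.
- **Endpoint semantics for paths** are free parameters: networks are
  undirected, so source/target labels (such as an ATPase motif II residue
  versus a DNA-insertion-helix residue) can be swapped without changing the
  path set.

## Worked example

```{r example}
set.seed(1)
gen <- generate_planted_ensembles(planted_config(n_frames = 200, seed = 1))
maps <- lapply(gen$ensembles, compute_contact_map)
maps$apo

cons <- build_consensus_network(maps)
part <- girvan_newman_partition(cons)
part

deltas <- hydrolysis_cycle_deltas(maps, part)
round(deltas[["apo->ATP"]], 2)

# cycle closure
max(abs(Reduce(`+`, deltas)), na.rm = TRUE)

# correlation-weighted network and suboptimal paths in the ATP state
corr <- cross_correlation(gen$ensembles$ATP)
net <- build_dynamic_network(maps$ATP, corr, persistence = 0.75)
ps <- soan_suboptimal_paths(net, "A:1", "C:10", k = 20, hop_radius = 2)
ps
path_composition(ps, query = c("A:8", "B:1"))$on_path_fraction
```

## Known limitations

- Exact betweenness recomputation makes community detection O(V·E²)-ish;
  fine for consensus networks up to a few thousand nodes, slow beyond.
- Path enumeration cost grows with the density of the reduced graph; a
  hop radius covering a dense graph approaches exhaustive enumeration.
- Contact classification without hydrogens uses heavy-atom distance
  criteria only; donor–H–acceptor angles apply only when hydrogens are
  present in the model.
- The MRC/CCP4 reader handles single-volume mode-2 (float32) maps with
  axis permutations — the common case for deposited cryo-EM maps — and
  nothing more exotic.
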