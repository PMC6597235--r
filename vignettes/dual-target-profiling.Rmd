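---
title: "Dual-target binding profiles and screening evaluation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-target binding profiles and screening evaluation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualprofiler)
```

dualprofiler takes the outputs of a docking campaign against two protein
targets — poses as PDB complexes and dock-score tables — and answers the
downstream questions: which residues bind the ligand and how strongly,
which enumerated analogues look drug-like, which compounds rank highly
against *both* targets, and whether the screen enriches known actives over
decoys. This vignette records the models, the parameters that matter, the
numerical choices, and what the synthetic benchmarks do and do not
demonstrate. The docking engine itself is out of scope throughout: poses
and scores are inputs.

## Per-residue binding profiles

### Buried accessible surface area

The accessible surface area (ASA) of an atom is the area traced by the
centre of a solvent probe rolled over its van der Waals sphere, excluding
regions occluded by neighbouring atoms. `shrake_rupley()` implements the
classic test-point algorithm: each atom's expanded sphere (radius
$r_i + r_\mathrm{probe}$) carries $n$ test points, and the ASA is the
exposed fraction times $4\pi (r_i + r_\mathrm{probe})^2$.

Numerical choices:

* **Test points are a deterministic golden-angle spiral lattice**, not a
  random sample. Two runs on the same structure are bit-identical, which a
  Monte-Carlo point set would not give without seed bookkeeping, and the
  lattice's near-uniform coverage converges faster than uniform random
  points at equal $n$.
* **$n = 960$ points per atom** (default). At this density the summed ASA
  of small clusters agrees with an independent high-sample Monte-Carlo
  oracle to well within 2% (the test suite enforces this on systems of up
  to 20 atoms); 96–240 points are adequate for rank-level questions and
  are used in some fast tests.
* **Probe radius 1.4 Å**, the conventional water probe.
* **Radii** are element-keyed, Chothia-style heavy-atom values
  (C 1.87, N 1.65, O 1.40, S 1.85 Å …); unknown elements fall back to
  1.80 Å with a warning. Analyses are heavy-atom only: crystal structures
  and docking outputs usually lack hydrogens, and dropping any that are
  present keeps free and bound states consistent.

The per-residue loss on binding is
$\Delta\mathrm{ASA} = \mathrm{ASA}_{free} - \mathrm{ASA}_{complex}$,
with the ligand acting purely as an extra occluder in the bound state and
the protein conformation held fixed (rigid assumption — the as-docked
conformation serves for both states, so conformational relaxation on
binding is deliberately not modelled). With identical point lattices in
both states the loss is provably non-negative. A residue is classified as
*participating in binding* when it loses **strictly more than 10 Å²**; the
strict inequality is intentional, so a residue at exactly the threshold
does not pass. The threshold is a long-standing interface-analysis
convention and is configurable.

### Contacts and hydrogen bonds

`find_contacts()` and `find_hbonds()` are geometric, heavy-atom
criteria in the style of 2-D interaction-diagram programs:

| parameter | default | meaning |
|---|---|---|
| `contact_min` | 2.9 Å | lower edge of the non-bonded window |
| `contact_max` | 3.9 Å | upper edge of the non-bonded window |
| `hbond_max` | 3.35 Å | donor–acceptor heavy-atom cutoff |
| donor/acceptor elements | N, O, S | H-bond-capable chemistry |

Without hydrogens no angular criterion is possible, so hydrogen-bond
detection is distance + element chemistry only; this is reproducible and
matches heavy-atom practice, but it will occasionally accept a
geometrically impossible donor–acceptor pair that an explicit-hydrogen
analysis would reject. An atom pair that qualifies as a hydrogen bond is
*excluded* from the non-bonded contact list, so the two counts never
double-count a pair. Both detectors are verified against an exhaustive
$O(n^2)$ pair scan in the test suite.

`build_profile()` outer-joins the per-residue counts with the
$\Delta$ASA map (missing side filled with zero), and `key_residues()`
reports the argmax residues of the two columns separately, **including all
ties** — the buried-area maximum and the contact-count maximum are
different questions and are never merged into one score. For comparative
work, `common_residues()` intersects *interacting* residue sets, where
interacting means at least one contact or hydrogen bond; this is looser
than the 10 Å² rule on purpose, since published residue tables list
contact-making residues even when their buried area is small.

## Combinatorial library and drug-likeness

`enumerate_library()` splices R1/R2 fragment strings into a scaffold at
`[R1]`/`[R2]` markers and canonicalizes each product through openbabel.
Compound numbering is **R1-major**: compound
$(i - 1)\,|R2| + j$ pairs the $i$-th R1 with the $j$-th R2, so the
reference 9 × 5 layout yields compounds 1–45. "Systematic substitution"
admits either loop order; the choice is recorded in the output columns
(`r1_index`, `r2_index`) so the alternative ordering is a trivial
re-sort. The shipped scaffold and R1 fragments are documented synthetic
placeholders (`default_library_config()`); the five R2 groups are the
classic small substituents −OCH₃, −OH, −NH₂, −F, −Br. Fragments use ring
closure digit 9 so they cannot collide with scaffold ring numbering.

Descriptors (`compute_descriptors()`):

* molecular weight from standard atomic masses including implicit
  hydrogens (openbabel);
* H-bond donors = N/O bearing at least one hydrogen;
* H-bond acceptors = N + O count (the classic rule-of-five convention,
  deliberately not the pharmacophore-aware definition);
* rotatable bonds computed on the molecular graph by the stated rule —
  non-ring single bonds between heavy atoms each bearing a further heavy
  neighbour, amide C–N excluded — with ring membership from bridge
  detection, so the documented rule is exactly the computed one;
* logP by Wildman–Crippen atomic contributions (openbabel's model).
  logP models differ by several tenths between implementations; values
  from other predictors are not expected to match to the decimal.

`lipinski_evaluate()` applies **strict** `<` comparisons against
500 Da / 5 / 10 / 10 / 5. The classic formulation is "no more than"
(`<=`); the strict form is used here, the boundary behaviour is tested
(a molecular weight of exactly 500 fails), and the difference only
matters for values exactly at a limit.

## Screening, consensus and enrichment

Dock scores are ranked ascending (more negative = better) with ties broken
by compound id for determinism. `consensus_topk()` intersects the top-$k$
lists of each target ($k = 20$ default) and orders the intersection by
mean rank; intersections are provably nested in $k$, and a $k$ beyond the
library size clamps with a warning.

`energy_to_pkd()` converts binding free energy with
$pK_d = -\Delta G / (\ln 10 \cdot R \cdot T)$, $R = 1.9872 \times
10^{-3}$ kcal/mol/K, $T = 298$ K (denominator 1.3638 kcal/mol). Reported
values round to two decimals; round-tripping tabulated pairs can disagree
by ±0.01 from upstream rounding, so comparisons use a ±0.015 band.

The enrichment factor at fraction $f$ is
$$\mathrm{EF} = \frac{\mathrm{Hits}_{sample}/N_{sample}}
                     {\mathrm{Hits}_{database}/N_{database}},
\qquad N_{sample} = \lfloor f \cdot N_{database} \rfloor .$$
The floor convention makes 20% of 606 compounds a 121-compound subset.
Consequences worth stating explicitly: the expectation under uniformly
random ranking is exactly 1; and with 6 actives among 606 the *maximum*
achievable EF at the 20% level is $(6/121)/(6/606) \approx 5.01$ — the
formula's ceiling at fraction $f$ is $\min(1/f, N/\mathrm{Hits})$-bounded,
not $1/f = 5$ exactly, because of the floor. EF values above this ceiling
cannot arise from this formula at this composition, whatever the screen's
quality. `enrichment_curve()` reports cumulative recovery and is the
better tool when single-number EF is ambiguous.

## The synthetic-data generator

`make_pocket_complex()` builds toy complexes in which every detectable
feature is planted by construction:

* residues are alanine-like heavy-atom templates (serine-like, with an OG
  oxygen, where a hydrogen-bond partner is needed), spaced ≥ 15 Å apart on
  a ring so that no unplanned cross pair can enter any detection window;
* planted contacts are ligand carbons placed at exact distances from a
  residue's CB on outward rays; planted hydrogen bonds are ligand N/O
  placed off the OG; planted burial is a cap of carbons at 2.6 Å —
  *below* the 2.9 Å contact window — which buries surface without
  registering a single contact;
* after placement the generator audits every protein–ligand pair and
  refuses specs in which any unplanned pair falls inside (or within
  0.05 Å of) a window;
* construction is fully deterministic: the same spec yields byte-identical
  PDB output.

`make_score_table()` draws decoy scores from
$\mathcal{N}(\mu, \sigma)$ and active scores from
$\mathcal{N}(\mu + \delta, \sigma)$; only rank order reaches the
enrichment statistics, so the Gaussian is a convenience, not a model of
dock-score physics. The default layout — 6 actives, 100 decoys per active,
606 compounds — is the standard decoy protocol at the reference
composition.

**What passing these benchmarks shows, and what it does not.** The planted
pockets prove the geometric code: detection equals ground truth, area loss
is non-negative, oracles agree. They do not emulate real binding sites —
no realistic side-chain packing or rotamers, no crowded pockets where
contact windows overlap between residues, no hydrogens, planar residue
placement. Likewise the Gaussian score tables validate the enrichment
arithmetic, not docking accuracy. Conclusions about real systems inherit
the quality of the upstream docking, not of these tests.

## Problem sizes and reproducibility

The shipped test suite runs the surface oracle on clusters of ≤ 20 atoms
at $10^5$ Monte-Carlo samples per atom, pair-detection oracles on pockets
of 3–7 residues over dozens of seeds, enrichment nulls at 606 compounds
over $10^3$–$10^4$ permutations, and full-pipeline determinism checks;
these sizes give stable statistics at interactive runtimes. All
randomness is seeded; every generator is reproducible from its spec alone.

## Known limitations

* No polar/apolar ASA split and no relative (percent) accessibility.
* No angular hydrogen-bond term and no π-stacking/aromatic detection.
* Rigid ΔASA: induced fit is invisible to the profile.
* SMILES splicing validates products chemically (parse + canonicalize)
  but cannot verify that a placeholder scaffold matches any particular
  published structure drawn only as an image.
* mmCIF, biological assemblies and structure preparation (protonation,
  minimization) are out of scope; inputs are taken as docked.
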