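---
title: "Nucleation-core contact analysis and strain classification for tau fibrils"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleation-core contact analysis and strain classification for tau fibrils}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taucore)
```

## The scientific problem

Aggregation of the microtubule-associated protein tau into amyloid fibrils
underlies Alzheimer's disease and the rarer tauopathies (Pick's disease,
progressive supranuclear palsy, corticobasal degeneration, and others). Two
hexapeptide motifs in the microtubule-binding repeats act as aggregation
nucleation cores: PHF6* (`VQIINK`, residues 275–280, the start of repeat R2)
and PHF6 (`VQIVYK`, residues 306–311, the start of repeat R3), in 2N4R
numbering. Three observations organise everything this package computes:

1. **An intact hexamer is necessary and sufficient.** Truncation constructs
   that retain either full hexamer aggregate in thioflavin-T (ThT) assays;
   constructs carrying only the trimeric consensus `VQI` do not.
2. **Cryo-EM protomer folds split into two strain classes.** In the folds of
   AD, CTE and Pick's disease only VQIVYK is ordered (single-core strains);
   in CBD, AGD, PSP, GGT and GPT both hexamers are ordered (dual-core
   strains).
3. **The structural environment of the hexamers explains both.** Under
   heavy-atom distance criteria — hydrogen bonds up to 3.3 Å, hydrophobic
   contacts up to 5.0 Å — the `VYK` suffix of VQIVYK makes several
   intra-molecular interactions with its spatial neighbours in every fold,
   while the `INK` suffix of VQIINK makes very few. Removing either suffix
   (conceptually, truncating to `VQI`) removes those interactions, which is
   why the consensus trimer cannot nucleate, and why VQIVYK ranks as the
   primary core.

## The contact model

All contact analysis is intra-protomer: one chain, one model, one alternate
conformer (`'A'`/blank), hydrogens excluded. Typing is a pure function of
`(residue, atom)` against fixed templates (`atom_templates()`):

* backbone N is a donor (not in proline), backbone O and OXT acceptors;
* sidechain donors/acceptors follow standard chemistry (TYR OH both, LYS NZ
  donor, ASP OD1/OD2 acceptors, HIS ND1/NE2 both, ...);
* an *apolar carbon* is a carbon not covalently bonded to N or O in the
  residue template — so CA and C are never apolar, and the TYR ring counts
  CG–CE2 but not CZ (bonded to OH);
* CYS SG and MET SD are treated as weakly donor/acceptor-capable by default
  (`contact_params(include_sulfur = FALSE)` switches this off).

A pair is a **hydrogen bond** iff one atom is donor-capable, the other
acceptor-capable, and the distance is ≤ 3.3 Å; a **hydrophobic contact** iff
both atoms are apolar carbons within 5.0 Å. Ties at exactly the cutoff are
included ("in maximum" criteria). The classes are disjoint at the atom
level, so no pair is double-counted; a polar pair between 3.3 and 5.0 Å is
*not* hydrophobic — type is decided by atom class, not by distance alone.
The criterion is distance-only, with no donor–H–acceptor angle: cryo-EM
depositions carry no hydrogens, and a pure length limit keeps the rule
auditable.

Two defaults shape the reported tables and are deliberate choices:

* `min_seq_separation = 3` suppresses the i±1/i±2 proximities forced by
  chain connectivity, which would otherwise swamp the tables; set 0 to
  audit.
* backbone–backbone pairs are excluded by default: the cross-β backbone
  ladder is ubiquitous in any fibril and carries no information about
  sidechain packing, which is what distinguishes folds.

The engine (`find_contacts()`) uses a cell-list spatial index with cell edge
equal to the hydrophobic cutoff; `brute_force_contacts()` is an independent
exhaustive all-pairs implementation kept solely as the oracle, and the test
suite asserts exact equality between the two on randomized fixtures.

## Synthetic fixtures: what they do and do not show

Every stage is testable offline through `make_contact_fixture()`: residues
are laid on a coarse 1D grid (spacing `2 * (decoy_min_distance + max
planted distance)`) with small per-residue jitter, and each planted atom
pair is placed analytically on a parallel planting row, one lattice site
per pair. This guarantees, by construction and by an a-posteriori all-pairs
check, that (a) planted distances are exact to well below 1e-6 Å and (b)
every other inter-residue atom pair is farther than `decoy_min_distance`
(default 8 Å). `make_minifibril()` stacks exact copies of a protomer along
z at a 4.7 Å rise — the canonical cross-β spacing — so inter-layer
equivalent-atom distances are exactly one rise.

These fixtures make the *rules* fully checkable: cutoff gating, typing,
exclusions, aggregation, loss reporting. They are deliberately not
physically realistic — no covalent geometry, no rotamers, no packing — so a
passing suite certifies the bookkeeping, not any structural biology of a
real deposition.

The eight-fold library (`synthetic_fold_protomer()`) extends this to the
strain analysis. Because the deposited coordinate sets are not bundled with
the package, each fold is represented by a synthetic stand-in encoding two
documented facts: the approximate modeled residue range of one protomer
chain (which alone determines hexamer resolution and hence the strain
class — e.g. the AD fold models 306–378, so VQIINK cannot be ordered; the
Pick fold is 3R tau, so its numbering jumps 274→306), and the published
suffix-truncation interaction pairs, planted at plausible hydrogen-bond
(2.8–3.2 Å) and hydrophobic (4.0–4.6 Å) distances. Classification results
on the library therefore reproduce the published two-class split by
construction of the *ranges*, and the loss reports recover the published
*pairs*; coordinate-level agreement with the real depositions is neither
claimed nor checkable here. Running `run_classify()` on the actual PDB/mmCIF
files (5O3L, 6NWP, 6GX5, 6TJO, 7P6D, 7P65, 7P66, 7P6A) is supported through
`read_structure()` whenever those files are available locally.

A caveat recorded in the open literature-facing outputs: published
per-fold interaction lists may be curated rather than exhaustive under the
stated cutoffs, so the package asserts *inclusion* of the named pairs, not
equality of full tables.

## Construct design

Constructs are sets of retained 1-based closed intervals on the 441-residue
2N4R template (packaged, UniProt P10636-8), optionally with an appended
motif. The default domain map places N1 at 45–73, N2 at 74–102, the
proline-rich region at 151–243, and R1–R4 at 244–274 / 275–305 / 306–336 /
337–368; it is validated against the template (R2 must begin `VQIINK`, R3
`VQIVYK`) and fully overridable via JSON, because the construct endpoints
of the original truncation series are not recoverable from domain names
alone. Purification tags are never appended: tags are plumbing, not motif
logic.

* **Isoforms** (`build_isoforms()`): all {0N,1N,2N} × {3R,4R} combinations;
  the six lengths come out at the canonical 352–441 residues.
* **Truncation series** (`build_truncation_series()`): the N-series cuts at
  successive domain starts (8 constructs), the C-series at successive domain
  ends working inward (5 constructs). Under the default map the C-series
  reproduces the observed amyloidogenicity flip between C3 (retains R2,
  aggregates) and C4 (ends at R1, does not).
* **Extensions** (`build_extension_constructs()`): C6 = C4 + `VQIINK`,
  C8 = C4 + `VQI` (both on the 2N4R parent, where R2 directly joins R1),
  and C7 on the 2N3R parent, where `VQIVYK` of R3 directly joins R1,
  truncated right after the hexamer.
* **Rule** (`predict_amyloidogenic()`): positive iff the sequence contains
  `VQIVYK` or `VQIINK` contiguously. The rule agrees with the encoded assay
  outcomes for all C-series, extension, and isoform records.

One known discrepancy is surfaced rather than hidden: under the default
map the N7 construct starts at 306 and so retains PHF6, predicting
positive, while the reported N7 outcome is negative — the real N-series
endpoints evidently differ from the bare domain starts. N-series
predictions are therefore flagged (`note` column) and never asserted
against observed outcomes.

## Kinetics

`simulate_tht()` generates plate-reader-like curves: logistic
`baseline + A/(1 + exp(-k (t - t50)))` plus additive Gaussian noise for
aggregating samples, flat baseline plus noise otherwise. Gaussian additive
noise is the simplest model consistent with ThT readouts; defaults
(A = 100 a.u., baseline = 10 a.u., t50 = 20 h, k = 0.5 /h, noise 2 a.u.,
80 h, 200 points) sit in the typical 40–80 h plateau window of
heparin-induced tau aggregation. The logistic (rather than, say,
Finke–Watzky) is a documented stand-in: the minimal sigmoid with an
interpretable half-time.

`fit_logistic()` is deterministic: Levenberg–Marquardt least squares with
initialisation at the first-decile baseline, observed range amplitude,
first half-range crossing for t50, and k = 1 /h; a constant model is fit
alongside, and non-convergence falls back to the flat model with a flag.
`call_aggregation()` declares a positive iff amplitude ≥ 3 × baseline *and*
the logistic residual sum of squares is ≤ 0.5 × the flat model's — both
thresholds are explicit parameters, since the underlying judgement
("signal plateaued well above background") is qualitative. At the default
noise level the simulation study in the test suite (100 positive + 100
flat curves) recovers t50 to well under an hour on average with
sensitivity and specificity of 1.

## Numerical choices and degenerate inputs

* Distances are Euclidean on heavy atoms; contact ties at the cutoff are
  *included*.
* Fixture construction fails loudly ("infeasible geometry") if a request
  cannot be realised — e.g. one atom in two planted pairs — rather than
  silently adjusting.
* `fit_logistic()` requires ≥ 10 points and strictly increasing time;
  noiseless flat curves give a zero-variance flat model and a negative
  call.
* Core ranking breaks ties alphabetically by motif name and flags them
  (`tied`), so a tie is never silently resolved.
* All generators restore the session RNG state; reproducibility comes from
  explicit seeds, never from global side effects.

## Problem sizes used in the checks

The randomized engine-vs-oracle comparison uses 50 fixtures of 10–200
residues (up to ~1,600 heavy atoms each); the kinetics study uses 100
aggregating plus 100 flat curves of 200 points. These sizes give exact
(engine equality) or tight (t50 error) checks in a few tens of seconds on
one core.

## Limitations

* The stand-in fold library encodes documented ranges and pairs, not
  structures; any claim that depends on real packing geometry (distances,
  completeness of neighbour lists, fold-shape similarity) requires the
  actual depositions.
* No energetics: "losing interactions destabilises the fold" is
  represented as counting, not as a free-energy estimate.
* No π-stacking, salt-bridge or cation-π typing; no solvent accessibility;
  no inter-protomer stacking contacts in the default report.
* The amyloidogenicity rule is a sequence rule; it deliberately ignores
  context effects (inhibitory flanking regions, PTMs) that real constructs
  may exhibit.

## A worked pass through the pipeline

```{r pipeline, eval = FALSE}
library(taucore)

# strain classification over the synthetic fold library
structs <- sapply(fold_names(), function(f) list(synthetic_fold_protomer(f)))
rep <- run_classify(structs)
rep$summary[, c("id", "label", "n_pairs_PHF6", "n_pairs_PHF6s", "primary_core")]

# construct catalogue
tab <- run_constructs()
table(tab$series)
tab[tab$name %in% c("C3", "C4", "C6", "C7", "C8"),
    c("name", "length", "predicted_amyloidogenic", "observed_amyloidogenic")]

# one simulated ThT curve, fitted and called
fit_logistic(simulate_tht(tht_sim_params(seed = 7)))
```
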