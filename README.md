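# hingeShear

Quantitative assignment of **hinge** and **shear** mechanisms to protein
domain movements from changes in interdomain residue contacts.

## The problem

When a two-domain protein is solved in two conformations, the movement of one
domain relative to the other has traditionally been labelled *hinge*
(domains rotate about a localized backbone hinge, creating a new interface)
or *shear* (domains slide along a preserved interface) by visual inspection —
a subjective call that does not scale to the tens of thousands of
conformational pairs now implied by the PDB. `hingeShear` implements an
objective, computable assignment intended for structural biologists analysing
DynDom-style domain decompositions.

## The method

Two residues are in contact when any heavy atom of one is within 4 Å of any
heavy atom of the other. For each conformation the interdomain contact pairs
are collected, after excluding bending-region residues and residues with a
heavy atom within 5.5 Å of the interdomain screw axis. The two contact sets
form a directed bipartite **dynamic contact graph** (DCG): an edge A→B for a
contact in conformation 1, B→A for conformation 2. The DCG decomposes into
four elemental contact changes, counted as
**N** = (N_maint, N_exchpart, N_exchpair, N_new):

* **maintained** — the same pair in contact in both conformations;
* **exchanged-partner** — one residue swaps partners (the sliding signature);
* **exchanged-pair** — disjoint pairs swap between conformations;
* **new** — a contact present in only one conformation.

Maintained contacts are extracted first; remaining forward/backward edges are
matched by an exact maximum-cardinality bipartite matching to maximize
exchanged-partner elements, then exchanged-pair, with the residue new.
The packaged logistic model maps **N** to a prediction value

    y(N) = 1 / (1 + exp(α)),
    α = −0.2387·N_maint − 0.0356·N_exchpart + 0.4249·N_exchpair
        + 0.2122·N_new + 0.1467

with classes **hinge** (0 ≤ y ≤ 0.45), **mixed** (0.45 < y < 0.55),
**shear** (0.55 ≤ y ≤ 1) and **no-contact** (N = 0). The package also
provides screw-axis annotation (axis outside the protein, mechanical hinges,
effective hinge axis, pitch, closure vs. twist), training/ROC/LOOCV/precision
machinery for refitting the model on labelled data, pooled two-proportion
z-tests for comparing hinge and shear populations, and deterministic
synthetic fixture generators.

## Worked example

Generate a synthetic 30° hinge-opening movement and classify it:

```r
library(hingeShear)

fix   <- makeMotionFixture("hinge", seed = 1)
paths <- writeFixture(fix, "fix")
res   <- runClassify(paths["conf1"], paths["conf2"],
                     paths["domains"], paths["axis"], outDir = "out")
#> parsed: 52 residues (conf1), 52 residues (conf2)
#> excluded residues (conf1 frame): 12
#> contacts: 20 (conf1), 0 (conf2)
#> N = (0, 0, 0, 20)
#> prediction value y = 0.01224; class = hinge
```

Twenty contacts exist in the closed conformation and none after opening, so
all twenty decompose as *new* contact changes; y = 0.012 is deep in the hinge
region. The axis report (`out/axis_analysis.txt`) shows the screw axis runs
through the protein and threads a bending region:

```
axis_outside_protein false
n_mechanical_hinges 1
effective_hinge_axis true
pitch_A_per_deg 0
motion_type closure
```

Evaluating the model on the citrate synthase count vector N = (10, 2, 2, 6)
gives y = 0.547 — printed as 0.55, and mixed because the exact value is below
the 0.55 shear boundary:

```r
predictMotion(c(10, 2, 2, 6))
#> [1] 0.546986
classifyMotion(c(10, 2, 2, 6))$class
#> [1] mixed
```

Comparing the rates of axes outside the protein body between 361 shear
(5 cases) and 884 hinge (9 cases) examples:

```r
z <- twoProportionZ(5, 361, 9, 884)
round(z$z, 2); round(z$pPercent, 1)
#> [1] 0.56
#> [1] 28.9
```

— no significant excess in the shear set, i.e. shear movements are not
translation-dominated.

A shell front end with `classify`, `train`, `simulate`, `dcg` and `stats`
subcommands ships in `inst/scripts/hingeshear`.

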