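# protomeR

Gas-phase charge-state prediction for ion-mobility mass spectrometry
(IM-MS).

When a small molecule is electrosprayed as `[M+H]+` or `[M-H]-`, the
proton can sit on any of several nitrogen or oxygen atoms, and the
resulting protomers/deprotomers have different gas-phase geometries and
collision cross sections. Resolving an IM-MS measurement against a 3D
structure therefore requires knowing *which* site carries the charge at
equilibrium — classically an expensive enumerate-everything-then-DFT
exercise, since titratable sites grow roughly linearly with molecular
size. protomeR implements a fast two-pass screen of the enumerated charge
sites for people who need a ranked, thermodynamically weighted shortlist
of charge-state models before committing to quantum-chemistry refinement.

## Method

For an input molecule (SMILES or XYZ) and an ion mode, the pipeline:

1. **Enumerates titratable sites** — every N/O that can accept a proton
   (`[M+H]+`) or give one up (`[M-H]-`), with graph-symmetric duplicates
   collapsed — and builds one charged model *Z* per site.
2. **Featurizes** each model with 10 rigid-motion-invariant descriptors:
   the charge-bearing atom's (CBA) polarizability; the distances
   CBA–COM, CBA–COE and COM–COE, where COE is the *center of
   electronegativity*

   COE = Σᵢ eᵢ rᵢ / E,  E = Σᵢ eᵢ

   (Pauling electronegativities eᵢ, atom positions rᵢ); the interaction
   angle at the COE between COM and CBA; a Shrake–Rupley molecular
   surface area; and the O, N, halogen and "othergen" (S/P/Se) counts.
3. **Ranks** the models (initial rank *r*) with a gradient-boosted-tree
   regressor trained on relative-energy (RE) labels, then prunes the
   list with the acceptance capacity

   ∧ = (1/3) · (RMSE + RE_min) / (σ + S),

   where RMSE is the regressor's held-out error and σ, S are the
   standard deviation and variance of the predicted REs; the top
   ⌈∧⌉ models advance (rank 1 always survives).
4. **Refines** the survivors with a short (50-step) "soft" geometry
   optimization under a pluggable potential backend. Elements outside
   the backend's supported set are temporarily swapped for surrogates
   (Br/I→Cl, P/Se→S) and restored afterwards.
5. **Reranks** on refined relative energies (final Rank *R*; Rank 1 is
   the assigned equilibrium charge state) and reports Boltzmann mole
   fractions xᵢ = exp(−REᵢ/RT)/Σⱼ exp(−REⱼ/RT) at 298.15 K.

Output is a `completed/<molecule>/` directory holding one XYZ per
forwarded model plus a human-readable job summary and a JSON sidecar.

## Worked example

```r
library(protomeR)

tab    <- synthetic_training_table(synthetic_spec(seed = 1))
ranker <- train_ranker(tab, seed = 1)
cfg    <- pipeline_config("[M+H]+", ranker = ranker, backend = "toy",
                          output_root = "out", seed = 1)
run_pipeline(toy_library()$glycine, cfg)
```

```
<job_report> glycine [M+H]+: 3 site(s) enumerated, 3 forwarded (capacity 13.653)
     model_id cba_element cba_index initial_rank_r final_rank_R predicted_re
 glycine_cba4           O         4              3            1     2.356793
 glycine_cba5           O         5              2            2     2.328798
 glycine_cba1           N         1              1            3     2.053288
 refined_re mole_fraction
   0.000000      0.333397
   0.000167      0.333303
   0.000174      0.333299
```

Glycine has three protonation sites (amine N, carbonyl O, hydroxyl O).
The GBT pass predicts each model's RE (kcal/mol) and ranks them
(`initial_rank_r`); the acceptance capacity here forwards all three.
After the soft optimization under the classical toy backend the refined
REs are nearly degenerate, so the final ranking (`final_rank_R`)
reshuffles and the Boltzmann mole fractions split almost evenly — with a
physically parametrized backend the spread, and hence the fractions,
become decisive. Three XYZ files and the two report files appear under
`out/completed/glycine/`.

A command-line front end with `run`, `train`, `mir` and `synth`
subcommands is installed at `inst/cli/protomer`.

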