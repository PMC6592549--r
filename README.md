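# modelrank

Ligand-guided ranking of GPCR homology-model ensembles.

## The problem

Aminergic G-protein coupled receptors (histamine, dopamine, serotonin,
muscarinic receptors, ...) bind their ligands through a hallmark salt bridge:
a positively charged amine of the ligand contacts the conserved aspartate at
Ballesteros–Weinstein position 3.32. When no crystal structure exists and a
homology-modelling run produces a large ensemble of candidate receptor models
(typically 1000), that one reliable interaction can be used to rank them —
without trusting docking scores, which correlate poorly with affinity.

`modelrank` is for structural bioinformaticians running ligand-guided
homology-model selection: it scores each model by the fraction of docked
ligand poses that can form the charged contact, ranks the ensemble, and then
localizes *which side-chain conformations* distinguish the best models from
the worst.

## The method

For a model with *n* docked poses (the reference protocol uses 9 ligands ×
10 poses, docked twice), the per-run score is

    s = (1/n) · #{ poses with  d(C_carboxyl(D3.32), cation) ≤ 6 Å }

measured from the carboxyl **carbon** (CG of Asp, CD of Glu) to the nearest
formally cationic ligand atom; the 6 Å boundary is inclusive. A model's
aggregate score is the mean of its replicate-run fractions; ranking is
descending with deterministic tie-breaks (smaller run discrepancy, then model
id). The 10 best and 10 worst models are then superposed onto the pooled
ensemble mean (backbone heavy-atom Kabsch fit) and the per-atom distance
between group mean positions is reported, sorted — the top entries nominate
the discriminating side chains. Ensemble flexibility is summarized as
RMSD-to-mean decomposed exactly into backbone and side-chain contributions:
n_all·RMSD²_all = n_bb·RMSD²_bb + n_sc·RMSD²_sc.

A ChEMBL-style curation pipeline (MW ≤ 500 Da, confidence 9, Ki/Kd/IC50/EC50,
relation "=", ≤ 10 nM, clear stereochemistry; binding-over-functional,
newer-over-older deduplication), Tanimoto/MaxMin diversity picking, and
Cheng–Prusoff utilities (Ki = IC50/(1 + L/Kd), pKi) cover the ligand-data
side of the workflow. A synthetic fixture generator emulates the modelling
and docking outputs with fully known ground truth, so the whole method runs
and is testable without external engines or databases.

## Worked example

Generate a synthetic 50-model study, score, rank and analyze it in memory:

```r
library(modelrank)

cfg <- fixture_config(n_models = 50, seed = 7)
ens <- make_receptor_ensemble(cfg)          # models + BW map + ground truth
sets <- make_pose_sets(cfg, ens)            # 100 pose sets, 90 poses each

long <- score_models(ens$models, sets, ens$bwmap)
ranked <- rank_models(long)
print(ranked, n = 3)
#> Model score table: 50 models, 2 run(s)
#>   top score 0.8333 (model_0005), median 0.4278, 1 model(s) at 0
#>     model_id score_run1 score_run2 aggregate discrepancy    pooled rank
#> 1 model_0005  0.8333333  0.8333333 0.8333333           0 0.8333333    1
#> 2 model_0015  0.8111111  0.8111111 0.8111111           0 0.8111111    2
#> 3 model_0029  0.8111111  0.8111111 0.8111111           0 0.8111111    3
#>   ... 47 more rows
```

The top model allows the charged contact in 83.3% of its poses (75 of 90 in
each run). Now compare the 10 best against the 10 worst models:

```r
ext <- select_extremes(ranked, k = 10)
rep <- group_mean_difference(ens$models[ext$best], ens$models[ext$worst])
rep <- annotate_report(rep, ens$bwmap, ens$site)
print(rep, n = 3)
#> Group mean-position differences (sidechain atoms), groups 10 vs 10:
#>   atom resname resno chain    subset delta residue_max_delta bw_label in_site
#> 1  OE2     GLU   206     A sidechain  4.82              4.82     5.46    TRUE
#> 2  CD2     LEU   401     A sidechain  1.99              1.99     7.42   FALSE
#> 3  CG2     VAL   113     A sidechain  1.55              1.55     3.31   FALSE
#>   ... 117 more atoms
```

The atom separating good from bad models the most is the carboxyl oxygen of
the glutamate at 5.46 (4.8 Å between group means here — the generator plants
a 4.7 Å flip of that side chain in low-scoring models), followed by a distal
carbon of the leucine at 7.42. Ensemble flexibility:

```r
ensemble_rmsd(unname(ens$models))
#> Ensemble of 50 models, average RMSD to reference (Angstrom):
#>   all heavy 1.17 | backbone 0.39 | sidechain 1.58
```

Side chains are four times as variable as the backbone, as expected for a
template-driven model ensemble.

## Command line

The same workflow over files (PDB models, SDF pose sets, TSV manifest):

```sh
inst/cli/modelrank fixtures --out study/ --n_models 1000 --seed 1
inst/cli/modelrank rank --manifest study/manifest.tsv --bwmap study/bwmap.tsv \
    --site study/site.yaml --out study/rank_out --k 10
inst/cli/modelrank diff --best id1,...,id10 --worst id991,...,id1000 \
    --models_dir study/models --bwmap study/bwmap.tsv --out study/diff_out
```

Subcommands: `fixtures`, `contacts`, `rank`, `diff`, `rmsd`, `curate`,
`pick`. All outputs embed the tool version, seed and a config hash; reruns
with the same seed are byte-identical.

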