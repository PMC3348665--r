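# prmt

Predicted Relative Metabolomic Turnover (PRMT) from metagenomic
enzyme-function annotations.

## What it does

Shotgun metagenomes can be annotated against enzyme function (EC) numbers,
giving per-sample counts of reads assigned to each enzyme function. Those
counts are a proxy for the community's capacity to catalyze each reaction.
`prmt` turns a set of such count profiles into per-metabolite scores that
predict, for every sample, whether the community's capacity to **consume**
or **produce** each metabolite is elevated or depressed relative to a
reference community (by default, the average across samples). The scores are
*relative* predictions of flux direction between communities — not absolute
concentrations and not a stoichiometric flux balance.

The pipeline:

1. **Reaction catalog** (`read_reaction_table`) — parse a reaction table
   (a generic TSV dialect or a KEGG-REACTION-style flat file) into a catalog
   of (reaction, enzyme function) pairs with substrate/product metabolite
   sets. Stoichiometric coefficients are deliberately discarded; only
   metabolite identity matters. Catalogs can be restricted to allowed
   pathways (`filter_by_pathways`) and stripped of currency metabolites
   (`apply_metabolite_blacklist`; a default blacklist of water, protons,
   nucleotide cofactors, NAD(P)(H), FAD and CoA ships with the package).
2. **Environmental Metabolome Matrix** (`build_connectivity`,
   `normalize_emm`) — expand reversible reactions into both directions,
   count signed (production − consumption) links per metabolite × enzyme
   cell, then normalize each metabolite row so positive entries sum to +1
   and negative entries to −1. Because a reversible reaction contributes
   both +1 and −1 to the same cell, a fully reversible enzyme cancels to a
   zero column: PRMT scores are *exactly* invariant to its abundance.
3. **Scoring** (`compute_eac`, `quantile_normalize`, `prmt_scores`) —
   transform counts to enzyme activity counts (default `log2(count + 1)`),
   quantile-normalize across samples so every sample shares one value
   distribution, and score each metabolite as
   `PRMT = -(M %*% (nEAC_sample - nEAC_reference))`. With the default
   consumption-positive convention a positive score means relatively more
   consumption capacity in that sample.
4. **Correlation analysis** (`correlate_sets`, `build_null`,
   `classify_strong`, `joint_band_probability`,
   `extract_correlated_subnetworks`) — Pearson-correlate PRMT scores with
   log relative abundances of measured parameters (environmental
   metabolites, taxa, subsystems), call a correlation "strong" when it
   falls outside the inclusive 5th–95th percentile band of a resampling
   null (random series pairs × random sample-order permutations; default
   10,000 iterations), estimate how probable a set of correlations in a
   band is under a normal fit to the null, and pull out the connected
   metabolic subnetworks whose metabolites all track a given taxon.
5. **I/O and CLI** (`prmt_cli`, `export_network`) — TSV readers/writers
   with provenance headers, Cytoscape-ready SIF/GraphML export, YAML
   configuration, and a `simulate / build-emm / score / correlate /
   subnetworks / export` command-line pipeline (thin wrapper in
   `inst/scripts/prmt`).
6. **Synthetic fixtures** (`fixture_spec`, `generate_catalog`,
   `generate_counts`, `generate_parameters`) — seeded generators that
   produce realistic count tables (per-enzyme lognormal baselines,
   per-sample depth factors, Poisson sampling) with *planted*
   consumption/production signals and parameter links, so every stage of
   the pipeline can be validated against a known ground truth.

## Worked example

Five glycolysis steps; `2.7.1.1`/`2.7.1.2` both consume glucose (C00031)
and produce G6P (C00092), `5.3.1.9` and `4.1.2.13` are reversible:

```r
library(prmt)
lines <- c(
  "reaction_id\tenzyme_id\tdirection\tsubstrates\tproducts\tpathway_ids",
  "R00299\t2.7.1.2\t=>\tC00031\tC00092\tmap00010",
  "R01786\t2.7.1.1\t=>\tC00031\tC00092\tmap00010",
  "R02740\t5.3.1.9\t<=>\tC00092\tC05345\tmap00010",
  "R00756\t2.7.1.11\t=>\tC05345\tC05378\tmap00010",
  "R01068\t4.1.2.13\t<=>\tC05378\tC00111;C00118\tmap00010")
f <- tempfile(); writeLines(lines, f)
catalog <- read_reaction_table(f)
catalog
#> reaction_catalog: 5 reactions (2 reversible), 5 enzyme functions, 6 metabolites

M <- normalize_emm(build_connectivity(expand_directions(catalog)))
round(unclass(M), 3)
#>        2.7.1.1 2.7.1.11 2.7.1.2 4.1.2.13 5.3.1.9
#> C00031    -0.5        0    -0.5        0       0
#> C00092     0.5        0     0.5        0       0
#> C00111     0.0        0     0.0        0       0
#> C00118     0.0        0     0.0        0       0
#> C05345     0.0       -1     0.0        0       0
#> C05378     0.0        1     0.0        0       0
```

Note the all-zero columns for the two reversible enzymes — their forward and
reverse contributions cancel, so their read counts can never move a score.
Now score three samples' worth of EC read counts:

```r
counts <- matrix(
  c(12L, 40L,  7L,
     3L,  9L, 30L,
    25L, 22L, 24L,
     6L, 18L,  2L,
    14L, 13L, 15L), 5, 3, byrow = TRUE,
  dimnames = list(c("2.7.1.2", "2.7.1.1", "5.3.1.9", "2.7.1.11", "4.1.2.13"),
                  c("site1", "site2", "site3")))
prmt <- prmt_scores(M, quantile_normalize(compute_eac(counts)))
round(unclass(prmt), 3)
#>         site1  site2  site3
#> C00031 -0.491  0.020  0.471
#> C00092  0.491 -0.020 -0.471
#> C00111  0.000  0.000  0.000
#> C00118  0.000  0.000  0.000
#> C05345  0.042  0.819 -0.861
#> C05378 -0.042 -0.819  0.861
```

Reading site3: hexokinase counts are highest there, so the community is
predicted to consume relatively more glucose (C00031 = +0.471,
consumption-positive) and accumulate capacity pressure toward G6P
(C00092 = −0.471, i.e. relatively more production). Mean-referenced scores
sum to zero across samples by construction.

Downstream, correlate scores against measured parameters:

```r
obs  <- correlate_sets(unclass(prmt), logrel_params)     # Pearson r per pair
null <- build_null(unclass(prmt), logrel_params,
                   iterations = 10000, seed = 1)
classify_strong(obs, null)                                # outside 5th-95th pct
```

## Command line

```sh
inst/scripts/prmt simulate  --seed 7 --out-dir sim/
inst/scripts/prmt build-emm --catalog sim/catalog.tsv --out-dir emm/
inst/scripts/prmt score     --emm emm/emm.tsv --counts sim/counts.tsv \
                            --out prmt_scores.tsv
inst/scripts/prmt correlate --prmt prmt_scores.tsv \
                            --parameters sim/parameters.tsv \
                            --iterations 10000 --seed 7 --out correlations.tsv
```

All outputs carry provenance headers (version, seed, config hash); pass
`--no-timestamp` for byte-identical reruns. Flags can also be supplied via
`--config config.yaml`.

## Testing

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "prmt", load_package = "installed")'
```

The suite is property-based: independent brute-force oracles, exhaustive
enumerations, planted-signal recovery, and round-trip identities rather
than golden files. See `vignettes/prmt-methods.Rmd` for the modeling
choices and their rationale.
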