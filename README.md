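# chemtriage

Tools for assembling diverse chemical collections for high-throughput
toxicity testing — for computational toxicologists and screening teams
who need to turn a long list of nominated chemicals into a purchasable,
dosable, mechanistically diverse panel, and to plan test concentrations
for it.

The package covers four connected pieces of machinery:

1. **Ionization-aware partitioning.** Henderson–Hasselbalch species
   fractions for up to diprotic acids/bases
   (`species_fractions()`), and ionization-corrected distribution ratios
   at a pH: air–water `D_aw = K_aw · f_neutral`, liposome–water
   `D_lip/w`, albumin–water `D_BSA/w`, and structural-protein–water
   `D_SP/w`, each a species-weighted sum of per-species constants
   predicted from log *K*<sub>ow</sub> through configurable linear maps.

2. **In vitro dosimetry.** A mass-balance model of serum-supplemented
   cell assays: the freely dissolved fraction

   *f*<sub>free</sub> = 1 / (1 + *D*<sub>medium/w</sub>·*V*<sub>protein+lipid</sub>/*V*<sub>medium</sub> + *D*<sub>cell/w</sub>·*V*<sub>cell</sub>/*V*<sub>medium</sub>)

   plus nominal and freely dissolved baseline cytotoxicity
   concentrations anchored to the critical membrane concentration of
   26 mmol/L lipid.

3. **Baseline-toxicity (narcosis) QSARs.** −log₁₀ EC = *a*·log
   *D*<sub>lip/w</sub> + *b* for five in vivo test systems
   (*C. elegans*, *D. magna*, *D. rerio*, *X. laevis*,
   *D. melanogaster*), de novo OLS fitting, and specificity-ratio
   classification (predicted baseline EC / experimental EC, cutoff 10)
   separating baseline from specific/reactive toxicants. ADME
   categories for intrinsic hepatic clearance and plasma unbound
   fraction.

4. **Staged triage.** A three-stage filter with full audit trail:
   physicochemical applicability (volatility *D*<sub>aw</sub> > 10⁻⁴,
   hydrophobicity log *D*<sub>lip/w</sub> > 4, stability), logistics
   (purity ≥ 98%, cost ≤ 1000 €, availability, restrictions, safety),
   and mechanism-of-action diversity (at most 1–2 chemicals per
   mechanism per toxicity group, priority to human-exposome and
   reference compounds). A seeded synthetic generator produces
   property-matched chemical pools and QSAR-consistent effect data so
   every stage runs offline.

## Worked example

```r
library(chemtriage)

pool <- generate_chemicals(synthetic_config(n = 500, seed = 42))
part <- compute_partitions(pool)                 # D_aw, D_lip/w, D_BSA/w, D_SP/w at pH 7.4
res  <- run_triage(pool, partitions = part,
                   config = triage_config(group_target_min = 0))
res
#> <triage_result: 500 in, 157 retained, 343 excluded>
#> # A tibble: 3 × 4
#>   stage             n_in n_excluded n_retained
#>   <chr>            <int>      <int>      <int>
#> 1 stage1_physchem    500        119        381
#> 2 stage2_logistics   381        112        269
#> 3 stage3_diversity   269        112        157
```

Stage 1 removed 119 of 500 synthetic nominees as volatile, too
hydrophobic, or unstable; logistics removed another 112; the diversity
stage capped mechanistic redundancy down to a 157-chemical panel.
`write_audit_report(res, "report.json")` stores every per-chemical
decision with all failed criteria.

Dosimetry for the same pool:

```r
avail <- assay_availability(part)   # default 10% FBS setup
head(avail, 3)
#> # A tibble: 3 × 4
#>   id           f_free ic10_nominal_mol_l ic10_free_mol_l
#>   <chr>         <dbl>              <dbl>           <dbl>
#> 1 7380926-31-1 0.0295          0.0000257     0.000000758
#> 2 1314572-07-0 0.941           0.00135       0.00127
#> 3 3023858-48-9 0.290           0.000584      0.000169
```

The first chemical (log *D*<sub>lip/w</sub> = 4.5) is 97% bound to
medium constituents, so its nominal baseline-cytotoxic dose (26 µmol/L)
is 34× its freely dissolved one — exactly the gap that makes nominal
dosing misleading for hydrophobic chemicals.

Baseline-toxicity prediction and specificity:

```r
m <- species_registry("D. rerio")
#> <qsar_model D. rerio [LC50_aqueous]: -log10(EC) = 0.99 * logDlip/w + 0.78>
predict_lc50(m, 2)
#> [1] 0.00174            # mol/L at log Dlip/w = 2
specificity_ratio(predicted_effect = 1e-3, experimental_effect = 1e-5)
#> SR = 100 -> specific/reactive
```

An experimental LC50 a hundredfold below the narcosis prediction flags
a specific or reactive mode of action.

## Package layout

| Path | Contents |
|---|---|
| `R/records.R`, `R/cas.R` | record model, CAS checksum, CSV/TSV I/O |
| `R/ionization.R`, `R/speciation.R` | pKa profiles, species fractions, `D_aw` |
| `R/partitioning.R` | partition maps, `D_lip/w`, `D_BSA/w`, `D_SP/w` |
| `R/invitro.R` | mass balance, `f_free`, IC10 nominal/free |
| `R/baseline_tox.R` | QSAR registry, prediction, fitting, specificity |
| `R/adme.R` | clearance and unbound-fraction categories |
| `R/triage.R`, `R/audit.R` | three-stage pipeline, JSON audit reports |
| `R/synthetic.R` | seeded chemical-pool and effect-data generators |
| `R/reporting.R` | category networks, collection summaries |
| `vignettes/chemtriage-methods.Rmd` | models, assumptions, design choices |
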