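# brachybed

Biologically effective dose (BED) calculations for multi-fraction
high-dose-rate balloon brachytherapy with strongly heterogeneous target dose
distributions — for medical physicists and radiobiology researchers studying
accelerated partial-breast irradiation and similar single-channel HDR
treatments.

## The problem and the model

A balloon applicator prescribes the fraction dose (typically 3.4 Gy × 10)
to the surface of a 1 cm expansion of the balloon. The dose inside that
1 cm target shell falls off roughly as the inverse square of the distance to
the source: more than 200 % of the prescription at the balloon surface, the
prescription itself only at the outer shell edge, and a cold region along
the catheter axis. The conventional BED,

    BED_C = n d (1 + d/(α/β)) − (ln 2) T / (α T_eff),

assumes every cell receives the prescribed d and cannot represent this.
`brachybed` implements the survival-averaged alternative: for a differential
DVH with bin doses d_i and fractional volumes v_i,

    BED_H = −(1/α) ln( Σ_i v_i exp[ −α n d_i (1 + d_i/(α/β)) ] ) − (ln 2) T / (α T_eff),

evaluated in the log domain (log-sum-exp), because per-bin exponents near
the balloon surface exceed the double-precision underflow threshold by an
order of magnitude. Per-fraction BEDs and their sum over delivered fractions
quantify the effect of interfraction changes of the applicator geometry
(constant case vs. interfraction variation case). A seeded synthetic-cohort
generator emulates balloon-like dose distributions, and a pipeline produces
per-patient comparison rows and cohort summary tables.

## Worked example

```r
library(brachybed)

scheme   <- fractionation_scheme(n_fractions = 10, fraction_dose = 3.4,
                                 elapsed_time = 5.5)
fibrosis <- default_endpoints()$fibrosis      # α/β = 2 Gy, late: no repopulation

bed_conventional(scheme, fibrosis)
#> BED [conventional, fibrosis]: 91.8 Gy (repopulation component 0.00 Gy)

# one synthetic patient: 4.6 cm balloon, prescription at the 1 cm expansion
geom <- balloon_geometry(balloon_radius = 2.3, excluded_volume_fraction = 0.05)
plan <- generate_fraction_ddvh(geom, perturbation_model(seed = 101),
                               patient_index = 1, fraction_index = 1)
plan
#> Differential DVH [p1_f1]: 566 bins of 0.01 Gy (per_fraction axis), 2.78..8.44 Gy, total 100.0000%

total <- rescale_dose_axis(plan, 10, "total_course")
c(mean = mean_dose(total), modal = modal_dose(total),
  at_rx_pct = fraction_in_range(total, 33.9, 34.1))
#>      mean     modal at_rx_pct
#> 45.886...  35.45     0.7995

bed_heterogeneous_cc(plan, scheme, fibrosis)
#> BED [heterogeneous_cc, fibrosis]: 85.4 Gy (repopulation component 0.00 Gy)

compare_h_c(plan, scheme, fibrosis, "patient01")[, c("bed_a", "bed_b", "rel_diff")]
#>   bed_a    bed_b  rel_diff
#> 1  91.8 85.35634 -7.019243
```

Reading: although the *mean* target dose (45.9 Gy) is well above the 34 Gy
prescription, the survival-averaged BED for a late endpoint (85.4 Gy) is
*lower* than the conventional 91.8 Gy — the small cold tail dominates the
survival average at α/β = 2 Gy. For acute endpoints (α/β = 8, 11 Gy) the
sign reverses and the conventional BED underestimates. Full-cohort studies
run with:

```r
co     <- generate_cohort(cohort_config(seed = 1))   # 19 patients × 10 fractions
report <- run_study(co, scheme, out_dir = "study_out")
```

A thin command-line front end over the same functions is installed at
`system.file("cli", "brachybed.R", package = "brachybed")` with subcommands
`bed`, `dvh-stats`, `simulate` and `compare`.

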