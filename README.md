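# pedidose

Internal dosimetry for the paediatric dynamic kidney test (⁹⁹ᵐTc-DTPA
renal scintigraphy). `pedidose` answers a question nuclear-medicine
physicists face when imaging children: **how much absorbed dose do the
kidneys and the gonads receive during a renogram, and how does that change
when one kidney's function is impaired?** Reference coefficients published
for this tracer give one number per organ for "normal" and "abnormal"
renal function, without distinguishing which kidney is impaired or by how
much; this package computes the doses mechanistically, per side and per
function level.

The pipeline:

1. **Phantom** — a stylized 5-year-old voxel phantom (2 mm voxels) with
   reference organ volumes, compositions and densities: kidneys, bladder
   (wall + urine), liver, lungs, heart, stomach, intestines, and testes or
   ovaries, inside a soft-tissue trunk.
2. **Biokinetics** — minute-by-minute source frames of the renogram:
   activity splits between the kidneys at t = 0 and transits to the
   bladder, completing at 20/f min for function level f (f = 1 is the
   nominal 20-min excretion; f = 0 retains).
3. **Transport** — photon Monte Carlo (Woodcock delta tracking,
   Klein–Nishina sampling by Kahn's method, kerma approximation, 10-keV
   cutoff) tallying per-organ energy deposition per decay with
   batch-means relative errors.
4. **Dosimetry** — the decay-weighted integral
   dose = Σₘ Aₘ · B₀ · R · k · ∫ₘ e^(−λt) dt with λ the ⁹⁹ᵐTc decay
   constant, R = 2.22 × 10⁹ decays per mCi-minute and
   k = 1.602 × 10⁻⁷ mGy per MeV/g, integrated to 100 min (normal) or
   1000 min (impaired), reported in mGy/mCi.
5. **Report** — left/right averaging, percent deviation from the ICRP
   reference coefficients, and function-level sweeps.

## Worked example

```r
library(pedidose)

ph  <- build_reference_phantom("male", voxel_mm = 2)
res <- run_scenario(ph, scenario(1, 1, sex = "male"),
                    histories_per_frame = 1e6, seed = 1)
subset(res$doses, organ %in% c("kidney_L", "kidney_R",
                               "testis_L", "testis_R"))
#>      organ  side T_min dose_mgy_per_mci rel_err
#> 3 testis_L  left   100            0.474 0.06117
#> 4 testis_R right   100            0.455 0.03888
#> 5 kidney_L  left   100            0.475 0.00321
#> 6 kidney_R right   100            0.480 0.00376

avg <- average_lr(0.475, 0.480)
pct_deviation(avg, icrp_reference()$normal[1])   # +17.3% vs the 0.407 reference
```

Under normal function both kidneys receive ≈0.47 mGy per mCi administered
(the reference coefficient is 0.407), and the testes — irradiated mostly
by the filling bladder above them — receive ≈0.45 mGy/mCi. A sweep over
degraded function levels (`sweep_scenarios()`) shows testis dose falling
monotonically as function degrades (less activity reaches the bladder),
and an impaired kidney accumulating far more dose than a normal one at
the 1000-min horizon.

A thin CLI mirroring these functions is installed at
`system.file("cli", "pedidose", package = "pedidose")`.

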