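# xylemtaper

Root-to-leaf scaling of xylem conduit dimensions and collapse safety.

## The problem

Water moves through trees under tension, pulled from soil to leaves through
a network of dead, hollow xylem conduits. Two physical constraints shape
conduit anatomy along that path:

1. **Hydraulic resistance.** A conduit of diameter *d* and length *l*
   resists flow as *r* = 128 *η l* / (*π d*⁴) (Hagen–Poiseuille), so total
   resistance depends steeply on how diameters vary along the path.
   Conduits widen from the leaf tip toward the base following an
   approximate power law *d* = *d*₀ *L*^*α*, where *L* is the distance from
   the leaf tip; competing optimization theories predict *α* between 0
   (uniform pipes) and ½. An analogous law *d* = *d*₀ *D*^*β* relates
   conduit diameter to the external diameter *D* of the stem or root that
   carries it.
2. **Wall collapse.** Sap tension loads conduit walls in bending. Treating
   the wall as a rectangular plate, collapse occurs when the squared
   thickness-to-span ratio (*t*/*b*)² falls below the critical value
   (*t*/*b*)²crit = *P β* / *σ*, where *P* is the local sap tension, *β* ≈
   0.25 the plate-bending coefficient and *σ* the modulus of rupture of
   green cell-wall material. Because tension is highest near the leaf tip,
   walls there must be proportionally more reinforced.

Estimating *α* and *β* from quantitative wood anatomy data has a
statistical catch: conduit counts per tissue section vary by orders of
magnitude along the path (one trunk core yields thousands of tracheids, a
leaf section a few dozen), so naive pooled regressions are dominated by a
few sampling positions. This package implements the bin-balanced
subsampling/bootstrap correction for that imbalance, the standardized major
axis (SMA) machinery used for allometric exponents, and a numerical
soil–plant–atmosphere model of the critical collapse limit — together with
a synthetic conduit-table generator with known exponents so the whole
pipeline is testable end to end.

It is aimed at plant hydraulics and quantitative wood anatomy researchers
working with conduit-level measurement tables (e.g. ROXAS-style output).

## What it computes

* **Anatomy metrics**: thickness-to-span ratio (t/b)² from four measured
  single walls (doubled minimum wall over the lumen span), Mork's index
  *M* = 4 *x*tan / *d*rad with latewood defined by *M* > 1, hydraulic
  diameter Σ*d*⁵/Σ*d*⁴, per-organ summaries.
* **Scaling fits**: SMA (slope = sign(r) · s_y/s_x) and OLS fits in
  log₁₀–log₁₀ space, slope and elevation tests, quadratic curvature,
  continuous breakpoint fits, AIC comparison of power / exponential /
  logarithmic / quadratic / piecewise forms on a common log₁₀ response.
* **Bin-balanced resampling**: equally spaced log₁₀ bins (finest binning
  with ≥ 100 observations per occupied bin), balancing by subsampling to
  the smallest bin or bootstrapping to the largest (retaining all raw
  records), iterated with a stability trace.
* **Collapse model**: discretized tip-to-base path (default 30 m in 100 µm
  segments), exact per-segment Hagen–Poiseuille resistance integrals, Darcy
  flow between ψ_soil = −1.5 MPa and ψ_leaf = −4.7 MPa, the resulting
  tension profile, critical (t/b)² profile, and per-conduit safety factors
  (observed (t/b)² over the local critical value).
* **Synthetic data**: conduit tables drawn from configurable power laws
  with log-normal scatter, exponential (t/b)² decay in relative path
  position, an earlywood/latewood mixture, and realistic count imbalance.

## Worked example

```r
library(xylemtaper)

cfg <- taper_config(n_species = 2, n_trees_per_species = 3, seed = 7)
conduits <- generate_conduits(cfg)   # 50,815 conduits, 7 organ classes

shoots <- conduits[conduits$organ %in% c("leaf", "twig", "branch", "trunk"), ]
fit <- iterate_fit(shoots, "L_m", mode = "bootstrap",
                   spec = fit_spec("L_m", "d_um"),
                   n_iterations = 200, seed = 7)
print(fit)
#> Balanced bootstrap fit (200 iterations, stability trace converged)
#>   SMA slope of d_um ~ L_m: 0.2322 (across-iteration 95% CI 0.2321 to 0.2324)
#>   bins on L_m: 5 occupied, counts 165 to 30000
```

The aggregate slope 0.2322 is the path-length scaling exponent *α*
estimated after balancing the raw counts (165 to 30,000 conduits per log-L
bin); the generator's true exponent is 0.23. The across-iteration CI
reflects only the bootstrap augmentation noise and is deliberately reported
alongside, not instead of, the per-iteration parametric CIs (see the
methods vignette on why it is anti-conservative).

```r
profile <- path_profile(collapse_config(alpha = fit$aggregate_slope))
round(c(attr(profile, "tb2_crit_tip"), attr(profile, "tb2_crit_base")), 3)
#> [1] 0.028 0.009

assessment <- safety_factors(conduit_metrics(conduits), profile)
print(assessment)
#> Collapse safety assessment: 50815 conduits, 100.00% safe (0 flagged)
#>   median safety factor 74.87 (IQR 45.81 to 114.28)
#>   by wood type:
#>  wood_type     n n_collapse fraction_safe median_safety iqr_lower iqr_upper
#>  earlywood  9689          0             1      21.62714  15.33014  31.87164
#>   latewood 41126          0             1      86.37416  61.14816 126.68140
```

The critical thickness-to-span ratio falls roughly threefold from 0.028 at
the leaf tip (tension 4.7 MPa) to 0.009 at the base (tension 1.5 MPa);
every synthetic conduit clears its local limit, latewood by a wider margin
than earlywood — the qualitative pattern expected when walls are built
against worst-case drought tensions.

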