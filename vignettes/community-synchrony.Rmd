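---
title: "Quantifying community synchrony in stream macroinvertebrate time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying community synchrony in stream macroinvertebrate time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(streamsync)
```

## The statistic

Multi-species communities fall on a continuum between synchrony — species
rising and falling in abundance together — and compensatory dynamics, where
declines in some species are offset by increases in others. `streamsync`
quantifies where a community sits on that continuum with the
Loreau–de Mazancourt variance ratio. For an annual density matrix
$X$ with $T$ years and $N$ taxa, with $x_i(t)$ the density of taxon $i$ in
year $t$,

$$\phi \;=\; \frac{\operatorname{var}\!\big(\sum_i x_i(t)\big)}
              {\big(\sum_i \operatorname{sd}(x_i)\big)^2},$$

the temporal variance of total community abundance over the squared sum of
species-level standard deviations. $\phi = 1$ means fully synchronous
fluctuations (all series perfectly proportional); $\phi = 0$ means perfect
compensation (the total never moves); Cauchy–Schwarz guarantees
$0 \le \phi \le 1$. The statistic is invariant to multiplying all densities
by a positive constant and to the variance divisor ($T$ vs $T-1$) as long as
numerator and denominator use the same one — we use the sample divisor
$T-1$ throughout, and a property test asserts the invariance. Taxa with zero
temporal variance are kept in the community: they contribute $0$ to the
denominator sum and a constant to the total, exactly as the formula says. An
all-constant matrix is the undefined ratio $0/0$ and raises an error rather
than returning a value.

For equal-variance communities with constant pairwise correlation $\rho$,
$\phi$ has the closed form $(1 + (N-1)\rho)/N$
(`expected_phi_compound_symmetry()`), which the test suite uses as an
analytic oracle: simulated compound-symmetry communities (N = 10, T = 200,
200 replicates) must recover it within three Monte Carlo standard errors at
$\rho \in \{0, 0.3, 1\}$.

## Annualization

Field programs sample a handful of events per year (three for the NEON
wadeable streams: spring, summer, fall). Densities are averaged across the
events within each year before any synchrony computation, giving one annual
density per taxon; synchrony is never computed on raw event series. A taxon
absent from a sampled event is treated as an observed zero in that average:
presence-only records imply absences wherever an event was sampled and the
taxon was not recorded. The data sources do not state whether their
within-year means imputed event zeros or averaged recorded events only; we
chose imputation because a sampled event without a record *is* an
observation of density zero, and the package documents this as its own
convention. Years with no sampled events are simply absent from the matrix —
no gap interpolation. Duplicate (site, year, event, taxon) rows are an
ingestion error rather than being summed, so taxonomic roll-ups must happen
explicitly upstream; taxon columns are ordered lexicographically so the
matrix does not depend on file row order.

## Monte Carlo nulls

Observed synchrony is judged against a null in which every taxon's annual
series is permuted independently across years
(`community_null_test()`, 999 randomizations by default). This preserves
each species' marginal distribution while destroying cross-species
correlation — the null used by the established synchrony software for this
statistic. The alternative of permuting whole years jointly would preserve
the very cross-species structure being tested, so independent columns are
the right null here. The p-value is one-tailed for *greater* synchrony than
the null, with the add-one correction

$$p = \frac{1 + \#\{\phi_{\text{null}} \ge \phi_{\text{obs}}\}}{n_{\text{reps}} + 1},$$

so $p \ge 1/(n_{\text{reps}}+1)$ and $p = 0$ is impossible. Because column
standard deviations are permutation-invariant, the denominator of $\phi$ is
fixed under the null and each replicate only needs the variance of the
permuted row sums; the implementation draws all replicate permutations of a
column in one vectorized pass, which is distributionally identical to
shuffling matrices one at a time and keeps a 999-replicate test on a
150-taxon site under a second. Calibration is tested directly: on 1,000
independent-taxon communities (20 taxa × 10 years, i.i.d. lognormal), the
null must reject at $\alpha = 0.05$ in 5% ± 2% of runs.

## Per-taxon contributions

A taxon's contribution to community synchrony (`taxon_contribution()`,
`all_contributions()`) randomizes *only that taxon's column* 100 times,
recomputes $\phi$ each time, and standardizes the observed value against
that null: $z = (\phi_{\text{obs}} - \bar\phi_{\text{null}})/
\operatorname{sd}(\phi_{\text{null}})$. Positive $z$ means shuffling the
taxon destroys synchrony it was carrying — it fluctuates with the community;
negative $z$ means its observed arrangement suppresses synchrony. The
classification threshold is $z_{\text{crit}} = 1.96$ ($\alpha = 0.05$,
two-sided normal quantile, applied one side at a time). Two numerical
choices are worth recording: the null SD uses the sample ($n-1$) divisor (at
100 replicates the alternative is a ~0.5% effect), and a constant column —
which permutation cannot change — yields a point-mass null and is flagged
`degenerate` with $z = 0$ instead of raising an error, because real data
contain constant columns and the pipeline must survive them. Note that the
one-sided event $z > 1.96$ has a nominal null rate of about 2.5%, and the
calibration tests treat it that way; the two-sided event $|z| > 1.96$ fires
at about 5% on null data. Each taxon gets its own RNG substream derived from
the master seed, so z-scores do not depend on evaluation order.

## Turnover, diversity, environmental variability

Temporal turnover between consecutive years is
$(\text{gains} + \text{losses}) / |\text{union}|$ on annual presence sets
(presence = positive annual density), averaged over the consecutive pairs —
the standard gained-or-lost proportion relative to all taxa observed in the
pair, symmetric within a pair and bounded in $[0,1]$. Simpson diversity is
the complement form $1 - \sum p_i^2$ (via `vegan`). Environmental
variability is the sample SD of the full temperature (°C) or discharge
(m³/s) series at its native resolution; we deliberately do not resample to
a common grid, since no resampling rule is part of the definition. Where a
published table reports "average variability" per site, this package's
single-SD-of-the-full-series definition is the one implemented.

## Association screens and the feeding-group model

Site-level relationships (synchrony against temperature SD, discharge SD,
turnover) use Spearman's rank correlation: Pearson correlation of midranks
with a two-sided t-approximation on $n-2$ df — at 18 sites with tied ranks
an exact permutation distribution is unavailable, and the approximation is
the standard choice. No multiple-testing correction is applied across the
three screens. Spatial structure is screened with Moran's I using
inverse great-circle (haversine) distance weights, zero diagonal,
row-standardized, and a 999-permutation two-sided p-value around the
exchangeability expectation $-1/(n-1)$. The weight specification is a
declared default (it is echoed in every result row) because distance-band
and nearest-neighbour schemes are equally defensible; tests verify the
statistic against an explicit double-sum and against an independent
implementation.

Feeding-group differences in contributions are fitted with
`lme4::lmer(z ~ group + (1|site) + (1|taxon), REML = TRUE)`: genera recur
across sites, so site and taxon enter as crossed random intercepts. Fixed
effects use treatment coding with the alphabetical reference level
(filterer), which the result object records — published t statistics for
such models are uninterpretable without a declared baseline, so we declare
ours. Singular or non-converged fits are flagged in the result (and the run
manifest), not raised as errors. Parameter recovery and label-permutation
calibration are part of the acceptance tests (12 sites × 60 genera at ~2/3
occupancy, 60 recovery replicates, 300 permutations).

## The synthetic study generator

`generate_study()` produces a NEON-shaped bundle — long community table,
weekly temperature and discharge series, feeding-group table, coordinates —
so every stage is testable offline. Defaults are the study conditions the
package targets: 18 sites × 8 years × 3 events, per-site richness drawn
from 100–230 genera out of a shared 230-genus pool (shared so genera cross
sites, as the crossed random effects require), gatherer-heavy group weights
(0.40 gatherer, 0.20 predator, 0.15 scraper, 0.15 shredder, 0.10 filterer),
temperature-SD targets spanning 1–18 °C and discharge-SD targets
0.002–0.44 m³/s — the ranges observed across the real sites.

Synchrony is imposed on the log scale by a factor model: annual latent
log-densities load on a site-wide driver ($\sqrt{\rho_b}$), a
feeding-group driver ($\sqrt{\rho_w - \rho_b}$), and idiosyncratic noise
($\sqrt{1-\rho_w}$), so pairwise log-density correlations are exactly
$\rho_w$ within and $\rho_b$ between groups — a construction with an exact
compound-symmetry target and a closed-form oracle, simpler and more
transparent than copulas. Defaults $\rho_w = 0.25$, $\rho_b = 0.15$ put
realized site $\phi$ near 0.12 on average, inside the 0.1–0.3 band typical
of these communities (on the abundance scale $\phi$ is attenuated relative
to the log-scale $\rho$ by the lognormal transform). Optional per-group
loadings on an extra site-level environmental driver let tests construct
group-decoupled scenarios; they default to 0 so the correlation targets
stay exact. Turnover is imposed by masking latent abundances to zero with a
per-year state-flip probability (default 0.2, giving realized mean turnover
near 0.27–0.3, the modal value in the real sites); masking rather than
regenerating keeps persisting taxa's correlations intact. Event densities
are the annual density times mean-one lognormal noise (log-SD 0.5), so
annualization is unbiased.

What the generator does *not* emulate: mechanistic population dynamics,
spatial dispersal among sites, observation-effort differences beyond event
noise, seasonal succession within years, or abundance–occupancy
relationships. Passing tests therefore demonstrate that the estimators and
nulls behave correctly under controlled correlation, turnover and noise —
not that any particular ecological mechanism generates the real data.

## Reproducibility and problem sizes

Every stochastic routine takes a seed; `run_pipeline()` derives per-site
and per-stage substreams from one master seed and reruns are byte-identical.
The test suite's simulation sizes are chosen to give tight Monte Carlo
error at interactive runtimes: 200 replicates of 200-year communities for
the closed-form recovery, 1,000 communities for null calibration, 2,000
z-scores for the contribution calibration, 300 seeds for the embedded-noise
check, and 60 recovery replicates plus 300 label permutations for the mixed
model.

## Known limitations

- $\phi$ is a single whole-series summary; it has no timescale resolution
  (no wavelet or band-specific synchrony) and no alternative indices are
  provided.
- The printed-precision site table bundled with the package carries rank
  ties that full-precision data would break; rank correlations computed
  from it can differ from values computed on unrounded data.
- Turnover is not decomposed into appearance and disappearance components,
  and no across-site beta diversity is computed.
- The mixed model is Gaussian-only; heavy-tailed z distributions are not
  modelled.
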