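# beatstab

Tempo and tempo-stability analysis of beat onset series.

Music used for rhythmic auditory cueing — gait rehabilitation for
Parkinson's disease, rhythmic exercise, dance — must hold a stable beat.
Beat trackers and metadata services report a single "average tempo" per
recording, but a point estimate says nothing about whether, or over which
stretch of the recording, that tempo is actually stable. `beatstab` fills
that gap: given the beat and barline onset timestamps produced by an
external beat tracker (the package does no beat tracking or audio decoding
itself), it quantifies how much beat-to-beat temporal instability the
recording contains and locates its longest temporally stable segment. The
resulting statistics can be thresholded to curate playlists for clinical or
recreational use.

## Method

Let `S` be the inter-beat-interval (IBeI) series, the first-order difference
of the beat timestamps.

1. **Tempo location λ.** The central tendency of `S` is the global mode of
   an adaptive Gaussian kernel density estimate whose bandwidth is selected
   by the diffusion (improved Sheather–Jones) fixed-point rule: the binned
   data are taken to the discrete cosine domain, the squared bandwidth `t*`
   solves a fixed-point equation found by bracketing root search, and the
   coefficients are attenuated by `exp(−k²π²t*/2)` before inversion. Unlike
   the mean, median, or a rule-of-thumb-bandwidth mode, this estimator stays
   on the dominant tempo when the recording contains several tempo sections
   (a multimodal interval distribution). Estimated Tempo is `60/λ` bpm.
2. **Stability mask.** Each interval gets a percentage deviation from
   location, `PDL_i = 100(S_i − λ)/λ`, and each successive pair a percentage
   change, `SPC_i = 100(S_{i+1} − S_i)/S_i`. An interval is flagged stable
   when `|PDL_i| ≤ θ_Local` (default 5%); then, scanning pairs of currently
   stable neighbours in ascending order, the second is demoted when
   `|SPC_i| > θ_Local`.
3. **Stable Segment.** Maximal strings of stable intervals are **Runs**,
   unstable strings are **Gaps**. Runs of duration ≥ `θ_Run` (default 10 s)
   qualify; consecutive qualifying Runs are chained when the time between
   them is ≤ `θ_Gap` (default 2.5 s). The chain spanning the most time is
   the **Stable Segment**.
4. **Nine summary statistics.** Stable Duration; Stable Percentage (of the
   full beat span); Run Percentage (of the segment that is Runs); Estimated
   Tempo; Estimated Tempo Mismatch against an external estimate; Estimated
   Meter (mean beats per bar over in-segment bar windows, integer only when
   every bar agrees); and three instability maxima over the segment's Runs —
   `PDL_max`, `SPC_max`, and `PTD_max`, the largest linear tempo drift
   fitted by least squares in 10-s half-overlapping windows, expressed as a
   percentage between the fitted window endpoints.

## Worked example

A synthetic recording at 120 bpm whose middle wobbles to a slower tempo for
~5 s (longer than `θ_Gap`, so the file splits into two stable halves):

```r
library(beatstab)
sim <- generate_onsets(list(section_spec(120, 0.5),   # 60 s at 120 bpm
                            section_spec(8, 0.65),    # ~5 s detour
                            section_spec(120, 0.5)),  # 60 s at 120 bpm
                       beats_per_bar = 4, seed = 1)
summarize_onsets(sim$beats, sim$bars, external_estimates(tempo = 120))
#> <beats_summary> synthetic
#>   estimated tempo   120.064 bpm (lambda = 0.499734 s)
#>   stable segment    [0.000, 60.033] s (duration 60.03 s, 47.9% of file)
#>   run percentage    100.0%
#>   estimated meter   4 beats/bar (integer)
#>   PDL_max 1.255%  SPC_max 1.689%  PTD_max 0.566%
#>   tempo mismatch    +0.053%
```

The tempo location lands on the dominant 0.5 s interval (120.06 bpm, within
0.1% of the external estimate). The 5-s detour exceeds the Gap threshold, so
the Stable Segment is the first 60-s half only — 47.9% of the file — with no
internal gaps (Run Percentage 100%) and all three instability maxima well
below the 5% threshold. A patient-ready playlist query would then filter a
batch summary table, e.g. keep rows with `stable_duration >= 90`,
`estimated_tempo` in [115, 125], and all maxima ≤ 5%.

From the shell, the same pipeline is:

```sh
./exec/beatstab simulate --spec spec.json --seed 1 --out fixtures
./exec/beatstab analyze --json fixtures/synthetic.json --out summary.tsv
./exec/beatstab filter --table summary.tsv --where 'estimated_tempo>=115' \
    --where 'estimated_tempo<=125' --where 'pdl_max<=5'
```

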