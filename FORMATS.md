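# File formats

All interchange formats are plain text (CSV / JSON), diff-able and
language-portable.

## Parameter sets (`*.json`)

```json
{
  "role": "estimated",            // or "reference"
  "description": "...",
  "values": { "HXT.Vmax": 1.7, "HXT.Km": 0.9, ... },
  "units":  { "HXT.Vmax": "mM/s", "HXT.Km": "mM", ... }
}
```

Keys are `REACTION.constant` over the full registry
(`model_parameters()`); unknown keys and non-positive constants are
rejected on read. Units: `Vmax` mM/s, `Km`/`Ki`/`Ka`/`K05`/`Ksat` mM,
`Keq`/Hill exponents dimensionless, rate constants 1/s (ADK: 1/(mM·s),
ATPase: Hill Vmax in mM/s).

## Observation bundles (`bundle.csv`)

One tidy CSV, columns:

| column  | meaning                                          |
|---------|--------------------------------------------------|
| table   | `concentration`, `flux`, or `enrichment`         |
| series  | species or reaction identifier                   |
| time_s  | cycle time in seconds, within [0, cycle length]  |
| value   | mM, mM/s, or percent                             |
| sd      | standard deviation, same unit (must be > 0)      |
| unit    | `mM`, `mM/s`, `percent`                          |

Row order is irrelevant (canonicalized on read); a missing `sd` column
defaults to 10% of |value| with a warning.

## Trajectories (`trajectory.csv`)

Tidy CSV: `time_s` (cycle time), `cycle`, `variable` (species or
reaction), `value`, `unit`. Written at full double precision (`%.17g`).

## Glycogen flux tables (`glycogen_*.csv`)

Two-column CSV `time_s`, `flux_mM_per_s`; piecewise-linear base flux over
one cycle, extended periodically. The realized flux is the interpolated
base times the UDPG saturation (synthesis, with a glycogen-capacity
factor) or glycogen saturation (degradation).

## Enrichment profiles (`enrichment.csv`)

Tidy CSV: `species`, `time_s`, `enrichment_percent` (0–100).

## Run manifests (`manifest.json`)

`command`, effective `config` (the raw CLI options), `seed`, package and R
versions, timestamp. Sufficient to reproduce the run.
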