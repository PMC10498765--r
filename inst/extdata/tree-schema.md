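# Coronary tree file formats (`ffru-tree/1`)

Two on-disk dialects are accepted by `load_tree()`; both are converted to
SI metres on load regardless of the declared unit.

## JSON dialect

```json
{
  "schema": "ffru-tree/1",
  "units": { "length": "mm" },
  "root": "LM",
  "segments": [
    { "id": "LM",  "length": 10, "d_prox": 4.0, "d_dist": 3.8 },
    { "id": "LAD", "parent": "LM", "length": 40, "d_prox": 3.2,
      "d_dist": 2.2,
      "profile": [[0, 3.2], [20, 2.8], [40, 2.2]] },
    { "id": "LCX", "parent": "LM", "length": 35, "d_prox": 2.8,
      "d_dist": 2.0 }
  ],
  "stenoses": [
    { "segment": "LAD", "start": 12, "length": 8,
      "severity": 0.5, "ref_diameter": 3.0 }
  ],
  "metadata": { "name": "example" }
}
```

* `units.length`: `"mm"`, `"cm"` or `"m"`; applies to every length,
  diameter, profile position and stenosis field. Default `"m"`.
* `segments[]`: `id`, `length`, `d_prox`, `d_dist` required; `parent`
  omitted (or `null`) exactly once — that segment is the root/inlet.
  `profile` is an optional ordered list of `[arc_position, diameter]`
  pairs; positions must be strictly increasing, starting at 0 and ending
  at `length`, with end diameters matching `d_prox`/`d_dist`.
* `stenoses[]`: optional; each lesion overrides the lumen diameter over
  `[start, start + length]` with `ref_diameter * (1 - severity)`,
  `0 < severity < 1`.
* Leaves of the tree are the outlets. Any branching order is allowed
  (bifurcations, trifurcations, single-child chains).

## CSV dialect

Two files, lengths in the unit passed to `load_tree(units = ...)`
(default `mm`):

`segments.csv` — columns `id, parent, length, d_prox, d_dist` (empty
`parent` marks the root).

`stenoses.csv` (optional) — columns
`segment, start, length, severity, ref_diameter`.

## Structural rules

Exactly one root; every non-root has exactly one existing parent; no
cycles; duplicate ids are an error. Value-level rules (positive lengths
and diameters, profile monotonicity, lesion bounds, severity in (0, 1))
are reported by `validate_tree()`.
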