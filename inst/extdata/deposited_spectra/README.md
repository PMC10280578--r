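# Deposited variety spectra (drop-in location)

The benchmark-reproduction test and the examples that operate on the
real maize-seed spectra expect the six per-variety reflectance tables
here:

```
deposited_spectra/
  manifest.yaml
  <variety>.csv   # six files, one per variety: 60 rows (seeds) x
                  # 176 numeric columns (bands, 400-1000 nm), no header
```

with `manifest.yaml` in the form

```yaml
files:
  - {path: huawan617.csv,   label: huawan617}
  - {path: longping208.csv, label: longping208}
  - {path: longping206.csv, label: longping206}
  - {path: longping259.csv, label: longping259}
  - {path: huawan263.csv,   label: huawan263}
  - {path: huawan267.csv,   label: huawan267}
```

These files are not shipped with the package. When they are absent the
benchmark test reports their absence and every other test runs on the
synthetic generator instead.
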