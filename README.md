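# esskit

Containerized packaging, validation and preprocessing of EEG studies in R.

EEG studies collected in different labs arrive as ad-hoc piles of recording
files, cryptic event codes and half-remembered processing steps, which makes
pooled and meta-analysis painful. `esskit` implements a *containerized*
convention for study data: each study becomes a folder with a pinned layout
and an XML manifest (`study_description.xml`) encoding sessions, subjects,
tasks, recording channel layouts, and a machine-readable mapping from event
codes to **Hierarchical Event Descriptor (HED)** tags — slash-delimited paths
into a standardized vocabulary tree such as
`Participant/Effect/Cognitive/Oddball/Target`. Containers exist at defined
processing levels:

- **Level 1** — raw recordings renamed into numbered `session/` folders, plus
  per-recording tab-separated *event-instance files*
  (`code TAB latency-seconds TAB HED-string`) so events are queryable without
  touching the binary signal files;
- **Level 2** — the automated preprocessing stage: noisy-channel detection
  (robust amplitude deviation `|z| > 5` on the per-channel robust SD, and a
  median max inter-channel correlation below 0.4 over 1-second windows),
  nearest-neighbor interpolation of flagged channels, and a *robust average
  reference* (each scalp channel re-referenced to the per-sample mean of the
  non-flagged scalp channels), with a per-recording quality report;
- **Level-derived** — any named filter function (e.g. `highPass` with
  `detrendCutoff = 0.5` Hz, a zero-phase 4th-order Butterworth) applied to
  every recording of a parent container, the parent manifest embedded
  verbatim, so the full provenance chain is recoverable from a single file.

A validator runs a catalog of 44 named checks (required fields, referential
integrity, channel-layout consistency, HED validity, the 20-character
event-label limit, on-disk file checks, ...) with safe auto-fixes such as
filling missing recording UUIDs. A synthetic-study generator produces
complete fake studies (1/f-noise EDF recordings, Poisson-timed event logs, a
draft manifest) so every stage is testable without real data. For audiences:
EEG researchers packaging a study for sharing, and tool authors who need a
stable programmatic interface to study metadata.

## Worked example

A 24-participant auditory oddball study — 64 scalp EEG plus 4 EOG channels at
1024 Hz, a frequent "ding" and a rare "buzz" target — is the generator's
default configuration:

```r
library(esskit)

cfg <- synth_config(seed = 1)                 # 24 sessions, 64+4 ch, 1024 Hz
m   <- generate_source_study(cfg, "rawdata")  # EDFs + event logs + draft manifest
res <- create_level1_container(m, "rawdata", "study_L1")
summarize_study(res$manifest)
#> Study: Synthetic auditory oddball study (ESS 2.0)
#>   sessions: 24  subjects: 24  recordings: 24
#>   tasks: oddball
#>   scalp EEG channels: 64  sampling rate(s): 1024 Hz

v <- validate_level1(res$manifest, containerRoot = "study_L1")
sum(v$issues$severity == "error")
#> [1] 0

l2 <- create_level2_container("study_L1", "study_L2")
d  <- apply_filter_to_container(l2$root, "study_HP",
        filter_description("highPass", list(detrendCutoff = 0.5)))
provenance_chain(file.path(d$root, "study_description.xml"))$levels
#> [1] "studyLevelDerived" "studyLevel2"       "studyLevel1"
```

The summary's 24 sessions / 64 scalp channels / 1024 Hz are the study shape;
the zero error count means the container is self-consistent and complete; the
provenance chain shows the derived container carries its entire ancestry.

Event queries work directly on the event-instance files:

```r
ev <- parse_event_instance_file(readChar(f, file.size(f)))  # any event file
search_event_instances(ev, hed_tag("Participant/Effect/Cognitive/Oddball"))
```

returns exactly the buzz-target events, because HED matching is hierarchical
prefix matching.

A command-line wrapper ships in `inst/cli/ess` with subcommands `validate`,
`containerize`, `level2`, `derive`, `report`, `simulate` and `search-events`.
`render_html_report()` turns any manifest into a self-contained HTML report.

## Acceptance script

`scripts/acceptance.R` rebuilds the worked example from scratch with the
installed package and recomputes the headline quantities — the containerized
session count, the size of the validation check catalog, and the accepted
event-label length boundary (scanned over lengths 1–64):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The methods vignette (`vignettes/ess-containers.Rmd`) documents the model,
the preprocessing stand-ins, all tunable thresholds, and what the synthetic
generator does and does not emulate.
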