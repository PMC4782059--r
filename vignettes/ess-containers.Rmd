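---
title: "EEG study containers: model, validation and preprocessing choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG study containers: model, validation and preprocessing choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The container model

`esskit` treats an EEG *study* — a self-contained set of recording sessions
answering one scientific question — as a data container: a folder with a
pinned layout and an XML manifest. The manifest binds together five concepts:

* **task** — a labelled, predefined activity (e.g. an auditory oddball
  detection task);
* **session** — all data recorded with one montage application from one
  subject (or several simultaneously recorded subjects);
* **data recording** — one continuous, synchronously sampled multichannel
  file;
* **recording parameter set** — a reusable channel-layout description,
  organized into *modalities*: contiguous, 1-based blocks of channels of one
  signal kind (EEG, EOG, ...) sharing a sampling rate, with channel labels
  and the list of non-scalp channels;
* **event-code mapping** — per task, the table translating the lab's event
  codes into the standardized HED vocabulary.

Subjects are deliberately anonymized: the schema exposes `labId`, group,
gender, age, handedness, height, weight, medication and an optional
channel-location file, and *no* identifying field (name, address, email,
phone, national id) exists anywhere in the type — tests assert this by
schema introspection.

## The pinned XML dialect

The reference container convention publishes its XML schema externally, and
its printed examples are images; the element vocabulary in this package
(`studyLevel1`, `recordingParameterSet`, `dataRecording`,
`originalFileNameAndPath`, ...) therefore follows the names that appear in
print and extends them in the same lowerCamelCase style. The dialect is
frozen by the XSD shipped at `inst/extdata/ess_level1.xsd` and is documented
as a reconstruction, not a byte-level clone of the original project's XSD.
Serialization is canonical: empty optional fields are written as empty
elements, paths use forward slashes relative to the container root, times are
seconds with up to six decimals, UUIDs are lowercase hyphenated version 4.
`read_level1_manifest()` and `write_level1_manifest()` are inverse
field-for-field; unknown root elements are preserved under
`additionalMetadata` so foreign metadata survives round-trips.

## HED tags and matching semantics

Events are annotated with Hierarchical Event Descriptors: slash-delimited
paths into a vocabulary tree. The package ships a trimmed HED 2.0 snapshot
(`inst/extdata/hed_vocabulary.txt`, an indentation-structured text format
with `[extensionAllowed]`/`[takesValue]` flags) covering the stimulus,
participant-effect, action and attribute branches used by typical
event-related paradigms. Three semantic decisions were genuinely open and are
fixed as follows:

* **Matching is case-insensitive prefix matching on paths.** The reference
  description motivates hierarchical annotation by the ability to "select or
  sort" on any level of detail but never states matching formally; prefix
  semantics is the natural reading and is what the search operation
  implements. Matching is therefore transitive along the hierarchy (tested as
  a property).
* **Groups are searched transparently.** A parenthesized group scopes
  related tags; a query matches an event if any tag at any group depth
  matches. No group-level attributes are implemented.
* **Vocabulary validation permits declared extensions.** A tag is valid if
  its path exists, or if it deviates only below a node with
  `extensionAllowed` (permission inherits downward), or supplies exactly one
  value below a `takesValue` node. The tilde role syntax of full HED 2.0 is
  rejected with a clear parse error rather than silently misparsed.

## Validation

`validate_level1()` runs a catalog of 44 named checks. The reference
tooling's own check list is not published — only its size ("more than 30")
and two concrete constraints (UUID auto-fill, the 20-character event-label
limit) are printed — so the catalog here is reconstructed by enforcing every
invariant the schema states, which lands above the published floor. Severity
policy: referential or structural breaks are errors; absent optional
metadata is a warning; generated identifiers (study and recording UUIDs) are
auto-fixed and reported with severity `fixed`. Validation is idempotent, and
duration-dependent checks are skipped with a warning when the raw file's
header is unreadable, rather than failed. Each catalog entry has a paired
mutation test that corrupts a valid manifest in exactly the way the check
targets and asserts that the check (and, where the invariant is isolable,
only that check) fires.

# Level-2 preprocessing: a documented stand-in

The published preprocessing pipeline for the reference convention is a
separate algorithm (robust referencing with RANSAC-based bad-channel
detection) that this package intentionally does **not** reimplement. The
default Level-2 pipeline is a simpler stand-in with the same interface and an
injection point (`create_level2_container(pipeline = ...)`) for a full
implementation:

* **Noisy-channel detection** (`deviationZ = 5`, `minCorrelation = 0.4`,
  both configurable): a scalp channel is flagged if the robust z-score of its
  robust SD (median/1.4826·MAD across channels) exceeds the threshold in
  magnitude, or if its median-across-windows maximum absolute correlation
  with any other scalp channel (1-second non-overlapping windows) falls below
  the floor. Correlation against a zero-variance signal is defined as 0, so
  flat-lined channels are flagged. Non-scalp channels are never flagged. The
  deviation criterion needs a realistic channel count (tens of channels) for
  the cross-channel MAD to be stable; with very few channels the spread
  estimate itself is noisy.
* **Interpolation** (`neighborCount = 4`): each bad channel is replaced by
  the unweighted mean of its nearest good scalp channels by Euclidean
  distance on electrode positions — a stand-in for spherical splines. When no
  measured positions exist, channels are placed on a unit circle in recording
  order, making "nearest" mean adjacent-in-montage.
* **Robust average reference**: the reference signal is the per-sample mean
  over scalp channels *excluding* the flagged ones, subtracted from *all*
  scalp channels (flagged included); the retained-channel mean is exactly
  zero afterwards (tested at 1e-9 relative).
* **Quality score** `1 − flagged/scalp` per recording, written with the
  flagged and interpolated channel lists into a per-recording report.

Processed signals are stored as EDF. The container convention leaves the
Level-2 payload format open; EDF is chosen because it is the one open format
already required on the input side. EDF is 16-bit: each channel is scaled by
its observed min/max (recorded in the header), so one quantization step is
`range/65535` per channel, and signal comparisons across a write/read cycle
are made after quantization. The codec canonicalizes the 8-character header
numerals so that a read-then-write cycle is byte-stable, which is what makes
"identity pipeline reproduces payload bytes" a testable invariant.

# Level-derived containers and provenance

`apply_filter_to_container()` applies a registered, named filter function to
every recording of a Level-1, Level-2 or derived container and writes a
derived container whose manifest records the filter name, its name–value
parameters, the tool version and timestamp — and embeds the parent's manifest
*verbatim* as nested XML rather than referencing it by path, so provenance
survives file moves and the whole chain is recoverable from one file
(`provenance_chain()`). A failing recording is marked `failed` and processing
continues; outputs are conserved one-per-parent-recording.

The built-in `highPass` filter interprets its `detrendCutoff` parameter as
the high-pass cutoff in Hz (matching the pairing of that parameter name with
a high-pass step in the reference description) and applies a zero-phase
forward-backward 4th-order Butterworth filter. No DSP package is available in
the supported dependency set, so the design is done from first principles
(analog prototype poles, low-pass→high-pass transform at the prewarped
cutoff, bilinear transform, unity gain at Nyquist); the coefficients agree
with standard implementations to machine precision, and tests compare the
measured steady-state sine response against the analytic squared Butterworth
magnitude (squared because the filter runs forward and backward) within 2%.
Startup transients are absorbed by odd-reflection padding of about three
filter time constants plus first-sample offset removal, which makes DC
rejection exact for constant inputs.

# The synthetic-study generator

`generate_source_study()` emulates the worked example that motivates the
schema: 24 participants performing an auditory oddball task, recorded with
64 scalp EEG and 4 non-scalp channels at 1024 Hz, a frequent standard
("ding") and a rare target ("buzz") — those counts are the generator's
defaults. Remaining quantities are not printed anywhere and were fixed once:

* **Session duration: 20 s** (default). Real sessions of this paradigm run
  about 15 minutes; at 68 channels × 1024 Hz that is gigabytes of synthetic
  signal with no additional testing value, since every consumer of the data
  scales linearly in duration. Structure (sessions, channels, rates, events)
  is what downstream code consumes.
* **Event rates: ding 0.5/s, buzz 0.125/s**, i.e. a 4:1 standard:oddball
  ratio typical for oddball paradigms, as homogeneous Poisson processes
  truncated to the recording (real paradigms use jittered but more regular
  stimulus-onset asynchronies; Poisson is the simplest stream with the right
  event-file shape).
* **Signals: 1/f-shaped Gaussian noise** (unit variance) per channel plus a
  shared 10 Hz sinusoid of amplitude 2 giving pairwise correlation ≈ 0.67,
  comparable to neighboring scalp electrodes. The shared component must be
  strong enough that clean channels clear the detector's correlation floor of
  0.4 — a weaker shared component (e.g. amplitude 0.5, correlation ≈ 0.11)
  makes the whole montage look "noisy" and breaks the planted-channel
  recovery property by construction, so the amplitude is pinned here and not
  revisited. An optional planted bad channel receives 100× noise variance
  and no shared component.
* **Determinism**: signals, events, subject metadata and the draft manifest
  are fully determined by `(seed, sessionIndex)`; generation restores the
  caller's RNG state.

What a green test on synthetic data does *not* establish: physiological
realism. There are no event-related potentials, no artifacts with realistic
spatio-temporal structure, no drifting electrode impedances, and the noisy
channel model (pure high-variance white noise) is the easiest possible
detection target. The generator validates the *plumbing* — formats, naming,
validation, referencing algebra, provenance — not preprocessing performance
on real EEG.

# Numerical and edge-case choices

* Event-instance files carry no header row and 6-decimal latencies (stable
  diffs, sub-millisecond precision at any plausible rate); ties in latency
  keep input order (stable sort).
* The ESS filename template is pinned to
  `<prefix>_session_<N>_<taskLabel>_<originalStem>.<ext>`; unsafe characters
  are replaced with underscores, never rejected.
* Container builds are all-or-nothing: every source recording and event log
  is resolved before the first byte is copied, and a non-empty destination
  requires an explicit overwrite flag.
* The EDF codec supports integer sampling rates with 1-second records and
  zero-pads a trailing partial record; mixed per-channel rates are rejected.
* A manifest with zero sessions is flagged by the validator as a warning,
  not an error: an empty study is incomplete but not inconsistent, and an
  empty Level-1 must remain transformable into a valid empty Level-2.

# Known limitations

* The trimmed HED snapshot is a small vocabulary subset; validation against
  it is a warning, not an error, so studies using the full vocabulary are not
  rejected.
* The Level-2 stand-in is not the published preprocessing pipeline; quality
  scores are comparable within this package only.
* In-band event extraction from vendor status channels is out of scope:
  events come from sidecar logs (`code TAB latency`).
* Only EDF payloads are processed at Levels 2+; other raw formats are
  carried opaquely through Level 1.
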