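---
title: "Methods: complete fact extraction from radiology reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: complete fact extraction from radiology reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The representation: facts, anchors, modifier slots

Free-text radiology reports carry assertions that entity-level tagging
cannot answer on its own: "No lesion observed" contains a perfectly
recognisable *lesion* entity, yet the clinical question "does this patient
have a lesion?" hinges on the negation and on how it binds to that entity.
radfacts therefore works at the level of complete **facts**: a fact is one
clinical assertion (a finding was observed, a follow-up is recommended, a
diagnosis is carried, a procedure happened, ...) tied to a *minimal
contiguous token span* of the report. Inside that span live:

* exactly one **anchor span** — the contiguous tokens naming the entity
  that defines the fact (the finding, the recommendation, the diagnosis);
* zero or more **modifier spans**, each filling a named slot phrased as
  the clinical question it answers: negation, uncertainty, conditionality,
  location ("where is the finding?" — the whole phrase "within the left
  kidney", preposition included), size, description, change over time,
  desired timing, temporal qualifier, person qualifier, diagnostic
  reasoning.

Modifier spans may be discontiguous (an ordered list of disjoint token
intervals); only the anchor must be contiguous. Modifier spans may overlap
each other and the anchor. Several facts may share one text span — a
conjunction such as "hepatic artery, portal vein, and hepatic veins are
patent" yields three anatomic-region-property facts with distinct anchors
and a common clause span. All spans are 0-based half-open intervals at
word-token granularity; half-open intervals compose cleanly and are the
convention throughout the package and its standoff file format.

The schema is a registry (`rf_schema`, YAML config), not a hard-coded
enumeration: fact types and slots are user-configurable, and both neural
networks size their output layers from the registry. The shipped default
(`default_schema()`) covers ten fact types reconstructed from the
vocabulary of abdominopelvic reporting; extending it requires no code
changes.

A deliberate limitation: facts require direct textual evidence. "The
gallbladder is surgically absent" yields an anatomic-region fact but no
procedure fact — there is no token span naming the cholecystectomy, and
the system does not infer implied facts.

## The two-stage neural extractor

**Stage 1 (document tagger).** Each token is embedded (see below) and the
document is encoded by a 2-layer bidirectional GRU. The concatenated
forward/backward states feed two independent dense heads: one scores every
token against every *fact type*, the other against every *anchor type*.
Both are multi-label sigmoid heads — a token may belong to several
overlapping facts — trained with binary cross-entropy, the two head losses
summed with equal weight (the relative weighting is not a sensitive choice
here and is configurable). Dropout 0.3 is applied to the GRU outputs
during training. Thresholding each label column (default 0.5) and taking
maximal runs of above-threshold tokens yields predicted fact spans and
anchor spans.

**Candidate generation.** Every predicted anchor span lying inside a
predicted fact span of the compatible type (the schema couples each anchor
type to the fact type that owns it) becomes a *fact candidate*. When
several nested compatible fact spans enclose an anchor, the smallest is
used, matching the minimal-span labeling convention; ties break toward
the earliest start.

**Stage 2 (refinement and slot filling).** Each candidate is processed by
a per-fact-type parameter bank — different fact types need different
learned information, and the stage-1 fact type selects the bank. The input
is the embedding matrix of the candidate *window*: the predicted fact span
plus up to 20 context tokens on each side, clipped (not padded) at
document boundaries — clipping avoids inventing padding semantics for the
extra input column, which is a 0/1 *anchor mask* marking predicted anchor
tokens. A single-layer bidirectional GRU encodes the window; a sigmoid
head emits token-level scores for each modifier slot plus one
anchor-refinement column, and a linear head emits begin/end scores whose
argmax over window positions gives the refined fact span (ties to the
earliest position; if the decoded end does not follow the begin, the
stage-1 span is kept). The loss is the sum of binary cross-entropy over
the token labels and softmax cross-entropy for the begin and end
positions, computed over the window (the network never sees tokens outside
it). The two-stage split matters because document-level supervision is
scarce (reports) while span-level supervision is plentiful (thousands of
facts per corpus); the refinement network trains on every labeled fact.

Stage 2 trains on *gold* candidates (teacher forcing): windows derived
from gold fact spans with gold anchors masked. Training on stage-1
predictions instead is possible but couples the stages' errors and is not
the default.

**Assembly.** At prediction time modifier spans are decoded per slot
column, clipped to the refined fact span; the anchor is refined to the
contiguous run in the anchor-refinement column overlapping the stage-1
anchor (falling back to the stage-1 anchor), and the refined span is
expanded if necessary so the fact always contains its anchor — every
emitted fact validates against the schema. Identical (type, anchor, span)
duplicates collapse.

## Token embeddings

Domain embeddings are trained on report text with the skip-gram objective
at 300 dimensions by default, composing each word vector from the word's
own vector plus hashed character 3-6-gram vectors (boundary markers
included, FNV-1a hashing into 20,000 buckets). The subword composition is
what makes the extractor robust to typographic noise and out-of-vocabulary
terms: any string receives a finite, spelling-informed vector. Training is
single-worker with a private RNG, so embeddings are bit-reproducible from
one seed. Tokens are lowercased for embedding purposes only.

An optional general-purpose pretrained table can be concatenated as
`[domain | general]`; it defaults to disabled so the package builds with
no downloads, and tokens missing from the general table receive a zero
general sub-vector (the subword component already covers OOV semantics).

## Training protocol

The corpus splits 80/10/10 at whole-report granularity (sentence-level
splitting would leak report style), sizes fixed by largest-remainder
rounding, permutation seeded. The stages train sequentially with Adam
(default 4e-3) and early stopping with patience 3: stage 1 stops on
validation token micro-F1 over fact and anchor labels, stage 2 on
validation micro-F1 over modifier and anchor-refinement labels of gold
candidates. Per-stage metrics are the natural early-stop signals for
sequential training; both belong to the same token-level micro-F1 family
used for final reporting. The best-epoch parameters are restored. One
master seed fans out to the split, initialisation, shuffling, and dropout,
so a training run is exactly reproducible. Optimizer choice, learning
rate, batch granularity (one document / one candidate per step), and
hidden sizes (defaults 128 and 64 per direction) are package choices,
exposed in `train_config()`.

## Evaluation

Metrics are token-level and micro-averaged: annotations expand into sets
of (token, label) pairs, so overlapping same-label facts count once per
token, and true/false positives pool over all classes before
precision/recall/F1. Three families are reported: fact spans
(`(t, fact_type)`), anchors (`(t, anchor_type)`), and *all labeled
information* — anchor pairs plus `(t, fact_type:slot)` modifier pairs.
Fact-span tokens are deliberately not double-counted in the third family:
it measures the labeled pieces of information (one anchor + one per slot
instance), the same convention the corpus statistics use, where modifier
slot labels are namespaced by fact type because slot semantics are
type-specific. Zero-denominator ratios are reported as 0 (conservative
convention). Predicted facts enter evaluation with their stage-2 refined
spans. Exact-span (entity-level) matching is not implemented; all
reported numbers are token-level.

## The synthetic corpus generator

The institutional corpora such a system is built for cannot be shipped,
so `generate_corpus()` produces gold-annotated radiology-style reports
with the statistical structure the extractor assumes, and every other
module is developed and tested against it. What it emulates:

* telegraphic multi-fact prose assembled from per-fact-type sentence
  templates with typed slots and filler lexicons (organs, lesion terms,
  sizes with units, change/timing phrases, negation/uncertainty/
  conditional cues);
* skewed fact-type frequencies — about half of all facts are imaging
  findings, while lab-result facts are capped at 9 per corpus regardless
  of size, reproducing the rare-class regime (the pre-cap sampling weight
  is 0.008 so that small uncapped held-out sets still contain a few rare
  facts to evaluate on);
* conjunction sentences packing 2-4 same-type facts into one shared
  clause span;
* optional anatomic section headers (uncovered by any fact, like real
  headers and metadata);
* typographic noise as single interior-character substitutions or
  transpositions, which never cross token boundaries, so gold token
  indices remain valid after injection.

Default conditions are fixed once: 44.1 mean facts per report (negative
binomial, dispersion 25), modifier attachment probabilities calibrated so
the corpus averages about 2.88 labeled spans per fact (one anchor plus
roughly 1.9 modifier instances), and header/period structure leaving
roughly 86% of tokens covered by at least one fact. Per-slot attachment
probabilities in real corpora are unknown; these are fixture parameters,
not estimates. Generation is deterministic given (seed, report index),
and generated text re-tokenizes exactly to the gold token stream.

What the generator does *not* emulate: real reports' vocabulary breadth,
long-range discourse, dictation artifacts, template idiosyncrasies across
authors, or clinical plausibility of fact combinations. Passing the
synthetic experiments therefore demonstrates that the architecture,
losses, decoding, and plumbing can recover the representation when its
assumptions hold — it says nothing quantitative about performance on
clinical text.

## Scaled experiment sizes and numerical choices

`label_recovery_experiment()` fixes the package's scaled study
conditions: 200 training reports (split 80/10/10 internally), 25
separately generated held-out reports, 100-dimensional embeddings, hidden
sizes 64/32, up to 30 epochs per stage with patience 3. These sizes keep
a full run in single-digit minutes on one CPU core while leaving the
acceptance thresholds (held-out fact-span micro-F1 at least 0.85,
all-spans at least 0.70) a wide margin; in practice the templated corpus
is recovered almost perfectly. The rare-class check mirrors the
observation that a fact type with fewer than 10 training instances scores
far below the dominant class.

Other numerical conventions, fixed and documented rather than tuned:
decision thresholds 0.5 per label; argmax ties toward the earliest
position; inconsistent begin/end decodes fall back to the stage-1 span;
anchor refinement is one extra label column rather than a separate
mechanism; empty documents yield zero facts; an empty validation split or
a non-finite loss aborts training with a diagnostic. Gradients of the GRU
backward pass are verified against central finite differences in the test
suite.

## Known limitations

* No contextual (language-model) encoders and no CRF/transition layer;
  span decoding is per-label thresholding.
* No joint decoding across candidates beyond collapsing identical
  duplicates.
* Rare fact types (single-digit training instances) are expected to fail;
  the per-class report makes this visible rather than hiding it in the
  micro average.
* The annotation format stores token indices against the token stream it
  embeds; annotations are not portable across tokenizers (the header
  records the tokenizer identity for that reason).
* No de-identification, ontology linking, or HL7/DICOM export.
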