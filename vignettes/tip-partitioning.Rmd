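---
title: "Partitioning FASTA alignments by FigTree tip attributes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning FASTA alignments by FigTree tip attributes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipsort)
```

## The procedure

`tipsort` implements a four-stage pipeline for recovering groups of FASTA
sequences selected interactively on an exploratory phylogeny:

1. **Parse** the taxa block of the FigTree-saved NEXUS file into per-tip
   records (label, optional color, optional annotation).
2. **Cross-check** the tip labels against the FASTA headers of the
   alignment the tree was built from, reporting duplicates and mismatches.
3. **Deconstruct** the selection scheme into the COLOR, ANNOT and COMBO
   group families.
4. **Extract** each group to a sequential FASTA file under
   `COLOR/`, `ANNOT/` and `COMBO/`, plus plain-text summaries.

The central assumption is that the tree-building program preserved the
FASTA headers verbatim as tip labels (RAxML does; this is why label
matching is byte-for-byte by default, see *Matching modes* below). The
topology itself is never consulted: every decision is a function of the
per-tip attribute pair, which is exactly what FigTree records in the taxa
block when the user colors or annotates tips or clades. Per-branch
attributes that FigTree writes into the trees block are deliberately
ignored — a clade coloring always also colors the member tips, and reading
only the taxa block keeps the input contract minimal and version-stable.

## The FigTree NEXUS dialect

A taxlabels entry is a label — bare, or single-quoted with `''` escaping an
embedded quote — optionally followed immediately by a comment
`[&key=value,...]`:

```
'Uncultured organism X12'[&!color=#0000ff,!name="Florideophyceae"]
```

Parsing choices, each made because FigTree output varies across versions:

- Attribute keys are matched case-insensitively and may appear in any
  order; unknown keys are ignored.
- Values may be bare, double-quoted, or `#`-prefixed.
- Colors appear in two encodings: `#rrggbb` hex text, and a signed decimal
  integer holding the two's-complement 32-bit ARGB value (older FigTree
  versions; `-65536` = `0xFFFF0000` = opaque red). `normalize_color()`
  reduces both to the uppercase 6-hex-digit RGB code, dropping the alpha
  byte, so the two encodings of one color always select the same group.
  The codomain is exactly $256^3 = 16{,}777{,}216$ codes.
- The annotation lives under a user-visible attribute name; FigTree's
  display-name attribute `!name` is the default key, and
  `annotation_key` overrides it for sessions that annotated under a
  different name.

Error handling is two-tiered. Structural absences — no taxa block, no
`taxlabels`, an empty FASTA — are fatal, because they mean the wrong file
was supplied. Everything local — a malformed attribute comment, an
unrecognized color value, an unbalanced quote — warns and degrades that one
tip to "no attributes", so a single bad entry never blocks a 4000-tip
extraction.

## Input normalization

Both readers first map CRLF and lone CR to LF, so files written on any
platform (and moved across platforms) parse identically; the FASTA reader
accepts interleaved and sequential layouts, strips internal whitespace from
sequences, and keeps records in file order. Output FASTA is always
sequential with LF endings and `.fas` extension — the simplest layout for
downstream consumption — and sequence bytes are written exactly as read, so
`read_fasta(write_fasta(x))` is the identity and re-runs are
byte-reproducible.

## Scheme deconstruction

Let each tip carry $(a, c)$ with $a$ the annotation or `NONAME` and $c$ the
color or `NOCOLOR`. The three families are the partitions induced by $c$,
by $a$, and by $(a, c)$, with three emission rules:

- `NOCOLOR` (resp. `NONAME`) groups exist only when at least one color
  (annotation) is in use — otherwise the "complement" would duplicate the
  entire input, contradicting the minimal two-file case (one color in use
  ⇒ exactly two files: the colored set and its complement).
- COMBO exists only when both attribute kinds are in use. Observed pairs
  with one placeholder component (`Group1_NOCOLOR`, `NONAME_FF0000`) are
  emitted, because the purpose of the full deconstruction is to let the
  user pick whichever subset matches their splitting goal; this is
  switchable off with `combo_strict = TRUE` for users who only want
  fully-attributed pairs.
- The doubly-absent pair `NONAME_NOCOLOR` is emitted only when such tips
  coexist with at least one fully-attributed tip. Consequently COMBO is a
  partition of the tip set except in that corner (and under
  `combo_strict`); the COLOR and ANNOT families are always exact
  partitions, and every COMBO group is a subset of exactly one COLOR and
  one ANNOT group. The test suite checks all of this against a brute-force
  per-label bucketing oracle.

Group order and within-group sequence order follow first appearance in the
taxa block, making plans and outputs deterministic.

## Matching modes and concordance

Label matching is byte-for-byte on the full header line by default: the
strictest and least surprising rule when the recommended tree builder
preserves headers exactly. Two relaxations are provided, off by default:

- `match_mode = "first"` compares against the header's first
  whitespace-delimited token, for FASTA files whose headers carry trailing
  descriptions.
- `translate_underscores = TRUE` reads `_` as a space on both sides, for
  tree builders that rewrite spaces. This is not applied silently because
  it would break the byte-preservation guarantee of the default workflow.

The concordance report (exact set differences plus duplicate lists on both
sides) is advisory: extraction always proceeds on the matched intersection,
each tip matched to a duplicated header contributing all of its records.
The one fatal case is zero matches, which distinguishes a wrong-file
pairing from a partial mismatch; writing a complete directory tree of
empty folders would hide that user error.

## Output conventions

Colored files are named by hex code (`FF0000.fas`) because human color
names do not exist for 16.7 million codes; `summary_by_color.txt` relates
each code to the labels written under it, and a `summary_by_annotation.txt`
twin is written for symmetry when annotations exist. Annotations are
sanitized to `[A-Za-z0-9._-]` for filenames (changes recorded in the
manifest); a post-sanitization collision is fatal with both offending names
reported, as is an attempt to overwrite a previous run without `force`.
Groups whose labels all fail to match produce no file — empty FASTA files
break downstream tools — and are listed as skipped in the manifest instead.

## The fixture generator

All tests run on synthetic data from `generate_fixture()`: a matched
(Newick, NEXUS, FASTA) triple with known ground truth. It emulates the
*file format*, not the biology — random bifurcating topologies by
sequential joins, uniform random branch lengths, i.i.d. uniform A/C/G/T
sequences — because correctness of the extraction depends only on the taxa
block and the header/sequence pairing. What it deliberately varies, under a
single Mersenne-Twister seed recorded in the file header, is everything the
parser must be robust to: quoting style per label, hex versus signed-ARGB
color encoding per tip, attribute key order, quoted versus bare values,
occasional unknown keys, interleaved versus sequential FASTA layout, and
the three line-ending conventions. Defects (duplicate headers, a missing or
extra record, a malformed comment, a conflicting duplicate label) are
injected with the expected concordance report computed by bookkeeping, so
warn-and-continue behavior is tested against ground truth rather than
against the code under test.

Passing these tests therefore shows that the machinery is exact on
well-formed and lightly-damaged inputs across the dialect space the
generator spans; it cannot certify behavior on FigTree dialects outside
that space (e.g. attribute conventions of future versions) or on real
alignments' header idiosyncrasies beyond the matching modes offered.

## Problem sizes used in the checks

The property suites run 200 random schemes against the bucketing oracle,
100 generator round-trips across quoting/encoding/EOL combinations, and
end-to-end runs at 20 taxa (the minimal monochromatic contract: exactly
two COLOR files) and at 4191 taxa × 3379 bp with 10 colors + annotations —
the shape of the largest reference-database use case the tool is meant
for — asserting count conservation and byte fidelity throughout. These
sizes were chosen to exercise the tool at and above its intended working
range while keeping the default test run fast.

## Known limitations

- Only the taxa block is read; selections expressed solely as branch
  colorings with no tip attributes are invisible.
- One annotation key per run; tips annotated under several keys need
  separate runs.
- An annotation literally named `NONAME` (or sanitizing to an existing
  group's filename) collides with the placeholder and is rejected at the
  collision check rather than silently merged.
- No fuzzy label matching: beyond the two offered relaxations, headers
  must match exactly — by design, since approximate matching is how wrong
  sequences end up in curated datasets.
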