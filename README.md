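# tipsort

Partition FASTA sequences by the color and annotation edits of a FigTree
tree.

## The problem

Public and project sequence databases are full of entries whose headers say
nothing useful about what they are — environmental clones labelled
"Uncultured organism", contaminants, misidentified accessions. In
DNA-based systematics the standard way to sort such sequences is
topological: build an exploratory phylogeny of the query sequences together
with reference taxa, then segregate the FASTA sequences of the clades of
interest for downstream work (curation, crypticism screens, ingroup/outgroup
selection). The tree viewer makes *seeing* the groups easy — FigTree lets
you color or annotate an entire clade in one click — but getting the
underlying DNA back out of the original FASTA file is tedious: the Newick
string holds no sequence data, so people fall back on hand-edited files or
ad hoc label lists.

`tipsort` closes that gap. You color and/or annotate tips or clades in
FigTree and save the tree as NEXUS; `tipsort` recovers the per-tip edits
from the NEXUS **taxa block**, matches the tip labels against the headers of
the FASTA alignment the tree was built from, and writes the sequences out in
subsets.

## What it computes

A FigTree-saved taxa block attaches attribute comments to tip labels:

```
taxlabels
'A'[&!color=#ff0000]
'C'[&!name="Group1",!color=#ff0000]
H
;
```

Each tip therefore carries an optional color *c* (normalized to a 6-digit
uppercase hex RGB code; FigTree versions that serialize colors as signed
32-bit ARGB integers, e.g. `-65536` for red, are handled identically) and an
optional annotation *a*. `tipsort` fully deconstructs this selection scheme
into three families of subsets:

- **COLOR/** — one FASTA per distinct hex code (`FF0000.fas`, …) plus
  `NOCOLOR.fas` for the uncolored tips (emitted only when colors are in
  use);
- **ANNOT/** — one FASTA per annotation plus `NONAME.fas` for unannotated
  tips;
- **COMBO/** — when both attribute kinds are in use, one FASTA per observed
  (annotation, color) pair, named `<annotation>_<HEX>.fas`, with
  `NONAME`/`NOCOLOR` placeholder components.

Within each family the groups partition the tip set, and every COMBO group
refines both a COLOR and an ANNOT group — so *nested* designs (one
annotation spanning several colors, or one color spanning several
annotations) extract the enclosing group and every nested subgroup
simultaneously, the same sequence landing in several files on purpose.

Before extraction, tree labels and FASTA headers are cross-checked:
duplicates and missing labels on either side are printed as warnings (and to
`concordance_report.txt`) and the run continues on the matched intersection.
Only a total mismatch — no label matches any header, i.e. a wrong file
pairing — is fatal. Because files may come from any platform, all three
line-ending conventions (LF, CRLF, CR) are accepted in both inputs, and both
interleaved and sequential FASTA parse identically.

## Worked example

A small synthetic nested design ships with the package: 20 taxa `A`–`T`,
an annotation `Group4` spanning three colors (nested by color), `Group2`
and `Group3` sharing one green color (nested by annotation), two blue tips
without annotation, three annotated tips without color, and two tips left
untouched.

```r
library(tipsort)
nex <- system.file("extdata", "synthetic_nested.nex", package = "tipsort")
fas <- system.file("extdata", "synthetic_nested.fas", package = "tipsort")
res <- tipsort(nex, fas, "example_out")
print(res)
```

```
Selection scheme: 20 taxa (15 colored across 5 colors, 16 annotated across 4 annotations)
Extraction plan
  COLOR: 6 group(s): A52A2A (2), FF0000 (3), FFC0CB (2), NOCOLOR (5), 00FF00 (6), 0000FF (2)
  ANNOT: 5 group(s): Group4 (7), NONAME (4), Group2 (3), Group3 (3), Group1 (3)
  COMBO: 8 group(s): Group4_A52A2A (2), Group4_FF0000 (3), Group4_FFC0CB (2), NONAME_NOCOLOR (2), Group2_00FF00 (3), Group3_00FF00 (3), NONAME_0000FF (2), Group1_NOCOLOR (3)
Extraction manifest: 19 file(s) written, 0 label(s) skipped
  COLOR/A52A2A.fas (2)
  COLOR/FF0000.fas (3)
  ...
  COMBO/Group1_NOCOLOR.fas (3)
```

Reading the output: all seven `Group4` sequences are together in
`ANNOT/Group4.fas` while its three color subclades are split across
`COLOR/A52A2A.fas`, `COLOR/FF0000.fas` and `COLOR/FFC0CB.fas` (and the
corresponding `COMBO/Group4_*.fas` files); conversely `Group2` and `Group3`
are united in `COLOR/00FF00.fas` and separated in the ANNOT folder. The two
untouched tips end up in `COLOR/NOCOLOR.fas` and `COMBO/NONAME_NOCOLOR.fas`.
`summary_by_color.txt` relates each hex code to the sequence labels written
under it, since hex file names are not human-friendly.

The same pipeline is available from the shell:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "tipsort.R", package = "tipsort"))') \
    tree.nex alignment.fasta -o outdir
```

with exit status 0 on success (warnings included), 2 for a parse error, 3
when no label matches, 4 for I/O or filename-collision errors. Options:
`--annotation-key`, `--match-first-token`, `--translate-underscores`,
`--combo-strict`, `--force`, `-q`.

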