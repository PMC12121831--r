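---
title: "Vector text mining by spaced-word projection: model, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vector text mining by spaced-word projection: model, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweeptm)
```

## The model

`sweeptm` embeds the words, documents and boolean queries of a literature
corpus in one Euclidean space, using alignment-free sequence-comparison
machinery rather than a trained language model. The pipeline has three
stages, each deterministic given its configuration.

**Stage 1 — text as a biological sequence.** A document is its title
concatenated with its abstract (single space between), normalized to a
declared character inventory (A–Z, digits, space, 20 punctuation marks):
uppercased, diacritics reduced to base letters, anything else replaced by
a space, whitespace collapsed. Two injective codecs re-express normalized
text over a biological alphabet:

* **AMINOcode** substitutes each character with a short code over the 20
  amino-acid letters. The shipped table
  (`inst/extdata/aminocode_default.tsv`) is *prefix-free*: nineteen amino
  letters code for themselves, `W` acts as an escape prefix (`W → WW`,
  other letters/digits/space as `W`+letter, punctuation as `WV`+letter),
  so greedy left-to-right decoding is unambiguous and
  `decode(encode(x)) = x` holds for every normalized string. The table is
  a file-level interface: a user holding a different canonical table can
  swap it in with `read_codec_table()`.
* **DNAbits** writes each character's 8-bit code as four nucleotides
  (`00→A, 01→C, 10→G, 11→T`, most significant pair first). The bit order
  and the 8-bit (Latin-1-range) character encoding are fixed conventions;
  any consistent choice works, but one must be declared for
  reproducibility.

AMINOcode is the default codec for text mining: at equal mask length a
20-letter alphabet yields a far richer spaced-word inventory than 4
nucleotides.

**Stage 2 — spaced-word projection.** A binary mask (default `11011`:
weight 4, span 5, starting and ending in a care position) slides over the
sequence. At each window the letters at care positions form a word that
indexes one cell of an `a^w`-dimensional vector — `20^4 = 160{,}000` cells
for the default — which is incremented (`counts`, the default: abstracts
are short, so multiplicity is informative) or set to one (`binary`, for
parity with genome-scale use). The sparse counts are stored as an index →
value map and never densified. The vector is then projected,

$$\mathrm{Wbase}_d = Q^\top h_d,$$

through a column-orthonormal basis $Q \in \mathbb{R}^{a^w \times p}$ drawn
once per configuration: a seeded standard-normal matrix orthonormalized by
Householder QR (LAPACK). Identical `(dimension, p, seed)` give
bit-identical bases; orthonormality holds to machine precision, and on
encoded documents the projected pairwise distances correlate with the
high-dimensional ones well above 0.95 (a Johnson–Lindenstrauss-type
guarantee checked explicitly by the test suite and acceptance script).
Base vectors are not length-normalized by default (an L2 flag exists):
document length is signal for the averaging stage below.

**Stage 3 — one space for everything, by averaging.** With the base
vectors fixed,

* a **word** is the mean of the base vectors of the documents containing
  it (set membership over the document's distinct tokens);
* a **document** is the mean of the vectors of the distinct embedded words
  it contains;
* a **query** is the mean of its resolved items (words first, then
  document ids, then expression labels);
* a **boolean expression** is the mean of the base vectors of the
  documents it matches.

All four constructions are plain arithmetic means, so every derived vector
lies in the convex hull of the vectors it averages, every space has the
same dimension `p`, and a word occurring in exactly one document coincides
with that document's base vector. The test suite pins each construction to
an independent loop-based oracle at `1e-12`.

## Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `mask` | `"11011"` | spaced-word pattern; weight 4 over 20 letters gives a 160,000-cell index space, comfortably above `p` |
| `codec` | `"aminocode"` | richer alphabet → more informative words at equal span |
| `mode` | `"counts"` | count multiplicity in short texts; `"binary"` available |
| `p` | `1369` | projection length, the length used for whole-corpus document vectors |
| `seed` | `42` | basis seed; part of the provenance of every matrix |
| `min_chars` | `300` | corpus filter: minimum normalized title+abstract length |
| `relevance_threshold` | `1.0` | a word is relevant when its corpus relative frequency is at least its background relative frequency |
| metric `k` | `0.3` | Lk-norm exponent for the per-word report trees |

The tokenizer is deliberately minimal: maximal alphabetic runs of the
normalized text, uppercased, length ≥ 3, no stemming and no stop list.
Function words are instead demoted by the relevance ratio against a
background frequency table; words missing from the background table
receive its minimum frequency, which makes rare domain terms maximally
relevant and avoids division by zero. The exact threshold that a published
word list used is generally not recoverable, so the cutoff is a parameter
and a deposited relevant-word list can be loaded verbatim instead.

## The query language

`LOGEXP` expressions combine literal substring patterns with `|`, `&`, `~`
and grouping by `()` or `{}`; `_` inside a pattern denotes a mandatory
space. Matching is case-insensitive on normalized text padded with one
leading and trailing space, so a word-initial pattern like `_CARDI`
matches at the start of a title. Precedence is NOT > AND > OR with
left-associative chains; published expression sets are fully grouped, so
precedence only affects hand-written queries. `~` is plain per-document
complement. The evaluator is property-tested against a truth-table oracle
on randomly generated expression trees, including the De Morgan duals and
hit-count monotonicity.

## Trees, metrics, reports

Dendrograms use Neighbor-Joining (`ape::nj` behind the package surface)
with negative branch lengths clamped to zero, a closed-form 2-leaf base
case, optional rooting at a designated leaf (e.g. the focal term of a
corpus), and a Newick writer that single-quotes labels containing
metacharacters — expression labels contain `|`, `&`, braces and spaces —
so trees survive a write/parse roundtrip. Euclidean distance is the
default retrieval metric and the metric for expression trees; the
fractional Lk-norm (`k = 0.3`) is used for the per-word trees of the HTML
reports. For `k < 1` the Lk-norm violates the triangle inequality and is
treated strictly as a dissimilarity.

The HTML-TM output is two static, style-inlined files: `WORDS.html` (per
relevant word: 7 best hits, a dendrogram over the 30 top related terms
drawn from the complete word list, the 30 nearest documents, and a
year-usage index — mean publication year plus per-year counts) and
`TEXTS.html` (per document: its 30 nearest documents). A word's own entry
is excluded from its hit list, document numbering is consistent across
files, and regeneration is byte-identical. PCA truncation
(`pca_truncate`, centered, unscaled) is available where more
generalization is wanted; cross-space comparisons in truncated coordinates
must share a single fit, which the function supports by accepting a
fitted basis.

## What the synthetic generator does and does not show

`generate_corpus()` plants `n_topics` clusters: each topic has a private
vocabulary and a unique title keyword; every title also carries the shared
focus term, emulating a search-term corpus; abstract tokens come from the
topic vocabulary with probability `topic_mix` (default 0.8) and otherwise
from a shared pool that includes genuine English stop words; abstracts are
padded past the 300-character filter; years are uniform over 1970–2022.
Defaults are 3 topics × 30 documents. A background table is co-generated
(stop words frequent, planted vocabulary rare) so relevance filtering is
testable offline. Tokens are pronounceable random strings (length 4–10),
which exercises the codecs' full alphabetic path.

Passing tests on this fixture demonstrate *mechanical* correctness —
exact averaging, exact matching, metric and tree behavior, recovery of
separations that were planted — on text whose statistics are far cleaner
than real abstracts: no synonymy, no morphology, no topical overlap, no
citation structure, and token frequencies that are nearly uniform within a
vocabulary. Recovery rates near 100% here say nothing quantitative about
recall on a real literature corpus; they say the geometry does what the
formulas claim.

## Numerical choices and degenerate inputs

* Ties in k-NN break lexicographically by label; NJ agglomeration ties
  break at the lowest index pair (both for reproducibility).
* Duplicate titles: the first occurrence in input order is kept.
* Documents containing no embedded vocabulary word are dropped from the
  document space with a warning rather than zero-filled.
* A word occurring only in year-less documents has no year-usage index
  (an error, not a silent zero); year-less documents are otherwise kept.
* Sequences shorter than the mask span index to the zero vector.
* Distance matrices are validated (symmetry `1e-8`, zero diagonal,
  nonnegativity) before tree construction.
* The full-scale basis build (160,000 × 1,369) is the one expensive step
  (~minutes); test-scale configurations use smaller masks and `p`, which
  the problem sizes quoted in the test files reflect.

## Known limitations

* The averaging model is bag-of-words at heart: word order contributes
  only through spaced words crossing token boundaries inside a document.
* The AMINOcode table is a faithful interface but not verifiably the
  original published table; swap the table file for strict parity.
* Coverage percentages and per-expression hit counts on a published
  corpus require the deposited corpus and expression tables; they load
  through `read_corpus(col_map = ...)` and `read_logexp()` but are not
  bundled.
* `Wwrd0` versus `Wwrd` (complete versus relevance-filtered vocabulary
  feeding the document embedding): the package defaults to the complete
  list, with `relevant_only = TRUE` available, because the document
  embedding is better conditioned when short documents still contain
  embedded words.
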