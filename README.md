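# sweeptm — vector text mining of literature corpora via spaced-word projection

`sweeptm` is an R implementation of a vector text-mining environment for
biomedical literature corpora (PubMed-style records: id, title, abstract,
year). Its purpose is to place **words, documents, boolean queries and
free-form queries in one geometric space**, so that a researcher can ask
"which terms and which papers are closest to this concept?" and navigate a
field — the motivating use case is the yoga-and-health literature — without
topic models or trained embeddings.

The machinery is borrowed from alignment-free sequence comparison:

1. **Text → biological sequence.** Each document's normalized
   title + abstract is re-expressed over a biological alphabet with one of
   two injective codecs: *AMINOcode* (character-wise substitution into the
   20 amino-acid letters through a prefix-free table) or *DNAbits* (each
   8-bit character code emitted as 4 nucleotides, `00→A, 01→C, 10→G, 11→T`,
   most significant pair first, so `"A"` = 65 = `CAAC`).
2. **Spaced-word projection (SWeeP).** A binary mask (default `11011`)
   slides over the sequence; the letters at its care positions index a cell
   of an `a^w`-dimensional count vector (default `20^4 = 160,000`). That
   sparse vector is compressed through a *seeded random orthonormal basis*
   to a fixed length `p` (default 1,369): `Wbase[d, ] = t(Q) %*% h(d)`.
3. **Co-embedding by averaging.** With `Wbase` fixed,

   - word vectors: `Wwrd[w] = mean(Wbase[d] : document d contains w)`
   - document vectors: `Wtxt[d] = mean(Wwrd[w] : w a distinct word of d)`
   - query vectors: `WQ = mean(resolved item vectors)`,
     e.g. `NEUROLOGICAL-BRAIN-CORTEX`
   - expression vectors: `Wlog[e] = mean(Wbase[d] : d matches e)`

4. **LOGEXP**, a boolean substring query language over documents and
   titles: `|` (or), `&` (and), `~` (not), `()`/`{}` (grouping), `_`
   (mandatory space), e.g. `{CHRONIC | ACUTE} & CONDITIONS` or
   `_CARDI & VASCUL`. Expressions filter the corpus, count document/title
   hits, and become vectors in the shared space.
5. **Search and structure.** k-nearest-neighbour retrieval (Euclidean, or
   the fractional Lk-norm `(Σ|xᵢ−yᵢ|^k)^{1/k}` with `k = 0.3` as a
   high-dimensional dissimilarity), Neighbor-Joining dendrograms with
   Newick output, relevance-filtered vocabularies (corpus frequency over
   background English frequency), and two static HTML files (WORDS.html /
   TEXTS.html) for offline navigation.

A synthetic-corpus generator with planted topic structure
(`generate_corpus()`) makes the whole pipeline testable end to end with no
downloads.

## Worked example

```r
library(sweeptm)

fx <- generate_corpus(synthetic_spec(n_topics = 3, docs_per_topic = 10,
                                     doc_length_mean = 40, seed = 7))
tm <- textmap(fx$corpus, sweep_config(mask = "101", codec = "dnabits",
                                      p = 12, seed = 3),
              background = fx$background)
print(tm)
#> Vector text-mining map
#>   corpus: 30 documents ('synthetic')
#>   vectorizer: mask 101, dnabits, p = 12, seed = 3
#>   vocabulary: 192 words (180 relevant)
#>   spaces: Wbase 30, Wwrd 192, Wtxt 30 rows
```

The fixture plants three topics whose title keywords here are `JETEK`,
`KIPIKE`, `TIFIHECOHI`. Semantic search around the first keyword ranks its
own topic's vocabulary and documents first:

```r
predict(tm, "JETEK", type = "terms", k = 5)
#>        label distance
#> 1      JETEK 0.000000
#> 2 VEHERIVUGA 1.914900
#> 3   KOFEGUFA 3.107580
#> 4      BIKAR 3.880505
#> 5       FOHA 4.879753

match_corpus("_JETEK_", fx$corpus)
#> <logexp _JETEK_: 10 documents, 10 titles>

cov <- coverage_report(sprintf("_%s_", fx$truth$keywords), fx$corpus)
#> union coverage: 100.00% of documents, 100.00% of titles
```

The distances are Euclidean distances in the shared 12-dimensional space:
`JETEK` is at distance 0 from itself, its closest neighbours are words
that co-occur with it in the same planted topic, and the three keyword
expressions together recover every document exactly once — which is how
the generator planted them.

`plot(tm, n = 30)` draws the Neighbor-Joining dendrogram of the 30 most
widespread relevant words; `build_html_tm()` writes the WORDS/TEXTS
navigation pages; `write_newick()` / `read_newick()` exchange trees with
standard viewers.

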