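# screenloop

Seed-driven relevance ranking for systematic-review title/abstract
screening, with the evaluation machinery to measure what it saves.

## The problem and who this is for

Title/abstract screening is the most time-consuming step of a systematic
review: search strategies return 10^3–10^4 candidate articles, each
taking ~30–45 s to screen by hand, and only a handful survive. screenloop
is for review teams and methods researchers who want (a) a semi-automated
screening loop that front-loads the relevant articles, and (b) honest,
reproducible measurements of the workload it saves.

## The method

Every record's title + abstract is embedded once per collection as a
numeric vector — deterministic tf-idf (smoothed idf, L2-normalized rows)
or distributed bag-of-words paragraph vectors trained with negative
sampling under a fixed seed. Given seed articles *S* (known-relevant
exemplars) and the set *F* of articles flagged so far, each unscreened
candidate *u* is scored

```
score(u) = max over r in (S ∪ F) of cos(v_u, v_r)
```

and the top 50 are presented as the next screening round; flags feed back
into the ranking only at round boundaries. The loop halts on pool
exhaustion or at a pre-agreed screened fraction. Evaluation uses the
standard work-saved-over-sampling statistic at recall level R,

```
WSS@R = (N − n_screened_at_R)/N − (1 − R)
```

together with percent-not-reviewed, rounds of 50, recall trajectories,
screening-rate and FTE-day/cost conversions. A synthetic labelled-corpus
generator (Zipf decoy vocabulary + an exclusive topic block injected into
relevant records at a controllable rate) makes the whole pipeline
testable without copyrighted review corpora.

## Worked example

```r
library(screenloop)

# read a (synthetic) RIS export and remove exact duplicates
ris <- system.file("extdata", "synthetic-example.ris", package = "screenloop")
corpus <- read_records(ris, format = "ris")
dd <- deduplicate(corpus)
dd$report
#> <duplicate_report> mode=strict, 1 record(s) removed in 1 group(s)

# generate a labelled corpus at the default study conditions and replay it
lc <- generate_corpus(synthetic_spec(rng_seed = 2026))
lc
#> <labelled_corpus> 500 record(s), 15 flagged, 6 final
res <- replay(lc, seed_ids = lc$final_ids[1], method = "tfidf", rng_seed = 2026)
res
#> <simulation_result> N = 500: 1 seed(s), 14 reviewed in 1 round(s) of 50,
#>   485 not reviewed (97% of corpus not reviewed); halted: all_final_found

threshold_analysis(lc, lc$final_ids[1], rng_seed = 2026)
#> <threshold_analysis> WSS@95 = 92%, WSS@100 = 97%
#> # A tibble: 7 x 3
#>   interval n_screened n_final_found
#> 1     0.05         25             6
#> 2     0.1          50             6
#> ...

workload_savings(118, 24, rate = 26)$cost_saving
#> [1] 2444
```

Reading the numbers: with one final article as the seed, the ranker found
the other 5 final articles after 14 decisions, so 97% of the 500-record
corpus never needed review (WSS@100 = 97%); all 6 finals sit inside the
first 5% of the ranking. The last line converts a 118 h manual screen vs
a 24 h assisted screen at USD 26/h into the USD 2444 saving.

A command-line interface wraps the same functions
(`generate | dedup | simulate | thresholds | seedsense | metrics | screen`):

```sh
CLI=$(Rscript -e 'cat(system.file("cli","screenloop",package="screenloop"))')
Rscript "$CLI" generate --out-dir out/gen --seed 1
Rscript "$CLI" simulate --corpus out/gen/corpus.csv --labels out/gen/labels.csv \
    --seeds SYN00123 --out-dir out/sim
```

Every run writes a `manifest.json`; identical manifests produce
byte-identical outputs.

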