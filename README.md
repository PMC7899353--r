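# capl2score

Batch scoring for the **Canadian Assessment of Physical Literacy, second
edition (CAPL-2)** — the standard field protocol for assessing physical
literacy in children aged 8–12. Given a rectangular table of the 60 raw
variables a CAPL-2 assessment produces per child (shuttle-run laps, plank
hold time, CAMSA obstacle-course trials, a week of pedometer logs, and
questionnaire responses), the package derives the 40 variables researchers
report: protocol scores, four domain scores, an overall physical literacy
score, age- and gender-specific interpretive categories, and per-domain
completeness statuses.

It is aimed at researchers and practitioners who hold raw CAPL-2 data for
hundreds or thousands of children and want scoring that is fast,
reproducible, and *quiet*: invalid or missing raw values never halt a run —
they become `NA` and propagate through the documented rules.

## The scoring model

Each domain is a weighted sum of component scores; a single missing
component is reweighted away, two or more make the domain missing:

| Domain | Components | Score |
|---|---|---|
| Physical competence (pc) | PACER (/10) + plank (/10) + CAMSA (/10) | /30 |
| Daily behaviour (db) | step score (/25) + self-report PA (/5), **no reweighting** | /30 |
| Motivation & confidence (mc) | predilection + adequacy + intrinsic motivation + PA competence (each /7.5) | /30 |
| Knowledge & understanding (ku) | 4 × 1-point items + fill-in-the-blanks (/6) | /10 |
| **Overall physical literacy** | pc + db + mc + ku | **/100** |

With exactly one component `c` missing from a domain with maximum `M`,

```
score = (sum of available components) × M / (M − max(c))
```

Key protocol rules: PACER score = `min(floor(laps_20m / 5), 10)` with 15 m
laps first converted through a lookup chart; CAMSA score =
`max(trial1, trial2) / 2.8` over two 1–28 skill+time trials; the step score
requires ≥ 4 valid pedometer days (1,000–30,000 steps *and* ≥ 10 h wear
time), with one day imputed by seeded resampling when exactly 3 are valid.
Interpretive categories (`beginning`, `progressing`, `achieving`,
`excelling`) come from a normative table keyed by protocol × gender ×
integer age. Constants that live in the CAPL-2 administration manual
(conversion chart, bins, answer keys, norms) are externalized in editable
config files; the packaged defaults are clearly-marked provisional
stand-ins — see `vignette source in vignettes/scoring-methods.Rmd`.

## Worked example

```r
library(capl2score)

demo   <- capl_demo_data(500, seed = 42)   # messy raw table, 500 x 60
scored <- score_capl_data(demo, seed = 42) # adds the 40 derived columns
dim(scored)
#> [1] 500 100

scored[1:5, c("age", "gender", "pacer_score", "pc_score", "db_score",
              "mc_score", "ku_score", "capl_score",
              "capl_interpretation", "capl_status")]
#>   age gender pacer_score pc_score db_score mc_score ku_score capl_score
#> 1   8   Male          10 27.50000       17       NA 1.000000   65.00000
#> 2  12      M          10 27.85714       16 13.73333 4.000000   61.59048
#> 3   8      F          10 30.00000       19 18.60000 2.222222   69.82222
#> 4   8 Female          10 21.78571       25 16.40000 1.000000   64.18571
#> 5   9   girl           2  4.50000       14 17.00000       NA   39.44444
#>   capl_interpretation      capl_status
#> 1           achieving missing protocol
#> 2           achieving         complete
#> 3           achieving         complete
#> 4           achieving         complete
#> 5         progressing missing protocol
```

Row 1 shows the machinery at work: the child's mc subscales were
incomplete, so `mc_score` is `NA`, the overall score was reweighted from
the other three domains (`(27.5 + 17 + 1) × 100/70 = 65`), and the status
flags the missing protocol. Row 5's `pc_score` of 4.5 is a reweighted
two-protocol score. Statuses across the table:

```r
table(scored$capl_status)
#>               complete             incomplete missing interpretation
#>                    341                     17                     53
#>       missing protocol
#>                     89
```

Every intermediate is exposed as its own vectorized function
(`pacer_score()`, `step_average()`, `mc_score()`,
`capl_interpretation()`, ...), and `capl_bar_plot()` draws mean scores by
interpretive category. A command-line wrapper lives at
`system.file("cli", "capl2score", package = "capl2score")` with `score`,
`demo`, and `plot` subcommands.

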