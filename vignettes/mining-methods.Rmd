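---
title: "Methods: content-based and temporal mining of patient-community posts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: content-based and temporal mining of patient-community posts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postmine)
```

postmine characterizes the Facebook-style activity of patient communities —
the motivating case is Spanish rare-disease groups — along two axes: what is
said (engagement stratification, distinctive vocabulary, keyness against a
reference priority document, sentiment) and when it is said (hour, weekday
and daypart patterns). This vignette describes each method, the parameters
that matter, the synthetic-data model that stands in for the non-public
group data, and the numerical conventions the implementation fixes.

## Engagement and tertile stratification

A post's engagement is the sum of its comments, shares and reactions.
Likes are deliberately *not* added as a fourth component: Facebook counts a
like as one of the six reaction types (love, haha, wow, sad, angry, like),
so the reaction total already contains it, and adding it again would double
count. This definition makes engagement linear in its components, which is
also a useful internal consistency check for the characterization table
produced by `characterize()`: on every row, the engagement mean must equal
the sum of the comment, share and reaction means.

`tertile_split()` stratifies posts into low / medium / high engagement at
the empirical tertiles. The thresholds are nearest-rank order statistics:
with $n$ posts sorted by engagement, $q_\mathrm{low}$ is the
$\lceil n/3 \rceil$-th value and $q_\mathrm{high}$ the
$\lceil 2n/3 \rceil$-th. A post is *low* if its engagement is
$\le q_\mathrm{low}$, *high* if $> q_\mathrm{high}$, otherwise *medium*.
Interaction counts are heavily tied, so a convention is unavoidable; this
one sends all boundary ties to the lower group and is deterministic and
order-independent. When $q_\mathrm{low} = q_\mathrm{high}$ (for instance,
all engagements equal, or more than a third of posts sharing one value at
both cut points) no post is separable from the middle of the distribution
and everything is assigned *medium*; with realistic overdispersed counts
this does not occur. The alternative convention — cutting at ranks rather
than values — splits ties arbitrarily between groups and was rejected for
that reason.

## Tokenization and tf-idf group vocabulary

Tokens are maximal runs of Unicode letters, lowercased, with a minimum
length of 2 characters. Accents are preserved: accented Spanish word forms
("después", "síndrome") are vocabulary, not noise. Digits are dropped, and
URLs and @-handles are stripped before tokenization because low-engagement
content in these groups is dominated by spam artifacts built from them. A
configurable stopword list (a compact Spanish list is bundled) removes
function words. No stemming or lemmatization is applied — keyness and
tf-idf work at the level of surface forms, which keeps every reported term
directly readable.

For the engagement word tables, the three concatenated group corpora are
treated as a three-document collection and each term is weighted by
tf-idf with $\mathrm{idf}(t) = \ln(3 / d_t)$, $d_t$ the number of groups
containing $t$ (natural logarithm). The choice of the three groups as the
document unit is the point of the scheme here: any term present at all
three engagement levels has idf $\ln 1 = 0$ and weight exactly zero, so the
shared topical vocabulary disappears and each group's table keeps only what
distinguishes it. For a single reference document there is no across-group
contrast to exploit, so `top_terms()` ranks it by raw frequency instead.
Ranking ties are broken lexicographically, making every reported table
deterministic.

## Keyness: the two-term log-likelihood

The core comparison statistic asks, per term, whether the term's rate
differs between corpus A (the posts, $c$ tokens) and corpus B (the
reference document, $d$ tokens). With observed counts $a$ and $b$, the
expected counts under a shared rate are

$$E_1 = \frac{c\,(a+b)}{c+d}, \qquad E_2 = \frac{d\,(a+b)}{c+d},$$

and the score is the two-term log-likelihood ratio

$$LL = 2\left(a \ln \frac{a}{E_1} + b \ln \frac{b}{E_2}\right),$$

with the convention $0 \ln(0/E) := 0$ so terms confined to one corpus get a
finite score. $LL$ is zero exactly when $a/c = b/d$ and grows as the term's
use diverges; it is a score, not a p-value, and no multiple-testing
correction is applied — the output is a ranking, read from the top. Because
the score is symmetric in direction, each row also records which corpus the
term is enriched in, from the relative-frequency comparison. The
textbook four-term variant of the statistic (which adds the
"all other words" cells) is intentionally not the default: the published
score table this package reproduces is numerically consistent with the
two-term form, and `calibrate_ratio()` demonstrates that consistency.

`rank_keywords()` scores the full union vocabulary (minimum combined count
1 by default, since published tables include terms with $b = 1$) and sorts
by score with a lexicographic tie-break.

### Recovering an unprinted corpus-size ratio

Published keyness tables often print, per term, the score and the two
counts $a, b$ — but not the corpus totals. The two-term $LL$ depends on
$(c, d)$ only through $p = c/(c+d)$, since $E_1 = (a+b)\,p$ and
$E_2 = (a+b)(1-p)$. `calibrate_ratio()` therefore recovers the single
unknown $p$ by bounded one-dimensional least squares against the printed
scores. Two things follow. First, each printed row can be re-derived from
the others (calibrate on the remaining rows, evaluate the formula at the
row's own $a, b$) — the package's reproduction check, also run by
`scripts/acceptance.R`. Second, the *joint* fit is a structural test: a
single $\hat p$ fits all twelve bundled rows with a maximum residual of
about 0.03 LL units, which would not happen had the table been produced by
the four-term statistic or by per-row varying totals. $\hat p$ is an
estimate, never a published value, and is reported as such.

## Sentiment scoring

`score_text()` is a transparent lexicon average with the conventional
range semantics: polarity in $[-1, 1]$, subjectivity in $[0, 1]$. Matching
is token-based against a CSV lexicon (term, polarity, subjectivity, role,
factor); a small bundled Spanish + English lexicon drives defaults, and any
lexicon in the same format can be supplied. Modifier rules, fixed so tests
can be exact: a negator among the 3 tokens preceding a match multiplies
that match's polarity by $-0.5$ (negation flips and dampens — "not good" is
milder than "bad"); each intensifier in the same window multiplies it by
the intensifier's factor. Polarity is the mean of modified match weights,
subjectivity the unmodified mean of matched subjectivity weights, both
clamped to their ranges; no matches scores $(0, 0)$.

Two deliberate narrowings. The trained pattern lexicons of black-box
sentiment toolkits are not reproduced, so absolute scores are comparable
only within one lexicon; across scorers only signs are. The bundled tests
assert exactly that: sign agreement on four published example texts, not
magnitude agreement. Second, no machine-translation step precedes scoring:
the scorer works in the source language against a matching lexicon, which
keeps the pipeline deterministic and offline.

## Temporal analysis

Hour and weekday are extracted in the timezone the timestamps carry —
set when the table is read, defaulting to Europe/Madrid, the zone of the
motivating study population. Export dialects differ in whether timestamps
carry an offset; zoneless values are interpreted in the configured zone,
and a diurnal analysis without a fixed zone would be meaningless.

Dayparts are the four six-hour bands morning [6, 12), afternoon [12, 18),
evening [18, 24) and night [0, 6), half-open on the right: a post at
exactly 12:00 is afternoon. `aggregate_metric()` reports per-key counts
and means with empty keys kept (n = 0, mean NA), so hourly tables always
have 24 rows and counts are conserved by construction.

`one_way_anova()` is the classical equal-variance F test, computed via
`anova(lm(...))` because hour-of-day factors routinely contain singleton
cells that stricter implementations refuse; the all-identical degenerate
case is defined as $(F = 0, p = 1)$. Published per-dataset ANOVA p-values
are data-dependent and not reproduction targets; the operation is instead
validated by simulation (null type-I error $\approx 5\%$) and closed-form
small cases. Both the 24-level hour factor and the 4-level daypart factor
are exposed, since either may be the analyst's intent.

The association screen uses Spearman correlation with average ranks for
ties (count data are heavily tied) and the t-approximation on $n-2$
degrees of freedom for p-values — appropriate at corpus sample sizes; an
exact permutation p-value would matter only at very small $n$. Cells with
$|\rho| \ge 0.10$ are flagged, and no multiple-testing correction is
applied to the 2×5 grid, matching how such screens are conventionally
presented.

## The synthetic-data generator

The original group data cannot be redistributed, so `generate_posts()`
produces a corpus with the statistical structure the analysis assumes,
under a single integer seed and a documented draw order (types, days,
hours, minutes/seconds, counts per type in fixed type order, then
messages). Defaults emulate one year of activity of Spanish rare-disease
groups:

* **Size and type mix.** 3917 posts; type probabilities proportional to a
  published per-type instance breakdown (statuses and links dominate).
* **Interaction counts.** Per-type negative-binomial draws at published
  per-type means and spreads — the spread exceeds the mean nearly
  everywhere in real data, and overdispersion is what makes tertile splits
  and correlation screens behave realistically. Reactions are generated as
  likes + non-like reactions, so the invariant reactions ≥ likes holds by
  construction. Where the configured spread does not exceed the mean the
  draw degrades to Poisson, and a zero mean yields structural zeros.
* **Diurnal rhythm.** Timestamps are drawn with hourly weights that are
  bimodal — peaks at 13:00–15:00 and 20:00–24:00, minimum at 6:00 — and
  weekday weights heaviest on Monday, declining over the week.
* **Vocabulary.** Messages are bags of words: shared topical terms, a
  long rare tail (without one, every term occurs at every engagement level
  and the tf-idf tables are identically zero), planted enriched keywords
  (gratitude/family terms over-represented in posts,
  administrative/priority terms in the reference document, factors 5–10),
  and sentiment-lexicon tokens.
* **Polarity drift.** The probability that a sentiment token is positive
  is $0.5 + \mathrm{drift}(hour)$, with drift positive in the morning and
  negative late at night, so daypart polarity means decline from morning
  to night.

What the generator does *not* emulate: message syntax (word order carries
no signal), spam bursts, reply threads, correlation between message content
and interaction counts, and seasonal structure. Tests passing on synthetic
corpora therefore validate the pipeline's statistical machinery —
recovery of planted enrichment, rhythms and drift — not its performance on
any real group's data.

## Problem sizes and numerical conventions

The test suite exercises corpora of 100–20,000 posts (20,000 for
sampling-error bounds on type frequencies and per-type means, 3917 — the
default — for end-to-end recovery, smaller for unit tests), chosen so the
statistical assertions have comfortable margins at sub-minute runtimes.
Calibration uses `stats::optimize()` on $(10^{-9}, 1-10^{-9})$ with
tolerance $10^{-12}$; scores at the balanced point are clamped at zero to
absorb floating-point residue of order $10^{-16}$; all report CSVs round
scores and means to one decimal while the JSON summary keeps full
precision; every ranked table breaks ties lexicographically.

## Limitations

Keyness against a very short reference document is noisy — with a few
hundred tokens, single-occurrence terms dominate the low end of the
ranking, and conclusions should rest on the top of the table only. The
sentiment scorer is bounded by its lexicon: out-of-lexicon affect
(irony, emoji, elongation) scores neutral. The engagement tertile
convention matters at heavily tied low counts, where group sizes can be
visibly unequal; the thresholds are reported so any downstream reader can
see where the cuts fell.
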