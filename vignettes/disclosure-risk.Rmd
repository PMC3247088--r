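---
title: "Measuring re-identification risk under approximate adversary knowledge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring re-identification risk under approximate adversary knowledge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(privrisk)
```

## The threat model

De-identified person-level data is conventionally judged by k-anonymity:
every record's quasi-identifier tuple must be shared by at least k − 1
others. That criterion implicitly assumes an adversary with *exact*
knowledge. Two realistic departures motivate this package:

1. **Approximate knowledge.** An attacker who overheard a consultation or
   misread handwriting holds a name that is wrong by a few characters.
   Against a phonebook, an approximate name is still devastating if few
   names lie near it. k-l-anonymity captures this: record $r$ has
   $k(r) = 1 + \#\{x \neq r : \mathrm{dist}(v_r, v_x) \le l\}$ under the
   Levenshtein distance, and a dataset satisfies k-l-anonymity when
   $\min_r k(r) \ge k$. At $l = 0$ this reduces exactly to k-anonymity on
   that field, which is both a sanity anchor and a tested invariant.
2. **Cross-source aggregation.** Partial profiles scattered across forums,
   directories and phonebooks chain together through shared identifiers.
   Each disclosure is individually mild; their transitive closure is a
   dossier.

## Distance computation and numerical choices

* **Unit of edit**: one Unicode code point, applied after normalization.
  Distances are therefore platform- and encoding-independent.
* **Normalization default**: case-fold, strip apostrophes/hyphens/periods,
  collapse whitespace. Phonebook typography (O'Brien vs OBrien) should not
  count as spelling distance. Whether distances are better computed on raw
  or cleaned strings is genuinely open; the policy is configurable via
  `norm_policy()` and the default is the cleaned form.
* **Index mechanism**: values are deduplicated, sorted by length, pruned by
  the length-difference lower bound $|{\,|a|-|b|\,}| \le l$, and compared
  with a banded dynamic program (band half-width $l$, early exit when a row
  minimum exceeds $l$). The mechanism is an implementation detail: the
  contract, enforced by tests against a full $O(n^2)$
  dynamic-programming scan (`utils::adist`, an independent code path), is
  exact equality with brute force for every query and threshold. A sweep
  over $l \in \{0..4\}$ on a 25,000-record phonebook runs in about a
  minute on one CPU.
* **Field granularity**: every operation takes an explicit `field`. Risk
  reports over a concatenated `full_name` and over `first` alone are both
  supported and give very different answers (first names collide heavily);
  neither is privileged.

## The adversary simulator

`perturb()` draws insert/delete/substitute operations uniformly (positions
uniform, characters uniform over a–z) and rejection-resamples until the
result is at distance *exactly* `e`, verified by the full dynamic program.
Exact-distance semantics — rather than "e sloppy edits" — make the key
guarantee provable and testable: if $e \le l$ the triangle inequality
forces the target into the candidate set, so the recovery rate is exactly
1.0, with no statistical tolerance. The error model is general edits by
default; a substitutions-only mode is provided because transcription-error
channels differ and the choice is not dictated by the threat model.
A corollary worth noting: at $l = 0$ an exact-distance-$e>0$ perturbation
can *never* return the target itself, so the recovery rate there is
exactly 0; the informative quantity is the candidate-set size, whose
expectation under the sampler's enumerable single-edit distribution is
checked in the tests.

Targets are sampled uniformly with replacement (the simplest unbiased
estimator); all randomness flows from one seed, so experiments are exactly
reproducible.

## Linkage: evidence, confidence, merging

Strong evidence is an exact post-normalization match on an
identifier-class attribute — email (case-folded), phone (digits only, with
`phone`/`home_phone`/`cell_phone` pooled, since the same number appears
under different labels across sources), username (name-normalized). Weak
evidence is consistency of gender, location, and age: equal ages, equal
birthdates, or a birthdate within ±1 year (default slack) of a self-reported
age at the configured reference date — self-reported ages have unknown
observation dates, hence the slack.

Evidence combines by noisy-or, $1 - \prod_i (1 - w_i)$: independent weak
signals accumulate, no single signal is decisive, and adding evidence never
lowers confidence. The default weights (email 0.95, phone 0.95, username
0.7, weak 0.3) encode the usual identifier-strength ranking — email and
phone near-unique, usernames relatively unique — and are configuration, not
empirical claims; no published value exists for the "certain confidence
level" at which two forum profiles are linkable, so the threshold is
likewise a config parameter (default 0.5). Note the interaction with the
default weights: three weak signals reach $1 - 0.7^3 \approx 0.657$, so at
threshold 0.5 purely demographic coincidences can link profiles within a
small town. That is faithful to the small-town argument (a quasi-identifier
match in a 15k-person town *is* evidence), but for precision-critical use a
threshold of 0.7 restricts links to identifier-backed ones; the
ground-truth tests exercise both regimes. A conceivable refinement —
scaling a weak signal's weight by the rarity of the matched tuple in a
reference population — is not implemented; per-attribute weights are fully
configurable, which covers the same need explicitly.

Merging is the transitive closure (connected components, via igraph) of
links at or above the threshold — chosen because the demonstration scenario
links its five profiles in a chain, not a clique. The output is always a
partition of the input profiles; raising the threshold only refines it.
Single-valued attributes that disagree inside a component are recorded as
conflicts, with the primary value taken from the highest-priority source;
emails, phones and usernames are treated as multi-valued and accumulate.

Inference is deliberately minimal: a fixed spousal-term rule list
("my husband" ⇒ female, "my wife" ⇒ male) plus birthdate→age arithmetic.
Free-text NLP and statistical inference of attributes are out of scope.

## The synthetic world

The generators state a world; they are not tuned to any empirical target.

* **Names**: bundled lexicons of ~130 female, ~130 male given names and
  ~240 surnames, frequency-ordered, sampled under a Zipf rank-frequency law
  with exponent 1 — the classic first-order approximation for personal-name
  frequencies. Exponent and lexicons are user-replaceable.
* **Population defaults**: one town of notional size 15,000 (the
  small-town setting of the motivating scenario), balanced gender,
  birthdates uniform over 1930–1999, unique 10-digit phone numbers.
* **Phonebook coverage** defaults to 0.64 — residential phonebooks cover
  only part of a population — with the subset size fixed as
  `round(coverage * n)` under round-half-to-even for cross-platform
  determinism.
* **Profiles**: per-source attribute subsets, independent per-attribute
  disclosure probabilities, typos as single edits at distance exactly 1
  (composable with the adversary's exact-distance semantics), and a
  per-person canonical username shared across sources with configurable
  probability. The identity map returned alongside is the ground truth for
  precision/recall.
* **Reference date**: profile ages are computed at a configurable "crawl
  date" (default 2011-11-24) so that birthdate-vs-age consistency is
  well-defined.

What the generator does **not** emulate: real name-frequency tails and
cultural mixtures, household structure (beyond a spouse field),
geographically correlated surnames, account-name idiosyncrasies. A green
test therefore establishes that the *metrics and attacks behave as
specified* (reductions, monotonicities, oracle equalities, recovery
guarantees, ground-truth recovery), not that any particular real population
exhibits a particular uniqueness level; empirical fractions reported on
synthetic worlds characterize those worlds only. In particular, the
uniqueness of a ~300×240-name synthetic lexicon world is well below what
real phonebooks show, because the true name distribution has a far heavier
tail of rare names — the package measures, it does not extrapolate.

## Degenerate inputs and edge behavior

Empty datasets are legal everywhere they can be answered coherently
(`kl_profile` returns an empty profile; `satisfies_kl` is vacuously true;
histograms and uniqueness on empty data are errors, as there is nothing to
summarize). Duplicate identifier values count as neighbors of each other at
every threshold — the only reading under which the $l=0$ reduction holds.
Missing values round-trip CSV as empty fields; fields being indexed or
profiled must be complete, and the error says so rather than silently
dropping records.

## Known limitations

* Weak-evidence false positives are inherent at default weights in small
  populations; precision-sensitive analyses should raise the threshold or
  supply rarity weighting.
* The CLI's config files are JSON (no YAML parser among the package's
  dependencies).
* No phonetic or keyboard-adjacency error models; distances are purely
  Levenshtein.
* The toolkit measures risk; it does not anonymize.
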