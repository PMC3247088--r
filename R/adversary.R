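#' @name adversary-module
#' @title Simulating the approximate-knowledge attacker
#'
#' @description
#' Models an adversary who overheard, misread or transcribed a target's
#' name and therefore holds a version of it that is wrong by some number of
#' edits. [perturb()] produces a string at an exact Levenshtein distance e
#' from the truth (verified internally by dynamic programming);
#' [attack_once()] runs one lookup of the perturbed name against an indexed
#' dataset at threshold l; [recovery_experiment()] repeats the attack over
#' seeded random targets and reports the recovery rate and the distribution
#' of candidate-set sizes. Because perturbations are at distance exactly e,
#' the triangle inequality guarantees recovery whenever e <= l.
NULL

ALPHABET <- letters

apply_random_edit <- function(cp, ops) {
  n <- length(cp)
  choices <- if (identical(ops, "substitution")) {
    if (n == 0L) stop_privrisk("cannot substitute in an empty string")
    "sub"
  } else {
    if (n == 0L) "ins" else c("ins", "del", "sub")
  }
  op <- if (length(choices) == 1L) choices else sample(choices, 1L)
  ch <- utf8ToInt(sample(ALPHABET, 1L))
  switch(op,
    ins = append(cp, ch, after = sample.int(n + 1L, 1L) - 1L),
    del = cp[-sample.int(n, 1L)],
    sub = { cp[sample.int(n, 1L)] <- ch; cp })
}

#' Perturb a name to an exact edit distance
#'
#' Applies `e` random single-character edits (insertion / deletion /
#' substitution at a uniform position, replacement characters drawn from
#' the lowercase alphabet) and rejection-resamples until the result is at
#' Levenshtein distance exactly `e` from the input, verified by the full
#' dynamic program. Deterministic given `seed`.
#'
#' @param name the true string; must be non-empty when `e > 0` unless
#'   insertions can reach distance `e`.
#' @param e non-negative integer: the exact number of edit errors.
#' @param seed optional integer seed; `NULL` draws from the current RNG
#'   stream.
#' @param ops `"any"` (default) or `"substitution"` for a
#'   substitutions-only error model.
#' @param max_attempts rejection-sampling budget before giving up.
#' @return A string with `levenshtein(name, result) == e`.
#' @export
perturb <- function(name, e, seed = NULL, ops = c("any", "substitution"),
                    max_attempts = 1000L) {
  ops <- match.arg(ops)
  e <- as.integer(e)
  if (length(e) != 1L || is.na(e) || e < 0L)
    stop_privrisk("e must be a single non-negative integer")
  name <- as.character(name)
  if (length(name) != 1L || is.na(name)) stop_privrisk("name must be one string")
  if (e == 0L) return(name)
  if (ops == "substitution" && e > nchar(name))
    stop_privrisk(sprintf("cannot reach distance %d by substitutions in a %d-char string",
                          e, nchar(name)))
  with_seed(seed, {
    orig <- utf8ToInt(name)
    for (attempt in seq_len(max_attempts)) {
      cp <- orig
      for (i in seq_len(e)) cp <- apply_random_edit(cp, if (ops == "substitution") "substitution" else "any")
      cand <- intToUtf8(cp)
      if (lev_pairs_cpp(list(orig), list(cp))[1] == e) return(cand)
    }
    stop_privrisk(sprintf("could not reach exact distance %d from '%s' in %d attempts",
                          e, name, max_attempts))
  })
}

#' One attack: look up a perturbed identifier
#'
#' Perturbs the target's field value to exact distance `e`, then retrieves
#' every record within distance `l` of the perturbed string. When
#' `e <= l` the target is guaranteed to be among the candidates.
#'
#' @param md a `microdata` object.
#' @param field identifier attribute to attack.
#' @param target record id of the target.
#' @param e exact perturbation distance (attacker error).
#' @param l search threshold used by the attacker.
#' @param seed optional integer seed for the perturbation.
#' @param idx optional prebuilt [build_index()] over `field` (avoids
#'   rebuilding in repeated attacks).
#' @param ops error model passed to [perturb()].
#' @return List with `candidates` (record ids, ascending distance then id),
#'   `hit` (is the target among them), and `perturbed` (the string used).
#' @export
attack_once <- function(md, field, target, e, l, seed = NULL, idx = NULL,
                        ops = "any") {
  if (is.null(idx)) idx <- build_index(md, field)
  pos <- match(target, idx$record_id)
  if (is.na(pos)) stop_privrisk(sprintf("unknown target record id: %s", target))
  perturbed <- perturb(idx$values[pos], e, seed = seed, ops = ops)
  candidates <- query_within(idx, perturbed, l)
  list(candidates = candidates, hit = target %in% candidates,
       perturbed = perturbed)
}

#' Repeated-attack recovery experiment
#'
#' Samples targets uniformly with replacement and mounts [attack_once()]
#' on each. Fully deterministic under `seed`.
#'
#' @inheritParams attack_once
#' @param n_trials number of attacks, >= 1.
#' @param seed integer seed for target sampling and perturbation.
#' @return A `recovery_stats` object: `n_trials`, `recovery_rate` (fraction
#'   of trials whose candidate set contained the true target),
#'   `candidate_size_dist` (named integer vector: candidate-set size ->
#'   trial count), plus the experiment parameters.
#' @export
recovery_experiment <- function(md, field, e, l, n_trials, seed = NULL,
                                ops = "any") {
  n <- n_records(md)
  if (n == 0L) stop_privrisk("empty dataset")
  n_trials <- as.integer(n_trials)
  if (length(n_trials) != 1L || is.na(n_trials) || n_trials < 1L)
    stop_privrisk("n_trials must be a single integer >= 1")
  idx <- build_index(md, field)
  with_seed(seed, {
    targets <- sample.int(n, n_trials, replace = TRUE)
    hits <- logical(n_trials)
    sizes <- integer(n_trials)
    for (i in seq_len(n_trials)) {
      res <- attack_once(md, field, md$record_id[targets[i]], e, l,
                         seed = NULL, idx = idx, ops = ops)
      hits[i] <- res$hit
      sizes[i] <- length(res$candidates)
    }
    tab <- table(sizes)
    structure(list(field = field, e = as.integer(e), l = as.integer(l),
                   n_trials = n_trials,
                   recovery_rate = mean(hits),
                   candidate_size_dist = stats::setNames(as.integer(tab), names(tab))),
              class = "recovery_stats")
  })
}

#' @export
frac_at_most.recovery_stats <- function(x, m) {
  sizes <- as.integer(names(x$candidate_size_dist))
  sum(x$candidate_size_dist[sizes <= m]) / x$n_trials
}

#' @export
print.recovery_stats <- function(x, ...) {
  cat(sprintf("<recovery_stats: e = %d, l = %d, %d trials>\n", x$e, x$l, x$n_trials))
  cat(sprintf("  recovery rate: %.3f\n", x$recovery_rate))
  cat(sprintf("  candidate sets of size <= 5: %.1f%%\n", 100 * frac_at_most(x, 5L)))
  invisible(x)
}
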