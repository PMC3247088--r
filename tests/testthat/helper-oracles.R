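# Independent oracles and small fixture builders.
#
# The brute-force Levenshtein oracle is base R's utils::adist (generalized
# edit distance with unit costs), kept deliberately separate from the
# package's own C++ kernel so every distance-dependent result can be
# checked through two independent routes.

oracle_lev <- function(a, b) {
  as.integer(utils::adist(a, b))
}

# Full O(n^2) scan: per-record k values at threshold l.
oracle_kl <- function(values, l) {
  d <- utils::adist(values, values)
  as.integer(rowSums(d <= l))
}

# Full scan neighborhood query.
oracle_query <- function(values, record_ids, query, l) {
  d <- as.integer(utils::adist(query, values))
  keep <- which(d <= l)
  ids <- record_ids[keep]
  ids[order(d[keep], ids, method = "radix")]
}

random_strings <- function(n, min_len = 0, max_len = 8,
                           alphabet = letters[1:6]) {
  vapply(seq_len(n), function(i) {
    len <- sample(min_len:max_len, 1)
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# Minimal one-field microdata holding a vector of name strings.
names_md <- function(values, field = "name") {
  df <- data.frame(v = as.character(values), stringsAsFactors = FALSE)
  names(df) <- field
  args <- list(c("identifier", "text"))
  names(args) <- field
  microdata(df, do.call(attribute_schema, args))
}

# All strings at Levenshtein distance exactly 1 from `name` over `alphabet`
# (single insertions, deletions, substitutions; exact duplicates and the
# original removed).
enumerate_dist1 <- function(name, alphabet = letters) {
  cp <- strsplit(name, "")[[1]]
  n <- length(cp)
  out <- character(0)
  for (pos in 0:n) for (ch in alphabet)
    out <- c(out, paste(append(cp, ch, after = pos), collapse = ""))
  if (n > 0) for (pos in 1:n) {
    out <- c(out, paste(cp[-pos], collapse = ""))
    for (ch in alphabet) {
      s <- cp; s[pos] <- ch
      out <- c(out, paste(s, collapse = ""))
    }
  }
  setdiff(unique(out), name)
}

# Exact single-edit outcome distribution of the package's perturbation
# sampler for e = 1, ops = "any", on a non-empty name: enumerates every
# (operation, position, character) draw, accumulates raw probabilities per
# resulting string, drops distance-0 outcomes (the sampler rejects them)
# and renormalizes.
perturb1_distribution <- function(name, alphabet = letters) {
  cp <- strsplit(name, "")[[1]]
  n <- length(cp)
  probs <- new.env(parent = emptyenv())
  add <- function(s, p) {
    cur <- if (exists(s, envir = probs, inherits = FALSE))
      get(s, envir = probs) else 0
    assign(s, cur + p, envir = probs)
  }
  p_op <- 1 / 3
  for (pos in 0:n) for (ch in alphabet)
    add(paste(append(cp, ch, after = pos), collapse = ""),
        p_op / ((n + 1) * length(alphabet)))
  for (pos in 1:n)
    add(paste(cp[-pos], collapse = ""), p_op / n)
  for (pos in 1:n) for (ch in alphabet)
    add(paste(`[<-`(cp, pos, ch), collapse = ""),
        p_op / (n * length(alphabet)))
  out <- unlist(as.list(probs))
  out <- out[names(out) != name]   # rejected: distance 0
  out / sum(out)
}
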