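#' @name strdist-module
#' @title Edit distance and neighborhood search
#'
#' @description
#' The distance function underlying k-l-anonymity is the Levenshtein (edit)
#' distance: the minimum number of single-character insertions, deletions
#' and substitutions transforming one string into the other. The unit of
#' edit is the Unicode code point, applied after name normalization, so
#' results are platform-independent. [build_index()] builds a neighborhood
#' index over one attribute of a microdata table; [query_within()] returns
#' exactly the records a full scan would return (the index is a speed-up
#' with length-difference pruning and banded dynamic programming, never an
#' approximation).
NULL

#' Levenshtein edit distance
#'
#' Vectorized over `a` and `b` (recycled to a common length).
#'
#' @param a,b character vectors.
#' @return Integer vector of edit distances; `NA` inputs give `NA`.
#' @examples
#' levenshtein("kitten", "sitting")  # 3
#' @export
levenshtein <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- max(length(a), length(b))
  if (n == 0L) return(integer(0))
  a <- rep_len(a, n); b <- rep_len(b, n)
  out <- rep(NA_integer_, n)
  ok <- !is.na(a) & !is.na(b)
  if (any(ok))
    out[ok] <- lev_pairs_cpp(lapply(a[ok], utf8ToInt), lapply(b[ok], utf8ToInt))
  out
}

#' Name normalization policy
#'
#' Default: case-fold, strip apostrophes/hyphens/periods, collapse internal
#' whitespace and trim. Phonebook and profile names vary in punctuation;
#' distances are intended to measure spelling, not typography.
#'
#' @param case_fold lower-case the string.
#' @param strip regex character class of characters to remove.
#' @param collapse_whitespace collapse runs of whitespace to one space and
#'   trim the ends.
#' @return A `norm_policy` object.
#' @export
norm_policy <- function(case_fold = TRUE, strip = "['’.-]",
                        collapse_whitespace = TRUE) {
  structure(list(case_fold = case_fold, strip = strip,
                 collapse_whitespace = collapse_whitespace),
            class = "norm_policy")
}

#' Normalize a raw name string
#'
#' Idempotent: `normalize_name(normalize_name(x)) == normalize_name(x)`.
#'
#' @param raw character vector.
#' @param policy a [norm_policy()].
#' @return Normalized character vector.
#' @examples
#' normalize_name("  O'Brien ")  # "obrien"
#' @export
normalize_name <- function(raw, policy = norm_policy()) {
  stopifnot(inherits(policy, "norm_policy"))
  x <- as.character(raw)
  if (policy$case_fold) x <- tolower(x)
  if (nzchar(policy$strip)) x <- gsub(policy$strip, "", x, perl = TRUE)
  if (policy$collapse_whitespace) {
    x <- gsub("[[:space:]]+", " ", x)
    x <- trimws(x)
  }
  x
}

#' Build a Levenshtein neighborhood index over one attribute
#'
#' @param md a `microdata` object; the field's values are taken as-is
#'   (normalize first if desired) and must be non-missing.
#' @param field attribute name holding text values.
#' @return A `neighbor_index` object.
#' @export
build_index <- function(md, field) {
  values <- md_values(md, field)
  if (anyNA(values))
    stop_privrisk(sprintf("field '%s' has missing values; cannot index", field))
  values <- as.character(values)
  uniq <- unique(values)
  grp <- match(values, uniq)
  structure(list(field = field,
                 record_id = md$record_id,
                 values = values,
                 uniq = uniq,
                 grp = grp,
                 cp = lapply(uniq, utf8ToInt)),
            class = "neighbor_index")
}

#' @export
print.neighbor_index <- function(x, ...) {
  cat(sprintf("<neighbor_index on '%s': %d records, %d distinct values>\n",
              x$field, length(x$values), length(x$uniq)))
  invisible(x)
}

# Distances from a query to every distinct indexed value; l+1 means "> l".
index_query_dists <- function(idx, query, l) {
  if (length(idx$uniq) == 0L) return(integer(0))
  lev_query_cpp(utf8ToInt(as.character(query)), idx$cp, as.integer(l))
}

#' Records whose indexed value lies within edit distance l of a query
#'
#' Result is exactly the set a brute-force scan would return and is
#' monotonically non-decreasing (as a set) in `l`.
#'
#' @param idx a `neighbor_index` from [build_index()].
#' @param query query string.
#' @param l non-negative integer distance threshold.
#' @return Character vector of record ids, sorted by ascending distance and
#'   then record id.
#' @export
query_within <- function(idx, query, l) {
  stopifnot(inherits(idx, "neighbor_index"))
  l <- as.integer(l)
  if (length(l) != 1L || is.na(l) || l < 0L)
    stop_privrisk("l must be a single non-negative integer")
  d_uniq <- index_query_dists(idx, query, l)
  d_rec <- d_uniq[idx$grp]
  keep <- which(d_rec <= l)
  if (length(keep) == 0L) return(character(0))
  ids <- idx$record_id[keep]
  ids[order(d_rec[keep], ids, method = "radix")]
}
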