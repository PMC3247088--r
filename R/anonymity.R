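#' @name anonymity-module
#' @title k-anonymity, k-l-anonymity, and quasi-identifier uniqueness
#'
#' @description
#' A record is k-anonymous on a quasi-identifier set when at least k - 1
#' other records share its exact projected tuple. k-l-anonymity relaxes
#' exact equality to edit-distance proximity on an identifier field: a
#' record's k counts itself plus every other record whose value lies within
#' Levenshtein distance l, so k = 1 means "uniquely identifiable even by an
#' attacker whose knowledge is wrong by up to l edits". At l = 0 the two
#' notions coincide. [risk_sweep()] profiles a table across thresholds and
#' [k_histogram()] summarizes a profile as the distribution of k.
NULL

qi_key <- function(proj) {
  if (ncol(proj) == 0L) return(rep("", nrow(proj)))
  cols <- lapply(proj, function(col) {
    col <- as.character(col)
    col[is.na(col)] <- "\r<NA>\r"
    col
  })
  do.call(paste, c(cols, sep = "\x1f"))
}

#' Exact-match equivalence classes on a quasi-identifier set
#'
#' @param md a `microdata` object.
#' @param qi_attrs character vector of quasi-identifier attribute names.
#' @return A data frame with the projected attribute columns plus
#'   `class_size`, one row per equivalence class, in order of first
#'   appearance. Class sizes sum to `n_records(md)`. Missing values compare
#'   equal to each other.
#' @export
k_anonymity_classes <- function(md, qi_attrs) {
  proj <- project(md, qi_attrs)
  key <- qi_key(proj)
  first <- !duplicated(key)
  out <- proj[first, , drop = FALSE]
  rownames(out) <- NULL
  out$class_size <- as.integer(table(key)[key[first]])
  out
}

#' Per-record k values under an edit-distance threshold
#'
#' For each record r, `k(r) = 1 + #\{x != r : dist(value(r), value(x)) <= l\}`
#' on the given field. Duplicate values count: two identical names are each
#' other's neighbor even at l = 0, which is exactly what makes the l = 0
#' case reduce to classic k-anonymity class sizes.
#'
#' @param md a `microdata` object.
#' @param field attribute holding (normalized) text values, no missing.
#' @param l non-negative integer edit-distance threshold.
#' @return An `anonymity_profile`: field, l, and `k_values` (named integer
#'   vector, one entry per record id).
#' @export
kl_profile <- function(md, field, l) {
  l <- as.integer(l)
  if (length(l) != 1L || is.na(l) || l < 0L)
    stop_privrisk("l must be a single non-negative integer")
  values <- md_values(md, field)
  if (anyNA(values))
    stop_privrisk(sprintf("field '%s' has missing values", field))
  values <- as.character(values)
  k <- kl_k_matrix(values, l)[, l + 1L]
  new_anonymity_profile(field, l, stats::setNames(as.integer(k), md$record_id))
}

# k values for all thresholds 0..max_l at once; returns n x (max_l+1) matrix.
kl_k_matrix <- function(values, max_l) {
  if (length(values) == 0L)
    return(matrix(integer(0), nrow = 0L, ncol = max_l + 1L))
  uniq <- unique(values)
  grp <- match(values, uniq)
  counts <- tabulate(grp, nbins = length(uniq))
  mat <- kl_counts_cpp(lapply(uniq, utf8ToInt), as.integer(counts),
                       as.integer(max_l))
  mat[grp, , drop = FALSE]
}

new_anonymity_profile <- function(field, l, k_values) {
  structure(list(field = field, l = l, k_values = k_values),
            class = "anonymity_profile")
}

#' @export
print.anonymity_profile <- function(x, ...) {
  n <- length(x$k_values)
  cat(sprintf("<anonymity_profile on '%s', l = %d: %d records, %.1f%% with k = 1>\n",
              x$field, x$l, n,
              if (n) 100 * mean(x$k_values == 1L) else NA_real_))
  invisible(x)
}

#' Does a dataset satisfy k-l-anonymity?
#'
#' Universal reading: every record must have at least k - 1 neighbors
#' within distance l. `k = 1` is always satisfied.
#'
#' @inheritParams kl_profile
#' @param k required anonymity level, integer >= 1.
#' @return `TRUE` or `FALSE` (vacuously `TRUE` on an empty dataset).
#' @export
satisfies_kl <- function(md, field, k, l) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L)
    stop_privrisk("k must be a single integer >= 1")
  prof <- kl_profile(md, field, l)
  if (length(prof$k_values) == 0L) return(TRUE)
  min(prof$k_values) >= k
}

#' Histogram of k values
#'
#' The first bar (k = 1) is the uniquely identifiable fraction of the
#' population under the profile's threshold.
#'
#' @param profile an `anonymity_profile` from [kl_profile()].
#' @return A `k_histogram`: `counts` (named integer vector, names are k),
#'   `n`, `unique_fraction`.
#' @export
k_histogram <- function(profile) {
  stopifnot(inherits(profile, "anonymity_profile"))
  kv <- profile$k_values
  if (length(kv) == 0L) stop_privrisk("empty profile: no records to histogram")
  tab <- table(kv)
  counts <- stats::setNames(as.integer(tab), names(tab))
  structure(list(field = profile$field, l = profile$l, counts = counts,
                 n = length(kv),
                 unique_fraction = sum(kv == 1L) / length(kv)),
            class = "k_histogram")
}

#' @export
print.k_histogram <- function(x, ...) {
  cat(sprintf("<k_histogram on '%s', l = %d: n = %d, unique fraction %.3f>\n",
              x$field, x$l, x$n, x$unique_fraction))
  invisible(x)
}

#' Fraction of a distribution at or below a cutoff
#'
#' For a [k_histogram()], the fraction of records with k <= m (how much of
#' the population an attacker pins to at most m candidates); for
#' [recovery_experiment()] stats, the fraction of trials whose candidate
#' set had at most m members.
#'
#' @param x a `k_histogram` or `recovery_stats` object.
#' @param m non-negative integer cutoff.
#' @return A fraction in `[0, 1]`.
#' @export
frac_at_most <- function(x, m) UseMethod("frac_at_most")

#' @export
frac_at_most.k_histogram <- function(x, m) {
  ks <- as.integer(names(x$counts))
  sum(x$counts[ks <= m]) / x$n
}

#' Fraction of records with a unique quasi-identifier tuple
#'
#' @param md a non-empty `microdata` object.
#' @param qi_attrs character vector of quasi-identifier attribute names.
#' @return Fraction in `[0, 1]` of records whose projected tuple occurs
#'   exactly once.
#' @export
uniqueness_fraction <- function(md, qi_attrs) {
  if (n_records(md) == 0L) stop_privrisk("empty dataset")
  key <- qi_key(project(md, qi_attrs))
  tab <- table(key)
  mean(tab[key] == 1L)
}

#' Anonymity histograms across a sweep of distance thresholds
#'
#' One [k_histogram()] per distinct threshold. Per record, k is
#' non-decreasing in l, hence the unique fraction is non-increasing:
#' the more wrong an attacker is allowed to be, the less identifiable
#' people are -- but also the larger every candidate set.
#'
#' @inheritParams kl_profile
#' @param l_values non-empty vector of non-negative integer thresholds
#'   (duplicates are dropped).
#' @return Named list of `k_histogram` objects, names are the thresholds in
#'   increasing order.
#' @export
risk_sweep <- function(md, field, l_values) {
  l_values <- sort(unique(as.integer(l_values)))
  if (length(l_values) == 0L || anyNA(l_values) || any(l_values < 0L))
    stop_privrisk("l_values must be non-empty non-negative integers")
  values <- md_values(md, field)
  if (anyNA(values))
    stop_privrisk(sprintf("field '%s' has missing values", field))
  kmat <- kl_k_matrix(as.character(values), max(l_values))
  out <- lapply(l_values, function(l) {
    prof <- new_anonymity_profile(field, l,
      stats::setNames(as.integer(kmat[, l + 1L]), md$record_id))
    k_histogram(prof)
  })
  stats::setNames(out, as.character(l_values))
}
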