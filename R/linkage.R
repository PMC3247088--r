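#' @name linkage-module
#' @title Cross-source profile linkage: attribution, inference, aggregation
#'
#' @description
#' The linkage attack reconstructs a dossier on an individual from partial
#' profiles scattered across sources (social networks, web directories,
#' phonebooks). It proceeds in three stages. Attribution: each source
#' contributes a [profile()] of declared attributes. Inference:
#' [infer_attributes()] derives further attributes by logical rules (a
#' mention of "my husband" implies the owner is female; a birthdate plus a
#' reference date yields an age). Aggregation: profile pairs are scored by
#' [match_strong()] (exact matches on identifier-class attributes: email,
#' phone, username) and [match_weak()] (consistency of gender, location,
#' age/birthdate), combined into a noisy-or confidence by
#' [link_confidence()]; links above a threshold are merged transitively by
#' [aggregate_profiles()] into provenance-annotated dossiers.
NULL

# Attributes that may legitimately take several values per person; a second
# distinct value is accumulated, not flagged as a conflict.
MULTI_VALUED_ATTRS <- c("email", "phone", "home_phone", "cell_phone",
                        "username", "free_text")
PHONE_ATTRS <- c("phone", "home_phone", "cell_phone")

#' Construct a profile
#'
#' @param profile_id unique token.
#' @param source label of the source the profile came from.
#' @param ... named attributes (e.g. `username`, `email`, `phone`,
#'   `home_phone`, `gender`, `location`, `birthdate`, `age`, `full_name`,
#'   `occupation`, `free_text`, ...); at least one, `NA`s dropped.
#' @return A `profile` object.
#' @export
profile <- function(profile_id, source, ...) {
  attrs <- list(...)
  attrs <- attrs[!vapply(attrs, function(v) length(v) != 1L || is.na(v), logical(1))]
  if (length(attrs) == 0L)
    stop_privrisk("a profile needs at least one non-missing attribute")
  if (is.null(names(attrs)) || any(!nzchar(names(attrs))))
    stop_privrisk("profile attributes must be named")
  structure(list(profile_id = as.character(profile_id),
                 source = as.character(source),
                 attrs = attrs),
            class = "profile")
}

#' @export
print.profile <- function(x, ...) {
  cat(sprintf("<profile %s [%s]: %s>\n", x$profile_id, x$source,
              paste(names(x$attrs), collapse = ", ")))
  invisible(x)
}

p_attr <- function(p, name) {
  v <- p$attrs[[name]]
  if (is.null(v) || (length(v) == 1L && is.na(v))) NULL else v
}

normalize_email <- function(x) tolower(trimws(x))
normalize_phone <- function(x) gsub("[^0-9]", "", x)

profile_phones <- function(p) {
  v <- unlist(lapply(PHONE_ATTRS, function(a) p_attr(p, a)), use.names = FALSE)
  unique(normalize_phone(v[!is.na(v)]))
}

#' Default logical inference rules
#'
#' Each rule is `list(attribute, pattern, value)`: when `pattern` (a regex,
#' case-insensitive) matches the profile's `free_text` and `attribute` is
#' absent, it is set to `value`. The built-ins encode spousal-term gender
#' inference.
#'
#' @return A list of rules for [infer_attributes()].
#' @export
default_inference_rules <- function() {
  list(
    list(attribute = "gender", pattern = "\\bmy husband\\b", value = "female"),
    list(attribute = "gender", pattern = "\\bmy wife\\b", value = "male")
  )
}

validate_rules <- function(rules) {
  for (i in seq_along(rules)) {
    r <- rules[[i]]
    if (!is.list(r) || !all(c("attribute", "pattern", "value") %in% names(r)) ||
        !is.character(r$attribute) || !nzchar(r$attribute) ||
        !is.character(r$pattern) || !nzchar(r$pattern))
      stop_privrisk(sprintf("malformed inference rule at position %d", i))
    ok <- tryCatch({ grepl(r$pattern, "", perl = TRUE); TRUE },
                   error = function(e) FALSE)
    if (!ok)
      stop_privrisk(sprintf("malformed regex in inference rule %d: %s", i, r$pattern))
  }
  rules
}

# Completed years between two ISO dates.
age_at <- function(birthdate, reference_date) {
  b <- as.Date(birthdate); r <- as.Date(reference_date)
  if (is.na(b) || is.na(r)) return(NA_integer_)
  by <- as.integer(format(b, "%Y")); ry <- as.integer(format(r, "%Y"))
  had_birthday <- format(r, "%m-%d") >= format(b, "%m-%d")
  as.integer(ry - by - !had_birthday)
}

#' Infer attributes by logical reasoning
#'
#' Applies the rule set to `free_text` and derives `age` from `birthdate`
#' at `reference_date`. Never overwrites an explicitly present attribute.
#'
#' @param p a [profile()].
#' @param rules rule set, validated at load; see
#'   [default_inference_rules()].
#' @param reference_date ISO date at which ages are computed (e.g. the
#'   crawl date); `NULL` skips age derivation.
#' @return An augmented copy of `p`.
#' @export
infer_attributes <- function(p, rules = default_inference_rules(),
                             reference_date = NULL) {
  stopifnot(inherits(p, "profile"))
  rules <- validate_rules(rules)
  txt <- p_attr(p, "free_text")
  if (!is.null(txt)) {
    for (r in rules) {
      if (is.null(p_attr(p, r$attribute)) &&
          grepl(r$pattern, txt, ignore.case = TRUE, perl = TRUE))
        p$attrs[[r$attribute]] <- r$value
    }
  }
  if (!is.null(reference_date) && is.null(p_attr(p, "age")) &&
      !is.null(p_attr(p, "birthdate"))) {
    a <- age_at(p_attr(p, "birthdate"), reference_date)
    if (!is.na(a)) p$attrs[["age"]] <- a
  }
  p
}

new_evidence <- function(kind, attribute, detail, weight) {
  if (!is.numeric(weight) || length(weight) != 1L || is.na(weight) ||
      weight <= 0 || weight > 1)
    stop_privrisk(sprintf("evidence weight for '%s' must be in (0, 1]", attribute))
  structure(list(kind = kind, attribute = attribute, detail = detail,
                 weight = weight),
            class = "evidence")
}

#' Strong evidence: exact matches on identifier-class attributes
#'
#' One piece of strong evidence per identifier-class attribute (email,
#' phone, username) that matches exactly after normalization (emails
#' case-folded, phones reduced to digits, usernames name-normalized). All
#' phone-bearing attributes (`phone`, `home_phone`, `cell_phone`) are
#' pooled: any shared number is a phone match.
#'
#' @param p,q [profile()] objects.
#' @param weights named list of per-attribute weights; see [link_config()].
#' @return List of `evidence` objects (possibly empty).
#' @export
match_strong <- function(p, q, weights = link_config()$weights) {
  ev <- list()
  pe <- p_attr(p, "email"); qe <- p_attr(q, "email")
  if (!is.null(pe) && !is.null(qe) && normalize_email(pe) == normalize_email(qe))
    ev <- c(ev, list(new_evidence("strong", "email",
      sprintf("identical email '%s'", normalize_email(pe)), weights$email)))
  shared <- intersect(profile_phones(p), profile_phones(q))
  if (length(shared))
    ev <- c(ev, list(new_evidence("strong", "phone",
      sprintf("shared phone number(s) %s", paste(shared, collapse = ", ")),
      weights$phone)))
  pu <- p_attr(p, "username"); qu <- p_attr(q, "username")
  if (!is.null(pu) && !is.null(qu) &&
      normalize_name(pu) == normalize_name(qu))
    ev <- c(ev, list(new_evidence("strong", "username",
      sprintf("identical username '%s'", normalize_name(pu)), weights$username)))
  ev
}

#' Weak evidence: consistency of quasi-identifying attributes
#'
#' Weak evidence accrues for: equal gender; equal normalized location;
#' age consistency (equal ages, equal birthdates, or a birthdate on one
#' side within `age_slack` years of the age on the other, computed at
#' `reference_date`). Attributes missing on either side contribute
#' nothing; disagreeing attributes contribute nothing here and surface as
#' conflicts at merge time.
#'
#' @param p,q [profile()] objects (run [infer_attributes()] first if
#'   inferred gender/age should count).
#' @param tolerances list with `age_slack` (years, default 1).
#' @param reference_date ISO date for birthdate-vs-age comparison.
#' @param weight weight of each piece of weak evidence.
#' @return List of `evidence` objects (possibly empty).
#' @export
match_weak <- function(p, q, tolerances = list(age_slack = 1),
                       reference_date = NULL,
                       weight = link_config()$weights$weak) {
  slack <- tolerances$age_slack %||% 1
  ev <- list()
  pg <- p_attr(p, "gender"); qg <- p_attr(q, "gender")
  if (!is.null(pg) && !is.null(qg) && tolower(pg) == tolower(qg))
    ev <- c(ev, list(new_evidence("weak", "gender",
      sprintf("gender '%s' agrees", tolower(pg)), weight)))
  pl <- p_attr(p, "location"); ql <- p_attr(q, "location")
  if (!is.null(pl) && !is.null(ql) &&
      normalize_name(pl) == normalize_name(ql))
    ev <- c(ev, list(new_evidence("weak", "location",
      sprintf("same location '%s'", normalize_name(pl)), weight)))
  age_ev <- age_consistency(p, q, slack, reference_date)
  if (!is.null(age_ev)) ev <- c(ev, list(new_evidence("weak", "age", age_ev, weight)))
  ev
}

age_consistency <- function(p, q, slack, reference_date) {
  pb <- p_attr(p, "birthdate"); qb <- p_attr(q, "birthdate")
  pa <- p_attr(p, "age"); qa <- p_attr(q, "age")
  if (!is.null(pb) && !is.null(qb)) {
    if (identical(as.Date(pb), as.Date(qb)))
      return(sprintf("identical birthdate %s", pb))
    return(NULL)
  }
  if (!is.null(pa) && !is.null(qa)) {
    if (as.integer(pa) == as.integer(qa))
      return(sprintf("equal age %s", pa))
    return(NULL)
  }
  if (!is.null(reference_date)) {
    chk <- function(bd, age) {
      a <- age_at(bd, reference_date)
      if (!is.na(a) && abs(a - as.integer(age)) <= slack)
        sprintf("birthdate %s consistent with age %s (+/- %s yr)", bd, age, slack)
      else NULL
    }
    if (!is.null(pb) && !is.null(qa)) return(chk(pb, qa))
    if (!is.null(qb) && !is.null(pa)) return(chk(qb, pa))
  }
  NULL
}

#' Combine evidence weights into a link confidence
#'
#' Noisy-or: `1 - prod(1 - w_i)`. Empty evidence gives 0; adding evidence
#' never lowers the confidence.
#'
#' @param evidences list of evidence objects (or bare weights in (0, 1]).
#' @return A number in `[0, 1]`.
#' @export
link_confidence <- function(evidences) {
  if (length(evidences) == 0L) return(0)
  w <- vapply(evidences, function(e) {
    v <- if (inherits(e, "evidence")) e$weight else e
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0 || v > 1)
      stop_privrisk("evidence weight out of (0, 1]")
    as.numeric(v)
  }, numeric(1))
  1 - prod(1 - w)
}

#' Linkage configuration
#'
#' Defaults reflect the usual ranking of identifier strength: email and
#' phone numbers are near-unique identifiers (0.95), usernames are
#' relatively unique (0.7), and each weak consistency signal is mild
#' corroboration (0.3) -- three weak signals alone reach 1 - 0.7^3 ~ 0.66.
#'
#' @param weights named list: `email`, `phone`, `username`, `weak`.
#' @param threshold minimum confidence for a link to be reported/merged.
#' @param reference_date ISO date for age computations (crawl date).
#' @param age_slack years of slack in birthdate-vs-age consistency.
#' @param use_weak include weak evidence in scoring (`FALSE` = strong
#'   identifiers only).
#' @param infer run [infer_attributes()] on every profile before matching.
#' @param source_priority character vector of source labels; at merge time
#'   the primary value of a conflicted attribute comes from the earliest
#'   listed source.
#' @param rules inference rule set.
#' @return A `link_config` list.
#' @export
link_config <- function(weights = list(email = 0.95, phone = 0.95,
                                       username = 0.7, weak = 0.3),
                        threshold = 0.5, reference_date = NULL,
                        age_slack = 1, use_weak = TRUE, infer = TRUE,
                        source_priority = NULL,
                        rules = default_inference_rules()) {
  structure(list(weights = weights, threshold = threshold,
                 reference_date = reference_date, age_slack = age_slack,
                 use_weak = use_weak, infer = infer,
                 source_priority = source_priority, rules = rules),
            class = "link_config")
}

pair_evidence <- function(p, q, config) {
  ev <- match_strong(p, q, config$weights)
  if (isTRUE(config$use_weak))
    ev <- c(ev, match_weak(p, q, list(age_slack = config$age_slack),
                           config$reference_date, config$weights$weak))
  ev
}

#' Score all profile pairs and return the links above threshold
#'
#' Every unordered pair is scored; scoring is symmetric and independent of
#' input order. Results are sorted by confidence (descending), then by the
#' id pair.
#'
#' @param profiles list of [profile()] objects with distinct ids.
#' @param config a [link_config()].
#' @return List of `link_result` objects: `pair` (sorted id pair),
#'   `evidences`, `confidence`.
#' @export
link_all <- function(profiles, config = link_config()) {
  ids <- vapply(profiles, function(p) p$profile_id, character(1))
  if (anyDuplicated(ids))
    stop_privrisk(sprintf("duplicate profile id(s): %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (isTRUE(config$infer))
    profiles <- lapply(profiles, infer_attributes, rules = config$rules,
                       reference_date = config$reference_date)
  n <- length(profiles)
  links <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        ev <- pair_evidence(profiles[[i]], profiles[[j]], config)
        conf <- link_confidence(ev)
        if (conf >= config$threshold) {
          pair <- sort(c(ids[i], ids[j]))
          links[[length(links) + 1L]] <-
            structure(list(pair = pair, evidences = ev, confidence = conf),
                      class = "link_result")
        }
      }
    }
  }
  if (length(links)) {
    key <- vapply(links, function(l) paste(l$pair, collapse = "\x1f"), character(1))
    conf <- vapply(links, function(l) l$confidence, numeric(1))
    links <- links[order(-conf, key, method = "radix")]
  }
  links
}

#' @export
print.link_result <- function(x, ...) {
  cat(sprintf("<link %s -- %s: confidence %.3f (%s)>\n",
              x$pair[1], x$pair[2], x$confidence,
              paste(vapply(x$evidences, function(e) e$attribute, character(1)),
                    collapse = "+")))
  invisible(x)
}

source_rank <- function(sources, priority) {
  if (is.null(priority)) return(match(sources, unique(sources)))
  r <- match(sources, priority)
  r[is.na(r)] <- length(priority) + match(sources[is.na(r)], unique(sources))
  r
}

#' Merge linked profiles into dossiers
#'
#' Connected components of the link graph (edges: links with confidence at
#' or above the threshold) are merged: the output is always a partition of
#' the input profiles. Within a component, each attribute's distinct values
#' are collected with source provenance; the primary value is the first by
#' source priority. Single-valued attributes (gender, location, birthdate,
#' full name, ...) with more than one distinct value are recorded as
#' conflicts; multi-valued attributes (emails, phones, usernames) simply
#' accumulate.
#'
#' @param profiles list of [profile()] objects.
#' @param links output of [link_all()].
#' @param threshold minimum link confidence for an edge; defaults to using
#'   every supplied link.
#' @param source_priority optional character vector; see [link_config()].
#' @return List of `merged_profile` objects, ordered by their smallest
#'   member id: `members`, `attrs` (attribute -> list of
#'   `(value, sources)`), `primary` (attribute -> value), `conflicts`,
#'   `links`.
#' @export
aggregate_profiles <- function(profiles, links, threshold = 0,
                               source_priority = NULL) {
  ids <- vapply(profiles, function(p) p$profile_id, character(1))
  keep <- Filter(function(l) l$confidence >= threshold, links)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  igraph::V(g)$name <- ids
  if (length(keep)) {
    edges <- unlist(lapply(keep, function(l) l$pair))
    g <- igraph::add_edges(g, match(edges, ids))
  }
  comp <- igraph::components(g)$membership
  rank <- source_rank(vapply(profiles, function(p) p$source, character(1)),
                      source_priority)
  merged <- lapply(split(seq_along(profiles), comp), function(members) {
    members <- members[order(rank[members], ids[members])]
    mem_ids <- sort(ids[members])
    attrs <- list()
    for (m in members) {
      p <- profiles[[m]]
      for (a in names(p$attrs)) {
        v <- as.character(p$attrs[[a]])
        cur <- attrs[[a]] %||% list()
        found <- FALSE
        for (k in seq_along(cur)) {
          if (identical(cur[[k]]$value, v)) {
            cur[[k]]$sources <- unique(c(cur[[k]]$sources, p$source))
            found <- TRUE
          }
        }
        if (!found) cur[[length(cur) + 1L]] <- list(value = v, sources = p$source)
        attrs[[a]] <- cur
      }
    }
    attrs <- attrs[order(names(attrs))]
    primary <- lapply(attrs, function(vs) vs[[1]]$value)
    conflict_attrs <- names(attrs)[vapply(attrs, length, integer(1)) > 1L &
                                     !names(attrs) %in% MULTI_VALUED_ATTRS]
    conflicts <- lapply(conflict_attrs, function(a)
      list(attribute = a,
           values = vapply(attrs[[a]], function(v) v$value, character(1))))
    comp_links <- Filter(function(l) all(l$pair %in% mem_ids), keep)
    structure(list(members = mem_ids, attrs = attrs, primary = primary,
                   conflicts = conflicts, links = comp_links),
              class = "merged_profile")
  })
  first <- vapply(merged, function(m) m$members[1], character(1))
  unname(merged[order(first, method = "radix")])
}

#' @export
print.merged_profile <- function(x, ...) {
  cat(sprintf("<merged_profile: %d member(s) [%s], %d attribute(s), %d conflict(s)>\n",
              length(x$members), paste(x$members, collapse = ", "),
              length(x$attrs), length(x$conflicts)))
  invisible(x)
}

#' Structured dossier report for a merged profile
#'
#' Enumerates the recovered attribute types, all values with per-source
#' provenance, conflicts, and the evidence behind the component's links.
#' Serialization is deterministic (attributes sorted by name).
#'
#' @param m a `merged_profile` from [aggregate_profiles()].
#' @return A list suitable for JSON serialization: `members`,
#'   `attribute_types`, `attributes` (name -> values + sources),
#'   `conflicts`, `links`.
#' @export
dossier_report <- function(m) {
  stopifnot(inherits(m, "merged_profile"))
  attributes <- lapply(m$attrs, function(vs)
    lapply(vs, function(v) list(value = v$value, sources = as.list(v$sources))))
  links <- lapply(m$links, function(l)
    list(pair = as.list(l$pair), confidence = l$confidence,
         evidence = lapply(l$evidences, function(e)
           list(kind = e$kind, attribute = e$attribute, detail = e$detail,
                weight = e$weight))))
  list(members = as.list(m$members),
       attribute_types = as.list(names(m$attrs)),
       attributes = attributes,
       conflicts = lapply(m$conflicts, function(cf)
         list(attribute = cf$attribute, values = as.list(cf$values))),
       links = links)
}

#' Pairwise precision and recall of a merge against ground truth
#'
#' Predicted pairs are all profile pairs sharing a merged component; true
#' pairs are all profile pairs mapped to the same person by the identity
#' map.
#'
#' @param merged output of [aggregate_profiles()].
#' @param identity_map data frame with columns `profile_id`, `person_id`.
#' @return List with `precision`, `recall`, `n_pred_pairs`, `n_true_pairs`.
#'   Precision is 1 when nothing is predicted; recall is 1 when no true
#'   pairs exist.
#' @export
linkage_precision_recall <- function(merged, identity_map) {
  pairs_of <- function(groups) {
    out <- character(0)
    for (g in groups) {
      g <- sort(g)
      if (length(g) >= 2L) {
        cmb <- utils::combn(g, 2L)
        out <- c(out, paste(cmb[1, ], cmb[2, ], sep = "\x1f"))
      }
    }
    unique(out)
  }
  pred <- pairs_of(lapply(merged, function(m) m$members))
  true <- pairs_of(split(identity_map$profile_id, identity_map$person_id))
  tp <- length(intersect(pred, true))
  list(precision = if (length(pred)) tp / length(pred) else 1,
       recall = if (length(true)) tp / length(true) else 1,
       n_pred_pairs = length(pred), n_true_pairs = length(true))
}

#' Read profiles from a per-source CSV file
#'
#' Columns: `profile_id` (optional; default `"<source>_<row>"`), `source`
#' (optional if given as argument), and one column per attribute. Empty
#' fields are missing.
#'
#' @param path CSV file.
#' @param source source label; overrides any `source` column.
#' @return List of [profile()] objects.
#' @export
read_profiles <- function(path, source = NULL) {
  if (!file.exists(path)) stop_privrisk(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character(0), fileEncoding = "UTF-8")
  if (is.null(source) && !"source" %in% names(raw))
    stop_privrisk("profiles need a 'source' column or a source argument")
  attr_cols <- setdiff(names(raw), c("profile_id", "source"))
  lapply(seq_len(nrow(raw)), function(i) {
    src <- source %||% raw$source[i]
    pid <- if ("profile_id" %in% names(raw)) raw$profile_id[i]
           else sprintf("%s_%d", src, i)
    vals <- lapply(attr_cols, function(a) {
      v <- raw[[a]][i]
      if (is.na(v) || v == "") NULL else v
    })
    names(vals) <- attr_cols
    do.call(profile, c(list(profile_id = pid, source = src),
                       vals[!vapply(vals, is.null, logical(1))]))
  })
}

#' Write profiles to a CSV file
#'
#' @param profiles list of [profile()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  attr_names <- sort(unique(unlist(lapply(profiles, function(p) names(p$attrs)))))
  rows <- lapply(profiles, function(p) {
    vals <- lapply(attr_names, function(a) {
      v <- p_attr(p, a)
      if (is.null(v)) "" else as.character(v)
    })
    names(vals) <- attr_names
    c(list(profile_id = p$profile_id, source = p$source), vals)
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, optional = TRUE)))
  utils::write.csv(df, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}
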