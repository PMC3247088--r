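#' @name syndata-module
#' @title Synthetic populations, phonebooks, and multi-source profiles
#'
#' @description
#' Real phonebook crawls and social-network profile sets cannot be
#' redistributed, so the package ships generators that emulate them.
#' Names are drawn from bundled frequency-ordered lexicons under a Zipf
#' rank-frequency model (weight of rank r proportional to `r^-s`), the
#' default exponent 1 being the classic approximation for personal-name
#' frequencies. [generate_phonebook()] subsamples a population at a
#' configurable coverage (residential phonebooks cover only part of a
#' town). [generate_profiles()] projects people onto per-source profiles
#' with configurable attribute disclosure probabilities, single-edit typo
#' rates and cross-source username sharing, returning a ground-truth
#' identity map so linkage output can be scored. Everything is
#' reproducible from (config, seed).
NULL

#' Rank-frequency name model
#'
#' @param first_names character vector of given names, most frequent
#'   first; the default mixes the bundled female and male lexicons.
#' @param last_names character vector of family names, most frequent first.
#' @param zipf_first,zipf_last Zipf exponents s >= 0: rank r gets sampling
#'   weight `r^-s` (0 = uniform).
#' @return A `name_model` object.
#' @export
name_model <- function(first_names = NULL, last_names = LAST_NAMES,
                       zipf_first = 1, zipf_last = 1) {
  if (is.null(first_names)) {
    # interleave so that rank order alternates female/male, mirroring the
    # roughly even split of common given names
    k <- max(length(FIRST_NAMES_FEMALE), length(FIRST_NAMES_MALE))
    first_names <- as.vector(rbind(FIRST_NAMES_FEMALE[seq_len(k)],
                                   FIRST_NAMES_MALE[seq_len(k)]))
    first_names <- unique(first_names[!is.na(first_names)])
  }
  if (length(first_names) == 0L || length(last_names) == 0L)
    stop_privrisk("name lexicons must be non-empty")
  if (zipf_first < 0 || zipf_last < 0)
    stop_privrisk("Zipf exponents must be non-negative")
  structure(list(first_names = first_names, last_names = last_names,
                 zipf_first = zipf_first, zipf_last = zipf_last),
            class = "name_model")
}

zipf_weights <- function(n, s) {
  w <- seq_len(n)^(-s)
  w / sum(w)
}

#' Schema of a generated population table
#' @return An [attribute_schema()] for [generate_population()] output.
#' @export
population_schema <- function() {
  attribute_schema(
    person_id = c("identifier", "text"),
    first     = c("identifier", "text"),
    last      = c("identifier", "text"),
    full_name = c("identifier", "text"),
    gender    = c("quasi_identifier", "category"),
    birthdate = c("quasi_identifier", "date"),
    location  = c("quasi_identifier", "category"),
    phone     = c("identifier", "text"),
    address   = c("other", "text")
  )
}

#' Generate a synthetic population
#'
#' Names come from the Zipf rank-frequency model; gender is balanced;
#' birthdates are uniform over `birth_range`; locations are assigned with
#' probability proportional to their size; phone numbers are unique
#' 10-digit strings; addresses combine a street number with a small street
#' lexicon. All name fields are stored pre-normalized (lowercase).
#'
#' @param n number of people, >= 0.
#' @param model a [name_model()].
#' @param locations data frame with columns `name` and `size` (relative
#'   population); default one town of 15,000.
#' @param seed integer seed; generation is fully deterministic under it.
#' @param birth_range character vector of two ISO dates.
#' @return A `microdata` object with [population_schema()], record ids
#'   `p0, p1, ...`.
#' @export
generate_population <- function(n, model = name_model(),
                                locations = data.frame(name = "smalltown",
                                                       size = 15000),
                                seed = NULL,
                                birth_range = c("1930-01-01", "1999-12-31")) {
  stopifnot(inherits(model, "name_model"))
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop_privrisk("n must be a non-negative integer")
  if (nrow(locations) == 0L) stop_privrisk("at least one location required")
  with_seed(seed, {
    first <- sample(model$first_names, n, replace = TRUE,
                    prob = zipf_weights(length(model$first_names), model$zipf_first))
    last <- sample(model$last_names, n, replace = TRUE,
                   prob = zipf_weights(length(model$last_names), model$zipf_last))
    gender <- sample(c("female", "male"), n, replace = TRUE)
    d0 <- as.Date(birth_range[1]); d1 <- as.Date(birth_range[2])
    birthdate <- format(d0 + sample.int(as.integer(d1 - d0) + 1L, n,
                                        replace = TRUE) - 1L, "%Y-%m-%d")
    location <- sample(as.character(locations$name), n, replace = TRUE,
                       prob = locations$size / sum(locations$size))
    phone <- sprintf("814%07d", sample.int(9999999L, n, replace = FALSE))
    address <- sprintf("%d %s %s", sample.int(999L, n, replace = TRUE),
                       sample(STREET_NAMES, n, replace = TRUE),
                       sample(STREET_TYPES, n, replace = TRUE))
    df <- data.frame(person_id = sprintf("p%d", seq_len(n) - 1L),
                     first = first, last = last,
                     full_name = paste(first, last),
                     gender = gender, birthdate = birthdate,
                     location = location, phone = phone, address = address,
                     stringsAsFactors = FALSE)
    if (n == 0L) df <- df[0, , drop = FALSE]
    microdata(df, population_schema(), record_id = df$person_id)
  })
}

#' Subsample a population into a phonebook
#'
#' A uniform random subset of `round(coverage * n)` people (round half to
#' even), in population order, with all fields retained.
#'
#' @param pop population `microdata` from [generate_population()].
#' @param coverage fraction of the population listed, in `[0, 1]`.
#' @param seed integer seed.
#' @return A `microdata` object.
#' @export
generate_phonebook <- function(pop, coverage, seed = NULL) {
  if (length(coverage) != 1L || is.na(coverage) || coverage < 0 || coverage > 1)
    stop_privrisk("coverage must be a fraction in [0, 1]")
  n <- n_records(pop)
  size <- as.integer(round(coverage * n))
  with_seed(seed, {
    idx <- sort(sample.int(n, size, replace = FALSE))
    md_subset(pop, idx)
  })
}

#' Specification of one profile source
#'
#' @param source source label (e.g. `"osn1"`).
#' @param attrs attributes the source exposes: a subset of the population
#'   attributes plus `username`, `email`, `age`.
#' @param disclose per-attribute disclosure probability: a single number
#'   or a named vector (unnamed attributes default to 1).
#' @param typo_rate probability that a disclosed value in `typo_fields`
#'   receives one random single-character edit (distance exactly 1).
#' @param share_username_prob probability that the profile carries the
#'   person's canonical cross-site username rather than a source-local
#'   variant.
#' @param participation probability that a person has a profile on this
#'   source at all.
#' @param typo_fields which attributes typos may hit.
#' @return A `source_spec` list.
#' @export
source_spec <- function(source, attrs, disclose = 1, typo_rate = 0,
                        share_username_prob = 1, participation = 1,
                        typo_fields = c("first", "last", "full_name",
                                        "username")) {
  probs <- c(disclose, typo_rate, share_username_prob, participation)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1))
    stop_privrisk("probabilities must lie in [0, 1]")
  structure(list(source = source, attrs = attrs, disclose = disclose,
                 typo_rate = typo_rate,
                 share_username_prob = share_username_prob,
                 participation = participation, typo_fields = typo_fields),
            class = "source_spec")
}

disclose_prob <- function(spec, attr) {
  d <- spec$disclose
  if (length(d) == 1L && is.null(names(d))) return(as.numeric(d))
  if (!is.null(names(d)) && attr %in% names(d)) return(as.numeric(d[[attr]]))
  1
}

canonical_username <- function(first, last, i) {
  sprintf("%s%s%04d", substr(first, 1L, 4L), substr(last, 1L, 1L), i)
}

canonical_email <- function(first, last, i) {
  sprintf("%s.%s%d@mail.example", first, last, i)
}

#' Generate per-source profiles with ground truth
#'
#' Each person participates in each source independently; a participating
#' person yields one profile carrying the source's attributes, each
#' disclosed with its stated probability. `username` and `email` are
#' synthesized per person (unique); with probability
#' `share_username_prob` a profile carries the person's canonical
#' username, otherwise a source-local variant. `age` is derived from the
#' birthdate at `reference_date`. Typos are single edits at Levenshtein
#' distance exactly 1, applied independently per disclosed field.
#'
#' @param pop population `microdata` from [generate_population()].
#' @param source_specs list of [source_spec()] objects.
#' @param seed integer seed.
#' @param reference_date ISO date at which profile ages are computed.
#' @return List with `profiles` (list of [profile()] objects) and
#'   `identity_map` (data frame `profile_id`, `person_id`, `source`
#'   covering every generated profile).
#' @export
generate_profiles <- function(pop, source_specs, seed = NULL,
                              reference_date = "2011-11-24") {
  n <- n_records(pop)
  with_seed(seed, {
    base_user <- canonical_username(md_values(pop, "first"),
                                    md_values(pop, "last"), seq_len(n))
    base_email <- canonical_email(md_values(pop, "first"),
                                  md_values(pop, "last"), seq_len(n))
    profiles <- list()
    map_pid <- character(0); map_person <- character(0); map_src <- character(0)
    for (spec in source_specs) {
      stopifnot(inherits(spec, "source_spec"))
      for (i in seq_len(n)) {
        if (stats::runif(1) > spec$participation) next
        pid <- sprintf("%s_%s", spec$source, pop$record_id[i])
        attrs <- list()
        for (a in spec$attrs) {
          if (stats::runif(1) > disclose_prob(spec, a)) next
          v <- switch(a,
            username = if (stats::runif(1) <= spec$share_username_prob)
              base_user[i] else paste0(base_user[i], substr(spec$source, 1L, 2L)),
            email = base_email[i],
            age = age_at(md_values(pop, "birthdate")[i], reference_date),
            md_values(pop, a)[i])
          if (a %in% spec$typo_fields && is.character(v) &&
              stats::runif(1) < spec$typo_rate)
            v <- perturb(v, 1L)
          attrs[[a]] <- v
        }
        if (length(attrs) == 0L) attrs$source_note <- spec$source
        profiles[[length(profiles) + 1L]] <-
          do.call(profile, c(list(profile_id = pid, source = spec$source), attrs))
        map_pid <- c(map_pid, pid)
        map_person <- c(map_person, pop$record_id[i])
        map_src <- c(map_src, spec$source)
      }
    }
    list(profiles = profiles,
         identity_map = data.frame(profile_id = map_pid,
                                   person_id = map_person,
                                   source = map_src,
                                   stringsAsFactors = FALSE))
  })
}

#' Deterministic five-profile case-study fixture
#'
#' A synthetic reconstruction of the canonical cross-site aggregation
#' scenario: one patient, five partial profiles. Two medical-forum
#' profiles share a username and are mutually consistent on gender
#' (inferred from a spousal phrase in one), location, and
#' birthdate-vs-age; a web directory entry shares the first profile's
#' email and adds a cell phone; a job page shares that cell phone and adds
#' the full name, a home phone and an occupation; a phonebook entry shares
#' the home phone and adds the spouse's name and the home address. Linked
#' transitively, all five merge into one dossier. All values are
#' synthetic.
#'
#' @return List with `profiles` (5 [profile()] objects), `expected_members`
#'   (all five profile ids), and `config` (a [link_config()] whose
#'   reference date matches the fixture's age/birthdate wiring).
#' @export
five_profile_fixture <- function() {
  profiles <- list(
    profile("osn1_jean", "medforum",
            username = "jz1962", email = "jean.z@mail.example",
            location = "Smalltown", birthdate = "1962-03-14",
            free_text = paste("living with type 2 diabetes; my husband",
                              "mark drives me to the lab every month")),
    profile("osn2_jean", "th1forum",
            username = "jz1962", email = "jeanz@webmail.example",
            gender = "female", location = "smalltown", age = 49,
            free_text = "interested in th1 therapy for diabetes type 2"),
    profile("job_jean", "jobpage",
            full_name = "jean zimmerman", phone = "814-555-0134",
            home_phone = "814-555-0188", occupation = "school librarian"),
    profile("dir_jean", "webdir",
            email = "jean.z@mail.example", phone = "8145550134",
            address = "po box 127, smalltown"),
    profile("pb_jean", "phonebook",
            full_name = "jean zimmerman", home_phone = "(814) 555-0188",
            spouse = "mark zimmerman", address = "12 oak ln, smalltown")
  )
  list(profiles = profiles,
       expected_members = sort(vapply(profiles, function(p) p$profile_id,
                                      character(1))),
       config = link_config(reference_date = "2011-11-24"))
}
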