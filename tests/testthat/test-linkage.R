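test_that("logical inference: spousal terms, age derivation, no overwrite", {
  p <- profile("p1", "osn", free_text = "me and my husband moved last year")
  out <- infer_attributes(p)
  expect_equal(out$attrs$gender, "female")
  # explicitly present gender is never overwritten
  p2 <- profile("p2", "osn", gender = "male",
                free_text = "my husband says hi")
  expect_equal(infer_attributes(p2)$attrs$gender, "male")
  # birthdate + reference date => completed years
  p3 <- profile("p3", "osn", birthdate = "1962-03-14")
  expect_equal(infer_attributes(p3, reference_date = "2011-11-24")$attrs$age, 49L)
  expect_equal(infer_attributes(p3, reference_date = "2012-03-13")$attrs$age, 49L)
  expect_equal(infer_attributes(p3, reference_date = "2012-03-14")$attrs$age, 50L)
  # no rule matches: unchanged
  p4 <- profile("p4", "osn", free_text = "nothing to see")
  expect_identical(infer_attributes(p4)$attrs, p4$attrs)
  expect_error(infer_attributes(p4, rules = list(list(pattern = "x"))),
               "malformed")
})

test_that("strong evidence: exact identifier matches after normalization", {
  a <- profile("a", "s1", email = "Jean.Z@Mail.example")
  b <- profile("b", "s2", email = "jean.z@mail.example")
  ev <- match_strong(a, b)
  expect_length(ev, 1)
  expect_equal(ev[[1]]$attribute, "email")
  expect_equal(ev[[1]]$kind, "strong")
  # phone AND username
  c1 <- profile("c", "s1", phone = "(814) 555-0134", username = "JZ1962")
  c2 <- profile("d", "s2", home_phone = "814-555-0134", username = "jz1962")
  ev2 <- match_strong(c1, c2)
  expect_setequal(vapply(ev2, function(e) e$attribute, character(1)),
                  c("phone", "username"))
  # nothing shared
  expect_length(match_strong(profile("e", "s1", gender = "female"),
                             profile("f", "s2", gender = "female")), 0)
})

test_that("weak evidence: gender/location/age consistency, silence on conflict", {
  a <- profile("a", "s1", gender = "female", location = "Smalltown",
               birthdate = "1962-03-14")
  b <- profile("b", "s2", gender = "Female", location = "smalltown", age = 49)
  ev <- match_weak(a, b, reference_date = "2011-11-24")
  expect_setequal(vapply(ev, function(e) e$attribute, character(1)),
                  c("gender", "location", "age"))
  expect_true(all(vapply(ev, function(e) e$kind, character(1)) == "weak"))
  # conflicting gender contributes nothing
  ev2 <- match_weak(profile("a", "s1", gender = "female"),
                    profile("b", "s2", gender = "male"))
  expect_length(ev2, 0)
  # missing on both sides contributes nothing
  expect_length(match_weak(profile("a", "s1", occupation = "x"),
                           profile("b", "s2", occupation = "x")), 0)
  # age slack: one year off is still consistent
  ev3 <- match_weak(a, profile("c", "s3", age = 48),
                    reference_date = "2011-11-24")
  expect_true("age" %in% vapply(ev3, function(e) e$attribute, character(1)))
})

test_that("link_confidence is noisy-or, monotone, bounded", {
  expect_equal(link_confidence(list()), 0)
  expect_equal(link_confidence(list(0.9)), 0.9)
  expect_equal(link_confidence(list(0.9, 0.5)), 0.95)
  expect_error(link_confidence(list(1.5)), "out of")
  expect_error(link_confidence(list(0)), "out of")
  set.seed(88)
  for (rep in 1:50) {
    w <- stats::runif(sample(1:6, 1), 0.05, 1)
    conf <- link_confidence(as.list(w))
    expect_gte(conf, max(w) - 1e-12)
    expect_lte(conf, 1)
    expect_gte(link_confidence(as.list(c(w, 0.3))), conf)
  }
})

test_that("link_all scores all pairs symmetrically above threshold", {
  a <- profile("a", "s1", email = "x@y.z", gender = "female")
  b <- profile("b", "s2", email = "x@y.z")
  c <- profile("c", "s3", gender = "female")
  links <- link_all(list(a, b, c), link_config(threshold = 0.5))
  expect_length(links, 1)
  expect_equal(links[[1]]$pair, c("a", "b"))
  expect_equal(links[[1]]$confidence, 0.95)
  # weak-only pair below threshold is excluded (single weak = 0.3 < 0.5)
  # input order does not matter
  links_rev <- link_all(list(c, b, a), link_config(threshold = 0.5))
  expect_equal(lapply(links_rev, function(l) l[c("pair", "confidence")]),
               lapply(links, function(l) l[c("pair", "confidence")]))
  expect_error(link_all(list(a, a)), "duplicate")
})

test_that("aggregate_profiles merges transitively into a partition", {
  a <- profile("a", "s1", email = "x@y.z")
  b <- profile("b", "s2", email = "x@y.z", phone = "5551234")
  c <- profile("c", "s3", phone = "555-1234")
  d <- profile("d", "s4", occupation = "baker")
  profiles <- list(a, b, c, d)
  links <- link_all(profiles, link_config(threshold = 0.5))
  merged <- aggregate_profiles(profiles, links, threshold = 0.5)
  members <- lapply(merged, function(m) m$members)
  expect_setequal(unlist(members), c("a", "b", "c", "d"))   # partition
  has_set <- function(sets, x) any(vapply(sets, identical, logical(1), y = x))
  expect_true(has_set(members, c("a", "b", "c")))
  expect_true(has_set(members, "d"))
  # no links: all singletons
  singles <- aggregate_profiles(profiles, list())
  expect_equal(lengths(lapply(singles, function(m) m$members)),
               rep(1L, 4))
  # raising the threshold never merges more
  for (thr in c(0, 0.5, 0.9, 0.96)) {
    m_lo <- aggregate_profiles(profiles, links, threshold = thr)
    expect_equal(sort(unlist(lapply(m_lo, function(m) m$members))),
                 c("a", "b", "c", "d"))
  }
  n_comp <- vapply(c(0, 0.5, 0.96),
                   function(thr) length(aggregate_profiles(profiles, links, thr)),
                   numeric(1))
  expect_true(all(diff(n_comp) >= 0))
})

test_that("merged attributes carry provenance; conflicts are recorded", {
  a <- profile("a", "osn1", gender = "female", email = "x@y.z")
  b <- profile("b", "osn2", gender = "male", email = "x@y.z",
               location = "town")
  links <- link_all(list(a, b), link_config(threshold = 0.5))
  m <- aggregate_profiles(list(a, b), links, threshold = 0.5,
                          source_priority = c("osn1", "osn2"))[[1]]
  expect_equal(m$primary$gender, "female")      # priority source wins
  conf_attrs <- vapply(m$conflicts, function(cf) cf$attribute, character(1))
  expect_equal(conf_attrs, "gender")
  expect_setequal(m$conflicts[[1]]$values, c("female", "male"))
  rep <- dossier_report(m)
  expect_true("gender" %in% unlist(rep$attribute_types))
  expect_length(rep$conflicts, 1)
  # singleton dossier: one source per attribute, no conflicts
  s <- aggregate_profiles(list(a), list())[[1]]
  rs <- dossier_report(s)
  expect_length(rs$conflicts, 0)
  expect_equal(unlist(rs$attributes$email[[1]]$sources), "osn1")
})

test_that("the five-profile fixture merges into one dossier; ablation splits it", {
  fx <- five_profile_fixture()
  links <- link_all(fx$profiles, fx$config)
  expect_gte(length(links), 4)
  merged <- aggregate_profiles(fx$profiles, links,
                               threshold = fx$config$threshold)
  expect_length(merged, 1)
  expect_equal(merged[[1]]$members, fx$expected_members)

  rep <- dossier_report(merged[[1]])
  types <- unlist(rep$attribute_types)
  expect_true(all(c("full_name", "birthdate", "spouse", "address",
                    "occupation", "email") %in% types))
  emails <- unique(vapply(rep$attributes$email, function(v) v$value,
                          character(1)))
  expect_length(emails, 2)
  phones <- unique(unlist(lapply(c("phone", "home_phone"), function(a)
    lapply(rep$attributes[[a]], function(v) gsub("[^0-9]", "", v$value)))))
  expect_length(phones, 2)

  # ablation: dropping the email from the first forum profile cuts the
  # bridge to the directory record, splitting {osn1, osn2} from the rest
  prof2 <- fx$profiles
  prof2[[1]]$attrs$email <- NULL
  links2 <- link_all(prof2, fx$config)
  merged2 <- aggregate_profiles(prof2, links2, threshold = fx$config$threshold)
  members2 <- lapply(merged2, function(m) m$members)
  expect_length(merged2, 2)
  has_set <- function(sets, x) any(vapply(sets, identical, logical(1), y = x))
  expect_true(has_set(members2, sort(c("osn1_jean", "osn2_jean"))))
  expect_true(has_set(members2, sort(c("dir_jean", "job_jean", "pb_jean"))))
})

test_that("profile CSV round trip preserves attributes and missingness", {
  fx <- five_profile_fixture()
  f <- withr::local_tempfile(fileext = ".csv")
  write_profiles(fx$profiles, f)
  back <- read_profiles(f)
  expect_length(back, 5)
  ids <- vapply(back, function(p) p$profile_id, character(1))
  expect_setequal(ids, fx$expected_members)
  orig <- fx$profiles[[match("pb_jean", vapply(fx$profiles, function(p) p$profile_id, character(1)))]]
  got <- back[[match("pb_jean", ids)]]
  expect_equal(got$attrs[order(names(got$attrs))],
               lapply(orig$attrs[order(names(orig$attrs))], as.character))
})
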