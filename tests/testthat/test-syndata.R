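test_that("population generation is deterministic and exactly sized", {
  pop1 <- generate_population(500, seed = 21)
  pop2 <- generate_population(500, seed = 21)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_table(pop1, f1); write_table(pop2, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical
  expect_equal(n_records(pop1), 500L)
  expect_false(anyNA(md_values(pop1, "full_name")))
  expect_true(all(md_values(pop1, "full_name") ==
                    paste(md_values(pop1, "first"), md_values(pop1, "last"))))
  expect_false(any(duplicated(md_values(pop1, "phone"))))
  # n = 0
  expect_equal(n_records(generate_population(0, seed = 1)), 0L)
  expect_error(generate_population(10, name_model(character(0))), "non-empty")
})

test_that("sampled name ranks are consistent with the Zipf model", {
  model <- name_model(zipf_first = 1)
  pop <- generate_population(20000, model, seed = 31)
  obs <- table(factor(md_values(pop, "first"), levels = model$first_names))
  expected_p <- seq_along(model$first_names)^(-1)
  expected_p <- expected_p / sum(expected_p)
  gof <- suppressWarnings(stats::chisq.test(as.integer(obs), p = expected_p))
  expect_gt(gof$p.value, 0.001)
  # rank-frequency shape: the top-ranked name is the most frequent
  expect_equal(names(which.max(obs)), model$first_names[1])
})

test_that("phonebook subsampling honours the round-half-even size rule", {
  pop <- generate_population(1000, seed = 41)
  pb <- generate_phonebook(pop, 0.64, seed = 42)
  expect_equal(n_records(pb), 640L)
  expect_true(all(pb$record_id %in% pop$record_id))
  expect_false(anyNA(md_values(pb, "phone")))
  expect_equal(n_records(generate_phonebook(pop, 1, seed = 1)), 1000L)
  expect_equal(n_records(generate_phonebook(pop, 0, seed = 1)), 0L)
  # round half to even: 2.5 -> 2
  pop5 <- generate_population(5, seed = 43)
  expect_equal(n_records(generate_phonebook(pop5, 0.5, seed = 44)), 2L)
  expect_error(generate_phonebook(pop, 1.2), "fraction")
})

test_that("noise-free profiles mirror the population; identity map is total", {
  pop <- generate_population(60, seed = 51)
  specs <- list(
    source_spec("osn1", c("username", "gender", "location", "birthdate")),
    source_spec("osn2", c("username", "email", "gender", "location", "age")))
  gen <- generate_profiles(pop, specs, seed = 52)
  expect_equal(length(gen$profiles), 120L)
  expect_equal(nrow(gen$identity_map), 120L)
  ids <- vapply(gen$profiles, function(p) p$profile_id, character(1))
  expect_setequal(gen$identity_map$profile_id, ids)
  # disclosure 1, typo 0: disclosed values equal the population values
  for (p in gen$profiles[1:10]) {
    person <- gen$identity_map$person_id[match(p$profile_id,
                                               gen$identity_map$profile_id)]
    i <- match(person, pop$record_id)
    for (a in intersect(names(p$attrs), c("gender", "location", "birthdate")))
      expect_equal(p$attrs[[a]], md_values(pop, a)[i])
  }
  # shared usernames agree across sources for the same person
  by_person <- split(seq_along(gen$profiles), gen$identity_map$person_id)
  for (g in by_person[1:10]) {
    us <- unlist(lapply(gen$profiles[g], function(p) p$attrs$username))
    expect_length(unique(us), 1)
  }
})

test_that("typo rate is statistically recoverable from generated profiles", {
  pop <- generate_population(800, seed = 61)
  gen <- generate_profiles(pop, list(
    source_spec("osn", c("first", "gender"), typo_rate = 0.2)), seed = 62)
  first_true <- md_values(pop, "first")[match(gen$identity_map$person_id,
                                              pop$record_id)]
  first_obs <- vapply(gen$profiles, function(p) p$attrs$first, character(1))
  d <- levenshtein(first_true, first_obs)
  expect_true(all(d %in% c(0L, 1L)))   # typos are single edits exactly
  rate <- mean(d == 1L)
  se <- sqrt(0.2 * 0.8 / length(d))
  expect_lt(abs(rate - 0.2), 3 * se)
  # untouched fields stay exact
  expect_true(all(vapply(gen$profiles, function(p) p$attrs$gender, character(1)) ==
                    md_values(pop, "gender")[match(gen$identity_map$person_id,
                                                   pop$record_id)]))
})

test_that("the five-profile fixture is reproducible", {
  expect_identical(five_profile_fixture(), five_profile_fixture())
})

test_that("invalid generator probabilities are rejected", {
  expect_error(source_spec("s", "first", disclose = 1.4), "probabilities")
  expect_error(source_spec("s", "first", typo_rate = -0.1), "probabilities")
})
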