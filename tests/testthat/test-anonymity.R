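qi_md <- function() {
  sch <- attribute_schema(gender = c("quasi_identifier", "category"),
                          location = c("quasi_identifier", "category"),
                          age = c("quasi_identifier", "integer"))
  microdata(data.frame(gender = c("F", "F", "M"),
                       location = c("Town", "Town", "Town"),
                       age = c(30L, 30L, 41L)), sch)
}

test_that("k_anonymity_classes partitions records by exact tuples", {
  md <- qi_md()
  cls <- k_anonymity_classes(md, c("gender", "location", "age"))
  expect_equal(sort(cls$class_size), c(1L, 2L))
  expect_equal(sum(cls$class_size), n_records(md))
  # all-distinct tuples: n singleton classes
  md2 <- names_md(letters[1:5])
  expect_equal(k_anonymity_classes(md2, "name")$class_size, rep(1L, 5))
  # empty dataset: empty partition
  expect_equal(nrow(k_anonymity_classes(names_md(character(0)), "name")), 0L)
  expect_error(k_anonymity_classes(md, "zipcode"), "zipcode")
})

test_that("kl_profile counts neighbors within l, duplicates included", {
  md <- names_md(c("ann", "anne", "bob"))
  prof <- kl_profile(md, "name", 1)
  expect_equal(unname(prof$k_values), c(2L, 2L, 1L))
  # l = 0 on duplicated values reduces to exact-match class sizes
  md2 <- names_md(c("ann", "ann", "bob"))
  expect_equal(unname(kl_profile(md2, "name", 0)$k_values), c(2L, 2L, 1L))
  # l at least the sum of the two longest lengths: everyone matches everyone
  expect_equal(unname(kl_profile(md, "name", 10)$k_values), rep(3L, 3))
})

test_that("kl_profile at l = 0 equals equivalence-class sizes on random data", {
  set.seed(303)
  for (rep in 1:20) {
    values <- random_strings(sample(1:80, 1), 0, 5, letters[1:3])
    md <- names_md(values)
    k0 <- unname(kl_profile(md, "name", 0)$k_values)
    sizes <- table(values)
    expect_equal(k0, as.integer(sizes)[match(values, names(sizes))])
  }
})

test_that("satisfies_kl uses the universal reading", {
  md <- names_md(c("ann", "anne", "ana"))
  expect_true(satisfies_kl(md, "name", k = 1, l = 0))
  expect_true(satisfies_kl(md, "name", k = 2, l = 1))
  expect_false(satisfies_kl(names_md(c("ann", "bob", "zoe")), "name", 2, 0))
  expect_error(satisfies_kl(md, "name", k = 0, l = 1), "k must")
})

test_that("k_histogram summarizes a profile and conserves counts", {
  md <- names_md(c("ann", "anne", "bob"))
  h <- k_histogram(kl_profile(md, "name", 1))
  expect_equal(h$counts, c("1" = 1L, "2" = 2L))
  expect_equal(h$unique_fraction, 1 / 3)
  expect_equal(frac_at_most(h, 1), 1 / 3)
  expect_equal(frac_at_most(h, 2), 1)
  # all unique
  h2 <- k_histogram(kl_profile(names_md(c("aq", "gh", "zz")), "name", 0))
  expect_equal(h2$counts, c("1" = 3L))
  expect_equal(h2$unique_fraction, 1)
  expect_error(k_histogram(kl_profile(names_md(character(0)), "name", 0)),
               "empty")
})

test_that("histogram equals a brute-force recount on a synthetic fixture", {
  set.seed(99)
  values <- random_strings(10, 1, 5, letters[1:4])
  md <- names_md(values)
  h <- k_histogram(kl_profile(md, "name", 1))
  oracle_k <- oracle_kl(values, 1)
  expect_equal(h$counts,
               {t <- table(oracle_k); stats::setNames(as.integer(t), names(t))})
  expect_equal(sum(h$counts), 10L)
})

test_that("uniqueness_fraction counts singleton quasi-identifier tuples", {
  md <- qi_md()
  expect_equal(uniqueness_fraction(md, c("gender", "location", "age")), 1 / 3)
  expect_equal(uniqueness_fraction(names_md(letters[1:4]), "name"), 1)
  expect_equal(uniqueness_fraction(names_md(c("a", "a")), "name"), 0)
  expect_error(uniqueness_fraction(names_md(character(0)), "name"), "empty")
})

test_that("risk_sweep: histograms per threshold, unique fraction non-increasing", {
  md <- names_md(c("ann", "anne", "bob"))
  sw <- risk_sweep(md, "name", c(0, 1, 2))
  expect_equal(names(sw), c("0", "1", "2"))
  expect_equal(vapply(sw, function(h) h$unique_fraction, numeric(1)),
               c("0" = 1, "1" = 1 / 3, "2" = 1 / 3))
  # duplicate thresholds are deduplicated
  expect_equal(names(risk_sweep(md, "name", c(1, 0, 1))), c("0", "1"))
  # single l = 0 sweep matches the exact-match histogram
  sw0 <- risk_sweep(md, "name", 0)
  expect_equal(sw0[["0"]]$counts, k_histogram(kl_profile(md, "name", 0))$counts)
})

test_that("per-record k is non-decreasing in l on random datasets", {
  set.seed(505)
  for (rep in 1:10) {
    values <- random_strings(sample(2:60, 1), 0, 6)
    md <- names_md(values)
    ks <- sapply(0:4, function(l) unname(kl_profile(md, "name", l)$k_values))
    expect_true(all(apply(ks, 1, function(r) all(diff(r) >= 0))))
    uf <- vapply(risk_sweep(md, "name", 0:4),
                 function(h) h$unique_fraction, numeric(1))
    expect_true(all(diff(uf) <= 0))
    expect_true(all(vapply(risk_sweep(md, "name", 0:4),
                           function(h) sum(h$counts), integer(1)) == length(values)))
  }
})
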