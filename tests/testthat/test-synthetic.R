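test_that("generator configuration is validated", {
  expect_error(roster_config(n_persons = 10, n_records = 5), "n_records")
  expect_error(roster_config(n_persons = 10, collision_pairs = 6,
                             n_records = 20), "collision_pairs")
  expect_error(roster_config(missing_rate = 1.2))
  expect_s3_class(roster_config(seed = 1), "roster_config")
})

test_that("population plants exactly the configured collisions", {
  cfg <- roster_config(n_persons = 100, n_records = 100, collision_pairs = 5,
                       missing_rate = 0, noise_rate = 0, seed = 8)
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop), 100L)
  expect_equal(length(unique(pop$service_number)), 95L)
  shared <- names(which(table(pop$service_number) == 2L))
  expect_equal(length(shared), 5L)
  for (sn in shared) {
    expect_setequal(pop$gender[pop$service_number == sn], c("M", "F"))
  }
  # zero collisions -> all distinct
  pop0 <- simulate_population(roster_config(n_persons = 100, n_records = 100,
                                            collision_pairs = 0, seed = 8))
  expect_equal(length(unique(pop0$service_number)), 100L)
})

test_that("a fixed seed reproduces the generator byte for byte", {
  cfg <- roster_config(n_persons = 50, n_records = 90, collision_pairs = 3,
                       missing_rate = 0.05, noise_rate = 0.3, seed = 123)
  expect_identical(simulate_population(cfg), simulate_population(cfg))
  expect_identical(simulate_roster(cfg)$roster, simulate_roster(cfg)$roster)
})

test_that("every person appears and record totals are exact", {
  cfg <- roster_config(n_persons = 80, n_records = 200, collision_pairs = 4,
                       missing_rate = 0, noise_rate = 0, seed = 6)
  sim <- simulate_roster(cfg)
  expect_equal(nrow(sim$roster), 200L)
  expect_setequal(unique(sim$truth$person_id), sim$population$person_id)
})

test_that("formatting noise is reversible by normalization", {
  cfg <- roster_config(n_persons = 60, n_records = 120, collision_pairs = 3,
                       missing_rate = 0, noise_rate = 1, seed = 9)
  sim <- simulate_roster(cfg)
  expect_true(any(sim$roster$gender != sim$truth$gender_true))
  cl <- clean_roster(sim$roster)
  expect_equal(nrow(cl$exclusions), 0L)
  expect_equal(cl$clean$gender, sim$truth$gender_true)
  expect_equal(cl$clean$service_number, sim$truth$service_number_true)
})

test_that("oracle statistics agree with a direct recount of the truth", {
  sim <- simulate_roster(roster_config(n_persons = 70, n_records = 140,
                                       collision_pairs = 6, missing_rate = 0.05,
                                       noise_rate = 0.2, seed = 14))
  orc <- oracle_statistics(sim)
  tr <- sim$truth
  keep <- !tr$missing_gender & !tr$missing_service_number
  expect_equal(unname(orc$crosstab["n"]), sum(keep))
  expect_equal(orc$n_distinct_gold,
               length(unique(tr$service_number_true[keep])))
  expect_equal(orc$crosstab[["a"]], orc$n_distinct_gold)
  expect_equal(orc$crosstab[["a"]] + orc$crosstab[["b"]], orc$n_distinct_hash)
  expect_equal(orc$crosstab[["c"]], 0)
})

test_that("planted collisions with full coverage surface as cell b", {
  for (k in c(0L, 3L)) {
    cfg <- roster_config(n_persons = 60, n_records = 100, collision_pairs = k,
                         missing_rate = 0, noise_rate = 0, seed = 21 + k)
    orc <- oracle_statistics(simulate_roster(cfg))
    expect_equal(orc$crosstab[["b"]], k)
    if (k == 0L) expect_equal(orc$specificity, 1)
  }
})
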