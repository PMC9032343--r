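breeding_two_years <- function() {
  data.frame(parent_id = c("A", "A"), year = c(2001, 2002),
             eggs = c(4L, 5L), hatchlings = c(3L, 4L),
             fledglings = c(2L, 3L), recruits = c(1L, 1L),
             broods = c(1L, 2L), stringsAsFactors = FALSE)
}

test_that("LRS sums stage counts over an individual's records", {
  b <- breeding_two_years()
  expect_equal(lrs(b, "A", "eggs"), 9L)
  expect_equal(lrs(b, "A", "hatchlings"), 7L)
  expect_equal(lrs(b, "A", "broods"), 3L)
  expect_message(z <- lrs(b, "nobody", "eggs"), "LRS = 0")
  expect_equal(z, 0L)
})

test_that("stage monotonicity holds for every simulated individual", {
  sim <- simulate_population(test_sim_config(seed = 31))
  b <- sim$breeding
  for (id in unique(b$parent_id)[1:50]) {
    v <- vapply(c("eggs", "hatchlings", "fledglings", "recruits"),
                function(s) as.numeric(suppressMessages(lrs(b, id, s))),
                numeric(1))
    expect_true(all(diff(v) <= 0), info = id)
  }
})

test_that("transition matrix matches the worked three-age example", {
  # individual surviving three years with 1, 2, 1 offspring at ages 1-3
  ped <- pedigree(ped_df(list("A", "-", "-", "male", 2000, 2003)))
  b <- data.frame(parent_id = "A", year = 2001:2003,
                  eggs = c(1L, 2L, 1L), hatchlings = c(1L, 2L, 1L),
                  fledglings = c(1L, 2L, 1L), recruits = c(1L, 2L, 1L),
                  broods = 1L)
  M <- build_transition_matrix(b, ped, "A", "recruits")
  expect_equal(unclass(M),
               matrix(c(0.5, 1, 0.5,
                        1,   0, 0,
                        0,   1, 0), 3, 3, byrow = TRUE))

  # single breeding age
  ped1 <- pedigree(ped_df(list("B", "-", "-", "male", 2000, 2001)))
  b1 <- data.frame(parent_id = "B", year = 2001, eggs = 1L, hatchlings = 1L,
                   fledglings = 1L, recruits = 1L, broods = 1L)
  expect_equal(unclass(build_transition_matrix(b1, ped1, "B", "eggs")),
               matrix(0.5, 1, 1))

  # no offspring, lifespan 2: zero first row, unit sub-diagonal
  ped2 <- pedigree(ped_df(list("C", "-", "-", "male", 2000, 2002)))
  b2 <- b1[0, ]
  M2 <- build_transition_matrix(b2, ped2, "C", "eggs")
  expect_equal(unclass(M2), matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE))

  ped0 <- pedigree(ped_df(list("D", "-", "-", "male", 2000, 2000)))
  expect_error(build_transition_matrix(b2, ped0, "D", "eggs"), "lifespan")
})

test_that("IGR agrees with the characteristic-polynomial oracle", {
  expect_equal(igr(transition_matrix(c(0.5, 1, 0.5))),
               charpoly_igr(c(0.5, 1, 0.5)), tolerance = 1e-9)
  expect_equal(igr(transition_matrix(0.5)), 0.5)
  expect_equal(igr(transition_matrix(c(0, 0, 0))), 0)

  set.seed(77)
  for (i in 1:100) {
    L <- sample(1:8, 1)
    f <- round(stats::rexp(L, rate = 0.5), 3)
    M <- transition_matrix(f)
    lam <- igr(M)
    expect_lt(abs(lam - charpoly_igr(f)), 1e-9)
    expect_lt(abs(lam - power_igr(unclass(M))), 1e-7)
  }
})

test_that("IGR is monotone in fecundity and ordered across stages", {
  set.seed(13)
  for (i in 1:100) {
    L <- sample(2:6, 1)
    f <- stats::rexp(L)
    a <- sample(L, 1)
    f2 <- f; f2[a] <- f2[a] + stats::rexp(1)
    expect_gte(igr(transition_matrix(f2)), igr(transition_matrix(f)) - 1e-12)
  }
  # recruits row is elementwise dominated by the eggs row
  sim <- simulate_population(test_sim_config(seed = 19))
  roster <- identify_founders(sim$pedigree, c(1998, 2002))
  ids <- roster$id[1:20]
  for (id in ids) {
    i <- match(id, sim$pedigree$id)
    if (sim$pedigree$death_year[i] - sim$pedigree$birth_year[i] < 1) next
    e <- igr_individual(sim$breeding, sim$pedigree, id, "eggs")
    r <- igr_individual(sim$breeding, sim$pedigree, id, "recruits")
    expect_gte(e, r - 1e-12)
  }
})

test_that("annual de-lifing reproduces forced arithmetic", {
  # survives, no surviving offspring, stable population of 2: p = 0
  ped <- pedigree(ped_df(
    list("A", "-", "-", "male", 1999, 2002),
    list("B", "-", "-", "female", 1999, 2002)
  ))
  cen <- data.frame(year = 2000:2002, n_adults = c(2L, 2L, 2L))
  b <- data.frame(parent_id = character(0), year = integer(0),
                  eggs = integer(0), hatchlings = integer(0),
                  fledglings = integer(0), recruits = integer(0),
                  broods = integer(0))
  expect_equal(delifed_annual(b, cen, ped, "A", 2000), 0)

  # dies, no surviving offspring, w = 1, N = 11: (0 - 1)/10 = -0.1
  ped2 <- pedigree(do.call(rbind, c(
    list(ped_df(list("D", "-", "-", "male", 1999, 2000))),
    lapply(1:10, function(i) ped_df(list(paste0("X", i), "-", "-", "female",
                                         1999, 2005)))
  )))
  cen2 <- data.frame(year = 2000:2001, n_adults = c(11L, 11L))
  expect_equal(delifed_annual(b, cen2, ped2, "D", 2000), -0.1)

  expect_error(delifed_annual(b, cen, ped, "A", 1999), "not an adult")
  expect_error(delifed_annual(b, cen, ped, "A", 2002), "census")
  cen1 <- data.frame(year = 2000:2001, n_adults = c(1L, 1L))
  expect_error(delifed_annual(b, cen1, ped, "A", 2000), "N_t >= 2")
})

test_that("a toy year matches an independent spreadsheet recomputation", {
  # Year 2000: adults A (m), B (f), C (m), D (f); A x B raise 2 recruits
  # born 2000; A, B, C survive to 2001, D dies; so N_2000 = 4, N_2001 = 5
  # (3 survivors + 2 recruits), w = 1.25.
  ped <- pedigree(ped_df(
    list("A", "-", "-", "male", 1999, 2003),
    list("B", "-", "-", "female", 1999, 2003),
    list("C", "-", "-", "male", 1999, 2003),
    list("D", "-", "-", "female", 1999, 2000),
    list("K1", "A", "B", "male", 2000, 2003),
    list("K2", "A", "B", "female", 2000, 2003)
  ))
  cen <- data.frame(year = 2000:2001, n_adults = c(4L, 5L))
  b <- data.frame(parent_id = c("A", "B"), year = 2000, eggs = 2L,
                  hatchlings = 2L, fledglings = 2L, recruits = 2L, broods = 1L)
  w <- 5 / 4
  # weight 1: A has xi = 2 + 1
  expect_equal(delifed_annual(b, cen, ped, "A", 2000), (3 - w) / 3)
  expect_equal(delifed_annual(b, cen, ped, "C", 2000), (1 - w) / 3)
  expect_equal(delifed_annual(b, cen, ped, "D", 2000), (0 - w) / 3)
  # weight 0.5 splits each offspring between its parents; the population
  # total is then exactly zero
  p_all <- vapply(c("A", "B", "C", "D"), function(id) {
    delifed_annual(b, cen, ped, id, 2000, offspring_weight = 0.5)
  }, numeric(1))
  expect_equal(unname(p_all[1]), (0.5 * 2 + 1 - w) / 3)
  expect_equal(sum(p_all), 0, tolerance = 1e-12)
})

test_that("de-lifing zero-sum holds population-wide at weight 0.5", {
  # zero-sum needs every new adult's parents censused: no blanked sires
  # and no introduced batch appearing out of nowhere mid-study
  sim <- simulate_population(test_sim_config(seed = 23, immigration_rate = 0,
                                             n_introduced = 0L))
  ped <- sim$pedigree; cen <- sim$census; b <- sim$breeding
  for (t in head(cen$year, -1)) {
    adults <- ped$id[ped$birth_year + 1 <= t & ped$death_year >= t]
    p <- vapply(adults, function(id) {
      delifed_annual(b, cen, ped, id, t, offspring_weight = 0.5)
    }, numeric(1))
    expect_lt(abs(sum(p)), 1e-10)
  }
})

test_that("lifetime de-lifing sums the annual values by age", {
  sim <- simulate_population(test_sim_config(seed = 29))
  ped <- sim$pedigree; cen <- sim$census; b <- sim$breeding
  roster <- identify_founders(ped, c(1998, 2002))
  id <- roster$id[which.max(
    ped$death_year[match(roster$id, ped$id)]
    - ped$birth_year[match(roster$id, ped$id)])]
  by_age <- annual_delifed_by_age(b, cen, ped, id)
  i <- match(id, ped$id)
  expect_equal(as.integer(names(by_age)),
               seq_len(min(ped$death_year[i], max(cen$year) - 1)
                       - ped$birth_year[i]))
  expect_equal(delifed_lifetime(b, cen, ped, id), sum(by_age))

  # single adult year: lifetime equals the annual value
  one <- ped$id[ped$death_year - ped$birth_year == 1 &
                  ped$birth_year + 1 < max(cen$year)][1]
  if (!is.na(one)) {
    expect_equal(delifed_lifetime(b, cen, ped, one),
                 delifed_annual(b, cen, ped, one, ped$birth_year[match(one, ped$id)] + 1))
  }
})

test_that("fitness table excludes incomplete life histories and keeps zeros", {
  sim <- simulate_population(test_sim_config(seed = 37))
  roster <- identify_founders(sim$pedigree, c(1998, 2002))
  ft <- fitness_table(sim$pedigree, sim$breeding, sim$census, roster)
  excl <- attr(ft, "excluded")
  expect_equal(nrow(ft) + nrow(excl), nrow(roster))
  expect_true(all(ft$lrs_eggs >= ft$lrs_hatchlings))
  expect_true(all(ft$lrs_fledglings >= ft$lrs_recruits))
  # zero-offspring individuals are retained with IGR 0
  zero <- ft$lrs_recruits == 0
  if (any(zero)) expect_true(all(ft$igr_recruits[zero] == 0))
  # sample size declines with age for the de-lifing age columns
  age_cols <- grep("^delifed_age", names(ft), value = TRUE)
  n_by_age <- vapply(age_cols, function(cl) sum(!is.na(ft[[cl]])), integer(1))
  expect_true(all(diff(n_by_age) <= 0))
})
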