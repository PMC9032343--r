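test_that("forced transmissions give exact reproductive values", {
  # founder pair A x B with single offspring C: C carries exactly one of
  # each founder's alleles, so in a year where only C is alive RV = 1
  ped <- pedigree(trio_df())
  gd <- run_gene_drop(ped, n_reps = 200, seed = 11)
  expect_equal(reproductive_value(gd, "A", 2004), 1)
  expect_equal(reproductive_value(gd, "B", 2004), 1)
  # while A and C are both alive: A's own 2 copies + exactly 1 in C
  expect_equal(reproductive_value(gd, "A", 2001), 3)
  expect_equal(allele_survival_probability(gd, "A"), 1)

  # founder with one offspring by an unknown mate: offspring always
  # carries one root allele, so RV = 3 in shared years, deterministic
  ped2 <- pedigree(ped_df(
    list("F", "-", "-", "male", 2000, 2003),
    list("O", "F", "-", "female", 2001, 2006)
  ))
  gd2 <- run_gene_drop(ped2, n_reps = 100, seed = 3)
  expect_equal(reproductive_value(gd2, "F", 2002), 3)
  expect_equal(reproductive_value(gd2, "F", 2005), 1)

  # childless founder dead before the final year
  ped3 <- pedigree(ped_df(
    list("Z", "-", "-", "female", 2000, 2001),
    list("Y", "-", "-", "male", 2000, 2006)
  ))
  gd3 <- run_gene_drop(ped3, n_reps = 100, seed = 5)
  expect_equal(reproductive_value(gd3, "Z", 2006), 0)
  expect_equal(allele_survival_probability(gd3, "Z"), 0)

  expect_error(reproductive_value(gd, "nobody", 2004), "unknown")
  expect_error(reproductive_value(gd, "A", 1800), "range")
})

test_that("grandchild-only survival happens in half of replicates", {
  # F -> C (other parent unknown) -> G (other parent unknown); only G is
  # alive in the final year. C carries exactly one F allele; G inherits
  # it with probability 1/2.
  ped <- pedigree(ped_df(
    list("F", "-", "-", "male", 2000, 2002),
    list("C", "F", "-", "female", 2001, 2004),
    list("G", "-", "C", "male", 2003, 2008)
  ))
  oracle <- enum_gene_drop(as.data.frame(ped))
  i <- match("F", oracle$roots)
  expect_equal(oracle$surv_prob[i], 0.5)
  gd <- run_gene_drop(ped, n_reps = 10000, seed = 21)
  p_mc <- allele_survival_probability(gd, "F")
  expect_lt(abs(p_mc - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("Monte-Carlo matches exhaustive enumeration within 3 SE", {
  for (nm in names(small_pedigrees())) {
    df <- small_pedigrees()[[nm]]
    ped <- pedigree(df)
    oracle <- enum_gene_drop(df)
    gd <- run_gene_drop(ped, n_reps = 10000, seed = 42,
                        years = oracle$years)
    perm <- match(oracle$roots, gd$roots$id)
    expect_false(anyNA(perm))
    for (r in seq_along(oracle$roots)) {
      for (k in seq_along(oracle$years)) {
        se <- oracle$sd[r, k] / sqrt(gd$n_reps)
        diff <- abs(gd$rv[perm[r], k] - oracle$rv[r, k])
        if (se == 0) {
          expect_equal(gd$rv[perm[r], k], oracle$rv[r, k],
                       info = paste(nm, oracle$roots[r], oracle$years[k]))
        } else {
          expect_lt(diff, 3 * se)
        }
      }
      p <- oracle$surv_prob[r]
      se_p <- sqrt(p * (1 - p) / gd$n_reps)
      diff_p <- abs(allele_survival_probability(gd, oracle$roots[r]) - p)
      if (se_p == 0) expect_equal(diff_p, 0) else expect_lt(diff_p, 3 * se_p)
    }
  }
})

test_that("copy counts are conserved and runs are seed-deterministic", {
  sim <- simulate_population(test_sim_config(seed = 9))
  gd <- run_gene_drop(sim$pedigree, n_reps = 300, seed = 17,
                      years = sim$census$year)
  expected <- matrix(2L * gd$alive_n, nrow = length(gd$alive_n),
                     ncol = gd$n_reps)
  expect_true(all(gd$totals == expected))

  gd2 <- run_gene_drop(sim$pedigree, n_reps = 300, seed = 17,
                       years = sim$census$year)
  expect_identical(gd, gd2)
  gd3 <- run_gene_drop(sim$pedigree, n_reps = 300, seed = 18,
                       years = sim$census$year)
  expect_false(identical(gd$rv, gd3$rv))
})

test_that("non-cohort roots are bucketed so conservation still holds", {
  # D is a root born outside the cohort window; its unknown-side allele
  # must be tracked even though it is not a cohort lineage
  df <- small_pedigrees()$chain
  ped <- pedigree(df)
  roster <- identify_founders(ped, c(2000, 2001))  # excludes D (born 2003)
  gd <- run_gene_drop(ped, roster, n_reps = 50, seed = 2)
  expect_true("D" %in% gd$roots$id)
  expect_false(gd$roots$cohort[gd$roots$id == "D"])
  expect_true(all(gd$totals == matrix(2L * gd$alive_n,
                                      nrow = length(gd$alive_n), ncol = 50)))
})

test_that("adding an offspring never decreases exact reproductive value", {
  base <- ped_df(
    list("A", "-", "-", "male", 2000, 2003),
    list("B", "-", "-", "female", 2000, 2003),
    list("C", "A", "B", "male", 2001, 2006)
  )
  extra <- rbind(base, ped_df(list("C2", "A", "B", "female", 2002, 2006)))
  o1 <- enum_gene_drop(base, years = 2000:2006)
  o2 <- enum_gene_drop(extra, years = 2000:2006)
  i1 <- match("A", o1$roots); i2 <- match("A", o2$roots)
  expect_true(all(o2$rv[i2, ] >= o1$rv[i1, ] - 1e-12))

  # deeper case: grandchild added under an existing descendant
  deep <- rbind(base, ped_df(list("G", "C", "-", "female", 2004, 2008)))
  o3 <- enum_gene_drop(deep, years = 2000:2006)
  i3 <- match("A", o3$roots)
  expect_true(all(o3$rv[i3, ] >= o1$rv[i1, ] - 1e-12))
})

test_that("allele survival is zero exactly when final-year RV is zero", {
  sim <- simulate_population(test_sim_config(seed = 4))
  roster <- identify_founders(sim$pedigree, c(1998, 2002))
  gd <- run_gene_drop(sim$pedigree, roster, n_reps = 400, seed = 8,
                      years = sim$census$year)
  final_rv <- gd$rv[, ncol(gd$rv)]
  surv <- vapply(gd$roots$id, allele_survival_probability, numeric(1), res = gd)
  expect_equal(unname(surv == 0), unname(final_rv == 0))
})

test_that("lineage longevity counts years to genealogical extinction", {
  ped <- pedigree(ped_df(
    list("R", "-", "-", "male", 2000, 2002),
    list("S", "-", "-", "female", 2000, 2010)
  ))
  out <- lineage_longevity(ped, "R", final_year = 2010)
  expect_equal(out$longevity, 2L)
  expect_false(out$survived)

  chain <- pedigree(small_pedigrees()$chain)
  out2 <- lineage_longevity(chain, "A", final_year = 2008)
  expect_equal(out2$longevity, 2008L - 2000L)  # E alive through 2008
  expect_true(out2$survived)
  # capping at final_year
  out3 <- lineage_longevity(chain, "A", final_year = 2006)
  expect_equal(out3$longevity, 6L)
  expect_true(out3$survived)
})

test_that("stabilisation curve ends at 1 and rises on synthetic data", {
  sim <- simulate_population(default_config(seed = 2))
  roster <- identify_founders(sim$pedigree, c(1998, 2002))
  gd <- run_gene_drop(sim$pedigree, roster, n_reps = 500, seed = 12,
                      years = sim$census$year)
  curve <- stabilisation_curve(gd)
  expect_equal(curve$correlation[nrow(curve)], 1)
  n <- nrow(curve)
  late <- mean(curve$correlation[(n - 3):(n - 1)])
  early <- mean(curve$correlation[3:5], na.rm = TRUE)
  expect_gt(late, early)
  expect_gt(late, 0.9)

  # two roots only: correlation is degenerate (+/-1 or undefined)
  ped <- pedigree(trio_df())
  gd2 <- run_gene_drop(ped, n_reps = 100, seed = 1)
  c2 <- stabilisation_curve(gd2)
  ok <- is.na(c2$correlation) | abs(abs(c2$correlation) - 1) < 1e-12
  expect_true(all(ok))
})

test_that("predicted stabilisation time is G log2 N", {
  expect_equal(round(stabilisation_time(2.35, 126.3), 1), 16.4)
  expect_equal(stabilisation_time(1, 2), 1)
  expect_equal(stabilisation_time(2, 1024), 20)
  expect_error(stabilisation_time(2, 1), "exceed 1")
  expect_error(stabilisation_time(0, 10), "positive")
})
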