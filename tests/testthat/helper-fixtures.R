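# compact pedigree constructor for fixtures
ped_df <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r[[1]], sire = r[[2]], dam = r[[3]], sex = r[[4]],
               birth_year = as.integer(r[[5]]), death_year = as.integer(r[[6]]),
               stringsAsFactors = FALSE)
  }))
  df$sire[df$sire == "-"] <- NA_character_
  df$dam[df$dam == "-"] <- NA_character_
  df
}

# A x B -> C; founders die in 2002, C lives to 2005
trio_df <- function() {
  ped_df(
    list("A", "-", "-", "male",   2000, 2002),
    list("B", "-", "-", "female", 2000, 2002),
    list("C", "A", "B", "male",   2001, 2005)
  )
}

# battery of small pedigrees for enumeration-oracle checks
small_pedigrees <- function() {
  list(
    trio = trio_df(),
    # chain: founder pair -> child -> grandchild (other parent unknown each step)
    chain = ped_df(
      list("A", "-", "-", "male",   2000, 2003),
      list("B", "-", "-", "female", 2000, 2002),
      list("C", "A", "B", "female", 2001, 2004),
      list("D", "-", "C", "male",   2003, 2006),
      list("E", "D", "-", "female", 2005, 2008)
    ),
    # sibship: two founder pairs, three sibs, one cross grandchild
    sibship = ped_df(
      list("A", "-", "-", "male",   2000, 2004),
      list("B", "-", "-", "female", 2000, 2003),
      list("C", "-", "-", "male",   2000, 2005),
      list("D", "-", "-", "female", 2000, 2004),
      list("S1", "A", "B", "male",   2001, 2006),
      list("S2", "A", "B", "female", 2001, 2005),
      list("S3", "C", "D", "female", 2002, 2007),
      list("G1", "S1", "S3", "male", 2004, 2009)
    ),
    # half-founder: H has known dam B, unknown sire; H's child
    half = ped_df(
      list("A", "-", "-", "male",   2000, 2003),
      list("B", "-", "-", "female", 2000, 2004),
      list("H", "-", "B", "male",   2001, 2006),
      list("K", "H", "-", "female", 2003, 2008)
    )
  )
}

# small fast simulation config for tests
test_sim_config <- function(...) {
  default_config(n_founders = 40L, n_introduced = 8L, years = 12L,
                 carrying_capacity = 80, immigration_rate = 0.5,
                 bottleneck = list(year = 2005L, severity = 0.5), ...)
}
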