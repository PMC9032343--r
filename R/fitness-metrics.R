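STAGES <- c("eggs", "hatchlings", "fledglings", "recruits", "broods")

#' Lifetime reproductive success at a developmental stage
#'
#' Sum of the individual's per-year offspring counts at the chosen stage
#' over all of its breeding records. An individual absent from the
#' breeding table is a valid zero-fitness parent and returns 0 (with a
#' message).
#'
#' @param breeding breeding-record data frame ([read_breeding()]).
#' @param individual parent id.
#' @param stage one of `"eggs"`, `"hatchlings"`, `"fledglings"`,
#'   `"recruits"`, `"broods"`.
#' @return non-negative integer count.
#' @export
lrs <- function(breeding, individual, stage = "recruits") {
  stage <- match.arg(stage, STAGES)
  rows <- breeding$parent_id == individual
  if (!any(rows)) {
    message("no breeding records for ", individual, "; LRS = 0")
    return(0L)
  }
  sum(breeding[[stage]][rows])
}

#' Individual population transition matrix
#'
#' A square matrix of dimension L = lifespan in breeding ages (1..L,
#' L = death_year - birth_year). The first row holds the offspring counts
#' produced at each parental age, divided by two (each parent contributes
#' half of an offspring's alleles); the sub-diagonal holds 1s (the
#' individual did survive those years); all other entries are 0.
#'
#' @param breeding breeding-record data frame.
#' @param ped a `pedigree` supplying birth/death years.
#' @param individual parent id.
#' @param stage developmental stage at which offspring are counted.
#' @return L x L numeric matrix of class `transition_matrix`.
#' @export
build_transition_matrix <- function(breeding, ped, individual,
                                    stage = "recruits") {
  stage <- match.arg(stage, STAGES)
  i <- match(individual, ped$id)
  if (is.na(i)) stop("unknown individual: ", individual)
  L <- ped$death_year[i] - ped$birth_year[i]
  if (L < 1L) stop("zero adult lifespan for ", individual,
                   " (died in its birth year); no transition matrix")
  rows <- which(breeding$parent_id == individual)
  f <- numeric(L)
  if (length(rows) > 0L) {
    age <- breeding$year[rows] - ped$birth_year[i]
    if (any(age < 1L | age > L)) {
      stop("breeding record at age outside 1..lifespan for ", individual)
    }
    for (k in seq_along(rows)) {
      f[age[k]] <- f[age[k]] + breeding[[stage]][rows[k]]
    }
  }
  transition_matrix(f / 2)
}

#' @rdname build_transition_matrix
#' @param fecundity_row numeric vector of first-row entries (per-age
#'   offspring counts already divided by two).
#' @export
transition_matrix <- function(fecundity_row) {
  L <- length(fecundity_row)
  stopifnot(L >= 1L, all(fecundity_row >= 0))
  M <- matrix(0, L, L)
  M[1L, ] <- fecundity_row
  if (L > 1L) M[cbind(2:L, 1:(L - 1L))] <- 1
  class(M) <- c("transition_matrix", class(M))
  M
}

#' Individual growth rate (IGR)
#'
#' The dominant eigenvalue of an individual population transition matrix.
#' For this non-negative matrix the spectral radius is attained at a real
#' non-negative eigenvalue (Perron-Frobenius), so the dominant eigenvalue
#' is taken as the largest real part among eigenvalues with negligible
#' imaginary part; no diagonalisability is assumed. A matrix with an
#' all-zero first row is nilpotent and has IGR 0.
#'
#' @param M a `transition_matrix` (or any square non-negative matrix).
#' @return the dominant eigenvalue, a non-negative real.
#' @export
igr <- function(M) {
  M <- unclass(M)
  stopifnot(is.matrix(M), nrow(M) == ncol(M), all(M >= 0))
  ev <- eigen(M, only.values = TRUE)$values
  re <- Re(ev[abs(Im(ev)) < 1e-9])
  if (length(re) == 0L) re <- Re(ev)   # conservative fallback; PF gives a real root
  max(0, re)
}

#' IGR for an individual at a stage
#'
#' Convenience wrapper: builds the transition matrix and returns its
#' dominant eigenvalue.
#'
#' @inheritParams build_transition_matrix
#' @return non-negative real.
#' @export
igr_individual <- function(breeding, ped, individual, stage = "recruits") {
  igr(build_transition_matrix(breeding, ped, individual, stage))
}

#' Annual de-lifed fitness
#'
#' The de-lifing estimate of individual i's contribution to population
#' growth in year t:
#' \deqn{p_{ti} = (\xi_t(i) - w_t) / (N_t - 1)}
#' where \eqn{\xi_t(i)} is the number of i's surviving offspring at the
#' end of the time step (offspring born in year t that are alive as
#' adults in year t+1), weighted by `offspring_weight`, plus 1 if i
#' itself survived to year t+1; \eqn{w_t = N_{t+1}/N_t} is the realised
#' annual growth ratio; and \eqn{N_t} is the adult census in year t.
#'
#' `offspring_weight = 1` follows the verbatim term definition (each
#' parent credited a whole offspring); `offspring_weight = 0.5` splits
#' each offspring between its two parents and is the choice under which
#' the population-level sum of \eqn{p_{ti}} over all adults is exactly 0.
#'
#' @param breeding breeding-record data frame (used for validation only;
#'   surviving offspring are read from the pedigree).
#' @param census census data frame with years t and t+1.
#' @param ped a `pedigree`.
#' @param individual id, alive as an adult in year t.
#' @param year year t.
#' @param offspring_weight 1 (default) or 0.5.
#' @return real number.
#' @export
delifed_annual <- function(breeding, census, ped, individual, year,
                           offspring_weight = 1) {
  i <- match(individual, ped$id)
  if (is.na(i)) stop("unknown individual: ", individual)
  if (ped$birth_year[i] + 1L > year || ped$death_year[i] < year) {
    stop(individual, " is not an adult alive in year ", year)
  }
  Nt <- census_n(census, year)
  Nt1 <- census_n(census, year + 1L)
  if (Nt < 2L) stop("de-lifing needs N_t >= 2 (year ", year, ")")
  w <- Nt1 / Nt
  kids <- which((!is.na(ped$sire) & ped$sire == individual) |
                  (!is.na(ped$dam) & ped$dam == individual))
  n_surv <- sum(ped$birth_year[kids] == year & ped$death_year[kids] >= year + 1L)
  xi <- offspring_weight * n_surv + as.integer(ped$death_year[i] >= year + 1L)
  (xi - w) / (Nt - 1)
}

#' Lifetime de-lifed fitness
#'
#' Sum of [delifed_annual()] over all of the individual's adult years for
#' which the census allows the annual value to be computed (year t and
#' t+1 both censused).
#'
#' @inheritParams delifed_annual
#' @return real number.
#' @export
delifed_lifetime <- function(breeding, census, ped, individual,
                             offspring_weight = 1) {
  sum(annual_delifed_by_age(breeding, census, ped, individual,
                            offspring_weight))
}

#' Annual de-lifed fitness by age class
#'
#' One entry per adult age attained (age = year - birth_year, from 1 up
#' to the age at death), restricted to years where the census provides
#' both t and t+1.
#'
#' @inheritParams delifed_annual
#' @return named numeric vector; names are ages.
#' @export
annual_delifed_by_age <- function(breeding, census, ped, individual,
                                  offspring_weight = 1) {
  i <- match(individual, ped$id)
  if (is.na(i)) stop("unknown individual: ", individual)
  yrs <- seq(ped$birth_year[i] + 1L, ped$death_year[i])
  yrs <- yrs[yrs %in% census$year & (yrs + 1L) %in% census$year]
  if (length(yrs) == 0L) return(stats::setNames(numeric(0), character(0)))
  p <- vapply(yrs, function(t) {
    delifed_annual(breeding, census, ped, individual, t, offspring_weight)
  }, numeric(1))
  stats::setNames(p, yrs - ped$birth_year[i])
}

#' Founder fitness table
#'
#' One row per roster individual with complete life history: LRS at every
#' stage, IGR at the four offspring stages, lifetime de-lifed fitness and
#' the annual de-lifed values by age. Individuals that died in their
#' birth year (no adult lifespan, hence no transition matrix) or whose
#' fate is unknown by `final_year` are excluded and reported in the
#' `excluded` attribute, mirroring the removal of founders with
#' incomplete life-history data.
#'
#' @param ped a `pedigree`.
#' @param breeding breeding-record data frame.
#' @param census census data frame.
#' @param roster founder roster ([identify_founders()]).
#' @param final_year last study year.
#' @param offspring_weight de-lifing offspring weight (1 or 0.5).
#' @param max_age highest de-lifing age column to emit; default the
#'   highest age attained in the roster.
#' @return data frame with attribute `excluded` (data frame id + reason).
#' @export
fitness_table <- function(ped, breeding, census, roster,
                          final_year = max(census$year),
                          offspring_weight = 1, max_age = NULL) {
  i <- match(roster$id, ped$id)
  lifespan <- ped$death_year[i] - ped$birth_year[i]
  reason <- rep(NA_character_, nrow(roster))
  reason[lifespan < 1L] <- "died as juvenile (no adult lifespan)"
  reason[is.na(reason) & ped$death_year[i] > final_year] <-
    "fate beyond final study year"
  keep <- is.na(reason)
  excluded <- data.frame(id = roster$id[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  ids <- roster$id[keep]

  by_age <- lapply(ids, function(id) {
    annual_delifed_by_age(breeding, census, ped, id, offspring_weight)
  })
  if (is.null(max_age)) {
    max_age <- max(c(1L, unlist(lapply(by_age, function(v) as.integer(names(v))))))
  }
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  for (s in STAGES) {
    out[[paste0("lrs_", s)]] <-
      vapply(ids, function(id) as.numeric(suppressMessages(lrs(breeding, id, s))),
             numeric(1))
  }
  for (s in setdiff(STAGES, "broods")) {
    out[[paste0("igr_", s)]] <-
      vapply(ids, function(id) igr_individual(breeding, ped, id, s), numeric(1))
  }
  out$delifed_lifetime <- vapply(by_age, sum, numeric(1))
  for (a in seq_len(max_age)) {
    out[[paste0("delifed_age", a)]] <- vapply(by_age, function(v) {
      k <- match(as.character(a), names(v))
      if (is.na(k)) NA_real_ else v[[k]]
    }, numeric(1))
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
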