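#' Monte-Carlo gene dropping through a pedigree
#'
#' Every lineage root (an individual with at least one unknown parent)
#' is assigned novel alleles on its unknown-parent side(s): two for a
#' founder, one for a half-founder (the known-parent side is inherited
#' like any other allele). Each fully-known transmission draws one of the
#' parent's two alleles uniformly at random, independently per offspring
#' and per replicate. Allele copies are then counted per lineage root in
#' every census year among all individuals alive that year (interval
#' `birth_year`..`death_year`).
#'
#' Roots born outside the analysis cohort still receive novel alleles and
#' are tracked (flagged `cohort = FALSE`), so that in every replicate and
#' year the copy counts over all roots sum to exactly twice the number of
#' individuals alive — the conservation property.
#'
#' Reproducibility: per-replicate seeds are derived once from `seed`, and
#' each replicate's transmission uniforms come from its own stream, so an
#' identical call reproduces the result bit-for-bit and any single
#' replicate can be regenerated in isolation.
#'
#' @param ped a validated [pedigree()].
#' @param roster founder roster from [identify_founders()]; roots outside
#'   it are kept as non-cohort roots. `NULL` means every root is cohort.
#' @param n_reps number of replicates (the study design uses 10,000).
#' @param seed integer RNG seed.
#' @param years census years over which copies are counted; default
#'   `min(birth_year):max(death_year)`.
#' @param reference `"alive"` counts copies among all individuals alive in
#'   a year; `"adults"` restricts to individuals of age >= 1.
#' @param keep_counts if `TRUE`, retain the full root x year x replicate
#'   count array (memory heavy; intended for small pedigrees/tests).
#' @return an object of class `gene_drop` with elements `roots` (data
#'   frame: id, cohort, n_root_alleles), `years`, `rv` (root x year mean
#'   copy counts), `final_counts` (root x replicate copy counts in the
#'   last year), `totals` (year x replicate total copies), `alive_n`,
#'   `n_reps`, `seed`, and optionally `counts`.
#' @export
run_gene_drop <- function(ped, roster = NULL, n_reps = 10000L, seed = 1L,
                          years = NULL, reference = c("alive", "adults"),
                          keep_counts = FALSE) {
  reference <- match.arg(reference)
  stopifnot(n_reps >= 1L)
  n <- nrow(ped)
  if (n == 0L) stop("empty pedigree")
  if (is.null(years)) years <- seq(min(ped$birth_year), max(ped$death_year))
  if (any(is.na(ped$birth_year)) || any(is.na(ped$death_year))) {
    stop("every individual needs birth and death years")
  }

  ord <- match(topological_order(ped), ped$id)
  sire <- match(ped$sire, ped$id)
  dam  <- match(ped$dam, ped$id)

  is_root <- is.na(sire) | is.na(dam)
  root_ids <- ped$id[is_root]
  nR <- length(root_ids)
  root_label <- integer(n)                      # 0 = not a root
  root_label[is_root] <- seq_len(nR)
  cohort <- if (is.null(roster)) rep(TRUE, nR) else root_ids %in% roster$id

  # per-replicate uniform streams
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  U <- matrix(0, nrow = 2L * n, ncol = n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    U[, r] <- stats::runif(2L * n)
  }

  pat <- matrix(0L, nrow = n, ncol = n_reps)
  mat <- matrix(0L, nrow = n, ncol = n_reps)
  for (i in ord) {
    si <- sire[i]; di <- dam[i]
    if (is.na(si)) {
      pat[i, ] <- root_label[i]
    } else {
      take_pat <- U[2L * i - 1L, ] < 0.5
      pat[i, ] <- ifelse(take_pat, pat[si, ], mat[si, ])
    }
    if (is.na(di)) {
      mat[i, ] <- root_label[i]
    } else {
      take_pat <- U[2L * i, ] < 0.5
      mat[i, ] <- ifelse(take_pat, pat[di, ], mat[di, ])
    }
  }
  rm(U)

  nY <- length(years)
  rv <- matrix(0, nrow = nR, ncol = nY, dimnames = list(root_ids, years))
  totals <- matrix(0L, nrow = nY, ncol = n_reps)
  alive_n <- integer(nY)
  counts <- if (keep_counts) array(0L, dim = c(nR, nY, n_reps),
                                   dimnames = list(root_ids, years, NULL)) else NULL
  final_counts <- matrix(0L, nrow = nR, ncol = n_reps,
                         dimnames = list(root_ids, NULL))

  min_year <- if (reference == "alive") ped$birth_year else ped$birth_year + 1L
  for (k in seq_len(nY)) {
    y <- years[k]
    alive <- which(min_year <= y & ped$death_year >= y)
    alive_n[k] <- length(alive)
    if (length(alive) == 0L) next
    L <- rbind(pat[alive, , drop = FALSE], mat[alive, , drop = FALSE])
    off <- rep.int(0:(n_reps - 1L), rep.int(nrow(L), n_reps)) * nR
    cnt <- tabulate(as.vector(L) + off, nbins = nR * n_reps)
    dim(cnt) <- c(nR, n_reps)
    rv[, k] <- rowMeans(cnt)
    totals[k, ] <- colSums(cnt)
    if (keep_counts) counts[, k, ] <- cnt
    if (k == nY) final_counts[, ] <- cnt
  }

  structure(list(
    roots = data.frame(id = root_ids, cohort = cohort,
                       n_root_alleles = is.na(sire[is_root]) + is.na(dam[is_root]),
                       stringsAsFactors = FALSE),
    years = years, rv = rv, final_counts = final_counts, totals = totals,
    alive_n = alive_n, n_reps = n_reps, seed = as.integer(seed),
    reference = reference, counts = counts
  ), class = "gene_drop")
}

#' @export
print.gene_drop <- function(x, ...) {
  cat("Gene-drop result:", nrow(x$roots), "lineage roots (",
      sum(x$roots$cohort), "cohort ),", x$n_reps, "replicates,",
      length(x$years), "years", min(x$years), "-", max(x$years), "\n")
  invisible(x)
}

root_index <- function(res, root) {
  i <- match(root, res$roots$id)
  if (is.na(i)) stop("unknown lineage root: ", root)
  i
}

#' Reproductive value of a lineage root in a given year
#'
#' The mean, over gene-drop replicates, of the number of the root's allele
#' copies carried by individuals alive in `year`. Absolute (a count of
#' expected copies), not normalised by population size.
#'
#' @param res a `gene_drop` result.
#' @param root lineage root id.
#' @param year census year inside the simulated range.
#' @return non-negative real.
#' @export
reproductive_value <- function(res, root, year) {
  i <- root_index(res, root)
  k <- match(year, res$years)
  if (is.na(k)) stop("year ", year, " outside simulated range")
  unname(res$rv[i, k])
}

#' Allele survival probability of a lineage
#'
#' Fraction of gene-drop replicates in which at least one of the root's
#' allele copies is carried by an individual alive in the final simulated
#' year.
#'
#' @inheritParams reproductive_value
#' @return probability in \[0, 1\].
#' @export
allele_survival_probability <- function(res, root) {
  i <- root_index(res, root)
  mean(res$final_counts[i, ] > 0L)
}

#' Lineage longevity and genealogical survival
#'
#' Years from the root's birth to the last year in which the root or any
#' genealogical descendant is alive, capped at `final_year`. The lineage
#' "survived" iff that last year reaches `final_year`. This is the
#' deterministic, genealogical notion (a single outcome per lineage), as
#' opposed to the per-replicate allele-survival of the gene drop.
#'
#' @param ped a `pedigree`.
#' @param root individual id of the lineage root.
#' @param final_year last study year.
#' @return list with `longevity` (integer years) and `survived` (logical).
#' @export
lineage_longevity <- function(ped, root, final_year) {
  i <- match(root, ped$id)
  if (is.na(i)) stop("unknown individual: ", root)
  members <- c(root, descendants(ped, root))
  last <- max(ped$death_year[match(members, ped$id)])
  list(longevity = min(last, final_year) - ped$birth_year[i],
       survived = last >= final_year)
}

#' Stabilisation curve of reproductive values
#'
#' Pearson correlation, per year, between the vector of per-root
#' reproductive values in that year and in the final year. As lineages
#' sort themselves out the curve rises towards 1 (exactly 1 in the final
#' year). Years in which either vector has zero variance give `NA`.
#'
#' @param res a `gene_drop` result.
#' @param final_year year to correlate against; default the last
#'   simulated year.
#' @param cohort_only use only cohort roots (default) or all roots.
#' @return data frame with columns `year` and `correlation`.
#' @export
stabilisation_curve <- function(res, final_year = max(res$years),
                                cohort_only = TRUE) {
  kf <- match(final_year, res$years)
  if (is.na(kf)) stop("final_year outside simulated range")
  rows <- if (cohort_only) which(res$roots$cohort) else seq_len(nrow(res$roots))
  if (length(rows) < 2L) stop("need at least 2 roots for a correlation")
  final <- res$rv[rows, kf]
  corr <- vapply(seq_along(res$years), function(k) {
    x <- res$rv[rows, k]
    if (stats::sd(x) == 0 || stats::sd(final) == 0) return(NA_real_)
    stats::cor(x, final)
  }, numeric(1))
  # final year against itself is 1 by definition (guard against fp noise)
  if (!is.na(corr[kf])) corr[kf] <- 1
  data.frame(year = res$years, correlation = corr)
}

#' Predicted stabilisation time of reproductive values
#'
#' Reproductive values stop changing rank after roughly `log2(N)`
#' generations, i.e. `G * log2(N)` years for generation time `G` and
#' population size `N`.
#'
#' @param G generation time in years, > 0.
#' @param N population size, > 1.
#' @return predicted stabilisation time in years.
#' @export
stabilisation_time <- function(G, N) {
  if (G <= 0) stop("generation time G must be positive")
  if (N <= 1) stop("population size N must exceed 1")
  G * log2(N)
}

#' Per-root summary of a gene-drop run
#'
#' One row per cohort lineage root: origin/status from the roster,
#' reproductive value in the final year, allele survival probability,
#' genealogical lineage longevity and survival indicator.
#'
#' @param res a `gene_drop` result.
#' @param ped the pedigree used for the run.
#' @param roster founder roster ([identify_founders()]).
#' @param final_year last study year; default the last simulated year.
#' @return data frame, one row per roster entry.
#' @export
gene_drop_summary <- function(res, ped, roster, final_year = max(res$years)) {
  kf <- match(final_year, res$years)
  if (is.na(kf)) stop("final_year outside simulated range")
  i <- match(roster$id, res$roots$id)
  if (any(is.na(i))) stop("roster id(s) absent from gene-drop result")
  lin <- lapply(roster$id, lineage_longevity, ped = ped, final_year = final_year)
  data.frame(
    id = roster$id,
    origin = roster$origin,
    status = roster$status,
    rv_final = res$rv[i, kf],
    allele_survival = vapply(roster$id, allele_survival_probability, numeric(1),
                             res = res),
    lineage_longevity = vapply(lin, `[[`, integer(1), "longevity"),
    survived = vapply(lin, `[[`, logical(1), "survived"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
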