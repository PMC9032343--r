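#' Construct and validate a pedigree
#'
#' A pedigree is a data frame with one row per individual and columns
#' `id`, `sire`, `dam`, `sex`, `birth_year`, `death_year` (plus optional
#' extra columns such as `origin`, which are carried along). Missing
#' parents are `NA`. Validation enforces: unique ids, every referenced
#' parent present, acyclic parent-offspring structure, `birth_year <=
#' death_year`, parents born strictly before their offspring, sires not
#' female and dams not male. A parent recorded with unknown sex is
#' assigned the sex implied by its role, with a warning.
#'
#' @param df data frame with the columns listed above.
#' @return the validated data frame with class `"pedigree"`.
#' @export
pedigree <- function(df) {
  req <- c("id", "sire", "dam", "sex", "birth_year", "death_year")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("pedigree is missing column(s): ", paste(miss, collapse = ", "))
  }
  df$id   <- as.character(df$id)
  df$sire <- as_parent(df$sire)
  df$dam  <- as_parent(df$dam)
  df$sex  <- as.character(df$sex)
  df$birth_year <- as.integer(df$birth_year)
  df$death_year <- as.integer(df$death_year)

  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0L) {
    stop("duplicate individual id(s): ", paste(unique(dup), collapse = ", "))
  }
  bad_sex <- !df$sex %in% c("male", "female", "unknown")
  if (any(bad_sex)) {
    stop("invalid sex value(s): ", paste(unique(df$sex[bad_sex]), collapse = ", "))
  }
  unknown_parent <- setdiff(c(df$sire, df$dam), c(df$id, NA))
  if (length(unknown_parent) > 0L) {
    stop("parent id(s) not present as individuals: ",
         paste(unknown_parent, collapse = ", "))
  }
  if (any(is.na(df$birth_year)) || any(is.na(df$death_year))) {
    stop("birth_year and death_year must be non-missing integers")
  }
  bad_life <- df$birth_year > df$death_year
  if (any(bad_life)) {
    stop("birth_year > death_year for: ", paste(df$id[bad_life], collapse = ", "))
  }

  # implied sex for parents recorded with unknown sex
  sires <- unique(df$sire[!is.na(df$sire)])
  dams  <- unique(df$dam[!is.na(df$dam)])
  both  <- intersect(sires, dams)
  if (length(both) > 0L) {
    stop("individual(s) appear as both sire and dam: ", paste(both, collapse = ", "))
  }
  sx <- match(sires, df$id)
  if (any(df$sex[sx] == "female")) {
    stop("female individual(s) listed as sire: ",
         paste(sires[df$sex[sx] == "female"], collapse = ", "))
  }
  dx <- match(dams, df$id)
  if (any(df$sex[dx] == "male")) {
    stop("male individual(s) listed as dam: ",
         paste(dams[df$sex[dx] == "male"], collapse = ", "))
  }
  fix_s <- sx[df$sex[sx] == "unknown"]
  if (length(fix_s) > 0L) {
    warning("assigning sex 'male' to sire(s) of unknown sex: ",
            paste(df$id[fix_s], collapse = ", "))
    df$sex[fix_s] <- "male"
  }
  fix_d <- dx[df$sex[dx] == "unknown"]
  if (length(fix_d) > 0L) {
    warning("assigning sex 'female' to dam(s) of unknown sex: ",
            paste(df$id[fix_d], collapse = ", "))
    df$sex[fix_d] <- "female"
  }

  # acyclicity (also catches self-parentage); errors list one cycle
  check_acyclic(df)

  # parents born strictly before offspring
  for (col in c("sire", "dam")) {
    p <- match(df[[col]], df$id)
    has <- !is.na(p)
    bad <- has & df$birth_year[p] >= df$birth_year
    if (any(bad, na.rm = TRUE)) {
      stop(col, " born in or after offspring's birth year for offspring: ",
           paste(df$id[which(bad)], collapse = ", "))
    }
  }

  rownames(df) <- NULL
  class(df) <- c("pedigree", "data.frame")
  df
}

as_parent <- function(x) {
  x <- as.character(x)
  x[!is.na(x) & (x == "" | x == "NA")] <- NA_character_
  x
}

# Kahn's algorithm; stops with one explicit cycle if the structure is cyclic
check_acyclic <- function(df) {
  ord <- topo_sort_ids(df)
  if (!is.null(attr(ord, "cycle"))) {
    stop("pedigree contains a cycle: ",
         paste(attr(ord, "cycle"), collapse = " -> "))
  }
  invisible(TRUE)
}

topo_sort_ids <- function(df) {
  n <- nrow(df)
  if (n == 0L) return(character(0))
  id <- df$id
  sire <- match(df$sire, id)
  dam  <- match(df$dam, id)
  indeg <- (!is.na(sire)) + (!is.na(dam))
  # children adjacency
  kids <- vector("list", n)
  for (j in seq_len(n)) {
    for (p in c(sire[j], dam[j])) {
      if (!is.na(p)) kids[[p]] <- c(kids[[p]], j)
    }
  }
  out <- integer(0)
  avail <- which(indeg == 0L)
  avail <- avail[order(id[avail])]
  while (length(avail) > 0L) {
    v <- avail[1L]
    avail <- avail[-1L]
    out <- c(out, v)
    ch <- kids[[v]]
    if (length(ch) > 0L) {
      indeg[ch] <- indeg[ch] - ifelse(!is.na(sire[ch]) & sire[ch] == v, 1L, 0L) -
        ifelse(!is.na(dam[ch]) & dam[ch] == v, 1L, 0L)
      newly <- ch[indeg[ch] == 0L]
      if (length(newly) > 0L) {
        avail <- sort(union(avail, newly))
        avail <- avail[order(id[avail])]
      }
    }
  }
  if (length(out) < n) {
    # walk parent links from a remaining node until a repeat gives a cycle
    left <- setdiff(seq_len(n), out)
    v <- left[1L]
    path <- v
    repeat {
      p <- if (!is.na(sire[v]) && sire[v] %in% left) sire[v] else dam[v]
      if (p %in% path) {
        cyc <- id[c(path[which(path == p)[1L]:length(path)], p)]
        res <- id[out]
        attr(res, "cycle") <- cyc
        return(res)
      }
      path <- c(path, p)
      v <- p
    }
  }
  id[out]
}

#' Read a pedigree file
#'
#' Reads a tab- or comma-separated file with header columns `id`, `sire`,
#' `dam`, `sex`, `birth_year`, `death_year`; a missing parent may be coded
#' as an empty cell or the string `NA`. Extra columns (e.g. `origin`) are
#' kept. The result is validated with [pedigree()].
#'
#' @param path file path.
#' @return a `pedigree` object.
#' @export
read_pedigree <- function(path) {
  df <- read_delimited(path)
  pedigree(df)
}

#' Write a pedigree file
#'
#' Writes the comma-separated dialect that [read_pedigree()] reads back
#' field-for-field (missing parents as `NA`).
#'
#' @param ped a `pedigree`.
#' @param path output file path.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.csv(as.data.frame(ped), path, row.names = FALSE, na = "NA",
                   quote = FALSE)
  invisible(path)
}

# sep sniffing: tab wins if present in the header line
read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""), colClasses = NA,
                    check.names = TRUE)
}

#' Read a breeding-record file
#'
#' Columns `parent_id`, `year`, `eggs`, `hatchlings`, `fledglings`,
#' `recruits`, `broods`. Counts must be non-negative and satisfy the
#' developmental-stage ordering `recruits <= fledglings <= hatchlings <=
#' eggs` within each record.
#'
#' @param path file path.
#' @param ped optional `pedigree`; if given, each record's year is checked
#'   to lie within the parent's breeding span
#'   (`birth_year + 1` to `death_year`).
#' @return a data frame of breeding records.
#' @export
read_breeding <- function(path, ped = NULL) {
  df <- read_delimited(path)
  validate_breeding(df, ped)
}

#' @rdname read_breeding
#' @param df a data frame of breeding records to validate in place.
#' @export
validate_breeding <- function(df, ped = NULL) {
  req <- c("parent_id", "year", "eggs", "hatchlings", "fledglings",
           "recruits", "broods")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) {
    stop("breeding table is missing column(s): ", paste(miss, collapse = ", "))
  }
  df$parent_id <- as.character(df$parent_id)
  for (col in req[-1L]) df[[col]] <- as.integer(df[[col]])
  cnt <- as.matrix(df[, c("eggs", "hatchlings", "fledglings", "recruits", "broods")])
  if (any(cnt < 0L)) stop("negative counts in breeding table")
  bad <- with(df, recruits > fledglings | fledglings > hatchlings | hatchlings > eggs)
  if (any(bad)) {
    stop("stage ordering violated (need recruits <= fledglings <= hatchlings <= eggs) ",
         "for parent(s): ", paste(unique(df$parent_id[bad]), collapse = ", "))
  }
  if (!is.null(ped)) {
    i <- match(df$parent_id, ped$id)
    if (any(is.na(i))) {
      stop("breeding records for unknown parent(s): ",
           paste(unique(df$parent_id[is.na(i)]), collapse = ", "))
    }
    bad <- df$year < ped$birth_year[i] + 1L | df$year > ped$death_year[i]
    if (any(bad)) {
      stop("breeding year outside parent's adult lifespan for: ",
           paste(unique(df$parent_id[bad]), collapse = ", "))
    }
  }
  df
}

#' Read an adult census file
#'
#' Columns `year` and `n_adults`; years must form a contiguous range and
#' all counts be at least 1.
#'
#' @param path file path.
#' @return a data frame with columns `year`, `n_adults`.
#' @export
read_census <- function(path) {
  df <- read_delimited(path)
  validate_census(df)
}

#' @rdname read_census
#' @param df census data frame to validate.
#' @export
validate_census <- function(df) {
  if (!all(c("year", "n_adults") %in% names(df))) {
    stop("census table needs columns year, n_adults")
  }
  df$year <- as.integer(df$year)
  df$n_adults <- as.integer(df$n_adults)
  df <- df[order(df$year), , drop = FALSE]
  if (nrow(df) > 1L && !all(diff(df$year) == 1L)) {
    stop("census years must be contiguous")
  }
  if (any(df$n_adults < 1L)) stop("census counts must be >= 1")
  rownames(df) <- NULL
  df
}

census_n <- function(census, year) {
  i <- match(year, census$year)
  if (any(is.na(i))) stop("census has no year ", paste(year[is.na(i)], collapse = ", "))
  census$n_adults[i]
}

#' Identify founders and half-founders
#'
#' Founders have both parents unknown and contribute two novel root
#' alleles; half-founders have exactly one parent unknown and contribute
#' one. Only individuals born inside `cohort_window` enter the roster
#' (the analysis cohort of lineage roots).
#'
#' @param ped a `pedigree`.
#' @param cohort_window length-2 integer vector `c(first, last)` of birth
#'   years admitted to the roster.
#' @return data frame with columns `id`, `origin`, `status`
#'   (`"founder"`/`"half_founder"`), `n_root_alleles`, `cohort_year`.
#' @export
identify_founders <- function(ped, cohort_window = range(ped$birth_year)) {
  stopifnot(length(cohort_window) == 2L)
  n_unk <- is.na(ped$sire) + is.na(ped$dam)
  keep <- n_unk > 0L &
    ped$birth_year >= cohort_window[1L] & ped$birth_year <= cohort_window[2L]
  origin <- if ("origin" %in% names(ped)) as.character(ped$origin) else
    rep("unknown", nrow(ped))
  roster <- data.frame(
    id = ped$id[keep],
    origin = origin[keep],
    status = ifelse(n_unk[keep] == 2L, "founder", "half_founder"),
    n_root_alleles = n_unk[keep],
    cohort_year = ped$birth_year[keep],
    stringsAsFactors = FALSE
  )
  roster <- roster[order(roster$id), , drop = FALSE]
  rownames(roster) <- NULL
  if (nrow(roster) == 0L) warning("empty founder roster for the given window")
  roster
}

#' Topological order of a pedigree
#'
#' Returns the individual ids ordered so that every parent precedes all of
#' its offspring; ties are broken by id sort, so the order is deterministic
#' for identical input.
#'
#' @param ped a `pedigree`.
#' @return character vector of ids.
#' @export
topological_order <- function(ped) {
  ord <- topo_sort_ids(ped)
  if (!is.null(attr(ord, "cycle"))) {
    stop("pedigree contains a cycle: ", paste(attr(ord, "cycle"), collapse = " -> "))
  }
  ord
}

#' Genealogical descendants of an individual
#'
#' @param ped a `pedigree`.
#' @param id individual id.
#' @return character vector of descendant ids (excluding `id` itself).
#' @export
descendants <- function(ped, id) {
  if (!id %in% ped$id) stop("unknown individual: ", id)
  out <- character(0)
  frontier <- id
  while (length(frontier) > 0L) {
    kids <- ped$id[(!is.na(ped$sire) & ped$sire %in% frontier) |
                     (!is.na(ped$dam) & ped$dam %in% frontier)]
    kids <- setdiff(kids, out)
    out <- c(out, kids)
    frontier <- kids
  }
  unique(out)
}
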