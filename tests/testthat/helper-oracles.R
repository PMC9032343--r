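# Independent oracles. These share no code with the package paths they
# check: the gene-drop oracle enumerates every Mendelian transmission
# outcome exhaustively; the growth-rate oracle finds characteristic-
# polynomial roots; the Fisher oracle sums hypergeometric probabilities.

# Exhaustive gene-drop enumeration for tiny pedigrees.
# Every (individual, known-parent) link is one binary choice; all 2^k
# outcomes are equally likely. Returns exact per-root x year mean copy
# counts, the outcome SD (for Monte-Carlo standard errors), and exact
# allele-survival probabilities.
enum_gene_drop <- function(df, years = NULL) {
  n <- nrow(df)
  if (is.null(years)) years <- seq(min(df$birth_year), max(df$death_year))
  sire <- match(df$sire, df$id)
  dam <- match(df$dam, df$id)
  # order so parents come first (insertion by repeated scan; tiny n)
  ord <- integer(0)
  left <- seq_len(n)
  while (length(left) > 0) {
    ready <- left[vapply(left, function(i) {
      (is.na(sire[i]) || sire[i] %in% ord) && (is.na(dam[i]) || dam[i] %in% ord)
    }, logical(1))]
    stopifnot(length(ready) > 0)
    ord <- c(ord, ready)
    left <- setdiff(left, ready)
  }
  is_root <- is.na(sire) | is.na(dam)
  roots <- df$id[is_root]
  nR <- length(roots)
  rlab <- integer(n); rlab[is_root] <- seq_len(nR)

  slots <- list()
  for (i in ord) {
    if (!is.na(sire[i])) slots[[length(slots) + 1L]] <- c(i, 1L)
    if (!is.na(dam[i]))  slots[[length(slots) + 1L]] <- c(i, 2L)
  }
  k <- length(slots)
  nY <- length(years)
  sum_cnt <- matrix(0, nR, nY)
  sumsq_cnt <- matrix(0, nR, nY)
  surv_cnt <- numeric(nR)

  for (g in 0:(2^k - 1)) {
    bits <- bitwAnd(bitwShiftR(g, 0:(max(k - 1, 0))), 1L)
    pat <- integer(n); mat <- integer(n)
    b <- 1L
    for (i in ord) {
      if (is.na(sire[i])) pat[i] <- rlab[i] else {
        pick <- bits[b]; b <- b + 1L
        pat[i] <- if (pick == 0L) pat[sire[i]] else mat[sire[i]]
      }
      if (is.na(dam[i])) mat[i] <- rlab[i] else {
        pick <- bits[b]; b <- b + 1L
        mat[i] <- if (pick == 0L) pat[dam[i]] else mat[dam[i]]
      }
    }
    cnt <- matrix(0, nR, nY)
    for (j in seq_len(nY)) {
      alive <- which(df$birth_year <= years[j] & df$death_year >= years[j])
      for (i in alive) {
        cnt[pat[i], j] <- cnt[pat[i], j] + 1
        cnt[mat[i], j] <- cnt[mat[i], j] + 1
      }
    }
    sum_cnt <- sum_cnt + cnt
    sumsq_cnt <- sumsq_cnt + cnt^2
    surv_cnt <- surv_cnt + (cnt[, nY] > 0)
  }
  nout <- 2^k
  mean_cnt <- sum_cnt / nout
  var_cnt <- pmax(sumsq_cnt / nout - mean_cnt^2, 0)
  list(roots = roots, years = years, rv = mean_cnt, sd = sqrt(var_cnt),
       surv_prob = surv_cnt / nout)
}

# Dominant eigenvalue of a Leslie-type transition matrix via the roots of
# its characteristic polynomial lambda^L = f1 lambda^(L-1) + ... + fL.
charpoly_igr <- function(fecundity_row) {
  f <- fecundity_row
  L <- length(f)
  if (all(f == 0)) return(0)
  coef <- c(-rev(f), 1)            # ascending powers
  r <- polyroot(coef)
  re <- Re(r[abs(Im(r)) < 1e-7])
  max(0, re)
}

# power iteration with deflation-free Rayleigh estimate (second oracle route)
power_igr <- function(M, iters = 50000, tol = 1e-13) {
  v <- rep(1, nrow(M))
  lam <- 0
  for (i in seq_len(iters)) {
    w <- M %*% v
    nl <- sqrt(sum(w^2))
    if (nl == 0) return(0)
    w <- w / nl
    lam_new <- as.numeric(t(w) %*% M %*% w)
    if (abs(lam_new - lam) < tol) return(lam_new)
    lam <- lam_new
    v <- w
  }
  lam
}

# Two-sided Fisher p by direct hypergeometric enumeration
enum_fisher_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(c1, r1)
  probs <- dhyper(lo:hi, r1, r2, c1)
  p_obs <- dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided rank-sum p by enumerating all subsets (no ties)
enum_ranksum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- rank(c(x, y))
  W_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(N, n1)
  W_all <- colSums(matrix(rk[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  p_lo <- mean(W_all <= W_obs)
  p_hi <- mean(W_all >= W_obs)
  min(1, 2 * min(p_lo, p_hi))
}
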