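# Frequency-spectrum tests of neutrality: Tajima's D, Fu & Li's D, D*, F,
# F* (with or without an outgroup), and Fu's Fs via the Ewens sampling
# distribution. Statistics that are undefined for the input (e.g. S = 0)
# return NA_real_ rather than raising, so summary tables render cleanly.

harmonic <- function(m) if (m < 1) 0 else sum(1 / seq_len(m))
harmonic2 <- function(m) if (m < 1) 0 else sum(1 / seq_len(m)^2)

tajima_constants <- function(n) {
  a1 <- harmonic(n - 1); a2 <- harmonic2(n - 1)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' \eqn{D = (\hat\pi - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}} with the Tajima
#' (1989) coefficients.
#'
#' @param n Sample size (>= 4).
#' @param S Number of segregating sites.
#' @param pi Mean pairwise differences.
#' @return The statistic, or `NA_real_` when `S == 0` (undefined).
#' @export
tajimas_d <- function(n, S, pi) {
  if (n < 4) stop("Tajima's D requires n >= 4")
  if (S < 1) return(NA_real_)
  k <- tajima_constants(n)
  (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

fu_li_constants <- function(n) {
  an <- harmonic(n - 1); bn <- harmonic2(n - 1); an1 <- harmonic(n)
  cn <- if (n == 2) 1 else 2 * (n * an - 2 * (n - 1)) / ((n - 1) * (n - 2))
  dn <- if (n == 2) 2 else
    cn + (n - 2) / (n - 1)^2 +
      2 / (n - 1) * (3 / 2 - (2 * an1 - 3) / (n - 2) - 1 / n)
  vD <- 1 + an^2 / (bn + an^2) * (cn - (n + 1) / (n - 1))
  uD <- an - 1 - vD
  vF <- (cn + 2 * (n^2 + n + 3) / (9 * n * (n - 1)) - 2 / (n - 1)) /
    (an^2 + bn)
  uF <- (1 + (n + 1) / (3 * (n - 1)) -
           4 * (n + 1) / (n - 1)^2 * (an1 - 2 * n / (n + 1))) / an - vF
  vDs <- ((n / (n - 1))^2 * bn + an^2 * dn -
            2 * n * an * (an + 1) / (n - 1)^2) / (an^2 + bn)
  uDs <- n / (n - 1) * (an - n / (n - 1)) - vDs
  # F* variance coefficients: Simonsen, Churchill & Aquadro (1995)
  # corrected form of Fu & Li's expression
  vFs <- ((2 * n^3 + 110 * n^2 - 255 * n + 153) / (9 * n^2 * (n - 1)) +
            2 * (n - 1) * an / n^2 - 8 * bn / n) / (an^2 + bn)
  uFs <- ((4 * n^2 + 19 * n + 3 - 12 * (n + 1) * an1) /
            (3 * n * (n - 1))) / an - vFs
  list(an = an, bn = bn, uD = uD, vD = vD, uF = uF, vF = vF,
       uDs = uDs, vDs = vDs, uFs = uFs, vFs = vFs)
}

#' Fu & Li's tests
#'
#' With an outgroup, `eta_e` is the number of derived singleton (external)
#' mutations and the statistics are D and F; without, `eta_s` is the number
#' of singleton mutations and the starred statistics D* and F* apply.
#' Coefficients follow Fu & Li (1993) with the Simonsen et al. (1995)
#' corrections, matching common software behaviour.
#'
#' @param n Sample size.
#' @param eta Total number of mutations.
#' @param eta_external Derived singletons (`outgroup = TRUE`) or singleton
#'   mutations (`outgroup = FALSE`).
#' @param pi Mean pairwise differences (only used by F / F*).
#' @param outgroup Logical.
#' @return List with elements `D` and `F` (starred variants when
#'   `outgroup = FALSE`); `NA_real_` when `eta == 0`.
#' @export
fu_li_tests <- function(n, eta, eta_external, pi, outgroup = TRUE) {
  if (n < 4) stop("Fu & Li tests require n >= 4")
  if (eta < 1) return(list(D = NA_real_, F = NA_real_))
  k <- fu_li_constants(n)
  if (outgroup) {
    D <- (eta - k$an * eta_external) / sqrt(k$uD * eta + k$vD * eta^2)
    F <- (pi - eta_external) / sqrt(k$uF * eta + k$vF * eta^2)
  } else {
    D <- (n / (n - 1) * eta - k$an * eta_external) /
      sqrt(k$uDs * eta + k$vDs * eta^2)
    F <- (pi - (n - 1) / n * eta_external) /
      sqrt(k$uFs * eta + k$vFs * eta^2)
  }
  list(D = D, F = F)
}

# log |s(n, k)| for k = 1..n (unsigned Stirling numbers of the first kind),
# by the log-sum-exp recurrence |s(n+1,k)| = n|s(n,k)| + |s(n,k-1)|.
# Rows are memoised per n: Fs is evaluated thousands of times at fixed n
# inside simulation p-values.
.stirling_cache <- new.env(parent = emptyenv())

log_stirling_row <- function(n) {
  key <- as.character(n)
  if (!is.null(.stirling_cache[[key]])) return(.stirling_cache[[key]])
  ls <- log_stirling_row_raw(n)
  .stirling_cache[[key]] <- ls
  ls
}

log_stirling_row_raw <- function(n) {
  ls <- 0  # row for n = 1: |s(1,1)| = 1
  if (n == 1) return(ls)
  for (m in 1:(n - 1)) {
    prev <- c(-Inf, ls, -Inf)  # pad k = 0 and k = m+1
    ls <- vapply(seq_len(m + 1), function(k) {
      a <- log(m) + prev[k + 1]  # m * |s(m, k)|
      b <- prev[k]               # |s(m, k-1)|
      mx <- max(a, b)
      if (is.infinite(mx)) -Inf else mx + log(exp(a - mx) + exp(b - mx))
    }, 0)
  }
  ls
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (is.infinite(m) && m < 0) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Fu's Fs
#'
#' \eqn{F_s = \ln(S'/(1-S'))} with \eqn{S' = \Pr(K \ge k \mid \hat\theta,
#' n)} under the Ewens sampling distribution, \eqn{\Pr(K = j) =
#' |s(n,j)|\,\theta^j / \theta^{(n)}}; \eqn{\hat\theta} is conventionally
#' the mean pairwise difference. Computed in log space (Stirling numbers by
#' log-sum-exp recurrence), so large n is safe.
#'
#' @param n Sample size.
#' @param k Observed number of distinct haplotypes.
#' @param theta Estimate of theta (> 0), conventionally MNPD.
#' @return The statistic; `NA_real_` when `theta <= 0`; `Inf`/`-Inf`
#'   sentinels (with a warning) when S' rounds to 1 or 0.
#' @export
fus_fs <- function(n, k, theta) {
  stopifnot(n >= 1, k >= 1, k <= n)
  if (is.na(theta) || theta <= 0) return(NA_real_)
  ls <- log_stirling_row(n)
  lth <- log(theta)
  lrise <- sum(log(theta + 0:(n - 1)))
  lp <- ls + seq_len(n) * lth - lrise   # log Pr(K = j), j = 1..n
  logS <- logsumexp(lp[k:n])
  log1mS <- if (k == 1) -Inf else logsumexp(lp[seq_len(k - 1)])
  if (log1mS == -Inf) {
    warning("Pr(K < k) underflows to 0; returning +Inf sentinel")
    return(Inf)
  }
  if (logS == -Inf) {
    warning("Pr(K >= k) underflows to 0; returning -Inf sentinel")
    return(-Inf)
  }
  logS - log1mS
}

# ---- spectrum ingredients from HVS-I sequences -----------------------------

#' Frequency-spectrum ingredients of a sample
#'
#' @param seqs List of `hvs1_seq`.
#' @param outgroup Optional outgroup haplotype (motif string or
#'   `mt_variants`) used to polarise mutations.
#' @param exclude_indels Drop indel variants.
#' @return List with `n`, `S` (segregating sites), `eta` (mutations),
#'   `eta_s` (singleton mutations), `eta_e` (derived singletons, `NA`
#'   without an outgroup), `pi` (MNPD), `k` (distinct haplotypes).
#' @export
spectrum_summary <- function(seqs, outgroup = NULL, exclude_indels = TRUE) {
  n <- length(seqs)
  toks <- lapply(seqs, seq_tokens, exclude_indels = exclude_indels)
  counts <- table(unlist(lapply(toks, unique)))
  seg <- counts[counts < n]          # tokens fixed in the sample don't segregate
  eta <- length(seg)
  S <- length(unique(sub("[^0-9].*$", "", names(seg))))
  eta_s <- sum(pmin(as.vector(seg), n - as.vector(seg)) == 1)
  eta_e <- NA_integer_
  if (!is.null(outgroup)) {
    og <- as_mt_variants(outgroup)$token
    derived_counts <- ifelse(names(seg) %in% og,
                             n - as.vector(seg), as.vector(seg))
    eta_e <- sum(derived_counts == 1)
  }
  pi_hat <- mean_pairwise_diff(seqs, exclude_indels)$value
  keys <- vapply(toks, function(t) paste(sort(t), collapse = "|"), "")
  list(n = n, S = S, eta = eta, eta_s = eta_s, eta_e = eta_e,
       pi = pi_hat, k = length(unique(keys)))
}

#' Neutrality test summary for one sample set
#'
#' @inheritParams spectrum_summary
#' @param reps Simulation replicates for p-values; `0` skips them.
#' @param seed Optional seed for the p-value simulations.
#' @return List of class `neutrality_summary`: the statistics, the
#'   ingredients, and (if requested) simulation p-values.
#' @export
neutrality_summary <- function(seqs, outgroup = NULL, reps = 0, seed = NULL) {
  sp <- spectrum_summary(seqs, outgroup)
  td <- tajimas_d(sp$n, sp$S, sp$pi)
  fl_star <- fu_li_tests(sp$n, sp$eta, sp$eta_s, sp$pi, outgroup = FALSE)
  fl <- if (!is.null(outgroup))
    fu_li_tests(sp$n, sp$eta, sp$eta_e, sp$pi, outgroup = TRUE)
  else list(D = NA_real_, F = NA_real_)
  fs <- fus_fs(sp$n, sp$k, sp$pi)
  p <- list()
  if (reps > 0) {
    if (!is.null(seed)) set.seed(seed)
    p$tajima_d <- simulate_pvalue("tajima_d", td, sp$n, S = sp$S, reps = reps)
    p$fu_fs <- simulate_pvalue("fu_fs", fs, sp$n, S = sp$S, reps = reps)
    p$fu_li_d_star <- simulate_pvalue("fu_li_d_star", fl_star$D, sp$n,
                                      S = sp$S, reps = reps)
    p$fu_li_f_star <- simulate_pvalue("fu_li_f_star", fl_star$F, sp$n,
                                      S = sp$S, reps = reps)
  }
  structure(list(tajima_d = td, fu_li_d = fl$D, fu_li_f = fl$F,
                 fu_li_d_star = fl_star$D, fu_li_f_star = fl_star$F,
                 fu_fs = fs, p_values = p, inputs = sp),
            class = "neutrality_summary")
}

#' @export
print.neutrality_summary <- function(x, ...) {
  cat(sprintf("n=%d S=%d eta=%d pi=%.3f k=%d\n", x$inputs$n, x$inputs$S,
              x$inputs$eta, x$inputs$pi, x$inputs$k))
  cat(sprintf("Tajima's D=%.3f  Fs=%.3f  D*=%.3f  F*=%.3f  D=%.3f  F=%.3f\n",
              x$tajima_d, x$fu_fs, x$fu_li_d_star, x$fu_li_f_star,
              x$fu_li_d, x$fu_li_f))
  invisible(x)
}

# ---- simulation p-values ---------------------------------------------------

# Evaluate a named statistic on coalescent-simulated spectrum ingredients.
null_statistic <- function(statistic, n, sim) {
  S <- sim[, 1]; pi <- sim[, 2]; xi1 <- sim[, 3]; k <- sim[, 4]
  eta_s <- sim[, 3] + sim[, 5]   # folded singletons: counts 1 and n-1
  switch(statistic,
    tajima_d = vapply(seq_along(S), function(i) {
      if (S[i] < 1) 0 else tajimas_d(n, S[i], pi[i])
    }, 0),
    fu_fs = vapply(seq_along(S), function(i) {
      v <- suppressWarnings(fus_fs(n, k[i], pi[i]))
      if (is.na(v)) 0 else v
    }, 0),
    fu_li_d = vapply(seq_along(S), function(i) {
      if (S[i] < 1) 0 else fu_li_tests(n, S[i], xi1[i], pi[i], TRUE)$D
    }, 0),
    fu_li_f = vapply(seq_along(S), function(i) {
      if (S[i] < 1) 0 else fu_li_tests(n, S[i], xi1[i], pi[i], TRUE)$F
    }, 0),
    fu_li_d_star = vapply(seq_along(S), function(i) {
      if (S[i] < 1) 0 else fu_li_tests(n, S[i], eta_s[i], pi[i], FALSE)$D
    }, 0),
    fu_li_f_star = vapply(seq_along(S), function(i) {
      if (S[i] < 1) 0 else fu_li_tests(n, S[i], eta_s[i], pi[i], FALSE)$F
    }, 0),
    stop("unknown statistic: ", statistic))
}

#' Simulation p-value for a frequency-spectrum statistic
#'
#' Simulates neutral constant-size coalescent samples, conditioned either
#' on the observed number of segregating sites `S` (mutations placed on the
#' genealogy proportionally to branch length) or on `theta` (Poisson
#' mutations at rate theta/2 per unit branch length), and returns the
#' lower-tail empirical probability \eqn{\Pr(T_{sim} \le T_{obs})}, ties
#' counted — the convention for detecting population growth.
#'
#' @param statistic Name (`"tajima_d"`, `"fu_fs"`, `"fu_li_d"`,
#'   `"fu_li_f"`, `"fu_li_d_star"`, `"fu_li_f_star"`) or a function
#'   `f(n, S, pi, xi1, k)` applied per replicate.
#' @param observed Observed statistic value.
#' @param n Sample size.
#' @param S,theta Exactly one conditioning value.
#' @param reps Replicates (>= 1000 recommended).
#' @return Empirical p-value in `[0, 1]`.
#' @export
simulate_pvalue <- function(statistic, observed, n, S = NULL, theta = NULL,
                            reps = 1000) {
  if (is.na(observed)) return(NA_real_)
  stopifnot(xor(is.null(S), is.null(theta)))
  sim <- coalescent_null_stats(n, reps, S = S, theta = theta)
  vals <- if (is.function(statistic))
    vapply(seq_len(nrow(sim)), function(i)
      statistic(n, sim[i, 1], sim[i, 2], sim[i, 3], sim[i, 4]), 0)
  else null_statistic(statistic, n, sim)
  mean(vals <= observed + 1e-12)
}

#' Neutral coalescent spectrum ingredients
#'
#' @param n Sample size.
#' @param reps Replicates.
#' @param S Condition on this many segregating sites, or
#' @param theta condition on this scaled mutation rate.
#' @return Matrix with columns `S`, `pi`, `xi1` (derived singletons), `k`
#'   (distinct haplotypes), one row per replicate.
#' @export
coalescent_null_stats <- function(n, reps, S = NULL, theta = NULL) {
  stopifnot(xor(is.null(S), is.null(theta)))
  sim <- coalsim_stats_cpp(as.integer(n), as.integer(reps),
                           if (is.null(theta)) -1 else theta,
                           if (is.null(S)) -1L else as.integer(S))
  colnames(sim) <- c("S", "pi", "xi1", "k", "xin1")
  sim
}
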