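# Coalescent simulation of Y-STR haplotypes under exponential-growth-from-
# constant demography, the stepwise mutation model, and TMRCA estimation:
# a moment estimator (ASD) and a Bayesian Metropolis-within-Gibbs sampler
# over (genealogy, N, growth, mutation rate) in the spirit of BATWING.

#' Exponential-growth-from-constant demographic model
#'
#' Haploid (male effective) population size
#' \eqn{N(t) = N_{anc} e^{\alpha (t_{onset} - t)}} for times
#' \eqn{t < t_{onset}} before present, and \eqn{N_{anc}} earlier; time in
#' generations before present.
#'
#' @param N_anc Ancestral constant haploid size (>= 2).
#' @param alpha Exponential growth rate per generation (>= 0).
#' @param t_onset Generations before present when growth began.
#' @param generation_years Years per generation (default 25).
#' @return Object of class `demographic_model`.
#' @export
demographic_model <- function(N_anc, alpha = 0, t_onset = 0,
                              generation_years = 25) {
  stopifnot(N_anc >= 2, alpha >= 0, t_onset >= 0, generation_years > 0)
  structure(list(N_anc = N_anc, alpha = alpha, t_onset = t_onset,
                 generation_years = generation_years),
            class = "demographic_model")
}

#' Population size at time t (generations before present)
#' @param model A `demographic_model`.
#' @param t Time(s) in generations before present.
#' @return N(t).
#' @export
pop_size_at <- function(model, t) {
  ifelse(t >= model$t_onset, model$N_anc,
         model$N_anc * exp(model$alpha * (model$t_onset - t)))
}

# Draw the next coalescence time for k lineages starting from time t0,
# integrating the piecewise intensity C(k,2)/N(t). Vectorised over reps.
next_coal_time <- function(t0, k, model, E) {
  ck <- k * (k - 1) / 2
  N0 <- pop_size_at(model, 0)          # present-day size
  a <- model$alpha; ton <- model$t_onset
  t1 <- t0
  out <- numeric(length(t0))
  in_growth <- t0 < ton & a > 0
  if (any(in_growth)) {
    tg <- t0[in_growth]; Eg <- E[in_growth]
    # hazard in growth phase: ck/N0 * exp(a s) integrated from tg
    arg <- exp(a * tg) + Eg * N0 * a / ck
    tc <- log(arg) / a
    # hazard available until onset
    Hmax <- ck / (N0 * a) * (exp(a * ton) - exp(a * tg))
    spill <- Eg - Hmax
    done <- tc <= ton
    res <- numeric(length(tg))
    res[done] <- tc[done]
    res[!done] <- ton + spill[!done] * model$N_anc / ck
    out[in_growth] <- res
  }
  flat <- !in_growth
  if (any(flat)) {
    tf <- pmax(t0[flat], if (a > 0) ton else 0)
    out[flat] <- tf + E[flat] * model$N_anc / ck
  }
  out
}

#' Simulate a coalescent genealogy
#'
#' Standard coalescent with time-rescaling for the piecewise demography:
#' pairwise coalescence intensity \eqn{\binom{k}{2} / N(t)}.
#'
#' @param n Number of sampled lineages (>= 2).
#' @param model A [demographic_model()].
#' @param seed Optional RNG seed.
#' @return List of class `coalescent_tree`: `n`, `parent` (2n-1 nodes,
#'   leaves first, 0 for the root), `times` (generations before present;
#'   `times[2n-1]` is the TMRCA), `model`.
#' @export
simulate_tree <- function(n, model, seed = NULL) {
  stopifnot(n >= 2)
  if (!is.null(seed)) set.seed(seed)
  nnode <- 2L * n - 1L
  parent <- integer(nnode); times <- numeric(nnode)
  active <- seq_len(n); t <- 0
  nxt <- n + 1L
  for (k in n:2) {
    t <- next_coal_time(t, k, model, stats::rexp(1))
    pick <- sample(length(active), 2L)
    parent[active[pick]] <- nxt
    times[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  structure(list(n = n, parent = parent, times = times, model = model),
            class = "coalescent_tree")
}

#' TMRCA samples without storing topologies
#'
#' @param n Sample size.
#' @param model A [demographic_model()].
#' @param reps Number of independent genealogies.
#' @return Numeric vector of root times (generations), vectorised over
#'   replicates.
#' @export
sim_tmrca <- function(n, model, reps) {
  t <- numeric(reps)
  for (k in n:2) t <- next_coal_time(t, k, model, stats::rexp(reps))
  t
}

#' Published Y-STR mutation rate sets
#'
#' Reads the bundled table of per-locus rates for the evolutionary rate
#' (EMR), two observed genealogical rates (OMRB, OMRS) and the
#' logistic-model-adjusted genealogical rate (lmMR). The bundled values
#' are set-level average calibrations (mutations/locus/generation) with
#' sources annotated in the file; users may supply their own per-locus
#' table.
#'
#' @param name One of `"EMR"`, `"OMRB"`, `"OMRS"`, `"lmMR"`.
#' @param loci Locus names (default the 15 dating loci).
#' @param path Rate table (TSV with columns `set`, `rate`).
#' @return Named numeric vector of per-locus rates.
#' @export
mutation_rates <- function(name = c("OMRB", "EMR", "OMRS", "lmMR"),
                           loci = Y_STR_DATING_LOCI,
                           path = uniparent_extdata("ystr_mutation_rates.tsv")) {
  name <- match.arg(name)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  r <- df$rate[df$set == name]
  if (length(r) != 1L) stop("rate set not found: ", name)
  stats::setNames(rep(r, length(loci)), loci)
}

#' Drop STR mutations on a genealogy (single-step model)
#'
#' Per-branch Poisson(mu_l * length) mutation counts; each mutation moves
#' the allele +/-1 repeat with equal probability. Alleles are reflected
#' back into the 5..40 range (with a reflection counter attribute) if they escape.
#'
#' @param tree A [simulate_tree()] result.
#' @param rates Named per-locus rates (mutations/locus/generation).
#' @param root_haplotype Named integer vector (default all loci at 14).
#' @param seed Optional RNG seed.
#' @return Integer matrix n x loci of leaf haplotypes.
#' @export
mutate_strs <- function(tree, rates, root_haplotype = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  loci <- names(rates)
  if (is.null(root_haplotype))
    root_haplotype <- stats::setNames(rep(14L, length(rates)), loci)
  root_haplotype <- root_haplotype[loci]
  nnode <- 2L * tree$n - 1L
  hap <- matrix(0L, nnode, length(loci), dimnames = list(NULL, loci))
  hap[nnode, ] <- root_haplotype
  reflections <- 0L
  reflect <- function(x) {
    while (x < 5 || x > 40) {
      if (x < 5) x <- 10 - x
      if (x > 40) x <- 80 - x
      reflections <<- reflections + 1L
    }
    as.numeric(x)
  }
  for (v in (nnode - 1L):1L) {
    len <- tree$times[tree$parent[v]] - tree$times[v]
    m <- stats::rpois(length(loci), rates * len)
    step <- vapply(m, function(k)
      if (k == 0L) 0L else sum(sample(c(-1L, 1L), k, replace = TRUE)), 0L)
    hap[v, ] <- as.integer(vapply(hap[tree$parent[v], ] + step, reflect, 0))
  }
  if (reflections > 0L)
    warning(reflections, " allele(s) reflected at the [5,40] boundary")
  out <- hap[seq_len(tree$n), , drop = FALSE]
  rownames(out) <- paste0("s", seq_len(tree$n))
  out
}

#' ASD moment estimator of TMRCA
#'
#' Average squared allele-size distance (ASD) from the founder haplotype;
#' E\[ASD\] = mu t under the single-step model, so
#' \eqn{\hat t = \mathrm{mean}_l\, \mathrm{ASD}_l/\mu_l} generations,
#' scaled to years.
#'
#' @param haplotypes Integer matrix samples x loci.
#' @param rates Named per-locus mutation rates.
#' @param founder Founder haplotype; default the locus-wise modal
#'   haplotype.
#' @param generation_years Years per generation.
#' @return Estimated TMRCA in years.
#' @export
asd_tmrca <- function(haplotypes, rates, founder = NULL,
                      generation_years = 25) {
  loci <- intersect(colnames(haplotypes), names(rates))
  if (!length(loci)) stop("no shared loci between haplotypes and rates")
  h <- haplotypes[, loci, drop = FALSE]
  if (is.null(founder))
    founder <- apply(h, 2, function(x)
      as.integer(names(sort(table(x), decreasing = TRUE))[1]))
  else founder <- founder[loci]
  asd <- colMeans((t(t(h) - founder))^2)
  mean(asd / rates[loci]) * generation_years
}

# log coalescent prior density of the ordered coalescence times of a
# labeled genealogy under the demography (up to the topology's uniform
# probability, which is constant across our time moves).
coal_log_prior <- function(times_sorted, n, model) {
  ts <- c(0, times_sorted)
  lp <- 0
  for (i in seq_len(n - 1)) {
    k <- n - i + 1
    ck <- k * (k - 1) / 2
    t0 <- ts[i]; t1 <- ts[i + 1]
    if (t1 < t0) return(-Inf)
    lp <- lp + log(ck / pop_size_at(model, t1)) -
      ck * intensity_integral(model, t0, t1)
  }
  lp
}

# integral of 1/N(t) dt over [t0, t1]
intensity_integral <- function(model, t0, t1) {
  a <- model$alpha; ton <- model$t_onset
  N0 <- pop_size_at(model, 0)
  g0 <- min(t0, ton); g1 <- min(t1, ton)
  I <- 0
  if (a > 0 && g1 > g0) I <- I + (exp(a * g1) - exp(a * g0)) / (N0 * a)
  if (t1 > max(t0, ton)) I <- I + (t1 - max(t0, ton)) / model$N_anc
  if (a == 0) I <- (t1 - t0) / model$N_anc
  I
}

#' Default priors for the Bayesian TMRCA sampler
#'
#' Lognormal on the ancestral size N (median 1000), exponential on the
#' growth rate alpha, lognormal on the growth onset, and gamma on the
#' mutation rate centred on the chosen calibration set. All overridable.
#'
#' @param rate_set Calibration set name for the mu prior centre.
#' @param mu_mean Override for the mu prior mean.
#' @return List of prior hyperparameters.
#' @export
batwing_priors <- function(rate_set = "OMRB", mu_mean = NULL) {
  if (is.null(mu_mean)) mu_mean <- unname(mutation_rates(rate_set)[1])
  list(N_meanlog = log(1000), N_sdlog = 1,
       alpha_rate = 1 / 0.01,        # mean growth 0.01 per generation
       onset_meanlog = log(240), onset_sdlog = 0.8,  # ~6 kya at 25 y/gen
       mu_shape = 10, mu_rate = 10 / mu_mean)
}

param_log_prior <- function(p, priors) {
  stats::dlnorm(p$N, priors$N_meanlog, priors$N_sdlog, log = TRUE) +
    stats::dexp(p$alpha, priors$alpha_rate, log = TRUE) +
    stats::dlnorm(p$t_onset, priors$onset_meanlog, priors$onset_sdlog,
                  log = TRUE) +
    stats::dgamma(p$mu, priors$mu_shape, priors$mu_rate, log = TRUE)
}

draw_from_priors <- function(priors) {
  list(N = stats::rlnorm(1, priors$N_meanlog, priors$N_sdlog),
       alpha = stats::rexp(1, priors$alpha_rate),
       t_onset = stats::rlnorm(1, priors$onset_meanlog, priors$onset_sdlog),
       mu = stats::rgamma(1, priors$mu_shape, priors$mu_rate))
}

param_model <- function(p, generation_years = 25)
  demographic_model(max(p$N, 2), p$alpha, p$t_onset, generation_years)

# SMM likelihood of haplotypes on a genealogy, via the compiled pruning
# kernel; the lattice eigensystem is precomputed once per dataset.
smm_lattice <- function(haplotypes, pad = 6L) {
  lo <- max(5L, min(haplotypes) - pad)
  hi <- min(40L, max(haplotypes) + pad)
  S <- hi - lo + 1L
  Q0 <- matrix(0, S, S)
  for (i in seq_len(S - 1)) {
    Q0[i, i + 1] <- Q0[i + 1, i] <- 0.5
  }
  diag(Q0) <- -rowSums(Q0)
  e <- eigen(Q0, symmetric = TRUE)
  list(lo = lo, V = e$vectors, lam = e$values)
}

smm_loglik <- function(tree, states0, lattice, mu) {
  smm_loglik_cpp(as.integer(tree$parent - 1L), tree$times, states0,
                 lattice$V, lattice$lam, mu)
}

#' Bayesian TMRCA estimation for Y-STR haplotypes
#'
#' Metropolis-within-Gibbs over (genealogy node times and topology, N,
#' alpha, growth onset, mutation rate) with a single-step mutation model
#' likelihood and the exponential-growth-from-constant coalescent prior.
#' Topology mixes through periodic independence redraws of the whole
#' genealogy from the coalescent prior (accepted by likelihood ratio).
#' TMRCA in years is the root height times the generation time —
#' equivalently the product of the population size and the tree height in
#' coalescent units.
#'
#' @param haplotypes Integer matrix samples x loci (n <= 200).
#' @param priors From [batwing_priors()].
#' @param cycles Total MCMC cycles.
#' @param burnin Discarded initial cycles.
#' @param thin Keep every `thin`-th cycle.
#' @param generation_years Years per generation.
#' @param seed RNG seed (same seed, same data: identical summaries).
#' @return List of class `batwing_fit`: `samples` (data frame of retained
#'   draws: `tmrca_years`, `expansion_years`, `N`, `alpha`, `mu`),
#'   `summary` (mean/median/SD per parameter), `ess` (effective sample
#'   size of the TMRCA trace, with a non-mixing warning below 100),
#'   `acceptance`.
#' @export
batwing_mcmc <- function(haplotypes, priors = batwing_priors(),
                         cycles = 4000, burnin = 1000, thin = 5,
                         generation_years = 25, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(haplotypes)
  stopifnot(n >= 2, n <= 200)
  if (any(priors$mu_shape / priors$mu_rate <= 0))
    stop("mutation rate prior must have positive mean")
  lattice <- smm_lattice(haplotypes)
  states0 <- haplotypes - lattice$lo
  storage.mode(states0) <- "integer"

  p <- draw_from_priors(priors)
  tree <- simulate_tree(n, param_model(p, generation_years))
  ll <- smm_loglik(tree, states0, lattice, p$mu)
  lp_tree <- coal_log_prior(sort(tree$times[(n + 1):(2 * n - 1)]), n,
                            param_model(p))
  lp_par <- param_log_prior(p, priors)

  nkeep <- floor((cycles - burnin) / thin)
  out <- matrix(NA_real_, nkeep, 5,
                dimnames = list(NULL, c("tmrca_years", "expansion_years",
                                        "N", "alpha", "mu")))
  acc <- c(time = 0, redraw = 0, param = 0)
  prop <- c(time = 0, redraw = 0, param = 0)
  kept <- 0L
  internals <- (n + 1):(2 * n - 1)

  for (it in seq_len(cycles)) {
    # --- node-time slide -----------------------------------------------
    v <- sample(internals, 1L)
    lo <- max(tree$times[which(tree$parent == v)])
    hi <- if (v == 2 * n - 1) tree$times[v] * 1.5 + 1 else tree$times[tree$parent[v]]
    prop["time"] <- prop["time"] + 1
    tnew <- stats::runif(1, lo, hi)
    cand <- tree; cand$times[v] <- tnew
    # the root window is state-dependent; balance the proposal densities
    # and reject outright when the reverse window cannot reach the old time
    qratio <- 0; feasible <- TRUE
    if (v == 2 * n - 1) {
      hi_rev <- tnew * 1.5 + 1
      if (tree$times[v] >= hi_rev) feasible <- FALSE
      else qratio <- log((hi - lo) / (hi_rev - lo))
    }
    if (feasible) {
      ll2 <- smm_loglik(cand, states0, lattice, p$mu)
      lp2 <- coal_log_prior(sort(cand$times[internals]), n, param_model(p))
      if (is.finite(lp2) &&
          log(stats::runif(1)) < ll2 - ll + lp2 - lp_tree + qratio) {
        tree <- cand; ll <- ll2; lp_tree <- lp2
        acc["time"] <- acc["time"] + 1
      }
    }
    # --- periodic full-genealogy redraw from the prior -----------------
    if (it %% 4 == 0) {
      prop["redraw"] <- prop["redraw"] + 1
      cand <- simulate_tree(n, param_model(p, generation_years))
      ll2 <- smm_loglik(cand, states0, lattice, p$mu)
      if (log(stats::runif(1)) < ll2 - ll) {
        tree <- cand; ll <- ll2
        lp_tree <- coal_log_prior(sort(tree$times[internals]), n,
                                  param_model(p))
        acc["redraw"] <- acc["redraw"] + 1
      }
    }
    # --- parameter updates (log random walks) --------------------------
    for (nm in c("N", "alpha", "t_onset", "mu")) {
      prop["param"] <- prop["param"] + 1
      p2 <- p
      if (nm == "alpha" && p$alpha < 1e-8) {
        p2$alpha <- stats::rexp(1, priors$alpha_rate)  # refresh from prior
      } else {
        p2[[nm]] <- p[[nm]] * exp(stats::rnorm(1, 0, 0.25))
      }
      lp_par2 <- param_log_prior(p2, priors)
      if (!is.finite(lp_par2)) next
      lp_tree2 <- coal_log_prior(sort(tree$times[internals]), n,
                                 param_model(p2))
      ll2 <- if (nm == "mu") smm_loglik(tree, states0, lattice, p2$mu) else ll
      # log-scale RW proposal Jacobian: q(x->x') ~ x'; refresh move for alpha
      jac <- if (nm == "alpha" && p$alpha < 1e-8)
        stats::dexp(p$alpha, priors$alpha_rate, log = TRUE) -
          stats::dexp(p2$alpha, priors$alpha_rate, log = TRUE)
      else log(p2[[nm]]) - log(p[[nm]])
      if (log(stats::runif(1)) <
          (ll2 - ll) + (lp_tree2 - lp_tree) + (lp_par2 - lp_par) + jac) {
        p <- p2; lp_par <- lp_par2; lp_tree <- lp_tree2; ll <- ll2
        acc["param"] <- acc["param"] + 1
      }
    }
    if (it > burnin && (it - burnin) %% thin == 0 && kept < nkeep) {
      kept <- kept + 1L
      out[kept, ] <- c(tree$times[2 * n - 1] * generation_years,
                       p$t_onset * generation_years, p$N, p$alpha, p$mu)
    }
  }
  samples <- as.data.frame(out[seq_len(kept), , drop = FALSE])
  summ <- do.call(rbind, lapply(names(samples), function(nm)
    data.frame(parameter = nm, mean = mean(samples[[nm]]),
               median = stats::median(samples[[nm]]),
               sd = stats::sd(samples[[nm]]))))
  ess <- ess_of(samples$tmrca_years)
  if (is.finite(ess) && ess < 100)
    warning("effective sample size of TMRCA trace below 100 (", round(ess),
            "); chain may not have mixed")
  structure(list(samples = samples, summary = summ, ess = ess,
                 acceptance = acc / pmax(prop, 1)),
            class = "batwing_fit")
}

# effective sample size from the autocorrelation function (initial
# positive sequence truncation)
ess_of <- function(x) {
  m <- length(x)
  if (m < 10 || stats::sd(x) == 0) return(NA_real_)
  ac <- stats::acf(x, lag.max = min(m - 1, 100), plot = FALSE)$acf[-1]
  pos <- which(ac < 0.05)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  m / (1 + 2 * sum(ac))
}

#' @export
print.batwing_fit <- function(x, ...) {
  print(x$summary, row.names = FALSE)
  cat(sprintf("ESS(TMRCA) = %.0f\n", x$ess))
  invisible(x)
}

#' Posterior credible interval for the TMRCA
#' @param fit A `batwing_fit`.
#' @param level Credible level (default 0.9).
#' @return Two-element vector (lower, upper) in years.
#' @export
tmrca_interval <- function(fit, level = 0.9) {
  a <- (1 - level) / 2
  unname(stats::quantile(fit$samples$tmrca_years, c(a, 1 - a)))
}
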