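# rho-statistic coalescence dating of mtDNA clades with Saillard standard
# errors and a calibrated HVS-I clock.

#' Default HVS-I clock: years per mutation in 16090-16365
#' @export
HVS1_CLOCK_YEARS_PER_MUTATION <- 18845

#' Default rho window (the calibrated HVS-I stretch)
#' @export
RHO_WINDOW <- c(16090L, 16365L)

#' The rho statistic
#'
#' Mean mutational distance (symmetric difference of variant sets) between
#' each sampled haplotype and the clade founder, restricted to the clock
#' window; indels are excluded by default, transversions counted.
#'
#' @param samples List of `hvs1_seq` belonging to the clade.
#' @param founder Founder haplotype: motif string or `mt_variants`.
#' @param window Inclusive coordinate window (default the calibrated
#'   16090-16365 stretch).
#' @param exclude_indels Drop indel variants before comparing.
#' @return Mean distance (`rho >= 0`).
#' @export
rho <- function(samples, founder, window = RHO_WINDOW,
                exclude_indels = TRUE) {
  if (length(samples) == 0L) stop("rho requires at least one sample")
  mean(rho_distances(samples, founder, window, exclude_indels))
}

rho_distances <- function(samples, founder, window = RHO_WINDOW,
                          exclude_indels = TRUE) {
  f <- as_mt_variants(founder)
  if (exclude_indels) f <- f[!f$kind %in% c("insertion", "deletion"), , drop = FALSE]
  f <- f[f$position >= window[1] & f$position <= window[2], , drop = FALSE]
  vapply(samples, function(s)
    token_distance(seq_tokens(s, exclude_indels, window), f$token), 0)
}

#' Saillard standard error of rho
#'
#' \eqn{\sigma_\rho = \sqrt{\sum_j n_j^2} / n} where mutation link j of the
#' genealogy connecting the samples to the founder subtends \eqn{n_j} of
#' the n samples (Saillard et al. 2000). For a star genealogy, where every
#' link subtends one sample, this reduces to \eqn{\sqrt{\rho/n}}.
#'
#' @param subtended Integer vector \eqn{n_j}, one entry per mutation link.
#' @param n Number of samples.
#' @return Standard error of rho.
#' @export
sigma_rho <- function(subtended, n) {
  stopifnot(n >= 1)
  if (length(subtended) == 0L) return(0)
  if (any(subtended < 1 | subtended > n))
    stop("each link must subtend between 1 and n samples")
  sqrt(sum(subtended^2)) / n
}

#' @rdname sigma_rho
#' @param rho_value The rho estimate (star-genealogy shortcut).
#' @export
sigma_rho_star <- function(rho_value, n) sqrt(rho_value / n)

#' Convert rho to an age in years
#'
#' @param rho_value Estimated rho.
#' @param sigma Standard error of rho (optional).
#' @param clock_rate Years per mutation (default the calibrated HVS-I
#'   clock, 18845).
#' @return List with `age_years` and `sd_years` (`NA` if no sigma given).
#' @export
age <- function(rho_value, sigma = NA_real_,
                clock_rate = HVS1_CLOCK_YEARS_PER_MUTATION) {
  stopifnot(clock_rate > 0)
  list(age_years = rho_value * clock_rate,
       sd_years = sigma * clock_rate)
}

#' Date a clade from its samples and founder
#'
#' Computes rho, its Saillard standard error and the calibrated age. The
#' error uses the genealogy implied by `subtended` when supplied, and the
#' star approximation (each observed mutation its own link) otherwise, with
#' a warning — appropriate for the near-star genealogies typical of
#' expanding uniparental clades.
#'
#' @inheritParams rho
#' @param haplogroup Clade label carried through to the result.
#' @param clock_rate Years per mutation.
#' @param subtended Optional per-link subtended sample counts.
#' @param warn_star Warn when falling back to the star approximation.
#' @return List of class `rho_result`: `haplogroup`, `n`, `rho`,
#'   `sigma_rho`, `age_years`, `sd_years`, `clock_rate`, `window`.
#' @export
rho_date <- function(samples, founder, haplogroup = NA_character_,
                     window = RHO_WINDOW,
                     clock_rate = HVS1_CLOCK_YEARS_PER_MUTATION,
                     subtended = NULL, exclude_indels = TRUE,
                     warn_star = FALSE) {
  d <- rho_distances(samples, founder, window, exclude_indels)
  n <- length(d)
  r <- mean(d)
  if (is.null(subtended)) {
    if (warn_star)
      warning("no genealogy supplied; using star approximation for sigma_rho")
    s <- sigma_rho_star(r, n)
  } else {
    s <- sigma_rho(subtended, n)
  }
  a <- age(r, s, clock_rate)
  structure(list(haplogroup = haplogroup, n = n, rho = r, sigma_rho = s,
                 age_years = a$age_years, sd_years = a$sd_years,
                 clock_rate = clock_rate, window = window),
            class = "rho_result")
}

#' @export
print.rho_result <- function(x, ...) {
  cat(sprintf("%s: n=%d rho=%.4f (se %.4f)  %0.f +/- %0.f years BP\n",
              if (is.na(x$haplogroup)) "clade" else x$haplogroup,
              x$n, x$rho, x$sigma_rho, x$age_years, x$sd_years))
  invisible(x)
}

#' Read a founder-motif fixture table
#'
#' TSV with columns `haplogroup`, `motif`. The bundled
#' `extdata/mt_founders.tsv` lists the founder motifs used by the
#' synthetic-data generator.
#'
#' @param path TSV file (default the bundled fixture).
#' @return Named character vector of motif strings keyed by haplogroup.
#' @export
read_founders <- function(path = uniparent_extdata("mt_founders.tsv")) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$motif[is.na(df$motif)] <- ""
  stats::setNames(df$motif, df$haplogroup)
}
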