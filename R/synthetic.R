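# Synthetic-data generator: emits mtDNA HVS-I and Y-SNP/STR datasets with
# the statistical structure the analyses assume (haplogroup mixes per
# population, within-haplogroup coalescent variation, post-glacial /
# Neolithic expansion demography), plus truth tables, so the entire
# pipeline runs and is tested without external downloads.

# HVS-I mutational hotspots (fast sites) within the analysis window; the
# generator gives them a 3x rate relative to other sites.
HVS1_HOTSPOTS <- c(16093L, 16129L, 16172L, 16189L, 16192L, 16223L, 16261L,
                   16278L, 16293L, 16304L, 16311L, 16362L)

#' Deterministic integer allocation of a probability mix
#'
#' Largest-remainder rounding of `n * mix`; used when a population spec is
#' given as frequencies but exact counts are wanted.
#'
#' @param mix Named probability vector (sums to 1).
#' @param n Total count.
#' @return Named integer vector summing to `n`.
#' @export
allocate_counts <- function(mix, n) {
  stopifnot(abs(sum(mix) - 1) < 1e-9, n >= 1)
  raw <- mix * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(mix))
}

#' Population specification for the generators
#'
#' @param name Population label.
#' @param n_samples Number of samples.
#' @param mix Named haplogroup probability vector (must sum to 1), or
#'   `NULL` if `counts` given.
#' @param counts Named integer haplogroup counts (overrides `mix`).
#' @param demography A [demographic_model()] applied within each
#'   haplogroup (default: post-glacial expansion, N_anc 500, growth 0.008
#'   per generation from 400 generations BP).
#' @return List of class `population_spec`.
#' @export
population_spec <- function(name, n_samples = NULL, mix = NULL, counts = NULL,
                            demography = demographic_model(500, 0.008, 400)) {
  if (is.null(counts)) {
    stopifnot(!is.null(mix), !is.null(n_samples))
    counts <- allocate_counts(mix, n_samples)
  }
  counts <- counts[counts > 0]
  structure(list(name = name, counts = counts,
                 n_samples = sum(counts), demography = demography),
            class = "population_spec")
}

strip_star <- function(x) sub("\\*$", "", x)

# coding-SNP states for a sample of clade `node`: derived along the path,
# ancestral for every other coding site in the tree
coding_states_for <- function(tree, node) {
  all_coding <- unique(unlist(lapply(tree$nodes, `[[`, "coding")))
  st <- stats::setNames(rep("ancestral", length(all_coding)), all_coding)
  for (p in tree_path(tree, node))
    st[tree$nodes[[p]]$coding] <- "derived"
  st
}

#' Generate an HVS-I dataset from population specs
#'
#' Per sample: the haplogroup is taken from the spec's (exact) counts, a
#' within-haplogroup coalescent genealogy is simulated under the spec's
#' demography, and mutations are superposed on the haplogroup's founder
#' motif with site-specific rates (3:1 hotspot:other) and a 20:1
#' transition:transversion bias. A mutation at a site carrying a founder
#' variant reverts it (finite-sites back mutation).
#'
#' @param specs List of [population_spec()]s.
#' @param tree mtDNA [haplogroup_tree()] (default the bundled subtree).
#' @param founders Named founder motifs (default the bundled fixture).
#' @param mu_window Total HVS-I window mutation rate per generation
#'   (default 25/18845, consistent with the rho clock).
#' @param seed RNG seed; same seed, same output.
#' @param window Analysis window.
#' @return List with `seqs` (list of `hvs1_seq`), `coding` (named list of
#'   coding-SNP state vectors), `truth` (data frame `sample_id`,
#'   `population`, `haplogroup`).
#' @export
generate_mt_dataset <- function(specs, tree = mt_subtree(),
                                founders = read_founders(),
                                mu_window = 25 / 18845, seed = 1,
                                window = c(16024L, 16488L)) {
  set.seed(seed)
  sites <- seq.int(window[1], window[2])
  site_w <- ifelse(sites %in% HVS1_HOTSPOTS, 3, 1)
  site_p <- site_w / sum(site_w)
  seqs <- list(); coding <- list(); truth <- list()
  idx <- 0L
  for (sp in specs) {
    for (hg in names(sp$counts)) {
      node <- strip_star(hg)
      if (!node %in% names(tree$nodes)) stop("unknown haplogroup: ", hg)
      if (!node %in% names(founders)) stop("no founder motif for: ", node)
      m <- sp$counts[[hg]]
      founder <- parse_motif(founders[[node]])
      gtree <- simulate_tree(max(m, 2L), sp$demography)
      leaf_sets <- drop_hvs1_mutations(gtree, founder$token, sites, site_p,
                                       mu_window)
      cs <- coding_states_for(tree, node)
      for (i in seq_len(m)) {
        idx <- idx + 1L
        sid <- sprintf("%s_%04d", sp$name, idx)
        toks <- leaf_sets[[i]]
        v <- tokens_to_variants(toks)
        seqs[[idx]] <- hvs1_sequence(sid, sp$name, v, window)
        coding[[sid]] <- cs
        truth[[idx]] <- data.frame(sample_id = sid, population = sp$name,
                                   haplogroup = hg, stringsAsFactors = FALSE)
      }
    }
  }
  list(seqs = seqs, coding = coding, truth = do.call(rbind, truth))
}

# walk the genealogy from the root (carrying the founder token set),
# toggling variants per mutation; returns per-leaf token sets
drop_hvs1_mutations <- function(gtree, founder_tokens, sites, site_p,
                                mu_window) {
  nnode <- 2L * gtree$n - 1L
  sets <- vector("list", nnode)
  sets[[nnode]] <- founder_tokens
  for (v in (nnode - 1L):1L) {
    len <- gtree$times[gtree$parent[v]] - gtree$times[v]
    cur <- sets[[gtree$parent[v]]]
    nmut <- stats::rpois(1, mu_window * len)
    if (nmut > 0) for (k in seq_len(nmut)) {
      pos <- sample(sites, 1L, prob = site_p)
      tv <- stats::runif(1) < 1 / 21
      tok <- if (tv) paste0(pos, sample(c("A", "C", "G", "T"), 1L)) else
        as.character(pos)
      # toggle any existing variant at this position, else add
      at_pos <- grepl(paste0("^", pos, "([ACGT]?$)"), cur)
      cur <- if (any(at_pos)) cur[!at_pos] else c(cur, tok)
    }
    sets[[v]] <- cur
  }
  sets[seq_len(gtree$n)]
}

tokens_to_variants <- function(toks) {
  if (!length(toks)) return(mt_variants())
  pos <- as.integer(sub("[ACGT]$", "", toks))
  tv <- grepl("[ACGT]$", toks)
  mt_variants(pos, ifelse(tv, "transversion", "transition"),
              ifelse(tv, substr(toks, nchar(toks), nchar(toks)), ""))
}

#' Generate a Y-SNP/STR dataset from population specs
#'
#' SNP states are set derived along the true path and ancestral elsewhere
#' (consistent with the tree by construction); STR haplotypes are
#' simulated on a within-haplogroup coalescent under the single-step
#' model, from a per-haplogroup founder haplotype.
#'
#' @param specs List of [population_spec()]s; haplogroup names may carry a
#'   `"*"` (paragroup) suffix.
#' @param tree Y [haplogroup_tree()] (default the bundled panel tree).
#' @param rates Named per-locus STR mutation rates.
#' @param seed RNG seed.
#' @param mask_fraction Fraction of SNP markers set to `"untyped"` per
#'   sample (default 0: complete typing).
#' @return List with `profiles` (list of `y_profile`), `truth` (data
#'   frame).
#' @export
generate_y_dataset <- function(specs, tree = y_panel_tree(),
                               rates = mutation_rates("OMRB"), seed = 1,
                               mask_fraction = 0) {
  set.seed(seed)
  panel <- tree_markers(tree)
  profiles <- list(); truth <- list()
  idx <- 0L
  for (sp in specs) {
    for (hg in names(sp$counts)) {
      node <- strip_star(hg)
      if (!node %in% names(tree$nodes)) stop("unknown haplogroup: ", hg)
      m <- sp$counts[[hg]]
      path <- tree_path(tree, node)
      derived <- unlist(lapply(path, function(p) tree$nodes[[p]]$variants))
      # per-haplogroup founder STR haplotype: modal 14 with reproducible
      # per-locus offsets so clades are separated in STR space
      off <- round(stats::rnorm(length(rates), 0, 1.5))
      founder <- as.integer(pmin(pmax(14 + off, 8), 20))
      names(founder) <- names(rates)
      gtree <- simulate_tree(max(m, 2L), sp$demography)
      haps <- mutate_strs(gtree, rates, root_haplotype = founder)
      for (i in seq_len(m)) {
        idx <- idx + 1L
        sid <- sprintf("%s_Y%04d", sp$name, idx)
        st <- stats::setNames(rep("ancestral", length(panel)), panel)
        st[derived] <- "derived"
        if (mask_fraction > 0) {
          mask <- sample(panel, round(mask_fraction * length(panel)))
          st[mask] <- "untyped"
        }
        profiles[[idx]] <- y_profile(sid, sp$name, st, haps[i, ])
        truth[[idx]] <- data.frame(sample_id = sid, population = sp$name,
                                   haplogroup = hg, stringsAsFactors = FALSE)
      }
    }
  }
  list(profiles = profiles, truth = do.call(rbind, truth))
}

#' Four-population study design (synthetic stand-in)
#'
#' Haplogroup-by-population count tables mirroring a four-population
#' uniparental survey of the western Sichuan corridor: two Horpa
#' populations (DB, DF) and two Khams Tibetan populations (XL, YJ), with
#' male (Y) sample sizes 18/16/46/47 and mtDNA sizes 46/40/119/192. The
#' counts are inferred from published percentage frequencies and are a
#' documented synthetic reconstruction, not deposited data.
#'
#' @param which `"y"` or `"mt"`.
#' @return List of [population_spec()]s.
#' @export
study_design <- function(which = c("y", "mt")) {
  which <- match.arg(which)
  path <- uniparent_extdata(sprintf("study_design_%s.tsv", which))
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(split(df, df$population)[unique(df$population)], function(g)
    population_spec(g$population[1],
                    counts = stats::setNames(as.integer(g$count),
                                             g$haplogroup)))
}

#' Macrohaplogroup of a haplogroup label
#'
#' Maps a (possibly starred) haplogroup label to its top-level clade —
#' the child of the tree root on its path (e.g. mtDNA `"D4j3"` to `"M"`).
#'
#' @param tree A [haplogroup_tree()].
#' @param labels Haplogroup labels.
#' @return Character vector of macrohaplogroup names.
#' @export
macrohaplogroup <- function(tree, labels) {
  vapply(strip_star(labels), function(l) {
    if (!l %in% names(tree$nodes)) return(NA_character_)
    p <- tree_path(tree, l)
    if (length(p) == 0) tree$root else p[1]
  }, "")
}
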