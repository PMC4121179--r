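# HVS-I variants relative to the rCRS, and the motif-string notation used
# throughout the mtDNA population-genetics literature.

MT_GENOME_LENGTH <- 16569L

# Positions in the 16184-16193 poly-C tract whose length variants are
# notoriously unstable; parsed but flagged hypervariable.
HVS1_POLYC_POSITIONS <- c(16182L, 16183L, 16194L)

#' Parse an HVS-I variant motif string
#'
#' Motif strings list variant positions relative to the rCRS, separated by
#' hyphens, en/em dashes or whitespace, e.g. `"16129-16223-16278-16362"`.
#' A bare number denotes a transition; a trailing base letter a transversion
#' to that base (`"16265C"`); a trailing `d` a deletion (`"16166d"`); and
#' `".1C"`-style suffixes an insertion (`"16193.1C"`).
#'
#' @param text A single motif string. The empty string denotes an
#'   rCRS-identical haplotype and yields zero variants.
#' @return An `mt_variants` data frame with columns `position`, `kind`
#'   (`"transition"`, `"transversion"`, `"insertion"`, `"deletion"`),
#'   `derived_state` and the canonical `token`.
#' @examples
#' parse_motif("16093-16298-16327")   # the C4d motif: three transitions
#' parse_motif("16223-16257A-16261")  # includes a transversion to A
#' @export
parse_motif <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("motif must be a single character string")
  text <- trimws(text)
  if (identical(text, "") || identical(text, "."))
    return(mt_variants())
  toks <- strsplit(text, "[-–—[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  parse_token <- function(tok) {
    if (grepl("^[0-9]+$", tok)) {
      c(tok, "transition", "")
    } else if (grepl("^[0-9]+[ACGTacgt]$", tok)) {
      n <- nchar(tok)
      c(substr(tok, 1L, n - 1L), "transversion", toupper(substr(tok, n, n)))
    } else if (grepl("^[0-9]+[dD]$", tok)) {
      c(sub("[dD]$", "", tok), "deletion", "")
    } else if (grepl("^[0-9]+\\.[0-9]+[ACGTacgt]+$", tok)) {
      m <- regmatches(tok, regexec("^([0-9]+)\\.([0-9]+)([ACGTacgt]+)$", tok))[[1]]
      c(m[2], "insertion", paste0(".", m[3], toupper(m[4])))
    } else {
      stop(sprintf("malformed motif token: '%s'", tok))
    }
  }
  parts <- vapply(toks, parse_token, character(3))
  pos <- as.integer(parts[1L, ])
  bad <- pos < 1L | pos > MT_GENOME_LENGTH
  if (any(bad))
    stop(sprintf("position out of range [1,%d]: %s", MT_GENOME_LENGTH,
                 paste(pos[bad], collapse = ", ")))
  mt_variants(position = pos, kind = parts[2L, ], derived_state = parts[3L, ])
}

#' Construct an mt_variants set
#'
#' @param position Integer rCRS positions (1-based).
#' @param kind One of `"transition"`, `"transversion"`, `"insertion"`,
#'   `"deletion"` per variant.
#' @param derived_state Base for transversions, `".1C"`-style descriptor for
#'   insertions, `""` otherwise.
#' @return A de-duplicated `mt_variants` data frame sorted by position.
#' @export
mt_variants <- function(position = integer(0), kind = character(0),
                        derived_state = character(0)) {
  stopifnot(length(position) == length(kind),
            length(kind) == length(derived_state))
  kinds <- c("transition", "transversion", "insertion", "deletion")
  if (!all(kind %in% kinds))
    stop("kind must be one of: ", paste(kinds, collapse = ", "))
  if (any(kind == "transversion" & !derived_state %in% c("A", "C", "G", "T")))
    stop("transversions require derived_state in {A,C,G,T}")
  token <- variant_token(position, kind, derived_state)
  df <- data.frame(position = as.integer(position), kind = kind,
                   derived_state = derived_state, token = token,
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df$token), , drop = FALSE]
  df <- df[order(df$position, df$kind, df$derived_state), , drop = FALSE]
  rownames(df) <- NULL
  df$hypervariable <- df$position %in% HVS1_POLYC_POSITIONS &
    df$kind %in% c("insertion", "deletion")
  class(df) <- c("mt_variants", "data.frame")
  df
}

variant_token <- function(position, kind, derived_state) {
  out <- as.character(position)
  out[kind == "transversion"] <- paste0(position, derived_state)[kind == "transversion"]
  out[kind == "deletion"] <- paste0(position, "d")[kind == "deletion"]
  out[kind == "insertion"] <- paste0(position, derived_state)[kind == "insertion"]
  out
}

#' Format variants back into a canonical motif string
#'
#' Inverse of [parse_motif()] on canonical motifs: tokens are emitted in
#' ascending positional order joined by `"-"`.
#'
#' @param variants An `mt_variants` object (or anything [as_mt_variants()]
#'   accepts).
#' @param sep Token separator.
#' @return A single motif string (`""` for an empty set).
#' @export
format_motif <- function(variants, sep = "-") {
  v <- as_mt_variants(variants)
  paste(v$token, collapse = sep)
}

#' Coerce motif strings or data frames to mt_variants
#' @param x An `mt_variants` object, a motif string, or a data frame with
#'   the `mt_variants` columns.
#' @return An `mt_variants` object.
#' @export
as_mt_variants <- function(x) {
  if (inherits(x, "mt_variants")) return(x)
  if (is.character(x) && length(x) == 1L) return(parse_motif(x))
  if (is.data.frame(x))
    return(mt_variants(x$position, x$kind, x$derived_state))
  stop("cannot coerce to mt_variants")
}

#' A sample's HVS-I haplotype
#'
#' Bundles a variant set (relative to the rCRS) with a sample id, a
#' population label and the analysed coordinate window.
#'
#' @param sample_id Sample identifier.
#' @param population Population label.
#' @param variants Motif string or `mt_variants`.
#' @param window Inclusive 1-based rCRS window actually sequenced
#'   (default `c(16024, 16488)`).
#' @return An object of class `hvs1_seq`.
#' @export
hvs1_sequence <- function(sample_id, population, variants,
                          window = c(16024L, 16488L)) {
  v <- as_mt_variants(variants)
  window <- as.integer(window)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  out <- v$position < window[1] | v$position > window[2]
  if (any(out))
    stop(sprintf("variant position(s) outside window [%d,%d]: %s",
                 window[1], window[2],
                 paste(v$position[out], collapse = ", ")))
  structure(list(sample_id = as.character(sample_id),
                 population = as.character(population),
                 variants = v, window = window),
            class = "hvs1_seq")
}

#' @export
print.hvs1_seq <- function(x, ...) {
  cat(sprintf("<hvs1_seq> %s [%s]: %s\n", x$sample_id, x$population,
              if (nrow(x$variants)) format_motif(x$variants) else "(rCRS)"))
  invisible(x)
}

# Variant tokens of a sequence, with indel / window filtering as used by
# the distance, diversity and rho computations.
seq_tokens <- function(seq, exclude_indels = TRUE, window = NULL) {
  v <- seq$variants
  if (exclude_indels) v <- v[!v$kind %in% c("insertion", "deletion"), , drop = FALSE]
  if (!is.null(window)) v <- v[v$position >= window[1] & v$position <= window[2], , drop = FALSE]
  v$token
}

# Pairwise difference between two token sets (symmetric difference size).
token_distance <- function(a, b) length(setdiff(a, b)) + length(setdiff(b, a))

#' Build a list of HVS-I sequences from a data frame
#'
#' @param df Data frame with columns `sample_id`, `population`, `motif`.
#' @param window Analysis window passed to [hvs1_sequence()].
#' @return List of `hvs1_seq` objects.
#' @export
hvs1_dataset <- function(df, window = c(16024L, 16488L)) {
  stopifnot(all(c("sample_id", "population", "motif") %in% names(df)))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in dataset")
  lapply(seq_len(nrow(df)), function(i)
    hvs1_sequence(df$sample_id[i], df$population[i], df$motif[i], window))
}

#' Flatten HVS-I sequences to a data frame of motif strings
#' @param seqs List of `hvs1_seq`.
#' @return Data frame with `sample_id`, `population`, `motif`.
#' @export
hvs1_table <- function(seqs) {
  data.frame(sample_id = vapply(seqs, `[[`, "", "sample_id"),
             population = vapply(seqs, `[[`, "", "population"),
             motif = vapply(seqs, function(s) format_motif(s$variants), ""),
             stringsAsFactors = FALSE)
}
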