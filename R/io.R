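# Readers/writers for the external representations: FASTA, genotype tables,
# frequency tables.

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-", "?")
Y_STR_LOCI <- c("DYS19", "DYS389I", "DYS389II", "DYS389b", "DYS390", "DYS391",
                "DYS392", "DYS393", "DYS385a", "DYS385b", "DYS438", "DYS439",
                "DYS437", "DYS448", "DYS456", "DYS458", "DYS635", "YGATAH4")
# 15-locus set used for lineage dating (DYS385a/b excluded, DYS389b replaces
# DYS389II which contains the DYS389I stretch).
Y_STR_DATING_LOCI <- c("DYS19", "DYS389I", "DYS389b", "DYS390", "DYS391",
                       "DYS392", "DYS393", "DYS438", "DYS439", "DYS437",
                       "DYS448", "DYS456", "DYS458", "DYS635", "YGATAH4")

is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

#' Read pre-aligned HVS-I sequences from a FASTA file
#'
#' Sequences must be aligned to the reference slice of the analysis window
#' (equal length, gaps as `-`). Variants are called column-wise against the
#' reference. FASTA headers are `sample_id` optionally followed by a
#' population label after whitespace or `|`.
#'
#' @param path FASTA file.
#' @param reference Reference sequence for the window: either a literal
#'   sequence string or the name of a record in the file (which is then
#'   excluded from the output).
#' @param window Inclusive rCRS window the alignment columns map to.
#' @return List of [hvs1_sequence()] objects.
#' @export
read_hvs1_fasta <- function(path, reference, window = c(16024L, 16488L)) {
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  chars <- lapply(as.character(recs), function(x) toupper(as.vector(x)))
  headers <- names(recs)
  if (length(reference) != 1L || !is.character(reference))
    stop("reference must be a single string (sequence or record name)")
  ids <- sub("[| \t].*$", "", headers)
  if (reference %in% ids) {
    ref <- chars[[match(reference, ids)]]
    keep <- ids != reference
    chars <- chars[keep]; headers <- headers[keep]; ids <- ids[keep]
  } else {
    ref <- strsplit(toupper(gsub("\\s", "", reference)), "")[[1]]
  }
  window <- as.integer(window)
  nref <- sum(ref != "-")
  if (nref != window[2] - window[1] + 1L)
    stop(sprintf("reference length %d does not match window [%d,%d]",
                 nref, window[1], window[2]))
  pops <- ifelse(grepl("[| \t]", headers),
                 sub("^[^| \t]+[| \t]+", "", headers), "NA")
  # rCRS coordinate of each alignment column (insertion columns carry the
  # coordinate of the preceding reference base).
  coord <- window[1] - 1L + cumsum(ref != "-")
  lapply(seq_along(chars), function(i) {
    s <- chars[[i]]
    if (length(s) != length(ref))
      stop(sprintf("sequence '%s' length %d does not match alignment length %d",
                   ids[i], length(s), length(ref)))
    bad <- !s %in% IUPAC_CODES
    if (any(bad))
      stop(sprintf("non-IUPAC symbol '%s' in sequence '%s'",
                   s[bad][1], ids[i]))
    pos <- integer(0); kind <- character(0); state <- character(0)
    ins_rank <- 0L
    for (j in seq_along(s)) {
      b <- s[j]; r <- ref[j]
      if (r == "-") {                      # insertion column
        ins_rank <- ins_rank + 1L
        if (b != "-" && b %in% c("A", "C", "G", "T")) {
          pos <- c(pos, coord[j]); kind <- c(kind, "insertion")
          state <- c(state, paste0(".", ins_rank, b))
        }
        next
      }
      ins_rank <- 0L
      if (b == r || b %in% c("N", "?")) next
      if (!b %in% c("A", "C", "G", "T", "-")) next  # ambiguity: treat missing
      if (b == "-") {
        pos <- c(pos, coord[j]); kind <- c(kind, "deletion"); state <- c(state, "")
      } else if (is_transition(r, b)) {
        pos <- c(pos, coord[j]); kind <- c(kind, "transition"); state <- c(state, "")
      } else {
        pos <- c(pos, coord[j]); kind <- c(kind, "transversion"); state <- c(state, b)
      }
    }
    hvs1_sequence(ids[i], pops[i], mt_variants(pos, kind, state), window)
  })
}

#' Write HVS-I sequences as an aligned FASTA file
#'
#' @param seqs List of `hvs1_seq`.
#' @param reference Reference sequence string for the window.
#' @param path Output file.
#' @param window rCRS window.
#' @return `path`, invisibly. Insertions are not representable in the fixed
#'   reference frame and raise an error.
#' @export
write_hvs1_fasta <- function(seqs, reference, path,
                             window = c(16024L, 16488L)) {
  ref <- strsplit(toupper(gsub("\\s", "", reference)), "")[[1]]
  window <- as.integer(window)
  stopifnot(length(ref) == window[2] - window[1] + 1L)
  con <- file(path, "w"); on.exit(close(con))
  complement_ts <- c(A = "G", G = "A", C = "T", T = "C")
  for (s in seqs) {
    x <- ref
    v <- s$variants
    if (any(v$kind == "insertion"))
      stop("insertions cannot be written in the fixed reference frame")
    for (k in seq_len(nrow(v))) {
      j <- v$position[k] - window[1] + 1L
      if (v$kind[k] == "transversion" && v$derived_state[k] == x[j])
        stop(sprintf("transversion %s: reference already carries %s",
                     v$token[k], x[j]))
      x[j] <- switch(v$kind[k],
                     transition = complement_ts[[x[j]]],
                     transversion = v$derived_state[k],
                     deletion = "-")
    }
    writeLines(c(sprintf(">%s %s", s$sample_id, s$population),
                 paste(x, collapse = "")), con)
  }
  invisible(path)
}

#' Derive DYS389b from the two DYS389 fragments
#'
#' DYS389II amplicons contain the DYS389I repeat stretch; the independent
#' locus DYS389b is obtained by subtracting the DYS389I allele.
#'
#' @param dys389I,dys389II Repeat counts.
#' @return `dys389II - dys389I`.
#' @export
adjust_dys389 <- function(dys389I, dys389II) {
  if (any(dys389II <= dys389I))
    stop("DYS389II must exceed DYS389I")
  dys389II - dys389I
}

#' Construct a Y-chromosome sample profile
#'
#' @param sample_id Sample identifier.
#' @param population Population label.
#' @param snp_states Named character vector over the marker panel with
#'   values `"derived"`, `"ancestral"` or `"untyped"`.
#' @param str_alleles Named numeric vector of STR repeat counts (may be
#'   empty). DYS389b is derived automatically when both DYS389 fragments
#'   are present.
#' @return An object of class `y_profile`.
#' @export
y_profile <- function(sample_id, population, snp_states,
                      str_alleles = numeric(0)) {
  stopifnot(is.character(snp_states), !is.null(names(snp_states)))
  bad <- !snp_states %in% c("derived", "ancestral", "untyped")
  if (any(bad)) stop("invalid SNP state: ", snp_states[bad][1])
  if (length(str_alleles)) {
    stopifnot(!is.null(names(str_alleles)))
    unknown <- setdiff(names(str_alleles), Y_STR_LOCI)
    if (length(unknown)) stop("unknown STR locus: ", unknown[1])
    ok <- is.na(str_alleles) | (str_alleles >= 5 & str_alleles <= 40)
    if (!all(ok)) stop("STR allele outside [5,40]")
    if (all(c("DYS389I", "DYS389II") %in% names(str_alleles)) &&
        !"DYS389b" %in% names(str_alleles))
      str_alleles[["DYS389b"]] <- adjust_dys389(str_alleles[["DYS389I"]],
                                                str_alleles[["DYS389II"]])
    if (all(c("DYS389I", "DYS389II", "DYS389b") %in% names(str_alleles)) &&
        !isTRUE(all.equal(str_alleles[["DYS389b"]],
                          str_alleles[["DYS389II"]] - str_alleles[["DYS389I"]])))
      stop("DYS389b must equal DYS389II - DYS389I")
  }
  structure(list(sample_id = as.character(sample_id),
                 population = as.character(population),
                 snp_states = snp_states, str_alleles = str_alleles),
            class = "y_profile")
}

SNP_STATE_ALIASES <- stats::setNames(
  c("derived", "derived", "derived", "derived",
    "ancestral", "ancestral", "ancestral", "ancestral",
    "untyped", "untyped"),
  c("derived", "+", "1", "D", "ancestral", "-", "0", "A", ".", ""))

#' Read a tab-delimited Y genotype table
#'
#' Columns: `sample_id`, `population`, then one column per SNP marker
#' (states `derived`/`ancestral`/`.` or `+`/`-`) and per STR locus
#' (integer repeat counts, `.` = untyped). STR columns are recognised by
#' their Yfiler locus names; everything else is treated as a SNP marker.
#'
#' @param path TSV file.
#' @return List of [y_profile()] objects.
#' @export
read_y_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  stopifnot(all(c("sample_id", "population") %in% names(df)))
  marker_cols <- setdiff(names(df), c("sample_id", "population"))
  str_cols <- intersect(marker_cols, Y_STR_LOCI)
  snp_cols <- setdiff(marker_cols, str_cols)
  lapply(seq_len(nrow(df)), function(i) {
    snp <- vapply(snp_cols, function(cn) {
      v <- df[[cn]][i]
      if (is.na(v) || !v %in% names(SNP_STATE_ALIASES))
        stop(sprintf("bad SNP state '%s' for %s/%s", v, df$sample_id[i], cn))
      SNP_STATE_ALIASES[[v]]
    }, character(1))
    names(snp) <- snp_cols
    str <- vapply(str_cols, function(cn) {
      v <- df[[cn]][i]
      if (is.na(v) || v %in% c(".", "")) NA_real_ else as.numeric(v)
    }, numeric(1))
    names(str) <- str_cols
    str <- str[!is.na(str)]
    y_profile(df$sample_id[i], df$population[i], snp, str)
  })
}

#' Write Y profiles to a tab-delimited genotype table
#' @param profiles List of `y_profile`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_y_table <- function(profiles, path) {
  snp_names <- unique(unlist(lapply(profiles, function(p) names(p$snp_states))))
  str_names <- unique(unlist(lapply(profiles, function(p) names(p$str_alleles))))
  str_names <- intersect(Y_STR_LOCI, str_names)  # canonical order
  rows <- lapply(profiles, function(p) {
    snp <- rep(".", length(snp_names)); names(snp) <- snp_names
    typed <- p$snp_states[p$snp_states != "untyped"]
    snp[names(typed)] <- unname(typed)
    str <- rep(".", length(str_names)); names(str) <- str_names
    have <- intersect(str_names, names(p$str_alleles))
    str[have] <- as.character(p$str_alleles[have])
    c(sample_id = p$sample_id, population = p$population, snp, str)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write HVS-I motif tables
#'
#' TSV with columns `sample_id`, `population`, `motif` (empty or `.` for
#' rCRS-identical).
#'
#' @param path TSV file.
#' @param window Analysis window.
#' @return `read_motif_table()`: list of `hvs1_seq`; `write_motif_table()`:
#'   `path` invisibly.
#' @export
read_motif_table <- function(path, window = c(16024L, 16488L)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  df$motif[is.na(df$motif)] <- ""
  hvs1_dataset(df, window)
}

#' @rdname read_motif_table
#' @param seqs List of `hvs1_seq`.
#' @export
write_motif_table <- function(seqs, path) {
  utils::write.table(hvs1_table(seqs), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Path to an installed fixture file
#' @param ... Path components under `extdata/`.
#' @return Absolute file path.
#' @export
uniparent_extdata <- function(...) {
  p <- system.file("extdata", ..., package = "uniparent", mustWork = FALSE)
  if (!nzchar(p)) stop("fixture not found: ", file.path(...))
  p
}
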