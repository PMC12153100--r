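# H2A.X variant census from the C-terminal SQ[DE][FY] motif. The terminal
# residue of the motif distinguishes the phosphorylatable H2A.X-Y (Tyr142)
# from the unmodifiable H2A.X-F (Phe142). Calls are aggregated per phylum
# and per supergroup, two-variant species are detected, and the aquatic
# fraction among them is computed when lifestyle labels are available.

#' Classify one protein from its C-terminal motif
#'
#' Finds the last occurrence of the pattern S-Q-\[D/E\]-\[F/Y\] whose four
#' residues lie entirely within the final `window` residues of the sequence
#' (so `window = 4` requires the motif to end at the terminus; the default
#' `window = 5` allows one trailing residue). The call is `H2AX_Y` when the
#' motif's final residue is Y, `H2AX_F` when F, otherwise `none`. When both
#' a Y and an F occurrence fall in the window the most C-terminal match
#' wins. `strict = TRUE` additionally requires the match to end at the final
#' residue.
#'
#' @param sequence Amino-acid string (upper case, 20-letter alphabet plus X;
#'   `-` gaps are ignored after removal by the caller).
#' @param window Terminal window length in residues, `>= 4`.
#' @param strict Require the motif to end at the final residue.
#' @return List: `class` (`"H2AX_Y"`, `"H2AX_F"` or `"none"`), `motif_start`,
#'   `motif_end` (`NA` when none), `terminal_distance` (residues between
#'   motif end and sequence end).
#' @export
classify_cterminal <- function(sequence, window = 5, strict = FALSE) {
  if (window < 4) stop("'window' must be >= 4 (motif length)")
  none <- list(class = "none", motif_start = NA_integer_,
               motif_end = NA_integer_, terminal_distance = NA_integer_)
  len <- nchar(sequence)
  if (is.na(sequence) || len < 4L) return(none)
  hits <- gregexpr("SQ[DE][FY]", sequence)[[1L]]
  if (hits[1L] == -1L) return(none)
  ends <- as.integer(hits) + 3L
  dist <- len - ends
  ok <- if (strict) dist == 0L else (len - as.integer(hits) + 1L) <= window
  if (!any(ok)) return(none)
  i <- max(which(ok))  # most C-terminal eligible match wins
  final <- substr(sequence, ends[i], ends[i])
  list(class = if (final == "Y") "H2AX_Y" else "H2AX_F",
       motif_start = as.integer(hits[i]), motif_end = ends[i],
       terminal_distance = dist[i])
}

#' Classify a set of proteins
#'
#' @param sequences Named character vector of amino-acid sequences
#'   (names = accessions), e.g. from [read_fasta()].
#' @inheritParams classify_cterminal
#' @return A `VariantCall` data frame: accession, class, motif_start,
#'   motif_end, terminal_distance.
#' @export
classify_proteins <- function(sequences, window = 5, strict = FALSE) {
  calls <- lapply(sequences, classify_cterminal, window = window, strict = strict)
  out <- data.frame(
    accession = names(sequences),
    class = vapply(calls, `[[`, character(1), "class"),
    motif_start = vapply(calls, `[[`, integer(1), "motif_start"),
    motif_end = vapply(calls, `[[`, integer(1), "motif_end"),
    terminal_distance = vapply(calls, `[[`, integer(1), "terminal_distance"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("VariantCall", "data.frame")
  out
}

#' Per-phylum census of H2A.X variants
#'
#' Joins variant calls to species metadata and collapses isoforms: a species
#' is "Y" when it has at least one H2AX_Y call, "F" when at least one
#' H2AX_F, "both" when both, "none" otherwise (species identity is the
#' case-normalized binomial name). Reports per-phylum species counts and the
#' percentage of two-variant species, a per-sequence tally, and globally the
#' number of two-variant species and the non-aquatic fraction among them
#' (reported as `NA` when aquatic labels are absent, never as zero).
#'
#' @param metadata Data frame with columns accession, species, phylum
#'   (optionally supergroup and logical aquatic).
#' @param calls A `VariantCall` data frame ([classify_proteins()]); every
#'   call must join to a metadata row.
#' @return A `CensusTable` list: `by_phylum` (phylum, n_species, n_Y, n_F,
#'   n_Y_only, n_F_only, n_both, n_none, pct_both), `by_sequence` (phylum,
#'   n_seq, n_seq_Y, n_seq_F), `species` (species-level calls),
#'   `n_both_species`, `pct_both_species`, `pct_non_aquatic_among_both`.
#' @export
census_by_phylum <- function(metadata, calls) {
  need <- c("accession", "species", "phylum")
  if (!all(need %in% colnames(metadata))) {
    stop("metadata needs columns: ", paste(need, collapse = ", "))
  }
  i <- match(calls$accession, metadata$accession)
  if (anyNA(i)) {
    stop("call(s) with no metadata record: ",
         paste(utils::head(calls$accession[is.na(i)], 5L), collapse = ", "))
  }
  df <- data.frame(species = tolower(metadata$species[i]),
                   species_label = metadata$species[i],
                   phylum = metadata$phylum[i],
                   class = calls$class, stringsAsFactors = FALSE)
  has_aquatic <- "aquatic" %in% colnames(metadata) && !all(is.na(metadata$aquatic))
  if (has_aquatic) df$aquatic <- metadata$aquatic[i]

  per_species <- do.call(rbind, lapply(split(df, df$species), function(d) {
    has_y <- any(d$class == "H2AX_Y")
    has_f <- any(d$class == "H2AX_F")
    data.frame(
      species = d$species_label[1L], phylum = d$phylum[1L],
      status = if (has_y && has_f) "both" else if (has_y) "Y"
               else if (has_f) "F" else "none",
      aquatic = if (has_aquatic) d$aquatic[1L] else NA,
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))

  by_phylum <- do.call(rbind, lapply(split(per_species, per_species$phylum), function(d) {
    n_both <- sum(d$status == "both")
    data.frame(
      phylum = d$phylum[1L], n_species = nrow(d),
      n_Y = sum(d$status %in% c("Y", "both")),
      n_F = sum(d$status %in% c("F", "both")),
      n_Y_only = sum(d$status == "Y"), n_F_only = sum(d$status == "F"),
      n_both = n_both, n_none = sum(d$status == "none"),
      pct_both = round(100 * n_both / nrow(d), 2),
      stringsAsFactors = FALSE, row.names = NULL
    )
  }))

  by_sequence <- do.call(rbind, lapply(split(df, df$phylum), function(d) {
    data.frame(phylum = d$phylum[1L], n_seq = nrow(d),
               n_seq_Y = sum(d$class == "H2AX_Y"),
               n_seq_F = sum(d$class == "H2AX_F"),
               stringsAsFactors = FALSE, row.names = NULL)
  }))

  both <- per_species[per_species$status == "both", , drop = FALSE]
  pct_non_aquatic <- if (has_aquatic && nrow(both) > 0 && !anyNA(both$aquatic)) {
    round(100 * sum(!both$aquatic) / nrow(both), 1)
  } else {
    NA_real_
  }
  structure(list(
    by_phylum = by_phylum[order(by_phylum$phylum), , drop = FALSE],
    by_sequence = by_sequence[order(by_sequence$phylum), , drop = FALSE],
    species = per_species[order(per_species$species), , drop = FALSE],
    n_both_species = nrow(both),
    pct_both_species = round(100 * nrow(both) / nrow(per_species), 1),
    pct_non_aquatic_among_both = pct_non_aquatic
  ), class = "CensusTable")
}

#' @export
print.CensusTable <- function(x, ...) {
  cat("CensusTable:", nrow(x$species), "species,", x$n_both_species,
      sprintf("with both variants (%.1f%%)\n", x$pct_both_species))
  if (!is.na(x$pct_non_aquatic_among_both)) {
    cat(sprintf("non-aquatic among two-variant species: %.1f%%\n",
                x$pct_non_aquatic_among_both))
  }
  print(x$by_phylum, row.names = FALSE)
  invisible(x)
}

#' Sequence-logo information content of an alignment
#'
#' Per-column information `R = log2(20) - H`, with `H` the Shannon entropy
#' of residue frequencies over non-gap characters; letter heights are
#' `f_a * R`. An optional small-sample correction
#' `e_n = 19 / (2 ln(2) n)` is subtracted from `R` (off by default).
#' Columns consisting entirely of gaps have undefined information (`NA`)
#' and contribute no letters.
#'
#' @param aligned_sequences Character vector of equal-length aligned
#'   amino-acid strings (gaps `-` or `.`).
#' @param positions Columns to use; default all. Use
#'   `tail(seq_len(width), 12)` to trim to the last 12 alignment positions
#'   (residues 131-142 in H2A.X numbering).
#' @param small_sample_correction Subtract `e_n` from each column's `R`.
#' @return List: `information` (named numeric per column, bits, in
#'   \[0, log2 20\] or `NA`), `heights` (data frame position, residue, freq,
#'   height), `n_nongap` (per column).
#' @export
logo_information <- function(aligned_sequences, positions = NULL,
                             small_sample_correction = FALSE) {
  if (length(aligned_sequences) == 0L) stop("no sequences")
  widths <- nchar(aligned_sequences)
  if (length(unique(widths)) != 1L) stop("sequences must be aligned (equal length)")
  width <- widths[1L]
  if (is.null(positions)) positions <- seq_len(width)
  if (any(positions < 1L | positions > width)) stop("positions out of range")
  chars <- do.call(rbind, strsplit(toupper(aligned_sequences), ""))
  info <- stats::setNames(rep(NA_real_, length(positions)), positions)
  n_nongap <- stats::setNames(integer(length(positions)), positions)
  heights <- list()
  for (j in seq_along(positions)) {
    col <- chars[, positions[j]]
    col <- col[!col %in% c("-", ".")]
    n_nongap[j] <- length(col)
    if (length(col) == 0L) next
    f <- table(col) / length(col)
    H <- -sum(f * log2(f))
    R <- log2(20) - H
    if (small_sample_correction) R <- R - 19 / (2 * log(2) * length(col))
    R <- max(R, 0)
    info[j] <- R
    heights[[j]] <- data.frame(position = positions[j], residue = names(f),
                               freq = as.numeric(f),
                               height = as.numeric(f) * R,
                               stringsAsFactors = FALSE)
  }
  list(information = info,
       heights = if (length(heights)) do.call(rbind, heights)
                 else data.frame(position = integer(), residue = character(),
                                 freq = numeric(), height = numeric()),
       n_nongap = n_nongap)
}
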