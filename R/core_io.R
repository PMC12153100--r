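#' Construct an expression matrix
#'
#' Container for one species' normalized gene-by-stage expression values.
#' Columns are developmental stages in chronological order (column order is
#' the developmental order; it is never re-sorted), rows are genes. Values
#' are non-negative, finite, already-normalized expression units (e.g.
#' DESeq2-normalized counts); the units are opaque to this package.
#'
#' @param values Numeric matrix (genes x stages) with unique rownames
#'   (gene ids) and unique colnames (stage labels).
#' @param species_id Single string identifying the species.
#' @return A numeric matrix of class `ExpressionMatrix` with a `species_id`
#'   attribute.
#' @export
expression_matrix <- function(values, species_id) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (length(species_id) != 1L || !is.character(species_id) || is.na(species_id)) {
    stop("'species_id' must be a single string")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must have gene ids as rownames and stage labels as colnames")
  }
  dup_g <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_g)) {
    stop("duplicate gene id(s): ", paste(unique(dup_g), collapse = ", "))
  }
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s)) {
    stop("duplicate stage label(s): ", paste(unique(dup_s), collapse = ", "))
  }
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "negative or non-finite expression value at gene '%s', stage '%s'",
      rownames(values)[bad[1L, 1L]], colnames(values)[bad[1L, 2L]]
    ))
  }
  structure(values, species_id = species_id,
            class = c("ExpressionMatrix", class(values)))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: species '%s', %d genes x %d stages\n",
              species_id(x), nrow(x), ncol(x)))
  cat("stages:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

#' Species identifier of an expression matrix
#' @param x An `ExpressionMatrix`.
#' @return The species id string.
#' @export
species_id <- function(x) attr(x, "species_id")

# Subsetting an ExpressionMatrix keeps class and species when the result is
# still a matrix.
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    structure(out, species_id = attr(x, "species_id"), class = class(x))
  } else {
    out
  }
}

#' Read an expression matrix from a tab-separated file
#'
#' Expects a header row of stage labels and a first column of gene ids.
#' Stage order is taken from file column order, never from a lexical sort.
#' Decimal point is `.`; no thousands separators. Missing values are not
#' permitted: absent genes must be absent rows.
#'
#' @param path Path to a TSV file.
#' @param species_id Species identifier to attach.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, species_id) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("expression file needs a gene-id column and >=1 stage column")
  gene_ids <- df[[1L]]
  stage_ids <- colnames(df)[-1L]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("malformed numeric cell at row %d (gene '%s'), column '%s': '%s'",
                 bad[1L, 1L], gene_ids[bad[1L, 1L]], stage_ids[bad[1L, 2L]],
                 vals[bad[1L, , drop = FALSE]]))
  }
  rownames(num) <- gene_ids
  colnames(num) <- stage_ids
  expression_matrix(num, species_id)
}

#' Write an expression matrix to a tab-separated file
#'
#' @param x An `ExpressionMatrix`.
#' @param path Output path.
#' @param id_column Name of the first (gene id) column in the header.
#' @export
write_expression <- function(x, path, id_column = "gene_id") {
  df <- data.frame(rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  write_table(df, path, sort_rows = FALSE)
}

#' Construct an ortholog map
#'
#' Long-format table of (group_id, species_id, gene_id) rows. A group is
#' "single-copy" for a set of species when each of those species contributes
#' exactly one gene to the group.
#'
#' @param df Data frame with columns `group_id`, `species_id`, `gene_id`.
#' @return The data frame with class `OrthologMap`.
#' @export
ortholog_map <- function(df) {
  need <- c("group_id", "species_id", "gene_id")
  if (!all(need %in% colnames(df))) {
    stop("ortholog map needs columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[, need]
  for (cn in need) df[[cn]] <- as.character(df[[cn]])
  class(df) <- c("OrthologMap", "data.frame")
  df
}

#' Read an ortholog map from a tab-separated file
#'
#' Columns: group_id, species_id, gene_id (header required). A species
#' appearing twice in a group is retained, but that group is not single-copy
#' for any subset containing the species.
#'
#' @param path Path to a TSV file.
#' @return An [ortholog_map()].
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) {
    warning("empty ortholog map: ", path)
    df <- data.frame(group_id = character(), species_id = character(),
                     gene_id = character())
  }
  ortholog_map(df)
}

#' Group ids single-copy for a set of species
#'
#' @param map An `OrthologMap`.
#' @param species Character vector of species ids.
#' @return Character vector of group ids in which every listed species has
#'   exactly one gene.
#' @export
single_copy_groups <- function(map, species) {
  stopifnot(inherits(map, "OrthologMap"), length(species) >= 1L)
  keep <- map[map$species_id %in% species, , drop = FALSE]
  if (nrow(keep) == 0L) return(character())
  tab <- table(keep$group_id, keep$species_id)
  full <- intersect(species, colnames(tab))
  if (length(full) < length(species)) return(character())
  ok <- rowSums(tab[, full, drop = FALSE] == 1L) == length(species)
  sort(rownames(tab)[ok])
}

#' Translate gene ids between species through single-copy orthologs
#'
#' @param map An `OrthologMap`.
#' @param from,to Species ids.
#' @return Named character vector mapping `from`-species gene ids to
#'   `to`-species gene ids, restricted to groups single-copy for both.
#' @export
ortholog_translation <- function(map, from, to) {
  groups <- single_copy_groups(map, c(from, to))
  if (length(groups) == 0L) return(stats::setNames(character(), character()))
  sub <- map[map$group_id %in% groups, , drop = FALSE]
  a <- sub[sub$species_id == from, ]
  b <- sub[sub$species_id == to, ]
  a <- a[match(groups, a$group_id), ]
  b <- b[match(groups, b$group_id), ]
  stats::setNames(b$gene_id, a$gene_id)
}

#' Write a tabular result as tab-separated text
#'
#' Writes with header, no quoting, `.` decimal point. By default rows are
#' sorted by the first column so output order is deterministic.
#'
#' @param rows Data frame.
#' @param path Output path.
#' @param sort_rows Sort rows by the first column (default `TRUE`).
#' @export
write_table <- function(rows, path, sort_rows = TRUE) {
  rows <- as.data.frame(rows)
  if (sort_rows && nrow(rows) > 1L) {
    rows <- rows[order(rows[[1L]], method = "radix"), , drop = FALSE]
  }
  ok <- tryCatch({
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("cannot write table to '", path, "': ", conditionMessage(ok))
  invisible(path)
}

#' Read a tab-separated table written by [write_table()]
#' @param path Path to a TSV file.
#' @return Data frame.
#' @export
read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' Per-species developmental stage configuration
#'
#' Declares which stage indices count as early (cleavage), late
#' (post-cleavage) and excluded (e.g. adult samples dropped from
#' comparisons); stages in none of the sets are transitional. An optional
#' larva stage splits the late phase into pre-larval (peak before the larva
#' stage) and post-larval (peak at or after it).
#'
#' @param species_id Species identifier.
#' @param early_stages,late_stages,excluded_stages Integer stage indices
#'   (1-based, chronological position). Must be pairwise disjoint.
#' @param larva_stage Optional single stage index; must lie within
#'   `late_stages`.
#' @param n_stages Optional total stage count for range checking.
#' @return A list of class `SpeciesStageConfig`.
#' @export
stage_config <- function(species_id, early_stages, late_stages,
                         excluded_stages = integer(), larva_stage = NULL,
                         n_stages = NULL) {
  early_stages <- as.integer(early_stages)
  late_stages <- as.integer(late_stages)
  excluded_stages <- as.integer(excluded_stages)
  sets <- list(early = early_stages, late = late_stages, excluded = excluded_stages)
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i < j && length(intersect(sets[[i]], sets[[j]]))) {
        stop(sprintf("stage sets '%s' and '%s' overlap", names(sets)[i], names(sets)[j]))
      }
    }
  }
  if (!is.null(larva_stage)) {
    larva_stage <- as.integer(larva_stage)
    if (length(larva_stage) != 1L || !(larva_stage %in% late_stages)) {
      stop("'larva_stage' must be a single index within 'late_stages'")
    }
  }
  all_idx <- c(early_stages, late_stages, excluded_stages)
  if (any(all_idx < 1L)) stop("stage indices must be >= 1")
  if (!is.null(n_stages) && any(all_idx > n_stages)) {
    stop("stage index exceeds n_stages = ", n_stages)
  }
  structure(list(species_id = species_id, early_stages = early_stages,
                 late_stages = late_stages, excluded_stages = excluded_stages,
                 larva_stage = larva_stage, n_stages = n_stages),
            class = "SpeciesStageConfig")
}

#' Read protein sequences from a FASTA file
#' @param path FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa), sub("\\s.*$", "", names(aa)))
}

#' Write protein sequences to a FASTA file
#' @param sequences Named character vector of amino-acid sequences.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  aa <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

# Package-level logger: messages to stderr, gated by option devhet.verbose.
devhet_log <- function(fmt, ...) {
  if (isTRUE(getOption("devhet.verbose", TRUE))) {
    message(sprintf(paste0("[devhet] ", fmt), ...))
  }
  invisible(NULL)
}
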