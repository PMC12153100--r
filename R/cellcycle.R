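# Marker-pair ("cyclone"-style) cell-cycle phase scoring, generalized from
# single cells to bulk developmental samples. A marker pair (a, b) for phase
# p is evidence for p when expression(a) > expression(b); the phase score of
# a sample is the fraction of informative (untied) pairs satisfied. Scores
# are rank-based and therefore invariant to any strictly monotone transform
# of expression.

#' Construct a marker-pair set
#'
#' @param df Data frame with columns `phase` (one of G1, S, G2M), `first`,
#'   `second` (gene ids; `first > second` is evidence for the phase). Pairs
#'   duplicated within a phase are an error.
#' @return The data frame with class `MarkerPairSet`.
#' @export
marker_pair_set <- function(df) {
  need <- c("phase", "first", "second")
  if (!all(need %in% colnames(df))) {
    stop("marker pairs need columns: ", paste(need, collapse = ", "))
  }
  df <- as.data.frame(df)[, need]
  bad <- setdiff(unique(df$phase), c("G1", "S", "G2M"))
  if (length(bad)) stop("unknown phase(s): ", paste(bad, collapse = ", "))
  key <- paste(df$phase, df$first, df$second)
  if (anyDuplicated(key)) stop("duplicated marker pair within a phase")
  class(df) <- c("MarkerPairSet", "data.frame")
  df
}

#' Read marker pairs from a tab-separated file
#' @param path TSV with header columns phase, first, second.
#' @return A [marker_pair_set()].
#' @export
read_marker_pairs <- function(path) {
  marker_pair_set(utils::read.delim(path, header = TRUE, sep = "\t",
                                    colClasses = "character"))
}

#' Restrict marker pairs to genes with single-copy orthologs
#'
#' Keeps only pairs whose both genes have a single-copy ortholog in the
#' target species and translates the gene ids. Mirrors the use of human
#' marker pairs on other species through one-to-one ortholog matches.
#'
#' @param pairs A [marker_pair_set()] in `source_species` gene ids.
#' @param map An [ortholog_map()] covering both species.
#' @param source_species,target_species Species ids.
#' @return A translated [marker_pair_set()]; a phase left without pairs
#'   triggers a warning (it will score as undefined).
#' @export
filter_pairs_by_orthology <- function(pairs, map, source_species, target_species) {
  stopifnot(inherits(pairs, "MarkerPairSet"))
  tr <- ortholog_translation(map, source_species, target_species)
  ok <- pairs$first %in% names(tr) & pairs$second %in% names(tr)
  out <- data.frame(phase = pairs$phase[ok],
                    first = unname(tr[pairs$first[ok]]),
                    second = unname(tr[pairs$second[ok]]),
                    stringsAsFactors = FALSE)
  lost <- setdiff(unique(pairs$phase), unique(out$phase))
  if (length(lost)) {
    warning("no mappable marker pairs left for phase(s): ",
            paste(lost, collapse = ", "), "; these will score as undefined")
  }
  marker_pair_set(out)
}

#' Score one sample against a list of ordered gene pairs
#'
#' `score = #\{(a,b): x_a > x_b\} / #\{(a,b): x_a != x_b\}`; tied pairs are
#' excluded from the denominator, and pairs with a gene absent from the
#' sample are skipped and counted as missing. With no informative pair the
#' score is undefined (`NA`).
#'
#' @param sample_expression Named numeric vector, gene -> expression value.
#' @param pairs Data frame with columns `first`, `second`.
#' @return List: `score` (in \[0,1\] or `NA`), `n_informative`, `n_tied`,
#'   `n_missing`.
#' @export
pair_score <- function(sample_expression, pairs) {
  if (nrow(pairs) == 0L) stop("'pairs' must be non-empty")
  a <- sample_expression[pairs$first]
  b <- sample_expression[pairs$second]
  missing <- is.na(a) | is.na(b)
  a <- a[!missing]; b <- b[!missing]
  informative <- a != b
  n_inf <- sum(informative)
  list(score = if (n_inf == 0L) NA_real_ else sum(a > b) / n_inf,
       n_informative = n_inf,
       n_tied = sum(!informative),
       n_missing = sum(missing))
}

#' Score a bulk time course (or any sample set) for cell-cycle phases
#'
#' Applies [pair_score()] per sample and phase. Bulk samples are scored
#' exactly like single cells; bulk scores reflect population averages over
#' the cells in the sample, not a single cell state. An optional assignment
#' rule labels each sample: G1 if the G1 score is >= 0.5 and the G2M score
#' < 0.5; G2M if G2M >= 0.5 and G1 < 0.5; otherwise S (undefined scores
#' propagate to an `NA` assignment). An optional within-sample permutation
#' null (pair labels permuted across the pooled pair list) yields empirical
#' score quantiles for users wanting cyclone-like calibrated scores; raw
#' proportions are the default output.
#'
#' @param matrix An [expression_matrix()] (genes x samples/stages).
#' @param pairs A [marker_pair_set()] in this species' gene ids.
#' @param assign Add a phase assignment per sample (default `FALSE`).
#' @param n_permutations Number of pair-label permutations for the optional
#'   null (0 = off).
#' @param seed Seed for the permutation null.
#' @return A `PhaseScores` list: `scores` (samples x phases, `NA` where
#'   undefined), `informative` (counts), `assignment` (or `NULL`),
#'   `null_quantile` (or `NULL`).
#' @export
score_timecourse <- function(matrix, pairs, assign = FALSE,
                             n_permutations = 0, seed = 1) {
  stopifnot(inherits(matrix, "ExpressionMatrix"), inherits(pairs, "MarkerPairSet"))
  phases <- c("G1", "S", "G2M")
  samples <- colnames(matrix)
  scores <- matrix(NA_real_, length(samples), length(phases),
                   dimnames = list(samples, phases))
  informative <- scores
  for (p in phases) {
    pp <- pairs[pairs$phase == p, , drop = FALSE]
    if (nrow(pp) == 0L) next
    for (s in seq_along(samples)) {
      x <- stats::setNames(unclass(matrix)[, s], rownames(matrix))
      ps <- pair_score(x, pp)
      scores[s, p] <- ps$score
      informative[s, p] <- ps$n_informative
    }
  }
  assignment <- NULL
  if (assign) {
    assignment <- apply(scores, 1L, function(sc) {
      if (any(is.na(sc[c("G1", "G2M")]))) return(NA_character_)
      if (sc["G1"] >= 0.5 && sc["G2M"] < 0.5) "G1"
      else if (sc["G2M"] >= 0.5 && sc["G1"] < 0.5) "G2M"
      else "S"
    })
  }
  null_quantile <- NULL
  if (n_permutations > 0) {
    set.seed(as.integer(seed))
    null_quantile <- scores
    for (s in seq_along(samples)) {
      x <- stats::setNames(unclass(matrix)[, s], rownames(matrix))
      for (p in phases) {
        obs <- scores[s, p]
        if (is.na(obs)) next
        n_p <- sum(pairs$phase == p)
        null_scores <- vapply(seq_len(n_permutations), function(i) {
          idx <- sample.int(nrow(pairs), n_p)
          pair_score(x, pairs[idx, , drop = FALSE])$score
        }, numeric(1))
        null_quantile[s, p] <- mean(null_scores <= obs, na.rm = TRUE)
      }
    }
  }
  structure(list(scores = scores, informative = informative,
                 assignment = assignment, null_quantile = null_quantile),
            class = "PhaseScores")
}

#' @export
print.PhaseScores <- function(x, ...) {
  cat("PhaseScores:", nrow(x$scores), "samples\n")
  print(utils::head(round(x$scores, 3)))
  if (nrow(x$scores) > 6L) cat("...\n")
  invisible(x)
}

#' Assign the highest-scoring phase per sample
#'
#' @param scores A `PhaseScores`.
#' @return Character vector of phases (argmax of the defined scores; `NA`
#'   when all scores are undefined). Ties break in column order G1, S, G2M.
#' @export
argmax_phase <- function(scores) {
  apply(scores$scores, 1L, function(sc) {
    if (all(is.na(sc))) return(NA_character_)
    names(sc)[which.max(sc)]
  })
}
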