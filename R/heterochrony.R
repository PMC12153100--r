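# Cross-species heterochrony detection: quadrant cross-tabulation of
# single-copy ortholog phase classes, heterochronic gene sets I-IV for a
# trio of species, and their role-specific intersections.

#' Cross-tabulate ortholog phase classes between two species
#'
#' Restricts to ortholog groups single-copy for the two species with both
#' genes present and non-excluded, then cross-tabulates their phase classes.
#' `mode = "cleavage"` crosses early vs late; any gene transitional in
#' either species falls into the `unclear` cell. `mode = "larval"` crosses
#' pre-larval vs post-larval among genes late in both species; genes without
#' a larval sub-class in either species go to `unclear`.
#'
#' @param phases_a,phases_b `GenePhaseTable`s (see [gene_phases()]).
#' @param map An [ortholog_map()] covering both species.
#' @param mode `"cleavage"` or `"larval"`.
#' @return A `QuadrantTable` list: `species` (c(A, B)), `mode`, `counts`
#'   (2 x 2 matrix, rows = species A class, cols = species B class),
#'   `unclear`, `universe` (eligible ortholog count), `percentages` (on the
#'   universe denominator), `genes` (data frame group_id, gene_a, gene_b,
#'   class_a, class_b, cell).
#' @export
quadrant_table <- function(phases_a, phases_b, map, mode = c("cleavage", "larval")) {
  mode <- match.arg(mode)
  sp_a <- attr(phases_a, "species_id")
  sp_b <- attr(phases_b, "species_id")
  stopifnot(!is.null(sp_a), !is.null(sp_b))
  groups <- single_copy_groups(map, c(sp_a, sp_b))
  sub <- map[map$group_id %in% groups, , drop = FALSE]
  ga <- sub$gene_id[sub$species_id == sp_a][match(groups, sub$group_id[sub$species_id == sp_a])]
  gb <- sub$gene_id[sub$species_id == sp_b][match(groups, sub$group_id[sub$species_id == sp_b])]
  ia <- match(ga, phases_a$gene_id)
  ib <- match(gb, phases_b$gene_id)
  present <- !is.na(ia) & !is.na(ib)
  groups <- groups[present]; ga <- ga[present]; gb <- gb[present]
  ia <- ia[present]; ib <- ib[present]
  keep <- phases_a$phase[ia] != "excluded" & phases_b$phase[ib] != "excluded"
  groups <- groups[keep]; ga <- ga[keep]; gb <- gb[keep]
  ia <- ia[keep]; ib <- ib[keep]
  if (length(groups) == 0L) stop("no eligible single-copy orthologs for this pair")

  if (mode == "cleavage") {
    cls <- c("early", "late")
    ca <- phases_a$phase[ia]
    cb <- phases_b$phase[ib]
    clear <- ca %in% cls & cb %in% cls
  } else {
    cls <- c("pre_larval", "post_larval")
    ca <- ifelse(phases_a$phase[ia] == "late", phases_a$sub_phase[ia], "unclear")
    cb <- ifelse(phases_b$phase[ib] == "late", phases_b$sub_phase[ib], "unclear")
    clear <- ca %in% cls & cb %in% cls
  }
  counts <- matrix(0L, 2L, 2L, dimnames = list(cls, cls))
  tab <- table(factor(ca[clear], levels = cls), factor(cb[clear], levels = cls))
  counts[] <- as.integer(tab)
  cell <- ifelse(clear, paste(ca, cb, sep = "/"), "unclear")
  universe <- length(groups)
  structure(list(
    species = c(sp_a, sp_b), mode = mode,
    counts = counts, unclear = sum(!clear), universe = universe,
    percentages = round(100 * counts / universe, 1),
    genes = data.frame(group_id = groups, gene_a = ga, gene_b = gb,
                       class_a = ca, class_b = cb, cell = cell,
                       stringsAsFactors = FALSE)
  ), class = "QuadrantTable")
}

#' @export
print.QuadrantTable <- function(x, ...) {
  cat(sprintf("QuadrantTable (%s): %s (rows) vs %s (cols), universe = %d\n",
              x$mode, x$species[1], x$species[2], x$universe))
  print(x$counts)
  cat("unclear/other:", x$unclear, "\n")
  invisible(x)
}

# Ortholog group ids in a quadrant cell, with `first`/`second` classes given
# in the table's own species order.
quadrant_cell_groups <- function(quad, class_first, class_second) {
  g <- quad$genes
  g$group_id[g$class_a == class_first & g$class_b == class_second]
}

#' Heterochronic gene sets I-IV and their intersections
#'
#' From three pairwise quadrant tables over a shared ortholog universe
#' (species A and B indirect developers, species C direct developer),
#' builds the four heterochronic gene sets:
#' set I = early in A, late in B; set II = late in A, early in B;
#' set III = late in B, early in C; set IV = late in A, early in C.
#' Their intersections isolate role-specific shifts: I intersect III are
#' genes late only in B (B-specific delay), II intersect IV late only in A
#' (A-specific delay), and III intersect IV are genes consistently
#' pre-displaced to early expression in the direct developer C.
#'
#' @param quad_ab Quadrant table for the pair (A, B).
#' @param quad_cb Quadrant table for (C, B) in either species order.
#' @param quad_ca Quadrant table for (C, A) in either species order.
#' @param roles Named character vector `c(A = ..., B = ..., C = ...)` giving
#'   the species id filling each role; C is the direct developer.
#' @return A `HeterochronySets` list of group-id character vectors:
#'   `set_I`..`set_IV`, `delayed_in_B` (I int III), `delayed_in_A`
#'   (II int IV), `consistent_direct` (III int IV), plus `roles`.
#' @export
heterochronic_sets <- function(quad_ab, quad_cb, quad_ca, roles) {
  if (is.null(names(roles)) || !all(c("A", "B", "C") %in% names(roles))) {
    stop("'roles' must be a named vector with elements A, B and C")
  }
  cell <- function(quad, sp_first, class_first, sp_second, class_second) {
    if (identical(quad$species, c(sp_first, sp_second))) {
      quadrant_cell_groups(quad, class_first, class_second)
    } else if (identical(quad$species, c(sp_second, sp_first))) {
      quadrant_cell_groups(quad, class_second, class_first)
    } else {
      stop(sprintf("quadrant table covers (%s, %s); expected (%s, %s)",
                   quad$species[1], quad$species[2], sp_first, sp_second))
    }
  }
  A <- roles[["A"]]; B <- roles[["B"]]; C <- roles[["C"]]
  set_I <- cell(quad_ab, A, "early", B, "late")
  set_II <- cell(quad_ab, A, "late", B, "early")
  set_III <- cell(quad_cb, C, "early", B, "late")
  set_IV <- cell(quad_ca, C, "early", A, "late")
  structure(list(
    set_I = set_I, set_II = set_II, set_III = set_III, set_IV = set_IV,
    delayed_in_B = intersect(set_I, set_III),
    delayed_in_A = intersect(set_II, set_IV),
    consistent_direct = intersect(set_III, set_IV),
    roles = roles
  ), class = "HeterochronySets")
}

#' @export
print.HeterochronySets <- function(x, ...) {
  cat("HeterochronySets (roles:",
      paste(names(x$roles), x$roles, sep = "=", collapse = ", "), ")\n")
  for (nm in c("set_I", "set_II", "set_III", "set_IV",
               "delayed_in_B", "delayed_in_A", "consistent_direct")) {
    cat(sprintf("  %-18s %d genes\n", nm, length(x[[nm]])))
  }
  invisible(x)
}

#' Summarize gene sets as counts and percentages of a universe
#'
#' Percentages use the stated universe as denominator and are reported to
#' one decimal (so 29 genes out of 65 reads 44.6).
#'
#' @param sets Named list of gene-id character vectors (e.g. a
#'   `HeterochronySets`, or any subset of it).
#' @param universe_size Denominator, `> 0`.
#' @return Data frame: set, n, pct.
#' @export
summarize_sets <- function(sets, universe_size) {
  if (universe_size <= 0) stop("'universe_size' must be > 0")
  if (inherits(sets, "HeterochronySets")) {
    sets <- sets[c("set_I", "set_II", "set_III", "set_IV",
                   "delayed_in_B", "delayed_in_A", "consistent_direct")]
  }
  n <- vapply(sets, length, integer(1))
  data.frame(set = names(sets), n = as.integer(n),
             pct = round(100 * n / universe_size, 1),
             stringsAsFactors = FALSE)
}
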