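# Synthetic study-condition generators: multi-species developmental time
# courses with planted cluster archetypes and heterochronic shifts, marker-
# pair cell-cycle datasets, and proteomes with planted C-terminal motifs.
# Each generator returns ground truth alongside the data for recovery tests.

# Round half away from zero, so planted-fraction bookkeeping is exact.
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Gaussian stage archetype: baseline + amplitude * exp(-(s - peak)^2 / (2 w^2))
archetype_profile <- function(n_stages, peak, width, amplitude = 10, baseline = 1) {
  s <- seq_len(n_stages)
  baseline + amplitude * exp(-(s - peak)^2 / (2 * width^2))
}

# Evenly spaced archetype peaks covering the stage range.
archetype_peaks <- function(n_stages, n_archetypes) {
  if (n_archetypes == 1L) return(round((n_stages + 1) / 2))
  round(seq(1, n_stages, length.out = n_archetypes))
}

# Mirror a peak across the early/late boundary (early = stages 1..boundary).
# Early peaks map into the late block and vice versa, preserving relative
# position, so a planted shift always changes the phase class.
mirror_peak <- function(peak, boundary, n_stages) {
  if (peak <= boundary) {
    boundary + max(1L, min(n_stages - boundary, round(peak * (n_stages - boundary) / boundary)))
  } else {
    max(1L, min(boundary, round((peak - boundary) * boundary / (n_stages - boundary))))
  }
}

# Shared machinery: build matrices for several species over one ortholog
# universe. `peaks` is a genes x species integer matrix of per-species
# archetype peaks. Noise is multiplicative lognormal with log-sd `noise_sd`.
build_species_set <- function(peaks, species_ids, n_stages, width,
                              amplitude, baseline, noise_sd) {
  n_genes <- nrow(peaks)
  groups <- sprintf("og%05d", seq_len(n_genes))
  mats <- vector("list", length(species_ids))
  names(mats) <- species_ids
  stage_ids <- sprintf("stage%02d", seq_len(n_stages))
  for (sp in seq_along(species_ids)) {
    base <- t(vapply(peaks[, sp], function(p)
      archetype_profile(n_stages, p, width, amplitude, baseline),
      numeric(n_stages)))
    noise <- matrix(exp(stats::rnorm(n_genes * n_stages, 0, noise_sd)),
                    n_genes, n_stages)
    vals <- base * noise
    rownames(vals) <- paste0(species_ids[sp], "_g", sprintf("%05d", seq_len(n_genes)))
    colnames(vals) <- stage_ids
    mats[[sp]] <- expression_matrix(vals, species_ids[sp])
  }
  map <- ortholog_map(data.frame(
    group_id = rep(groups, times = length(species_ids)),
    species_id = rep(species_ids, each = n_genes),
    gene_id = unlist(lapply(mats, rownames), use.names = FALSE)
  ))
  list(matrices = mats, map = map, groups = groups)
}

#' Generate a synthetic species pair with planted heterochronic shifts
#'
#' Emulates two species' developmental time courses over a shared single-copy
#' ortholog universe. Each gene follows a Gaussian stage archetype
#' (baseline + amplitude * exp(-(s - peak)^2 / (2 width^2))) with
#' multiplicative lognormal noise. A fraction of genes is "shifted": their
#' archetype peak is mirrored across the early/late stage boundary in species
#' B only, so their planted phase class differs between the species
#' (pre-displaced when the peak moves earlier in B, post-displaced when it
#' moves later). The early/late boundary is `floor(n_stages / 2)`.
#'
#' @param n_genes Number of ortholog pairs.
#' @param n_stages Number of developmental stages per species.
#' @param n_archetypes Number of temporal archetypes (evenly spaced peaks).
#' @param frac_shifted Fraction of genes with a planted shift; the count is
#'   `round_half_away(frac_shifted * n_genes)`.
#' @param noise_sd Log-sd of the multiplicative lognormal noise (0 = none).
#' @param seed Integer seed; generation is fully reproducible.
#' @param width Archetype width in stages.
#' @param amplitude,baseline Archetype scale parameters.
#' @return List with elements `matrix_a`, `matrix_b` ([expression_matrix()]),
#'   `map` ([ortholog_map()]), `truth` (data frame: group_id, gene_a, gene_b,
#'   archetype, peak_a, peak_b, shifted, shift_direction), `config_a`,
#'   `config_b` ([stage_config()] with the planted early/late boundary), and
#'   `boundary`.
#' @export
generate_species_pair <- function(n_genes = 500, n_stages = 8, n_archetypes = 4,
                                  frac_shifted = 0.2, noise_sd = 0.2, seed = 1,
                                  width = 0.8, amplitude = 10, baseline = 1) {
  stopifnot(n_archetypes <= n_stages, frac_shifted >= 0, frac_shifted <= 1,
            noise_sd >= 0, n_genes >= 1, n_stages >= 2)
  boundary <- floor(n_stages / 2)
  if (frac_shifted > 0 && (boundary < 1L || boundary >= n_stages)) {
    stop("no stage on the far side of the early/late boundary; cannot plant shifts")
  }
  set.seed(as.integer(seed))
  peaks_pool <- archetype_peaks(n_stages, n_archetypes)
  arch <- sample.int(n_archetypes, n_genes, replace = TRUE)
  peak_a <- peaks_pool[arch]
  peak_b <- peak_a
  n_shift <- as.integer(round_half_away(frac_shifted * n_genes))
  shifted_idx <- if (n_shift > 0) sample.int(n_genes, n_shift) else integer()
  direction <- rep("none", n_genes)
  for (i in shifted_idx) {
    peak_b[i] <- mirror_peak(peak_a[i], boundary, n_stages)
    direction[i] <- if (peak_b[i] < peak_a[i]) "pre_displaced" else "post_displaced"
  }
  built <- build_species_set(cbind(peak_a, peak_b), c("speciesA", "speciesB"),
                             n_stages, width, amplitude, baseline, noise_sd)
  truth <- data.frame(
    group_id = built$groups,
    gene_a = rownames(built$matrices[[1L]]),
    gene_b = rownames(built$matrices[[2L]]),
    archetype = arch,
    peak_a = as.integer(peak_a),
    peak_b = as.integer(peak_b),
    shifted = seq_len(n_genes) %in% shifted_idx,
    shift_direction = direction,
    stringsAsFactors = FALSE
  )
  cfg <- function(sp) stage_config(sp, early_stages = seq_len(boundary),
                                   late_stages = (boundary + 1L):n_stages,
                                   n_stages = n_stages)
  list(matrix_a = built$matrices[[1L]], matrix_b = built$matrices[[2L]],
       map = built$map, truth = truth,
       config_a = cfg("speciesA"), config_b = cfg("speciesB"),
       boundary = boundary)
}

#' Generate a synthetic species trio with a direct-developer shift pattern
#'
#' Three species (A, B indirect developers; C direct developer) over one
#' shared ortholog universe. A fraction of genes is pre-displaced in C: their
#' archetype peaks lie in the late block in A and B but are mirrored into the
#' early block in C, emulating consistent life-cycle heterochronies. The
#' remaining genes share one archetype across all three species.
#'
#' @inheritParams generate_species_pair
#' @param frac_pre_displaced Fraction of genes pre-displaced in species C.
#' @return List with `matrices` (named list A/B/C of [expression_matrix()]),
#'   `map`, `truth` (group_id, archetype, peaks per species, pre_displaced_c),
#'   `configs` (named list of [stage_config()]), and `boundary`.
#' @export
generate_species_trio <- function(n_genes = 300, n_stages = 8, n_archetypes = 4,
                                  frac_pre_displaced = 0.1, noise_sd = 0.2,
                                  seed = 1, width = 0.8, amplitude = 10,
                                  baseline = 1) {
  stopifnot(n_archetypes <= n_stages, frac_pre_displaced >= 0,
            frac_pre_displaced <= 1)
  boundary <- floor(n_stages / 2)
  set.seed(as.integer(seed))
  peaks_pool <- archetype_peaks(n_stages, n_archetypes)
  late_pool <- peaks_pool[peaks_pool > boundary]
  if (frac_pre_displaced > 0 && length(late_pool) == 0L) {
    stop("no late archetype available to pre-displace")
  }
  arch <- sample.int(n_archetypes, n_genes, replace = TRUE)
  peak <- peaks_pool[arch]
  n_shift <- as.integer(round_half_away(frac_pre_displaced * n_genes))
  shifted_idx <- if (n_shift > 0) sample.int(n_genes, n_shift) else integer()
  peak_ab <- peak
  # shifted genes are forced onto a late archetype in A and B ...
  peak_ab[shifted_idx] <- late_pool[1 + (arch[shifted_idx] %% length(late_pool))]
  peak_c <- peak_ab
  # ... and mirrored into the early block in C
  for (i in shifted_idx) peak_c[i] <- mirror_peak(peak_ab[i], boundary, n_stages)
  species <- c("speciesA", "speciesB", "speciesC")
  built <- build_species_set(cbind(peak_ab, peak_ab, peak_c), species,
                             n_stages, width, amplitude, baseline, noise_sd)
  truth <- data.frame(
    group_id = built$groups,
    archetype = arch,
    peak_a = as.integer(peak_ab), peak_b = as.integer(peak_ab),
    peak_c = as.integer(peak_c),
    pre_displaced_c = seq_len(n_genes) %in% shifted_idx,
    stringsAsFactors = FALSE
  )
  cfgs <- lapply(species, function(sp)
    stage_config(sp, early_stages = seq_len(boundary),
                 late_stages = (boundary + 1L):n_stages, n_stages = n_stages))
  names(cfgs) <- species
  list(matrices = built$matrices, map = built$map, truth = truth,
       configs = cfgs, boundary = boundary)
}

#' Generate a synthetic marker-pair cell-cycle dataset
#'
#' Builds, for each cell-cycle phase (G1, S, G2M), `n_pairs_per_phase`
#' ordered marker pairs (a, b) and an expression matrix over samples with
#' known phases such that in samples of a pair's own phase
#' `E[x_a] - E[x_b] = effect` and 0 otherwise, with i.i.d. Gaussian noise
#' on a positive baseline (values clamped at zero).
#'
#' @param n_pairs_per_phase Marker pairs per phase (>= 1).
#' @param n_samples Number of samples (columns).
#' @param effect Positive mean expression difference in the pair's own phase.
#' @param noise_sd Standard deviation of the additive Gaussian noise.
#' @param seed Integer seed.
#' @param baseline Baseline mean expression.
#' @return List with `matrix` ([expression_matrix()] genes x samples),
#'   `pairs` ([marker_pair_set()]) and `truth` (data frame sample_id, phase).
#' @export
generate_marker_dataset <- function(n_pairs_per_phase = 50, n_samples = 200,
                                    effect = 2, noise_sd = 1, seed = 1,
                                    baseline = 10) {
  if (n_pairs_per_phase < 1) stop("'n_pairs_per_phase' must be >= 1")
  if (effect <= 0) stop("'effect' must be > 0")
  set.seed(as.integer(seed))
  phases <- c("G1", "S", "G2M")
  pairs <- do.call(rbind, lapply(phases, function(p) {
    data.frame(phase = p,
               first = sprintf("%s_a%03d", p, seq_len(n_pairs_per_phase)),
               second = sprintf("%s_b%03d", p, seq_len(n_pairs_per_phase)),
               stringsAsFactors = FALSE)
  }))
  genes <- c(rbind(pairs$first, pairs$second))
  true_phase <- sample(phases, n_samples, replace = TRUE)
  vals <- matrix(stats::rnorm(length(genes) * n_samples, baseline, noise_sd),
                 nrow = length(genes),
                 dimnames = list(genes, sprintf("sample%03d", seq_len(n_samples))))
  for (p in phases) {
    in_phase <- which(true_phase == p)
    firsts <- pairs$first[pairs$phase == p]
    vals[firsts, in_phase] <- vals[firsts, in_phase] + effect
  }
  vals[vals < 0] <- 0
  list(matrix = expression_matrix(vals, "synthetic"),
       pairs = marker_pair_set(pairs),
       truth = data.frame(sample_id = colnames(vals), phase = true_phase,
                          stringsAsFactors = FALSE))
}

# Amino-acid alphabet without the motif-forming shortcut removed; sequences
# are scrubbed of SQ[DE][FY] occurrences so background never matches.
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) {
  s <- paste(sample(AA20, len, replace = TRUE), collapse = "")
  # scrub any accidental motif anywhere (keeps the truth table exact)
  while (grepl("SQ[DE][FY]", s)) s <- sub("SQ([DE])([FY])", "SA\\1\\2", s)
  s
}

#' Generate a synthetic proteome with planted H2A.X C-terminal motifs
#'
#' Creates one or two protein records per species. Planted variants carry a
#' C-terminal tail ending in SQ[DE]Y (phosphorylatable, H2A.X-Y) or SQ[DE]F
#' (unmodifiable, H2A.X-F); background sequences contain no SQ[DE][FY]
#' occurrence anywhere. Species receive a phylum, eukaryotic supergroup and
#' aquatic/non-aquatic label recorded in the truth table. Class counts use
#' round-half-away-from-zero on the requested fractions, assigned in the
#' order both, Y-only, F-only, none.
#'
#' @param n_species Number of species.
#' @param frac_Y,frac_F Fractions of species with only the Y (resp. F) variant.
#' @param frac_both Fraction of species carrying both variants.
#' @param frac_aquatic Fraction of species labelled aquatic.
#' @param seed Integer seed.
#' @param seq_length Core sequence length before the motif tail.
#' @return List with `sequences` (named character, FASTA-ready), `metadata`
#'   (data frame accession, species, phylum, supergroup, aquatic) and `truth`
#'   (data frame species, phylum, aquatic, class in both/Y/F/none).
#' @export
generate_proteome <- function(n_species = 100, frac_Y = 0.3, frac_F = 0.3,
                              frac_both = 0.2, frac_aquatic = 0.5, seed = 1,
                              seq_length = 130) {
  fr <- c(frac_Y, frac_F, frac_both, frac_aquatic)
  if (any(fr < 0) || any(fr > 1) || frac_Y + frac_F + frac_both > 1) {
    stop("fractions must lie in [0,1] with frac_Y + frac_F + frac_both <= 1")
  }
  set.seed(as.integer(seed))
  phyla <- c(Chordata = "Opisthokonta", Mollusca = "Opisthokonta",
             Cnidaria = "Opisthokonta", Arthropoda = "Opisthokonta",
             Annelida = "Opisthokonta", Echinodermata = "Opisthokonta",
             Streptophyta = "Archaeplastida", Chlorophyta = "Archaeplastida")
  n_both <- as.integer(round_half_away(frac_both * n_species))
  n_y <- as.integer(round_half_away(frac_Y * n_species))
  n_f <- as.integer(round_half_away(frac_F * n_species))
  n_y <- min(n_y, n_species - n_both)
  n_f <- min(n_f, n_species - n_both - n_y)
  classes <- rep(c("both", "Y", "F", "none"),
                 c(n_both, n_y, n_f, n_species - n_both - n_y - n_f))
  classes <- sample(classes)
  n_aq <- as.integer(round_half_away(frac_aquatic * n_species))
  aquatic <- sample(rep(c(TRUE, FALSE), c(n_aq, n_species - n_aq)))
  species <- sprintf("Species sp%03d", seq_len(n_species))
  phylum <- sample(names(phyla), n_species, replace = TRUE)

  tail_for <- function(final) paste0("ATQA", "SQ", sample(c("D", "E"), 1L), final)
  seqs <- character(0)
  meta <- list()
  for (i in seq_len(n_species)) {
    core <- random_protein(seq_length)
    recs <- switch(classes[i],
      both = c(h2axy = paste0(core, tail_for("Y")),
               h2axf = paste0(random_protein(seq_length), tail_for("F"))),
      Y = c(h2axy = paste0(core, tail_for("Y"))),
      F = c(h2axf = paste0(core, tail_for("F"))),
      none = c(other = core))
    acc <- sprintf("sp%03d_%s", i, names(recs))
    seqs[acc] <- unname(recs)
    meta[[i]] <- data.frame(accession = acc, species = species[i],
                            phylum = phylum[i],
                            supergroup = unname(phyla[phylum[i]]),
                            aquatic = aquatic[i], stringsAsFactors = FALSE)
  }
  list(sequences = seqs,
       metadata = do.call(rbind, meta),
       truth = data.frame(species = species, phylum = phylum,
                          aquatic = aquatic, class = classes,
                          stringsAsFactors = FALSE))
}
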