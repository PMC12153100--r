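test_that("quadrant counts match a brute-force enumeration", {
  # 6 orthologs: 2 early/early, 1 early/late, 2 late/late, 1 transitional
  pa <- phase_table("A", paste0("a", 1:6),
                    c("early", "early", "early", "late", "late", "transitional"))
  pb <- phase_table("B", paste0("b", 1:6),
                    c("early", "early", "late", "late", "late", "early"))
  map <- paired_map(paste0("a", 1:6), paste0("b", 1:6))
  q <- quadrant_table(pa, pb, map)
  # independent oracle: count every combination by direct enumeration
  combos <- table(paste(pa$phase, pb$phase))
  expect_identical(q$counts["early", "early"], 2L)
  expect_identical(q$counts["early", "late"], 1L)
  expect_identical(q$counts["late", "early"], 0L)
  expect_identical(q$counts["late", "late"], 2L)
  expect_identical(q$unclear, 1L)
  expect_identical(unname(combos["early early"]), 2L)
  # conservation of the ortholog universe
  expect_identical(sum(q$counts) + q$unclear, q$universe)
  expect_identical(q$universe, 6L)
})

test_that("swapping the species transposes the quadrant table", {
  set.seed(51)
  phases <- c("early", "late", "transitional")
  pa <- phase_table("A", paste0("a", 1:40), sample(phases, 40, TRUE))
  pb <- phase_table("B", paste0("b", 1:40), sample(phases, 40, TRUE))
  map <- paired_map(paste0("a", 1:40), paste0("b", 1:40))
  q1 <- quadrant_table(pa, pb, map)
  q2 <- quadrant_table(pb, pa, map)
  expect_identical(q2$counts, t(q1$counts))
  expect_identical(q2$unclear, q1$unclear)
})

test_that("excluded genes leave the universe before percentages", {
  pa <- phase_table("A", paste0("a", 1:4), c("early", "late", "excluded", "early"))
  pb <- phase_table("B", paste0("b", 1:4), c("early", "late", "late", "excluded"))
  map <- paired_map(paste0("a", 1:4), paste0("b", 1:4))
  q <- quadrant_table(pa, pb, map)
  expect_identical(q$universe, 2L)
  expect_equal(q$percentages["early", "early"], 50.0)
})

test_that("larval mode cross-tabulates sub-phases among late/late genes", {
  pa <- phase_table("A", paste0("a", 1:4), c("late", "late", "late", "early"),
                    c("pre_larval", "post_larval", "pre_larval", "none"))
  pb <- phase_table("B", paste0("b", 1:4), c("late", "late", "early", "late"),
                    c("pre_larval", "pre_larval", "none", "post_larval"))
  map <- paired_map(paste0("a", 1:4), paste0("b", 1:4))
  q <- quadrant_table(pa, pb, map, mode = "larval")
  expect_identical(q$counts["pre_larval", "pre_larval"], 1L)
  expect_identical(q$counts["post_larval", "pre_larval"], 1L)
  expect_identical(q$unclear, 2L)  # genes not late in both species
})

test_that("heterochronic sets follow their definitions on a constructed trio", {
  genes <- sprintf("g%02d", 1:8)
  # ortholog universe shared by three species, gene i <-> i
  map <- ortholog_map(data.frame(
    group_id = rep(sprintf("og%02d", 1:8), 3),
    species_id = rep(c("A", "B", "C"), each = 8),
    gene_id = c(paste0("a", 1:8), paste0("b", 1:8), paste0("c", 1:8))
  ))
  # g1: early A, late B, late C (set I only);
  # g2: late A, early B, late C (set II only);
  # g3: transitional A, late B, early C (set III only);
  # g4: late A, early B, early C (sets II and IV -> delayed_in_A);
  # g5: late A, late B, early C (sets III and IV -> consistent_direct);
  # g6: early A, late B, early C (sets I and III -> delayed_in_B);
  # g7: late A, early B, early C (sets II and IV -> delayed_in_A);
  # g8: early everywhere (no set).
  pa <- phase_table("A", paste0("a", 1:8),
                    c("early", "late", "transitional", "late", "late", "early", "late", "early"))
  pb <- phase_table("B", paste0("b", 1:8),
                    c("late", "early", "late", "early", "late", "late", "early", "early"))
  pc <- phase_table("C", paste0("c", 1:8),
                    c("late", "late", "early", "early", "early", "early", "early", "early"))
  q_ab <- quadrant_table(pa, pb, map)
  q_cb <- quadrant_table(pc, pb, map)
  q_ca <- quadrant_table(pc, pa, map)
  sets <- heterochronic_sets(q_ab, q_cb, q_ca, roles = c(A = "A", B = "B", C = "C"))
  expect_setequal(sets$set_I, c("og01", "og06"))
  expect_setequal(sets$set_II, c("og02", "og04", "og07"))
  expect_setequal(sets$set_III, c("og03", "og05", "og06"))
  expect_setequal(sets$set_IV, c("og04", "og05", "og07"))
  expect_setequal(sets$delayed_in_B, "og06")
  expect_setequal(sets$delayed_in_A, c("og04", "og07"))
  expect_setequal(sets$consistent_direct, "og05")
  # sets I and II never overlap (opposite directions on the same pair)
  expect_length(intersect(sets$set_I, sets$set_II), 0)
  # every intersection is a subset of both parents
  expect_true(all(sets$consistent_direct %in% sets$set_III))
  expect_true(all(sets$consistent_direct %in% sets$set_IV))
  # species order in the quadrant tables must not matter
  sets2 <- heterochronic_sets(q_ab, quadrant_table(pb, pc, map),
                              quadrant_table(pa, pc, map),
                              roles = c(A = "A", B = "B", C = "C"))
  expect_identical(sets2[1:7], sets[1:7])
})

test_that("planted trio pre-displacements land in consistent_direct exactly", {
  tr <- generate_species_trio(n_genes = 150, frac_pre_displaced = 0.1,
                              noise_sd = 0.05, seed = 52)
  phases <- lapply(names(tr$matrices), function(sp) {
    fit <- cluster_timecourse(tr$matrices[[sp]], k_range = 4, seed = 52)
    gene_phases(fit$clustering, classify_clusters(fit$clustering, tr$configs[[sp]]))
  })
  names(phases) <- names(tr$matrices)
  q_ab <- quadrant_table(phases$speciesA, phases$speciesB, tr$map)
  q_cb <- quadrant_table(phases$speciesC, phases$speciesB, tr$map)
  q_ca <- quadrant_table(phases$speciesC, phases$speciesA, tr$map)
  sets <- heterochronic_sets(q_ab, q_cb, q_ca,
                             roles = c(A = "speciesA", B = "speciesB", C = "speciesC"))
  truth <- tr$truth$group_id[tr$truth$pre_displaced_c]
  expect_setequal(sets$consistent_direct, truth)
  expect_length(sets$set_I, 0)
  expect_length(sets$set_II, 0)
})

test_that("set summaries report one-decimal percentages of the stated universe", {
  sets <- list(shifted = paste0("g", 1:29), same = paste0("h", 1:27))
  s <- summarize_sets(sets, universe_size = 65)
  expect_equal(s$pct[s$set == "shifted"], 44.6)
  expect_equal(summarize_sets(list(empty = character()), 10)$pct, 0.0)
  expect_error(summarize_sets(sets, 0), "universe_size")
  # disjoint cells' percentages sum to 100 within rounding
  set.seed(53)
  for (i in 1:20) {
    n <- sample(20:200, 1)
    cuts <- sort(sample(0:n, 3))
    parts <- diff(c(0, cuts, n))
    sets_i <- split(paste0("g", seq_len(n)), rep(seq_along(parts), parts))
    s_i <- summarize_sets(sets_i, n)
    expect_lte(abs(sum(s_i$pct) - 100), 0.1 * length(parts))
  }
})

test_that("identical inputs give identical quadrant tables and sets", {
  tr <- generate_species_trio(n_genes = 80, seed = 54)
  run <- function() {
    phases <- lapply(names(tr$matrices), function(sp) {
      fit <- cluster_timecourse(tr$matrices[[sp]], k_range = 4, seed = 54)
      gene_phases(fit$clustering, classify_clusters(fit$clustering, tr$configs[[sp]]))
    })
    quadrant_table(phases[[1]], phases[[2]], tr$map)
  }
  expect_identical(run()$counts, run()$counts)
})
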