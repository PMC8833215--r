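test_that("processing sites derive from mature-arm coordinates", {
  h <- mirna_hairpin("mir-x", strrep("A", 100), mature5p = c(10, 31),
                     mature3p = c(65, 86))
  ps <- processing_sites(h)
  expect_equal(unname(ps$drosha), c(9L, 86L))
  expect_equal(unname(ps$dicer), c(31L, 64L))

  # one-armed entry yields only the derivable cuts
  h5 <- mirna_hairpin("mir-y", strrep("A", 100), mature5p = c(10, 31))
  ps5 <- processing_sites(h5)
  expect_equal(unname(ps5$drosha["five"]), 9L)
  expect_true(is.na(ps5$drosha["three"]))
  expect_true(is.na(ps5$dicer["three"]))

  expect_error(mirna_hairpin("bad", strrep("A", 50), mature5p = c(40, 60)),
               "malformed")
  expect_error(mirna_hairpin("bad", strrep("A", 50), mature5p = c(30, 40),
                             mature3p = c(35, 45)), "precede")
})

test_that("hairpin annotation round-trips through GFF3 and friends", {
  sim <- simulate_mirnome(n_hairpins = 3,
                          plants = data.frame(hairpin = 1,
                                              motif = "5'GAG/3'CCC",
                                              site = "DROSHA", distance = 0),
                          seed = 11)
  stem <- tempfile("mirnome")
  write_mirnome(sim, stem)
  back <- read_mirna_hairpins(paste0(stem, ".fa"), paste0(stem, ".db"),
                              paste0(stem, ".gff3"),
                              paste0(stem, "_expression.tsv"),
                              paste0(stem, "_disease.tsv"))
  expect_equal(names(back), names(sim$hairpins))
  for (id in names(back)) {
    expect_equal(back[[id]]$sequence, sim$hairpins[[id]]$sequence)
    expect_equal(back[[id]]$dotbracket, sim$hairpins[[id]]$dotbracket)
    expect_equal(back[[id]]$mature5p, sim$hairpins[[id]]$mature5p)
    expect_equal(back[[id]]$mature3p, sim$hairpins[[id]]$mature3p)
    expect_equal(back[[id]]$expression_rpm, sim$hairpins[[id]]$expression_rpm)
    expect_equal(back[[id]]$disease, sim$hairpins[[id]]$disease)
    expect_equal(processing_sites(back[[id]]),
                 processing_sites(sim$hairpins[[id]]))
  }
})

test_that("mining finds planted motifs at their processing sites", {
  sim <- simulate_mirnome(n_hairpins = 4,
                          plants = data.frame(hairpin = c(1, 2),
                                              motif = c("5'GAG/3'CCC",
                                                        "5'AAC/3'ACA"),
                                              site = c("DROSHA", "DICER"),
                                              distance = c(0, 1)),
                          seed = 19)
  hits <- mine_motifs(sim$hairpins, c("5'GAG/3'CCC", "5'AAC/3'ACA"), K = 2)
  expect_equal(nrow(hits), 2L)
  gag <- hits[hits$motif == "5'GAG/3'CCC", ]
  expect_equal(gag$hairpin_id, "syn-mir-001")
  expect_equal(gag$site, "DROSHA")
  expect_equal(gag$distance_nt, 0L)
  aac <- hits[hits$motif == "5'AAC/3'ACA", ]
  expect_equal(aac$site, "DICER")
  expect_equal(aac$distance_nt, 1L)

  # motifs absent from the hairpin set yield no hits
  expect_equal(nrow(mine_motifs(sim$hairpins, "5'UUU/3'GGG")), 0L)

  # hits are self-consistent: the motif matches a window at the coordinates
  for (r in seq_len(nrow(hits))) {
    h <- sim$hairpins[[hits$hairpin_id[r]]]
    loops <- extract_internal_loops(h)
    at <- vapply(loops, function(lp) lp$i == hits$outer_i[r], logical(1))
    expect_true(hits$motif[r] %in% window_3x3(loops[[which(at)]]))
  }
})

test_that("tandem motif copies in one hairpin yield one hit each", {
  # two 5'GAG/3'CCC loops at and near the Drosha site, as in an oncogenic
  # primary miRNA carrying tandem binding sites
  sim <- simulate_mirnome(n_hairpins = 1,
                          plants = data.frame(hairpin = c(1, 1),
                                              motif = "5'GAG/3'CCC",
                                              site = "DROSHA",
                                              distance = c(0, 6)),
                          seed = 7)
  hits <- mine_motifs(sim$hairpins, "5'GAG/3'CCC", K = 2)
  expect_equal(nrow(hits), 2L)
  expect_equal(sum(hits$site == "DROSHA"), 1L)   # the distal copy is outside K
  expect_setequal(hits$distance_nt, c(0L, 6L))
})

test_that("planted-motif recovery is exact with supplied structures", {
  plants <- data.frame(hairpin = c(1, 2, 3),
                       motif = c("5'GAG/3'CCC", "5'AAC/3'ACA",
                                 "5'CAG/3'GCC"),
                       site = "DROSHA", distance = c(0, 2, 4))
  sim <- simulate_mirnome(n_hairpins = 6, plants = plants, seed = 23)
  decoys <- c("5'UUU/3'GGG", "5'GGG/3'UUU")
  hits <- mine_motifs(sim$hairpins, c(plants$motif, decoys), K = 2)
  expect_setequal(hits$motif, plants$motif)              # 100% sensitivity
  expect_equal(nrow(hits), 3L)                           # no false hits
  expect_equal(hits$hairpin_id[match(plants$motif, hits$motif)],
               sprintf("syn-mir-%03d", plants$hairpin))
})

test_that("structureless hairpins error unless folding is requested", {
  h <- mirna_hairpin("nofold", "GGGGGAAAACCCCC", mature5p = c(1, 4),
                     mature3p = c(11, 14))
  expect_error(mine_motifs(list(h), "5'GAG/3'CCC"), "no structure")
  expect_warning(mine_motifs(list(h), "5'GAG/3'CCC", fold = TRUE),
                 "base-pair-maximization")
})

test_that("target ranking weights by expression with guarded ratios", {
  expect_equal(fold_difference(85900, 391), 220)
  expect_equal(fold_difference(500, 500), 1)
  expect_equal(fold_difference(10, 0), Inf)

  hits <- data.frame(
    hairpin_id = c("hi", "lo", "zero", "na"),
    motif = "5'GAG/3'CCC",
    loop_start = 1L, loop_end = 1L, outer_i = 1L, outer_j = 9L,
    site = "DROSHA", distance_nt = 0L,
    expression_rpm = c(85900, 391, 0, NA),
    disease = TRUE, compounds = "c9", stringsAsFactors = FALSE)
  ranked <- rank_targets(hits)
  expect_equal(ranked$hairpin_id, c("hi", "lo", "zero", "na"))
  expect_equal(ranked$fold_vs_top, c(1, 220, Inf, NA))
  expect_true(ranked$expression_missing[4])
})

test_that("mining summaries recompute the printed percentages", {
  motifs <- sprintf("m%03d", 1:212)
  hits <- data.frame(hairpin_id = "h", motif = motifs[1:123],
                     site = "NONE", disease = TRUE,
                     stringsAsFactors = FALSE)
  s <- mining_summary(motifs, hits)
  expect_equal(s$n_in_mirnome, 123L)
  expect_equal(s$pct_in_mirnome, 58)

  s0 <- mining_summary(motifs, hits[0, ])
  expect_equal(s0$pct_in_mirnome, 0)

  hits2 <- data.frame(hairpin_id = c("a", "a", "b"),
                      motif = c("m1", "m2", "m3"),
                      site = c("DROSHA", "NONE", "DICER"),
                      disease = c(TRUE, TRUE, FALSE),
                      stringsAsFactors = FALSE)
  s2 <- mining_summary(sprintf("m%d", 1:10), hits2)
  expect_equal(s2$pct_in_mirnome, 30)
  # disease-flagged processing-site motifs only
  expect_equal(s2$n_in_processing_sites, 1L)
})
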