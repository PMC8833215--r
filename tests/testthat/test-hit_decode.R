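test_that("pattern matching decodes clean and singly-mutated reads", {
  sc <- small_scheme()
  m <- list(r1_index = 3L, acid_index = 4L, acyl = "R3")
  tag <- encode_member(m, sc)
  d <- match_pattern(tag, sc)
  expect_true(d$ok)
  expect_equal(d[c("r1_index", "acid_index", "acyl")],
               list(r1_index = 3L, acid_index = 4L, acyl = "R3"))

  # one substitution inside the r1 codon still decodes (errors < min_hamming/2)
  pos <- nchar(sc$primer5) + 2L
  mut <- tag
  substr(mut, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(tag, pos, pos))[1]
  d2 <- match_pattern(mut, sc, max_mismatch_per_codon = 1)
  expect_true(d2$ok)
  expect_equal(d2$r1_index, 3L)

  # two substitutions in one codon exceed the tolerance
  mut2 <- mut
  pos2 <- pos + 1L
  substr(mut2, pos2, pos2) <- setdiff(c("A", "C", "G", "T"),
                                      substr(tag, pos2, pos2))[1]
  expect_false(match_pattern(mut2, sc, max_mismatch_per_codon = 1)$ok)

  # truncated 5' primer cannot anchor
  d3 <- match_pattern(substr(tag, 5, nchar(tag)), sc)
  expect_false(d3$ok)
  expect_equal(d3$reason, "NO_ANCHOR")
})

test_that("bead calling recovers planted replicate classes exactly", {
  sc <- small_scheme()
  beads <- data.frame(r1_index = c(0L, 1L), acid_index = c(0L, 1L),
                      acyl = c("R2", "R3"), channel = "DY647",
                      n_beads = c(3L, 1L))
  sim <- simulate_bead_reads(beads, sc, reads_per_bead = 3, noise = 0,
                             seed = 1)
  tabs <- decode_beads(sim$reads, sc)
  tab <- tabs[["DY647"]]
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$k[tab$tag_id == "T000-000-R2"], 3L)
  expect_equal(tab$k[tab$tag_id == "T001-001-R3"], 1L)
  expect_equal(nrow(attr(tabs, "dropped")), 0L)
})

test_that("per-bead majority vote calls the dominant compound, ties drop", {
  sc <- small_scheme()
  tag_a <- encode_member(list(r1_index = 0L, acid_index = 0L, acyl = "R2"),
                         sc)
  tag_b <- encode_member(list(r1_index = 1L, acid_index = 1L, acyl = "R2"),
                         sc)
  reads <- data.frame(
    bead_id = c(rep("b1", 6), rep("b2", 2)),
    channel = "DY647",
    sequence = c(rep(tag_a, 5), tag_b, tag_a, tag_b),
    stringsAsFactors = FALSE)
  tabs <- decode_beads(reads, sc)
  tab <- tabs[["DY647"]]
  expect_equal(tab$tag_id, "T000-000-R2")          # b1 called A by majority
  expect_equal(tab$k, 1L)
  dropped <- attr(tabs, "dropped")
  expect_equal(dropped$bead_id, "b2")              # b2 tied, dropped
  expect_equal(dropped$reason, "TIE")
  # majority calling never inflates bead counts
  expect_lte(sum(tab$k), length(unique(reads$bead_id)))
})

test_that("noisy decoding accuracy is consistent with the binomial model", {
  sc <- small_scheme()
  n_beads <- 100L
  set.seed(13)
  beads <- data.frame(r1_index = sample(0:3, n_beads, replace = TRUE),
                      acid_index = sample(0:5, n_beads, replace = TRUE),
                      acyl = sample(c("R2", "R3"), n_beads, replace = TRUE),
                      channel = "DY647", n_beads = 1L)
  noise <- 0.01
  R <- 5L
  sim <- simulate_bead_reads(beads, sc, reads_per_bead = R, noise = noise,
                             seed = 7)
  tabs <- decode_beads(sim$reads, sc)
  tab <- tabs[["DY647"]]
  called <- rep(NA_character_, n_beads)
  for (i in seq_len(nrow(tab)))
    called[match(tab$bead_ids[[i]], sim$truth$bead_id)] <- tab$tag_id[i]
  acc <- mean(called == sim$truth$tag_id, na.rm = FALSE)
  expect_gte(sum(called == sim$truth$tag_id, na.rm = TRUE), 95L)

  # closed-form check: a read decodes if both primers are error-free and
  # every codon carries at most one substitution
  L <- sc$codon_length
  p_codon <- (1 - noise)^L + L * noise * (1 - noise)^(L - 1)
  p_read <- (1 - noise)^(nchar(sc$primer5) + nchar(sc$primer3)) * p_codon^3
  p_bead <- 1 - (1 - p_read)^R     # >= 1 decodable read (miscalls negligible)
  expect_gt(acc, p_bead - 3 * sqrt(p_bead * (1 - p_bead) / n_beads))
})

test_that("selectivity filter removes counter-channel compounds", {
  sc <- small_scheme()
  beads <- data.frame(
    r1_index = c(0L, 1L, 1L), acid_index = c(0L, 1L, 1L),
    acyl = "R2", channel = c("DY647", "DY647", "TAMRA"),
    n_beads = c(2L, 1L, 1L))
  sim <- simulate_bead_reads(beads, sc, reads_per_bead = 2, seed = 2)
  tabs <- decode_beads(sim$reads, sc)
  filtered <- selectivity_filter(tabs[["DY647"]], tabs[["TAMRA"]])
  expect_equal(filtered$tag_id, "T000-000-R2")     # B seen in both channels
  expect_length(intersect(filtered$tag_id, tabs[["TAMRA"]]$tag_id), 0L)
  # empty counter table is the identity
  empty <- tabs[["TAMRA"]][0, ]
  expect_equal(selectivity_filter(tabs[["DY647"]], empty)$tag_id,
               tabs[["DY647"]]$tag_id)
})

test_that("planted selective compounds survive the filter exactly", {
  sc <- small_scheme()
  sel <- data.frame(r1_index = 0:3, acid_index = 0:3, acyl = "R2",
                    channel = "DY647", n_beads = 1L)
  pro <- data.frame(r1_index = 0:1, acid_index = 4:5, acyl = "R3",
                    n_beads = 1L)
  beads <- rbind(sel,
                 cbind(pro[, 1:3], channel = "DY647", n_beads = pro$n_beads),
                 cbind(pro[, 1:3], channel = "TAMRA", n_beads = pro$n_beads))
  sim <- simulate_bead_reads(beads, sc, reads_per_bead = 2, seed = 8)
  tabs <- decode_beads(sim$reads, sc)
  filtered <- selectivity_filter(tabs[["DY647"]], tabs[["TAMRA"]])
  expect_setequal(filtered$tag_id, sprintf("T%03d-%03d-R2", 0:3, 0:3))
})

test_that("leader clustering follows k-ordered seeds and the threshold", {
  sc <- small_scheme()
  # custom fingerprints trace the leader algorithm:
  # sim(A,B) = sim(A,C) = 0.75 >= 0.7 but sim(B,C) = 0.6 < 0.7
  fps <- list("T000-000-R2" = 1:9,                  # A (max k -> seed)
              "T001-001-R2" = c(1:9, 10:12),        # B
              "T002-002-R2" = c(1:9, 13:15))        # C
  hits <- data.frame(tag_id = names(fps), r1_index = 0:2, acid_index = 0:2,
                     acyl = "R2", k = c(5L, 2L, 1L),
                     stringsAsFactors = FALSE)
  cl <- cluster_hits(hits, sc, threshold = 0.7, mode = "STRUCTURE",
                     structure_fp = function(m) fps[[m$tag_id]])
  expect_equal(length(unique(cl$cluster_id)), 1L)   # one cluster via seed A
  expect_equal(attr(cl, "clusters")$representative, "T000-000-R2")

  # pairwise-disjoint fingerprints give singletons
  fps2 <- list("T000-000-R2" = 1:3, "T001-001-R2" = 4:6,
               "T002-002-R2" = 7:9)
  cl2 <- cluster_hits(hits, sc, threshold = 0.5, mode = "STRUCTURE",
                      structure_fp = function(m) fps2[[m$tag_id]])
  expect_equal(length(unique(cl2$cluster_id)), 3L)
})

test_that("clustering partitions hits and is input-order invariant", {
  sc <- small_scheme()
  lib <- enumerate_del(sc)
  tags <- lib[!duplicated(lib$tag_id), ][1:12, ]
  set.seed(21)
  hits <- data.frame(tag_id = tags$tag_id, r1_index = tags$r1_index,
                     acid_index = tags$acid_index, acyl = tags$acyl,
                     k = sample(1:6, 12, replace = TRUE),
                     stringsAsFactors = FALSE)
  cl <- cluster_hits(hits, sc, threshold = 0.5)
  expect_setequal(cl$tag_id, hits$tag_id)           # partition: all assigned
  expect_equal(anyDuplicated(cl$tag_id), 0L)
  shuffled <- hits[sample(nrow(hits)), ]
  cl2 <- cluster_hits(shuffled, sc, threshold = 0.5)
  expect_equal(cl[order(cl$tag_id), c("tag_id", "cluster_id")],
               cl2[order(cl2$tag_id), c("tag_id", "cluster_id")],
               ignore_attr = TRUE)
  # every member joined a cluster whose seed it matches at >= threshold
  reps <- attr(cl, "clusters")
  for (ci in reps$cluster_id) {
    seed_tag <- reps$representative[reps$cluster_id == ci]
    seed_row <- hits[hits$tag_id == seed_tag, ]
    for (tg in cl$tag_id[cl$cluster_id == ci]) {
      row <- hits[hits$tag_id == tg, ]
      expect_gte(tanimoto(fingerprint(seed_row, sc), fingerprint(row, sc)),
                 0.5)
    }
  }
})

test_that("hit rate and acylation summaries compute their percentages", {
  expect_equal(hit_rate(60, 750000), 0.008)
  expect_equal(hit_rate(0, 1000), 0)
  expect_equal(hit_rate(750000, 750000), 100)
  expect_error(hit_rate(1, 0), "positive")

  hits <- data.frame(tag_id = c("a", "b", "c"), r1_index = 0L,
                     acid_index = 0:2, acyl = c("R2", "R2", "R3"),
                     k = c(3L, 2L, 4L))
  expect_equal(acylation_summary(hits), c(R2 = 5L, R3 = 4L))
})
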