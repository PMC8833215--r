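#' Decode one sequencing read against an encoding scheme
#'
#' Anchors on the exact 5' primer, parses the three fixed-position codon
#' fields, checks the exact 3' primer, and maps each field to its nearest
#' codon within `max_mismatch_per_codon` substitutions. With codon tables at
#' pairwise Hamming distance `>= min_hamming` and a tolerance below
#' `min_hamming / 2`, the nearest codon is provably unique whenever it exists.
#'
#' Unresolvable reads are returned as failures with a reason code rather than
#' raised as errors, so decode statistics stay computable:
#' `NO_ANCHOR` (a primer not found at its expected position),
#' `CODON_MISMATCH` (a field beyond tolerance) or
#' `AMBIGUOUS_CODON` (two codons tie at the minimum distance).
#'
#' @param read DNA string.
#' @param scheme a `del_scheme`.
#' @param max_mismatch_per_codon substitutions tolerated per codon field.
#' @return list with `ok` (logical), `r1_index`, `acid_index`, `acyl`
#'   (NA on failure) and `reason` (`"OK"` or a failure code).
#' @export
match_pattern <- function(read, scheme, max_mismatch_per_codon = 1L) {
  L <- scheme$codon_length
  fail <- function(reason) list(ok = FALSE, r1_index = NA_integer_,
                                acid_index = NA_integer_,
                                acyl = NA_character_, reason = reason)
  p5 <- regexpr(scheme$primer5, read, fixed = TRUE)[1]
  if (p5 < 0L) return(fail("NO_ANCHOR"))
  start <- p5 + nchar(scheme$primer5)
  end3 <- start + 3L * L
  if (nchar(read) < end3 + nchar(scheme$primer3) - 1L)
    return(fail("NO_ANCHOR"))
  if (substr(read, end3, end3 + nchar(scheme$primer3) - 1L) != scheme$primer3)
    return(fail("NO_ANCHOR"))
  fields <- substring(read, start + c(0L, L, 2L * L),
                      start + c(L, 2L * L, 3L * L) - 1L)
  tables <- list(scheme$codons$r1, scheme$codons$acid, scheme$codons$acyl)
  idx <- integer(3L)
  for (f in 1:3) {
    obs <- strsplit(fields[f], "")[[1]]
    tab <- do.call(rbind, strsplit(tables[[f]], ""))
    d <- rowSums(tab != matrix(obs, nrow(tab), L, byrow = TRUE))
    dmin <- min(d)
    if (dmin > max_mismatch_per_codon) return(fail("CODON_MISMATCH"))
    if (sum(d == dmin) > 1L) return(fail("AMBIGUOUS_CODON"))
    idx[f] <- which.min(d)
  }
  list(ok = TRUE, r1_index = idx[1] - 1L, acid_index = idx[2] - 1L,
       acyl = c("R2", "R3")[idx[3]], reason = "OK")
}

#' Decode sorted-bead reads into per-channel hit tables
#'
#' Each bead's reads are decoded individually and the bead's compound is
#' called by majority vote over its successfully decoded reads; beads with no
#' decodable read or with a tied vote are dropped and logged. The replicate
#' class `k` of a compound is the number of distinct called beads carrying it
#' in a channel -- redundant isolation of the same compound on several sorted
#' beads is the screen's internal confidence measure.
#'
#' @param reads data frame with columns `bead_id`, `channel`, `sequence`
#'   (one row per read), e.g. from [read_bead_reads()] or
#'   [simulate_bead_reads()].
#' @param scheme a `del_scheme`.
#' @param max_mismatch_per_codon passed to [match_pattern()].
#' @return named list of hit tables, one per channel. Each hit table is a
#'   data frame (class `hit_table`) with columns `tag_id`, `r1_index`,
#'   `acid_index`, `acyl`, `k` and `bead_ids` (list column), sorted by
#'   decreasing `k` then `tag_id`. Dropped beads are recorded in the
#'   `"dropped"` attribute as a data frame (`bead_id`, `channel`, `reason`).
#' @export
decode_beads <- function(reads, scheme, max_mismatch_per_codon = 1L) {
  stopifnot(all(c("bead_id", "channel", "sequence") %in% names(reads)))
  dec <- lapply(reads$sequence, match_pattern, scheme = scheme,
                max_mismatch_per_codon = max_mismatch_per_codon)
  reads$call <- vapply(dec, function(d) {
    if (d$ok) sprintf("T%03d-%03d-%s", d$r1_index, d$acid_index, d$acyl)
    else NA_character_
  }, character(1))

  out <- list()
  dropped <- list()
  for (ch in unique(reads$channel)) {
    rc <- reads[reads$channel == ch, , drop = FALSE]
    calls <- split(rc$call, rc$bead_id)
    bead_call <- vapply(calls, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return("DROP:NO_DECODE")
      tt <- sort(table(v), decreasing = TRUE)
      if (length(tt) > 1L && tt[1] == tt[2]) return("DROP:TIE")
      names(tt)[1]
    }, character(1))
    drop_mask <- startsWith(bead_call, "DROP:")
    if (any(drop_mask)) {
      dropped[[ch]] <- data.frame(
        bead_id = names(bead_call)[drop_mask], channel = ch,
        reason = sub("^DROP:", "", bead_call[drop_mask]),
        stringsAsFactors = FALSE, row.names = NULL)
    }
    called <- bead_call[!drop_mask]
    if (!length(called)) {
      tab <- data.frame(tag_id = character(), r1_index = integer(),
                        acid_index = integer(), acyl = character(),
                        k = integer(), stringsAsFactors = FALSE)
      tab$bead_ids <- list()
    } else {
      by_tag <- split(names(called), unname(called))
      tab <- data.frame(tag_id = names(by_tag),
                        k = lengths(by_tag),
                        stringsAsFactors = FALSE, row.names = NULL)
      parts <- regmatches(tab$tag_id,
                          regexec("^T(\\d+)-(\\d+)-(R[23])$", tab$tag_id))
      tab$r1_index <- as.integer(vapply(parts, `[`, character(1), 2L))
      tab$acid_index <- as.integer(vapply(parts, `[`, character(1), 3L))
      tab$acyl <- vapply(parts, `[`, character(1), 4L)
      tab$bead_ids <- unname(by_tag)
      tab <- tab[order(-tab$k, tab$tag_id),
                 c("tag_id", "r1_index", "acid_index", "acyl", "k", "bead_ids")]
      rownames(tab) <- NULL
    }
    class(tab) <- c("hit_table", class(tab))
    out[[ch]] <- tab
  }
  attr(out, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
    else data.frame(bead_id = character(), channel = character(),
                    reason = character(), stringsAsFactors = FALSE)
  out
}

#' Two-channel selectivity filter
#'
#' Retains target-channel compounds that were never observed in the
#' counter-screen channel. This is the in-silico analogue of the two-color
#' sort gate: beads binding the fully base-paired control RNA flag their
#' compounds as nonselective, and those compound keys are removed wholesale.
#'
#' @param target,counter hit tables from [decode_beads()].
#' @return the filtered target hit table (subset of `target`, disjoint from
#'   `counter` by `tag_id`).
#' @export
selectivity_filter <- function(target, counter) {
  keep <- !(target$tag_id %in% counter$tag_id)
  out <- target[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Leader clustering of hits by Tanimoto similarity
#'
#' Deterministic leader-style clustering: hits are processed in order of
#' decreasing replicate class `k` (ties broken lexicographically by tag id);
#' each hit joins the first existing cluster whose seed it matches at
#' similarity `>= threshold`, otherwise it seeds a new cluster. The cluster
#' representative is its maximum-`k` member (ties lexicographic). Clusters are
#' returned sorted by size, then by representative `k`, both decreasing.
#' Because the processing order is fully determined by (`k`, `tag_id`), the
#' partition is invariant to input row order.
#'
#' @param hits a hit table ([decode_beads()] output element).
#' @param scheme a `del_scheme` (for block-one-hot fingerprints).
#' @param threshold similarity threshold for joining a cluster.
#' @param mode,structure_fp passed to [fingerprint()]. Tag-level keys carry no
#'   stereochemistry; block-one-hot fingerprints use the S diastereomer
#'   convention for all keys, which adds one bit common to every hit.
#' @return data frame with columns `tag_id`, `k`, `cluster_id` (1-based, in
#'   the sorted cluster order), `is_representative`; cluster sizes in the
#'   `"clusters"` attribute.
#' @export
cluster_hits <- function(hits, scheme, threshold = 0.8,
                         mode = "BLOCK_ONEHOT", structure_fp = NULL) {
  if (!nrow(hits)) {
    out <- data.frame(tag_id = character(), k = integer(),
                      cluster_id = integer(), is_representative = logical())
    attr(out, "clusters") <- data.frame(cluster_id = integer(),
                                        size = integer(),
                                        representative = character())
    return(out)
  }
  h <- hits[order(-hits$k, hits$tag_id), , drop = FALSE]
  fps <- lapply(seq_len(nrow(h)), function(i)
    fingerprint(h[i, ], scheme, mode = mode, structure_fp = structure_fp))
  seeds <- integer(0)                 # row indices of cluster seeds
  assign <- integer(nrow(h))
  for (i in seq_len(nrow(h))) {
    placed <- FALSE
    for (ci in seq_along(seeds)) {
      if (tanimoto(fps[[i]], fps[[seeds[ci]]]) >= threshold) {
        assign[i] <- ci
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      seeds <- c(seeds, i)
      assign[i] <- length(seeds)
    }
  }
  # representative per cluster: max k, ties lexicographic (h is so ordered)
  rep_row <- vapply(seq_along(seeds), function(ci) min(which(assign == ci)),
                    integer(1))
  sizes <- tabulate(assign, nbins = length(seeds))
  ord <- order(-sizes, -h$k[rep_row], h$tag_id[rep_row])
  new_id <- match(seq_along(seeds), ord)
  out <- data.frame(tag_id = h$tag_id, k = h$k,
                    cluster_id = new_id[assign],
                    stringsAsFactors = FALSE)
  out$is_representative <- seq_len(nrow(h)) %in% rep_row
  out <- out[order(out$cluster_id, -out$k, out$tag_id), ]
  rownames(out) <- NULL
  attr(out, "clusters") <- data.frame(
    cluster_id = seq_along(seeds),
    size = sizes[ord],
    representative = h$tag_id[rep_row][ord],
    stringsAsFactors = FALSE)
  out
}

#' FACS hit rate
#'
#' Percentage of screened beads that produced sort events.
#'
#' @param events number of sort events.
#' @param beads_screened number of beads screened (> 0).
#' @return `100 * events / beads_screened`.
#' @examples
#' hit_rate(60, 750000)  # 0.008
#' @export
hit_rate <- function(events, beads_screened) {
  if (any(beads_screened <= 0)) stop("beads_screened must be positive")
  100 * events / beads_screened
}

#' Acylation-position summary of a hit set
#'
#' Descriptive count of hits acylated at the pendant secondary amine (R2)
#' versus the primary amine (R3), weighted by replicate class (bead counts).
#'
#' @param hits a hit table.
#' @return named integer vector with elements `R2` and `R3` (bead counts).
#' @export
acylation_summary <- function(hits) {
  out <- c(R2 = 0L, R3 = 0L)
  if (nrow(hits)) {
    s <- tapply(hits$k, factor(hits$acyl, levels = c("R2", "R3")), sum)
    s[is.na(s)] <- 0L
    out[names(s)] <- as.integer(s)
  }
  out
}

#' Write a hit report TSV
#'
#' Columns: `compound_id` (tag-level), `r1`, `acid`, `acyl_position`, `k`,
#' `cluster_id`, `is_representative`.
#'
#' @param hits a hit table.
#' @param clusters output of [cluster_hits()] on the same hits.
#' @param path output file.
#' @param config optional list serialized into a `# config:` header line.
#' @return `path`, invisibly.
#' @export
write_hit_report <- function(hits, clusters, path, config = NULL) {
  m <- match(hits$tag_id, clusters$tag_id)
  df <- data.frame(compound_id = hits$tag_id,
                   r1 = hits$r1_index, acid = hits$acid_index,
                   acyl_position = hits$acyl, k = hits$k,
                   cluster_id = clusters$cluster_id[m],
                   is_representative = clusters$is_representative[m],
                   stringsAsFactors = FALSE)
  df <- df[order(df$cluster_id, -df$k, df$compound_id), ]
  write_tsv_with_config(df, path, config)
}
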