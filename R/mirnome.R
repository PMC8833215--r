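#' miRNA hairpin container
#'
#' A primary-miRNA hairpin with its predicted secondary structure, the
#' annotated mature-arm coordinates (1-based inclusive, as in miRBase GFF3),
#' a mature-miRNA expression level in reads per million, and a curated
#' disease-association flag. Coordinates are kept 1-based inclusive
#' throughout I/O; cleavage *bonds* are reported as 0-based inter-nucleotide
#' indices (bond `b` lies between positions `b` and `b + 1`).
#'
#' @param id hairpin identifier.
#' @param sequence RNA string.
#' @param dotbracket balanced dot-bracket structure (same length); if `NULL`
#'   the hairpin is left without structure and must be folded before mining.
#' @param mature5p,mature3p integer length-2 vectors `c(start, end)` of the
#'   mature arms, or `NULL` for one-armed entries.
#' @param expression_rpm mature-miRNA expression (reads per million).
#' @param disease disease-association flag.
#' @return object of class `mirna_hairpin`.
#' @export
mirna_hairpin <- function(id, sequence, dotbracket = NULL,
                          mature5p = NULL, mature3p = NULL,
                          expression_rpm = NA_real_, disease = FALSE) {
  n <- nchar(sequence)
  chk <- function(iv, nm) {
    if (is.null(iv)) return(NULL)
    iv <- as.integer(iv)
    if (length(iv) != 2L || iv[1] < 1L || iv[2] > n || iv[1] > iv[2])
      stop("malformed ", nm, " interval for ", id)
    iv
  }
  mature5p <- chk(mature5p, "mature5p")
  mature3p <- chk(mature3p, "mature3p")
  if (!is.null(mature5p) && !is.null(mature3p) && mature5p[2] >= mature3p[1])
    stop("mature 5p arm must precede the 3p arm (", id, ")")
  if (!is.null(dotbracket)) {
    if (nchar(dotbracket) != n) stop("structure length mismatch for ", id)
    pair_table(dotbracket)
  }
  structure(list(id = id, sequence = sequence, dotbracket = dotbracket,
                 mature5p = mature5p, mature3p = mature3p,
                 expression_rpm = expression_rpm, disease = isTRUE(disease)),
            class = "mirna_hairpin")
}

#' Drosha and Dicer processing sites of a hairpin
#'
#' Derives the nuclease cleavage bonds from the mature-arm annotation: Drosha
#' cuts at the 5' end of the 5p arm and the 3' end of the 3p arm; Dicer cuts
#' at the 3' end of the 5p arm and the 5' end of the 3p arm. Bonds are
#' 0-based inter-nucleotide indices, so a 5p arm `[10, 31]` gives Drosha bond
#' 9 (between positions 9 and 10) and Dicer bond 31. One-armed entries yield
#' only the derivable cuts; the rest are `NA`.
#'
#' @param h a `mirna_hairpin`.
#' @return list with integer vectors `drosha` and `dicer`, each with named
#'   elements `five` and `three` (NA when the arm is missing).
#' @export
processing_sites <- function(h) {
  stopifnot(inherits(h, "mirna_hairpin"))
  drosha <- c(five = NA_integer_, three = NA_integer_)
  dicer <- c(five = NA_integer_, three = NA_integer_)
  if (!is.null(h$mature5p)) {
    drosha["five"] <- h$mature5p[1] - 1L
    dicer["five"] <- h$mature5p[2]
  }
  if (!is.null(h$mature3p)) {
    dicer["three"] <- h$mature3p[1] - 1L
    drosha["three"] <- h$mature3p[2]
  }
  list(drosha = drosha, dicer = dicer)
}

## distance (nt) from a cut bond to an unpaired run [start, end];
## 0 if the bond touches or lies inside the run
bond_run_distance <- function(bond, start, end) {
  if (is.na(bond)) return(NA_integer_)
  if (bond >= start - 1L && bond <= end) return(0L)
  min(abs(bond - (start - 1L)), abs(bond - end))
}

#' Mine privileged motifs across a miRNA hairpin set
#'
#' Extracts the internal loops of every hairpin, windows them to the aligned
#' 3x3 pattern, and matches the windows against a table of privileged motifs.
#' Each match is annotated with its nearest processing site: the loop is "in"
#' a site when one of its unpaired runs lies within `K` nucleotides of a
#' cleavage bond (or spans it); otherwise the site is `NONE`. Every loop
#' occurrence is reported, not only site-overlapping ones, so tandem copies
#' of a motif in one hairpin yield one hit each.
#'
#' @param hairpins list of `mirna_hairpin` objects.
#' @param motif_table data frame with columns `motif` (canonical strings) and
#'   optionally `compound`, or a character vector of motifs.
#' @param K processing-site membership window (nt).
#' @param fold fold structureless hairpins with [nussinov_fold()] (with a
#'   warning) instead of erroring.
#' @return data frame of target hits: `hairpin_id`, `motif`, `loop_start`,
#'   `loop_end` (top-strand unpaired run; the closing-pair coordinates are in
#'   `outer_i`/`outer_j`), `site` (`DROSHA`/`DICER`/`NONE`), `distance_nt`,
#'   `expression_rpm`, `disease`, `compounds` (comma-collapsed).
#' @export
mine_motifs <- function(hairpins, motif_table, K = 2L, fold = FALSE) {
  if (is.character(motif_table))
    motif_table <- data.frame(motif = motif_table, compound = NA_character_,
                              stringsAsFactors = FALSE)
  if (is.null(motif_table$compound)) motif_table$compound <- NA_character_
  by_motif <- split(motif_table$compound, motif_table$motif)
  rows <- list()
  for (h in hairpins) {
    if (is.null(h$dotbracket)) {
      if (!fold) stop("hairpin ", h$id, " has no structure; supply one or ",
                      "set fold = TRUE")
      warning("folding ", h$id, " with the base-pair-maximization model")
      h$dotbracket <- nussinov_fold(h$sequence)
    }
    sites <- processing_sites(h)
    bonds <- c(DROSHA = unname(sites$drosha["five"]),
               DROSHA = unname(sites$drosha["three"]),
               DICER = unname(sites$dicer["five"]),
               DICER = unname(sites$dicer["three"]))
    loops <- extract_internal_loops(h)
    for (lp in loops) {
      if (lp$a > 3L || lp$b > 3L) next
      wins <- window_3x3(lp)
      hit_motifs <- intersect(wins, names(by_motif))
      if (!length(hit_motifs)) next
      runs <- list()
      if (lp$a > 0L) runs <- c(runs, list(c(lp$i + 1L, lp$i2 - 1L)))
      if (lp$b > 0L) runs <- c(runs, list(c(lp$j2 + 1L, lp$j - 1L)))
      d <- vapply(bonds, function(b) {
        dd <- vapply(runs, function(r)
          bond_run_distance(b, r[1], r[2]), integer(1))
        if (all(is.na(dd))) NA_integer_ else min(dd, na.rm = TRUE)
      }, integer(1))
      if (all(is.na(d))) {
        site <- "NONE"
        dist <- NA_integer_
      } else {
        best <- which.min(d)
        dist <- d[best]
        site <- if (dist <= K) names(bonds)[best] else "NONE"
      }
      for (mo in hit_motifs) {
        comp <- by_motif[[mo]]
        rows[[length(rows) + 1L]] <- data.frame(
          hairpin_id = h$id, motif = mo,
          loop_start = lp$i + 1L, loop_end = lp$i2 - 1L,
          outer_i = lp$i, outer_j = lp$j,
          site = site, distance_nt = dist,
          expression_rpm = h$expression_rpm, disease = h$disease,
          compounds = paste(stats::na.omit(comp), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(hairpin_id = character(), motif = character(),
                      loop_start = integer(), loop_end = integer(),
                      outer_i = integer(), outer_j = integer(),
                      site = character(), distance_nt = integer(),
                      expression_rpm = numeric(), disease = logical(),
                      compounds = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ratio of two expression levels, two significant figures
#'
#' @param a,b reads-per-million values.
#' @return `signif(a / b, 2)`; `Inf` when `b` is zero.
#' @examples
#' fold_difference(85900, 391)  # 220
#' @export
fold_difference <- function(a, b) {
  ifelse(b == 0, Inf, signif(a / b, 2))
}

#' Rank candidate targets by expression
#'
#' Groups hits by (motif, site) and ranks each group by mature-miRNA
#' expression, descending; hairpins without expression data rank last and
#' are flagged. Within a group the fold difference of the top-expressed
#' hairpin over each entry is reported (two significant figures; infinite
#' ratios over zero-rpm competitors are kept as `Inf`). Higher-expressed
#' targets are more occupied by a ligand at a given dose, so expression
#' weighting prioritizes the functionally vulnerable targets.
#'
#' @param hits data frame from [mine_motifs()].
#' @param expression optional data frame (`id`, `rpm`) overriding the
#'   per-hairpin expression carried in `hits`.
#' @return `hits` with added `rank_in_group`, `fold_vs_top` and
#'   `expression_missing`, ordered by motif, site and rank.
#' @export
rank_targets <- function(hits, expression = NULL) {
  if (!nrow(hits)) {
    hits$rank_in_group <- integer(0)
    hits$fold_vs_top <- numeric(0)
    hits$expression_missing <- logical(0)
    return(hits)
  }
  if (!is.null(expression))
    hits$expression_rpm <- expression$rpm[match(hits$hairpin_id,
                                                expression$id)]
  hits$expression_missing <- is.na(hits$expression_rpm)
  key <- paste(hits$motif, hits$site, sep = " | ")
  parts <- lapply(split(seq_len(nrow(hits)), key), function(idx) {
    g <- hits[idx, , drop = FALSE]
    ord <- order(g$expression_missing, -ifelse(is.na(g$expression_rpm), 0,
                                               g$expression_rpm))
    g <- g[ord, , drop = FALSE]
    g$rank_in_group <- seq_len(nrow(g))
    top <- g$expression_rpm[1]
    g$fold_vs_top <- ifelse(is.na(g$expression_rpm), NA_real_,
                            fold_difference(top, g$expression_rpm))
    g
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Summarize a mining run
#'
#' Counts how many privileged motifs occur at all in the hairpin set, the
#' corresponding percentage (nearest integer), how many occur in Drosha or
#' Dicer processing sites of disease-flagged hairpins, and per-motif hairpin
#' counts.
#'
#' @param privileged_motifs character vector of privileged motif strings.
#' @param hits data frame from [mine_motifs()] for those motifs.
#' @return list with `n_motifs`, `n_in_mirnome`, `pct_in_mirnome`,
#'   `n_in_processing_sites`, `per_motif_mirna_counts`.
#' @export
mining_summary <- function(privileged_motifs, hits) {
  privileged_motifs <- unique(privileged_motifs)
  n <- length(privileged_motifs)
  present <- unique(hits$motif)
  in_sites <- unique(hits$motif[hits$site != "NONE" & hits$disease])
  per_motif <- vapply(split(hits$hairpin_id, hits$motif),
                      function(x) length(unique(x)), integer(1))
  list(n_motifs = n,
       n_in_mirnome = length(present),
       pct_in_mirnome = if (n > 0) round(100 * length(present) / n) else 0,
       n_in_processing_sites = length(in_sites),
       per_motif_mirna_counts = per_motif)
}

#' Read / write miRBase-style hairpin annotation as GFF3
#'
#' Each hairpin becomes a `miRNA_primary_transcript` record spanning its full
#' length on its own seqid, with `miRNA` child records for the mature arms
#' carrying miRBase-style `ID` and `Derives_from` attributes. Coordinates are
#' 1-based inclusive.
#'
#' @param hairpins list of `mirna_hairpin` objects.
#' @param path GFF3 file path.
#' @return `read_mirna_gff3` returns a data frame with columns `id`, `arm`
#'   (`5p`/`3p`), `start`, `end`.
#' @export
write_mirna_gff3 <- function(hairpins, path) {
  grl <- list()
  for (h in hairpins) {
    n <- nchar(h$sequence)
    gr <- GenomicRanges::GRanges(
      seqnames = h$id,
      ranges = IRanges::IRanges(start = 1L, end = n),
      type = "miRNA_primary_transcript", ID = h$id)
    S4Vectors::mcols(gr)$Derives_from <- NA_character_
    arms <- list()
    if (!is.null(h$mature5p))
      arms[["5p"]] <- GenomicRanges::GRanges(
        seqnames = h$id,
        ranges = IRanges::IRanges(h$mature5p[1], h$mature5p[2]),
        type = "miRNA", ID = paste0(h$id, "-5p"), Derives_from = h$id)
    if (!is.null(h$mature3p))
      arms[["3p"]] <- GenomicRanges::GRanges(
        seqnames = h$id,
        ranges = IRanges::IRanges(h$mature3p[1], h$mature3p[2]),
        type = "miRNA", ID = paste0(h$id, "-3p"), Derives_from = h$id)
    grl[[h$id]] <- if (length(arms)) c(gr, do.call(c, unname(arms))) else gr
  }
  # hairpins live on distinct seqids; concatenation across them is intended
  all <- suppressWarnings(do.call(c, unname(grl)))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' @rdname write_mirna_gff3
#' @export
read_mirna_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  m <- gr[gr$type == "miRNA"]
  df <- data.frame(
    id = as.character(m$Derives_from),
    arm_id = as.character(m$ID),
    start = GenomicRanges::start(m),
    end = GenomicRanges::end(m),
    stringsAsFactors = FALSE)
  df$arm <- ifelse(grepl("-5p$", df$arm_id), "5p",
                   ifelse(grepl("-3p$", df$arm_id), "3p", NA))
  df[, c("id", "arm", "start", "end")]
}

#' Assemble miRNA hairpins from standard files
#'
#' @param fasta_path hairpin sequences (FASTA; T is read as U).
#' @param vienna_path dot-bracket structures ([read_vienna()] format).
#' @param gff3_path mature-arm coordinates ([read_mirna_gff3()] dialect).
#' @param expression_path optional TSV `id`, `rpm`, `n_experiments`.
#' @param disease_path optional TSV `id`, `disease` (logical).
#' @return named list of `mirna_hairpin` objects.
#' @export
read_mirna_hairpins <- function(fasta_path, vienna_path, gff3_path,
                                expression_path = NULL, disease_path = NULL) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  structs <- read_vienna(vienna_path)
  arms <- read_mirna_gff3(gff3_path)
  expr <- if (!is.null(expression_path))
    utils::read.delim(expression_path, stringsAsFactors = FALSE,
                      comment.char = "#") else NULL
  dis <- if (!is.null(disease_path))
    utils::read.delim(disease_path, stringsAsFactors = FALSE,
                      comment.char = "#") else NULL
  out <- list()
  for (i in seq_along(seqs)) {
    id <- ids[i]
    s <- chartr("Tt", "Uu", toupper(as.character(seqs[[i]])))
    a5 <- arms[arms$id == id & arms$arm == "5p", ]
    a3 <- arms[arms$id == id & arms$arm == "3p", ]
    out[[id]] <- mirna_hairpin(
      id = id, sequence = s,
      dotbracket = if (id %in% names(structs)) structs[[id]]$dotbracket,
      mature5p = if (nrow(a5)) c(a5$start[1], a5$end[1]),
      mature3p = if (nrow(a3)) c(a3$start[1], a3$end[1]),
      expression_rpm = if (!is.null(expr) && id %in% expr$id)
        expr$rpm[match(id, expr$id)] else NA_real_,
      disease = if (!is.null(dis) && id %in% dis$id)
        isTRUE(dis$disease[match(id, dis$id)]) else FALSE)
  }
  out
}
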