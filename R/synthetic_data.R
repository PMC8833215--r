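#' Simulate sorted-bead sequencing reads with planted compounds
#'
#' Emulates the sequencing input of the bead-sorting screen: each planted
#' bead yields `reads_per_bead` copies of its compound's DNA tag with
#' independent per-base substitution errors at rate `noise` (no indels; the
#' barcode layout is positional). A machine-readable truth table records the
#' bead-to-compound assignment so decoder recovery can be scored exactly.
#' Fully deterministic for a given seed.
#'
#' @param beads data frame with one row per planted bead group: `r1_index`,
#'   `acid_index`, `acyl`, `channel`, `n_beads`.
#' @param scheme a `del_scheme`.
#' @param reads_per_bead reads sequenced per bead.
#' @param noise per-base substitution probability in `[0, 1]`.
#' @param seed integer seed.
#' @return list with `reads` (data frame `bead_id`, `channel`, `sequence`)
#'   and `truth` (data frame `bead_id`, `channel`, `tag_id`, `r1_index`,
#'   `acid_index`, `acyl`).
#' @export
simulate_bead_reads <- function(beads, scheme, reads_per_bead = 5L,
                                noise = 0, seed = 1L) {
  stopifnot(noise >= 0, noise <= 1,
            all(c("r1_index", "acid_index", "acyl", "channel", "n_beads")
                %in% names(beads)))
  with_seed(seed, {
    idx <- rep(seq_len(nrow(beads)), beads$n_beads)
    truth <- beads[idx, c("r1_index", "acid_index", "acyl", "channel")]
    truth$tag_id <- sprintf("T%03d-%03d-%s", truth$r1_index,
                            truth$acid_index, truth$acyl)
    truth$bead_id <- sprintf("bead%05d", seq_len(nrow(truth)))
    truth <- truth[, c("bead_id", "channel", "tag_id",
                       "r1_index", "acid_index", "acyl")]
    rownames(truth) <- NULL
    tags <- encode_member(truth, scheme)
    reads <- data.frame(
      bead_id = rep(truth$bead_id, each = reads_per_bead),
      channel = rep(truth$channel, each = reads_per_bead),
      sequence = rep(tags, each = reads_per_bead),
      stringsAsFactors = FALSE)
    if (noise > 0 && nrow(reads)) {
      chars <- strsplit(reads$sequence, "")
      L <- nchar(reads$sequence[1])
      flat <- unlist(chars)
      hit <- stats::runif(length(flat)) < noise
      if (any(hit)) {
        # substitute with one of the three other bases, uniformly
        cur <- match(flat[hit], DNA_BASES)
        shift <- sample.int(3L, sum(hit), replace = TRUE)
        flat[hit] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
      }
      reads$sequence <- vapply(split(flat,
                                     rep(seq_len(nrow(reads)), each = L)),
                               paste, character(1), collapse = "")
      reads$sequence <- unname(reads$sequence)
    }
    list(reads = reads, truth = truth)
  })
}

#' Write / read bead reads as FASTQ
#'
#' Read headers carry the documented dialect
#' `<read-id> bead=<id> channel=<DY647|TAMRA>`; base qualities are constant
#' placeholders and ignored on read.
#'
#' @param reads data frame `bead_id`, `channel`, `sequence`.
#' @param path FASTQ file path.
#' @return `read_bead_reads` returns the reads data frame.
#' @export
write_bead_reads <- function(reads, path) {
  ids <- sprintf("read%06d bead=%s channel=%s", seq_len(nrow(reads)),
                 reads$bead_id, reads$channel)
  lines <- character(4L * nrow(reads))
  lines[seq(1, length(lines), by = 4)] <- paste0("@", ids)
  lines[seq(2, length(lines), by = 4)] <- reads$sequence
  lines[seq(3, length(lines), by = 4)] <- "+"
  lines[seq(4, length(lines), by = 4)] <- strrep("I", nchar(reads$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_bead_reads
#' @export
read_bead_reads <- function(path) {
  fmt <- if (grepl("\\.(fa|fasta)$", path)) "fasta" else "fastq"
  ss <- Biostrings::readDNAStringSet(path, format = fmt)
  hdr <- names(ss)
  bead <- sub(".*bead=(\\S+).*", "\\1", hdr)
  channel <- sub(".*channel=(\\S+).*", "\\1", hdr)
  if (any(bead == hdr) || any(channel == hdr))
    stop("read headers must carry 'bead=<id> channel=<DY647|TAMRA>'")
  data.frame(bead_id = bead, channel = channel,
             sequence = as.character(ss), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Simulate selection sequencing counts with planted enrichments
#'
#' Emulates the paired sequencing pools of the RNA-fold selection: the
#' starting-library pool is multinomial over the 4,096 library members with
#' uniform probabilities; the selected pool is multinomial with probabilities
#' proportional to per-motif enrichment factors (factor 1 = no enrichment).
#'
#' @param enrichment named numeric vector of enrichment factors, names being
#'   canonical motif strings; motifs not named have factor 1.
#' @param depth reads per pool.
#' @param compound,dose labels stamped on the output rows.
#' @param seed integer seed.
#' @return list with `counts` (data frame `motif`, `compound`, `dose`,
#'   `x_sel`, `n_sel`, `x_lib`, `n_lib`; one row per library member) and
#'   `truth` (the full factor vector).
#' @export
simulate_2dcs_counts <- function(enrichment = numeric(0), depth = 1e5,
                                 compound = "c1", dose = 1, seed = 1L) {
  ill <- enumerate_ill()
  fac <- rep(1, nrow(ill))
  names(fac) <- ill$motif
  if (length(enrichment)) {
    if (is.null(names(enrichment)) ||
        !all(names(enrichment) %in% ill$motif))
      stop("enrichment must be named by canonical library motifs")
    if (any(enrichment < 0)) stop("enrichment factors must be >= 0")
    fac[names(enrichment)] <- enrichment
  }
  with_seed(seed, {
    x_lib <- stats::rmultinom(1L, depth, rep(1, nrow(ill)))[, 1]
    x_sel <- stats::rmultinom(1L, depth, fac)[, 1]
    counts <- data.frame(motif = ill$motif, compound = compound, dose = dose,
                         x_sel = x_sel, n_sel = depth,
                         x_lib = x_lib, n_lib = depth,
                         stringsAsFactors = FALSE)
    list(counts = counts, truth = fac)
  })
}

## complementary random pair column (WC only, uniform)
random_pair_cols <- function(n) {
  top <- sample(RNA_BASES, n, replace = TRUE)
  bottom <- chartr("ACGU", "UGCA", top)
  list(top = top, bottom = bottom)
}

#' Simulate a toy miRnome with motifs planted at processing sites
#'
#' Builds stem-loop hairpins with a fixed geometry -- single-stranded flanks,
#' a lower stem below the Drosha cut, 22-nt mature arms, an upper stem and an
#' apical tetraloop -- and plants aligned 3x3 motif windows in the duplex at
#' requested distances from the Drosha or Dicer cleavage bonds on the 5' arm
#' side. All non-planted duplex columns are Watson-Crick pairs, so the
#' supplied dot-bracket structure is exact and planted loops are the only
#' internal loops. Window columns pair wherever the motif's aligned bases are
#' complementary (so `5'GAG/3'CCC` plants as a 1x1 loop closed by its two
#' G:C pairs, and a fully non-complementary window as a 3x3 loop). Mature
#' miRNA expression is drawn log-normal; a heavy right tail mirrors the very
#' skewed read-per-million distributions of real small-RNA sequencing.
#'
#' Placement semantics: `distance` is the mining distance from the cleavage
#' bond to the loop's first unpaired top-strand position (0 = the loop abuts
#' or spans the cut). Overlapping or stem-exhausting placements error.
#'
#' @param n_hairpins number of hairpins.
#' @param plants data frame with columns `hairpin` (1-based index), `motif`
#'   (canonical string), `site` (`"DROSHA"` or `"DICER"`), `distance`
#'   (nt, >= 0).
#' @param disease logical vector (recycled) flagging disease-associated
#'   hairpins.
#' @param expression_meanlog,expression_sdlog log-normal parameters of the
#'   reads-per-million distribution.
#' @param flank,lower_stem,arm_len,upper_stem geometry (nt / columns).
#' @param seed integer seed.
#' @return list with `hairpins` (named list of `mirna_hairpin`), `truth`
#'   (plants plus realized window coordinates) and `expression` (data frame
#'   `id`, `rpm`, `n_experiments`).
#' @export
simulate_mirnome <- function(n_hairpins = 10L,
                             plants = NULL,
                             disease = TRUE,
                             expression_meanlog = log(500),
                             expression_sdlog = 2,
                             flank = 10L, lower_stem = 11L,
                             arm_len = 22L, upper_stem = 9L,
                             seed = 1L) {
  apical <- "UUCG"
  W <- lower_stem + arm_len + upper_stem
  if (is.null(plants))
    plants <- data.frame(hairpin = integer(0), motif = character(0),
                         site = character(0), distance = integer(0))
  stopifnot(all(plants$hairpin >= 1L), all(plants$hairpin <= n_hairpins),
            all(plants$site %in% c("DROSHA", "DICER")),
            all(plants$distance >= 0L))
  with_seed(seed, {
    hairpins <- list()
    truth <- list()
    rpm <- signif(stats::rlnorm(n_hairpins, expression_meanlog,
                                expression_sdlog), 3)
    disease <- rep_len(disease, n_hairpins)
    for (hi in seq_len(n_hairpins)) {
      cols_top <- random_pair_cols(W)$top
      cols_bottom <- chartr("ACGU", "UGCA", cols_top)
      paired <- rep(TRUE, W)
      ph <- plants[plants$hairpin == hi, , drop = FALSE]
      used <- rep(FALSE, W)          # window columns incl. 1-col buffer
      win_at <- integer(nrow(ph))
      for (pi in seq_len(nrow(ph))) {
        pm <- parse_motif(ph$motif[pi])
        top_b <- strsplit(pm$top, "")[[1]]
        bot_b <- strsplit(pm$bottom, "")[[1]]
        col_paired <- can_pair(top_b, bot_b)
        if (all(col_paired))
          stop("motif ", ph$motif[pi],
               " is fully paired; no loop to plant")
        first_loop <- which(!col_paired)[1] - 1L   # 0-based offset
        base_col <- if (ph$site[pi] == "DROSHA") lower_stem
                    else lower_stem + arm_len
        start <- base_col + ph$distance[pi] + 1L - first_loop
        end <- start + 2L
        if (start < 2L || end > W - 1L)
          stop("plant ", pi, " in hairpin ", hi,
               " falls outside the duplex (columns ", start, "..", end, ")")
        span <- max(1L, start - 1L):min(W, end + 1L)  # 1-col pair buffer
        if (any(used[span]))
          stop("placement conflict in hairpin ", hi,
               ": overlapping planted windows")
        used[span] <- TRUE
        cols_top[start:end] <- top_b
        cols_bottom[start:end] <- bot_b
        paired[start:end] <- col_paired
        win_at[pi] <- start
      }
      id <- sprintf("syn-mir-%03d", hi)
      n5 <- flank
      top_seq <- paste(cols_top, collapse = "")
      bottom_seq <- paste(rev(cols_bottom), collapse = "")
      seqn <- paste0(paste(sample(RNA_BASES, flank, replace = TRUE),
                           collapse = ""),
                     top_seq, apical, bottom_seq,
                     paste(sample(RNA_BASES, flank, replace = TRUE),
                           collapse = ""))
      db <- paste0(strrep(".", flank),
                   paste(ifelse(paired, "(", "."), collapse = ""),
                   strrep(".", nchar(apical)),
                   paste(rev(ifelse(paired, ")", ".")), collapse = ""),
                   strrep(".", flank))
      N <- nchar(seqn)
      hairpins[[id]] <- mirna_hairpin(
        id = id, sequence = seqn, dotbracket = db,
        mature5p = c(n5 + lower_stem + 1L, n5 + lower_stem + arm_len),
        mature3p = c(N - n5 - lower_stem - arm_len + 1L, N - n5 - lower_stem),
        expression_rpm = rpm[hi], disease = disease[hi])
      if (nrow(ph)) {
        ph$hairpin_id <- id
        ph$window_start <- n5 + win_at
        ph$window_end <- n5 + win_at + 2L
        truth[[length(truth) + 1L]] <- ph
      }
    }
    truth <- if (length(truth)) do.call(rbind, truth)
             else cbind(plants, hairpin_id = character(0),
                        window_start = integer(0), window_end = integer(0))
    expression <- data.frame(id = names(hairpins), rpm = rpm,
                             n_experiments = rep(100L, n_hairpins),
                             stringsAsFactors = FALSE)
    list(hairpins = hairpins, truth = truth, expression = expression)
  })
}

#' Write a simulated miRnome to standard files
#'
#' Emits FASTA (sequences), Vienna dot-bracket (structures), GFF3
#' (mature-arm coordinates), and TSVs for expression and disease flags,
#' under a common file stem.
#'
#' @param sim output of [simulate_mirnome()].
#' @param stem path prefix; files `<stem>.fa`, `<stem>.db`, `<stem>.gff3`,
#'   `<stem>_expression.tsv`, `<stem>_disease.tsv` are written.
#' @return named character vector of the written paths.
#' @export
write_mirnome <- function(sim, stem) {
  paths <- c(fasta = paste0(stem, ".fa"),
             vienna = paste0(stem, ".db"),
             gff3 = paste0(stem, ".gff3"),
             expression = paste0(stem, "_expression.tsv"),
             disease = paste0(stem, "_disease.tsv"))
  seqs <- vapply(sim$hairpins, `[[`, character(1), "sequence")
  writeLines(as.vector(rbind(paste0(">", names(seqs)), seqs)), paths["fasta"])
  write_vienna(sim$hairpins, paths["vienna"])
  write_mirna_gff3(sim$hairpins, paths["gff3"])
  utils::write.table(sim$expression, paths["expression"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dis <- data.frame(id = names(sim$hairpins),
                    disease = vapply(sim$hairpins, `[[`, logical(1),
                                     "disease"))
  utils::write.table(dis, paths["disease"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
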