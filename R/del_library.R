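DNA_BASES <- c("A", "C", "G", "T")

## run expr with a private, seeded RNG stream; caller's stream untouched
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Design a Hamming-separated DNA codon table
#'
#' Selects `n` distinct DNA codons of a fixed length such that every pair of
#' codons differs in at least `min_hamming` positions. A minimum pairwise
#' distance of `2e + 1` guarantees unique nearest-codon decoding of reads
#' carrying up to `e` substitutions per codon.
#'
#' Candidates are drawn in a seeded random order from the full `4^codon_length`
#' codon space and accepted greedily, so the table is deterministic for a given
#' seed. Codons occurring as exact substrings of any sequence in `forbid`
#' (typically the PCR primers) are skipped.
#'
#' @param n number of codons required.
#' @param codon_length codon length in nucleotides.
#' @param min_hamming minimum pairwise Hamming distance.
#' @param seed integer seed controlling the (deterministic) search order.
#' @param forbid character vector of sequences that must not contain any
#'   selected codon as an exact substring.
#' @return character vector of `n` codons satisfying the distance contract.
#' @examples
#' assign_codons(4, 2, 2, seed = 1)
#' @export
assign_codons <- function(n, codon_length, min_hamming, seed = 1L,
                          forbid = character()) {
  stopifnot(n >= 1, codon_length >= 1, min_hamming >= 1)
  total <- 4^codon_length
  if (n > total) {
    stop("infeasible codon table: ", n, " codons requested but only ",
         total, " sequences of length ", codon_length, " exist")
  }
  with_seed(seed, {
    if (total <= 4^9) {
      order_idx <- sample.int(total)
      candidate <- function(i) {
        x <- order_idx[i] - 1L
        d <- integer(codon_length)
        for (p in seq_len(codon_length)) {
          d[p] <- x %% 4L
          x <- x %/% 4L
        }
        d
      }
      n_cand <- total
    } else {
      n_cand <- 500L * n
      candidate <- function(i) sample.int(4L, codon_length, replace = TRUE) - 1L
    }
    accepted <- matrix(0L, nrow = 0L, ncol = codon_length)
    for (i in seq_len(n_cand)) {
      cand <- candidate(i)
      if (nrow(accepted) > 0L) {
        d <- rowSums(accepted != matrix(cand, nrow(accepted), codon_length,
                                        byrow = TRUE))
        if (any(d < min_hamming)) next
      }
      codon <- paste(DNA_BASES[cand + 1L], collapse = "")
      if (length(forbid) && any(vapply(forbid, grepl, logical(1),
                                       pattern = codon, fixed = TRUE))) next
      accepted <- rbind(accepted, cand)
      if (nrow(accepted) == n) break
    }
    if (nrow(accepted) < n) {
      stop("infeasible codon table: could not find ", n, " codons of length ",
           codon_length, " at pairwise Hamming distance >= ", min_hamming)
    }
    apply(accepted, 1L, function(r) paste(DNA_BASES[r + 1L], collapse = ""))
  })
}

#' Construct a DEL encoding scheme
#'
#' Defines the DNA barcoding layout of the split-pool DEL. Each encoded tag is
#' `primer5 | codon(R1 amino acid) | codon(cycle-2 acid) | codon(acylation
#' position) | primer3`. The central hub stereochemistry is deliberately not
#' encoded: both diastereomers of a compound share one tag. All codons across
#' the three fields are drawn from one Hamming-separated pool, so any codon is
#' at distance `>= min_hamming` from every other codon in the scheme.
#'
#' @param n_r1 number of cycle-1 amino-acid building blocks.
#' @param n_acid number of cycle-2 carboxylic-acid building blocks.
#' @param codon_length codon length (nt).
#' @param min_hamming minimum pairwise Hamming distance between codons.
#' @param primer5,primer3 constant PCR primer binding sites flanking the tag.
#' @param seed seed for the deterministic codon search.
#' @return object of class `del_scheme` with elements `primer5`, `primer3`,
#'   `codon_length`, `min_hamming`, `seed` and `codons` (list with character
#'   vectors `r1`, `acid`, and `acyl` named `R2`/`R3`).
#' @examples
#' sc <- del_scheme(n_r1 = 2, n_acid = 3, codon_length = 5)
#' sc$codons$acyl
#' @export
del_scheme <- function(n_r1 = 96L, n_acid = 192L, codon_length = 8L,
                       min_hamming = 3L,
                       primer5 = "GTGCTGCAAGGCGATT",
                       primer3 = "AATTCGCCCTTGAGCA",
                       seed = 1L) {
  pool <- assign_codons(n_r1 + n_acid + 2L, codon_length, min_hamming,
                        seed = seed, forbid = c(primer5, primer3))
  scheme <- structure(list(
    primer5 = primer5, primer3 = primer3,
    codon_length = as.integer(codon_length),
    min_hamming = as.integer(min_hamming),
    seed = as.integer(seed),
    codons = list(
      r1   = pool[seq_len(n_r1)],
      acid = pool[n_r1 + seq_len(n_acid)],
      acyl = stats::setNames(pool[n_r1 + n_acid + 1:2], c("R2", "R3"))
    )
  ), class = "del_scheme")
  validate_scheme(scheme)
  scheme
}

#' Validate a DEL encoding scheme
#'
#' Checks codon lengths, within-cycle uniqueness, the pairwise Hamming
#' contract of each codon table (brute force, all pairs), and that neither
#' primer contains a codon as an exact substring.
#'
#' @param scheme a `del_scheme`.
#' @return the scheme, invisibly; errors on contract violation.
#' @export
validate_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "del_scheme"))
  all_codons <- unlist(scheme$codons, use.names = FALSE)
  if (!all(nchar(all_codons) == scheme$codon_length))
    stop("codon length mismatch")
  for (tab in scheme$codons) {
    if (anyDuplicated(tab)) stop("duplicated codon within a cycle")
    if (length(tab) > 1L) {
      m <- do.call(rbind, strsplit(tab, ""))
      for (i in seq_len(nrow(m) - 1L)) {
        d <- rowSums(m[(i + 1L):nrow(m), , drop = FALSE] !=
                       matrix(m[i, ], nrow(m) - i, ncol(m), byrow = TRUE))
        if (any(d < scheme$min_hamming))
          stop("codon table violates the Hamming distance contract")
      }
    }
  }
  for (p in c(scheme$primer5, scheme$primer3))
    if (any(vapply(all_codons, grepl, logical(1), x = p, fixed = TRUE)))
      stop("a primer contains a codon as an exact substring")
  invisible(scheme)
}

#' @export
print.del_scheme <- function(x, ...) {
  cat("DEL encoding scheme\n")
  cat("  cycle-1 amino acids:", length(x$codons$r1), "\n")
  cat("  cycle-2 acids:      ", length(x$codons$acid), "\n")
  cat("  codon length:", x$codon_length, "nt; min pairwise Hamming:",
      x$min_hamming, "\n")
  cat("  tag layout: primer5 | R1 | acid | acyl-position | primer3 (",
      nchar(x$primer5) + 3L * x$codon_length + nchar(x$primer3),
      " nt)\n", sep = "")
  invisible(x)
}

#' Enumerate the combinatorial DEL
#'
#' Expands the full split-pool library: every cycle-1 amino acid crossed with
#' every cycle-2 acid, acylated at either the secondary amine (R2, via Fmoc
#' deprotection) or the primary amine (R3, via azide reduction), on either hub
#' diastereomer (S or R). With the default 96 x 192 scheme this yields 73,728
#' compounds. Because hub stereochemistry is not encoded, the library carries
#' only 96 x 192 x 2 = 36,864 distinct DNA tags: diastereomer pairs share one.
#'
#' @param scheme a `del_scheme`.
#' @return data frame with one row per library member: `r1_index` (0-based),
#'   `acid_index` (0-based), `acyl` (`"R2"`/`"R3"`), `stereo` (`"S"`/`"R"`),
#'   `compound_id` and the tag-level key `tag_id` (shared by diastereomers).
#' @examples
#' sc <- del_scheme(n_r1 = 2, n_acid = 3, codon_length = 5)
#' nrow(enumerate_del(sc))  # 2 * 3 * 2 * 2 = 24
#' @export
enumerate_del <- function(scheme) {
  stopifnot(inherits(scheme, "del_scheme"))
  g <- expand.grid(
    stereo = c("S", "R"),
    acyl = c("R2", "R3"),
    acid_index = seq_along(scheme$codons$acid) - 1L,
    r1_index = seq_along(scheme$codons$r1) - 1L,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  g <- g[, c("r1_index", "acid_index", "acyl", "stereo")]
  g$tag_id <- sprintf("T%03d-%03d-%s", g$r1_index, g$acid_index, g$acyl)
  g$compound_id <- sprintf("%s-%s", sub("^T", "C", g$tag_id), g$stereo)
  rownames(g) <- NULL
  g
}

#' Encode library members as DNA tags
#'
#' Assembles the barcode `primer5 + codon(r1) + codon(acid) + codon(acyl) +
#' primer3` for one or more members. Hub stereochemistry does not enter the
#' tag, so S/R diastereomers encode identically.
#'
#' @param member data frame (or single-row list) with `r1_index`, `acid_index`
#'   and `acyl` columns, as produced by [enumerate_del()].
#' @param scheme a `del_scheme`.
#' @return character vector of DNA tags, one per row of `member`.
#' @export
encode_member <- function(member, scheme) {
  member <- as.data.frame(member)
  r1 <- member$r1_index
  ac <- member$acid_index
  if (any(r1 < 0L | r1 >= length(scheme$codons$r1)))
    stop("r1_index out of range")
  if (any(ac < 0L | ac >= length(scheme$codons$acid)))
    stop("acid_index out of range")
  if (!all(member$acyl %in% c("R2", "R3"))) stop("acyl must be 'R2' or 'R3'")
  paste0(scheme$primer5,
         scheme$codons$r1[r1 + 1L],
         scheme$codons$acid[ac + 1L],
         scheme$codons$acyl[member$acyl],
         scheme$primer3)
}

#' Fingerprint a DEL member
#'
#' `BLOCK_ONEHOT` mode sets one bit for each of the member's four synthetic
#' choices (cycle-1 block, cycle-2 block, acylation position, hub
#' stereochemistry) over a fixed-length bit space; it requires no chemical
#' structures and is the default used for hit clustering. `STRUCTURE` mode
#' delegates to a caller-supplied function mapping an assembled structure to a
#' bit set (e.g. a circular-substructure fingerprint), and errors when no such
#' function or no structures are available.
#'
#' @param member single-row data frame or list with `r1_index`, `acid_index`,
#'   `acyl` and optionally `stereo` (default `"S"`).
#' @param scheme a `del_scheme` (defines the bit-space dimensions).
#' @param mode `"BLOCK_ONEHOT"` or `"STRUCTURE"`.
#' @param structure_fp a function(member) returning sorted integer bit
#'   positions, required in `STRUCTURE` mode.
#' @return object of class `fingerprint`: list with integer `bits` (set
#'   positions, sorted) and `length` (bit-space size).
#' @export
fingerprint <- function(member, scheme, mode = c("BLOCK_ONEHOT", "STRUCTURE"),
                        structure_fp = NULL) {
  mode <- match.arg(mode)
  if (mode == "STRUCTURE") {
    if (is.null(structure_fp))
      stop("STRUCTURE fingerprints need a structure_fp function ",
           "(no building-block structures are bundled)")
    bits <- sort(unique(as.integer(structure_fp(member))))
    return(structure(list(bits = bits, length = max(bits, 1024L)),
                     class = "fingerprint"))
  }
  n_r1 <- length(scheme$codons$r1)
  n_ac <- length(scheme$codons$acid)
  stereo <- if (is.null(member$stereo)) "S" else member$stereo
  bits <- c(
    1L + member$r1_index,
    n_r1 + 1L + member$acid_index,
    n_r1 + n_ac + match(member$acyl, c("R2", "R3")),
    n_r1 + n_ac + 2L + match(stereo, c("S", "R"))
  )
  structure(list(bits = sort(as.integer(bits)),
                 length = n_r1 + n_ac + 4L),
            class = "fingerprint")
}

#' Tanimoto similarity of two fingerprints
#'
#' Jaccard coefficient of the set bits, `|a & b| / |a | b|`. Symmetric,
#' bounded in `[0, 1]`, equal to 1 exactly for identical non-empty sets;
#' defined as 0 when both sets are empty.
#'
#' @param a,b `fingerprint` objects of equal bit-space length.
#' @return similarity in `[0, 1]`.
#' @examples
#' f <- function(bits) structure(list(bits = bits, length = 8L),
#'                               class = "fingerprint")
#' tanimoto(f(c(1L, 2L, 3L)), f(c(2L, 3L, 4L)))  # 0.5
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$length != b$length) stop("fingerprint length mismatch")
  ni <- length(intersect(a$bits, b$bits))
  nu <- length(union(a$bits, b$bits))
  if (nu == 0L) return(0)
  ni / nu
}

#' Read a building-block table
#'
#' TSV with columns `cycle` (`AMINO_ACID`/`ACID`), `index` (0-based), `name`,
#' optional `smiles`, and `codon`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_building_blocks <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("cycle", "index", "name", "codon")
  if (!all(need %in% names(df)))
    stop("building-block table needs columns: ", paste(need, collapse = ", "))
  df
}

#' Write / read an encoding-scheme JSON config
#'
#' The config stores the primers, codon geometry and the seed; codon tables
#' are regenerated deterministically from the seed on read, so the JSON stays
#' small and the scheme reproducible.
#'
#' @param scheme a `del_scheme`.
#' @param path file path.
#' @return `read_scheme` returns a `del_scheme`.
#' @export
write_scheme <- function(scheme, path) {
  cfg <- list(primer5 = scheme$primer5, primer3 = scheme$primer3,
              codon_length = scheme$codon_length,
              min_hamming = scheme$min_hamming,
              n_r1 = length(scheme$codons$r1),
              n_acid = length(scheme$codons$acid),
              seed = scheme$seed)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_scheme
#' @export
read_scheme <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  del_scheme(n_r1 = cfg$n_r1, n_acid = cfg$n_acid,
             codon_length = cfg$codon_length, min_hamming = cfg$min_hamming,
             primer5 = cfg$primer5, primer3 = cfg$primer3, seed = cfg$seed)
}
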