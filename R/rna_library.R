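RNA_BASES <- c("A", "C", "G", "U")

rna_revcomp <- function(x) {
  chartr("ACGU", "UGCA",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

rna_rev <- function(x) {
  vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
         character(1), USE.NAMES = FALSE)
}

## Watson-Crick + GU wobble
can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
}

#' Canonical internal-loop motif notation
#'
#' A 3x3 window is written `5'XXX/3'YYY`: the top strand 5'->3' over the
#' bottom strand 3'->5', aligned column by column. Closing base pairs may sit
#' inside the window, e.g. `5'GAG/3'CCC` is a 1x1 A-across-C loop closed by
#' two G:C pairs. `canonical_motif` builds the string; `parse_motif` inverts
#' it.
#'
#' @param top,bottom 3-mers (top 5'->3', bottom 3'->5').
#' @param motif canonical string.
#' @return `canonical_motif`: character; `parse_motif`: list with `top` and
#'   `bottom`.
#' @examples
#' canonical_motif("GAG", "CCC")
#' parse_motif("5'GAG/3'CCC")$bottom
#' @export
canonical_motif <- function(top, bottom) {
  sprintf("5'%s/3'%s", top, bottom)
}

#' @rdname canonical_motif
#' @export
parse_motif <- function(motif) {
  m <- regmatches(motif, regexec("^5'([ACGU]+)/3'([ACGU]+)$", motif))[[1]]
  if (length(m) != 3L) stop("malformed motif string: ", motif)
  list(top = m[2], bottom = m[3])
}

#' Enumerate the 3x3 internal-loop library
#'
#' All `4^6 = 4096` assignments of the six randomized nucleotides: a top
#' 3-mer (5'->3') over a bottom 3-mer (3'->5'). Each member is one RNA 3D
#' fold candidate displayed by the selection library.
#'
#' @return data frame with columns `top3`, `bottom3`, `motif` (canonical
#'   string), 4096 rows.
#' @export
enumerate_ill <- function() {
  g <- expand.grid(p6 = RNA_BASES, p5 = RNA_BASES, p4 = RNA_BASES,
                   p3 = RNA_BASES, p2 = RNA_BASES, p1 = RNA_BASES,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  top3 <- paste0(g$p1, g$p2, g$p3)
  bottom3 <- paste0(g$p4, g$p5, g$p6)
  data.frame(top3 = top3, bottom3 = bottom3,
             motif = canonical_motif(top3, bottom3),
             stringsAsFactors = FALSE)
}

#' Default hairpin cassette for the 3x3 library
#'
#' A documented synthetic scaffold: 12-nt single-stranded tails carrying
#' primer binding sites, 6-bp GC-rich stems flanking the randomized window,
#' and a UUCG apical tetraloop. The true selection cassette can be dropped in
#' by overriding these fields.
#'
#' @return list with `tail5`, `stem_outer`, `stem_inner` (top-strand 5'->3';
#'   partners are their reverse complements), `apical`, `tail3`.
#' @export
ill_scaffold <- function() {
  list(tail5 = "GGAAUCGUCACA",
       stem_outer = "GGCAGC",
       stem_inner = "GCGGAC",
       apical = "UUCG",
       tail3 = "ACUAGUCCAAGG")
}

#' Build a hairpin construct displaying a 3x3 window
#'
#' Embeds the member's six variable nucleotides into the unimolecular hairpin
#' cassette. Reading the sequence 5'->3', the top 3-mer appears on the
#' ascending strand and the bottom 3-mer (stored 3'->5') appears reversed on
#' the descending strand. The default structure annotation pairs the scaffold
#' stems and leaves tails, apical loop and the 3x3 window unpaired.
#'
#' @param member one-row data frame or list with `top3` and `bottom3`.
#' @param scaffold scaffold config, see [ill_scaffold()].
#' @return object of class `hairpin`: list with `sequence` and `dotbracket`
#'   plus the 1-based variable-window offsets `top_at` and `bottom_at`.
#' @export
build_hairpin <- function(member, scaffold = ill_scaffold()) {
  need <- c("tail5", "stem_outer", "stem_inner", "apical", "tail3")
  if (!all(need %in% names(scaffold)))
    stop("malformed scaffold: needs ", paste(need, collapse = ", "))
  top3 <- member$top3
  bottom3 <- member$bottom3
  stopifnot(nchar(top3) == 3L, nchar(bottom3) == 3L)
  seq_parts <- c(scaffold$tail5, scaffold$stem_outer, top3,
                 scaffold$stem_inner, scaffold$apical,
                 rna_revcomp(scaffold$stem_inner), rna_rev(bottom3),
                 rna_revcomp(scaffold$stem_outer), scaffold$tail3)
  db_parts <- c(strrep(".", nchar(scaffold$tail5)),
                strrep("(", nchar(scaffold$stem_outer)), "...",
                strrep("(", nchar(scaffold$stem_inner)),
                strrep(".", nchar(scaffold$apical)),
                strrep(")", nchar(scaffold$stem_inner)), "...",
                strrep(")", nchar(scaffold$stem_outer)),
                strrep(".", nchar(scaffold$tail3)))
  top_at <- nchar(scaffold$tail5) + nchar(scaffold$stem_outer) + 1L
  bottom_at <- sum(nchar(c(scaffold$tail5, scaffold$stem_outer, top3,
                           scaffold$stem_inner, scaffold$apical,
                           scaffold$stem_inner))) + 1L
  hairpin(paste(seq_parts, collapse = ""), paste(db_parts, collapse = ""),
          top_at = top_at, bottom_at = bottom_at)
}

#' Hairpin structure container
#'
#' @param sequence RNA string.
#' @param dotbracket balanced dot-bracket structure of the same length.
#' @param ... extra fields stored on the object.
#' @return object of class `hairpin`.
#' @export
hairpin <- function(sequence, dotbracket, ...) {
  if (nchar(sequence) != nchar(dotbracket))
    stop("sequence and structure lengths differ")
  pair_table(dotbracket)  # validates balance/nesting
  structure(list(sequence = sequence, dotbracket = dotbracket, ...),
            class = "hairpin")
}

#' @export
print.hairpin <- function(x, ...) {
  cat(x$sequence, "\n", x$dotbracket, "\n", sep = "")
  invisible(x)
}

#' Pair table of a dot-bracket structure
#'
#' @param dotbracket structure string using `(`, `)` and `.`.
#' @return integer vector `pt` with `pt[i]` the partner of position `i`
#'   (0 if unpaired). Errors on unbalanced brackets; plain round-bracket
#'   notation cannot express pseudoknots, so a balanced string is nested.
#' @export
pair_table <- function(dotbracket) {
  ch <- strsplit(dotbracket, "")[[1]]
  if (!all(ch %in% c("(", ")", ".")))
    stop("structure may only contain '(', ')' and '.'")
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced structure: unmatched ')'")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j
      pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced structure: unmatched '('")
  pt
}

#' Extract internal loops from a hairpin structure
#'
#' Walks every base pair `(i, j)` of the nested structure and reports an
#' internal loop wherever exactly one base pair `(i', j')` lies immediately
#' inside with `a = i' - i - 1` unpaired nucleotides on the top strand,
#' `b = j - j' - 1` on the bottom strand, and `a + b >= 1`. Bulge loops
#' (`a = 0` or `b = 0`) are reported with `bulge = TRUE`; they are excluded
#' from 3x3 windowing by default since the library pattern is an internal
#' loop. Closing pairs may be Watson-Crick or GU.
#'
#' @param h a `hairpin` (or list with `sequence` and `dotbracket`).
#' @return list of `loop_motif` objects: each has `top` and `bottom` strings
#'   (loop nucleotides only; bottom written 3'->5'), closing-pair characters,
#'   coordinates `i, i2, j2, j` (outer pair `i:j`, inner pair `i2:j2`),
#'   loop sizes `a`, `b`, and `bulge` flag.
#' @export
extract_internal_loops <- function(h) {
  pt <- pair_table(h$dotbracket)
  s <- strsplit(h$sequence, "")[[1]]
  loops <- list()
  for (i in seq_along(pt)) {
    j <- pt[i]
    if (j <= i) next                      # only opening side
    # first paired position strictly inside (i, j)
    inner <- i + 1L
    while (inner < j && pt[inner] == 0L) inner <- inner + 1L
    if (inner >= j) next                  # hairpin loop
    i2 <- inner
    j2 <- pt[i2]
    if (j2 > j || j2 < i2) next           # defensive; nested => j2 in (i2, j)
    # bottom-side gap must be unpaired for an internal loop
    if (j2 + 1L <= j - 1L && any(pt[(j2 + 1L):(j - 1L)] != 0L)) next
    a <- i2 - i - 1L
    b <- j - j2 - 1L
    if (a + b < 1L) next                  # stacked pair
    top <- if (a > 0L) paste(s[(i + 1L):(i2 - 1L)], collapse = "") else ""
    bottom <- if (b > 0L) paste(rev(s[(j2 + 1L):(j - 1L)]), collapse = "")
              else ""
    loops[[length(loops) + 1L]] <- structure(list(
      top = top, bottom = bottom,
      close_outer = c(s[i], s[j]), close_inner = c(s[i2], s[j2]),
      i = i, i2 = i2, j2 = j2, j = j,
      a = a, b = b, bulge = (a == 0L || b == 0L)
    ), class = "loop_motif")
  }
  loops
}

#' All 3x3 windows containing an internal loop
#'
#' The library's selected "motifs" are aligned 3+3 windows that may contain
#' closing base pairs, so sub-3x3 loops must be padded out to the window
#' before matching. Padding proceeds in aligned base-pair columns drawn from
#' the loop's closing pairs: a symmetric `a x a` loop needs `3 - a` pad
#' pairs, split as evenly as possible between the two sides -- a 3x3 loop is
#' its own singleton window, a 2x2 loop yields the two one-sided pad choices,
#' a 1x1 loop the unique pad-one-pair-each-side window. Because pads are base
#' pairs (one nucleotide on each strand), asymmetric loops (`a != b`) cannot
#' be written as an aligned 3x3 window and yield an empty set, as do bulges.
#'
#' @param loop a `loop_motif` from [extract_internal_loops()].
#' @return character vector of canonical `5'XXX/3'YYY` window strings
#'   (possibly empty).
#' @export
window_3x3 <- function(loop) {
  if (loop$a > 3L || loop$b > 3L)
    stop("loop larger than 3x3 cannot be windowed")
  if (loop$bulge || loop$a != loop$b) return(character(0))
  a <- loop$a
  p <- 3L - a
  splits <- if (p == 0L) list(c(0L, 0L))
            else if (p == 1L) list(c(1L, 0L), c(0L, 1L))
            else list(c(1L, 1L))
  out <- character(0)
  for (sp in splits) {
    l <- sp[1]; r <- sp[2]
    top <- paste0(if (l) loop$close_outer[1] else "", loop$top,
                  if (r) loop$close_inner[1] else "")
    bottom <- paste0(if (l) loop$close_outer[2] else "", loop$bottom,
                     if (r) loop$close_inner[2] else "")
    out <- c(out, canonical_motif(top, bottom))
  }
  unique(out)
}

#' Nussinov base-pair-maximizing fold
#'
#' Dynamic-programming fold maximizing the number of nested Watson-Crick or
#' GU pairs, with a minimum hairpin-loop size. The traceback is
#' deterministic: at each interval the 5' base pairs with the leftmost
#' partner achieving the optimum, and pairing is preferred over leaving the
#' base unpaired. Intended for annotating synthetic constructs when no
#' structure is supplied; it is not a thermodynamic model.
#'
#' @param sequence RNA string.
#' @param min_hairpin minimum number of unpaired nucleotides in a hairpin
#'   loop.
#' @return dot-bracket string of the same length.
#' @export
nussinov_fold <- function(sequence, min_hairpin = 3L) {
  s <- strsplit(toupper(sequence), "")[[1]]
  if (!all(s %in% RNA_BASES)) stop("sequence must be RNA over A/C/G/U")
  n <- length(s)
  if (n == 0L) return("")
  N <- matrix(0L, n, n)
  k_range <- function(i, j) {
    lo <- i + min_hairpin + 1L
    if (lo > j) integer(0) else lo:j
  }
  for (span in seq_len(n - 1L)) {
    for (i in seq_len(n - span)) {
      j <- i + span
      best <- N[i + 1L, j]              # i left unpaired
      for (k in k_range(i, j)) {
        if (!can_pair(s[i], s[k])) next
        inner <- if (i + 1L <= k - 1L) N[i + 1L, k - 1L] else 0L
        rest <- if (k + 1L <= j) N[k + 1L, j] else 0L
        cand <- 1L + inner + rest
        if (cand > best) best <- cand
      }
      N[i, j] <- best
    }
  }
  db <- rep(".", n)
  trace <- function(i, j) {
    while (i < j) {
      target <- N[i, j]
      paired <- FALSE
      for (k in k_range(i, j)) {
        if (!can_pair(s[i], s[k])) next
        inner <- if (i + 1L <= k - 1L) N[i + 1L, k - 1L] else 0L
        rest <- if (k + 1L <= j) N[k + 1L, j] else 0L
        if (1L + inner + rest == target) {
          db[i] <<- "("
          db[k] <<- ")"
          if (i + 1L <= k - 1L) trace(i + 1L, k - 1L)
          i <- k + 1L
          paired <- TRUE
          break
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  trace(1L, n)
  paste(db, collapse = "")
}

#' Read / write Vienna dot-bracket files
#'
#' Plain-text records: a `>name` header line, the sequence line, and the
#' structure line.
#'
#' @param path file path.
#' @param hairpins named list of `hairpin` objects (names become headers).
#' @return `read_vienna` returns a named list of `hairpin` objects.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no '>' records in ", path)
  out <- list()
  for (s in starts) {
    if (s + 2L > length(lines)) stop("truncated Vienna record at line ", s)
    id <- sub("^>\\s*", "", lines[s])
    id <- sub("\\s.*$", "", id)
    out[[id]] <- hairpin(lines[s + 1L], lines[s + 2L])
  }
  out
}

#' @rdname read_vienna
#' @export
write_vienna <- function(hairpins, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(hairpins)) {
    writeLines(c(paste0(">", id), hairpins[[id]]$sequence,
                 hairpins[[id]]$dotbracket), con)
  }
  invisible(path)
}
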