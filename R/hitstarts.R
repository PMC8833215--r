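#' Pooled two-proportion enrichment statistic
#'
#' Compares a motif's frequency in the selected pool with its frequency in
#' the starting library by a pooled two-proportion z statistic:
#' `p_hat = (x_sel + x_lib) / (n_sel + n_lib)` and
#' `z = (x_sel/n_sel - x_lib/n_lib) / sqrt(p_hat (1 - p_hat) (1/n_sel + 1/n_lib))`.
#' Its square is the one-degree-of-freedom chi-square statistic of the 2x2
#' table without continuity correction. Returns 0 when the pooled proportion
#' is degenerate (0 or 1). An unpooled-variance variant
#' (`pooled = FALSE`) is provided for sensitivity analysis.
#'
#' @param x_sel,n_sel motif count and total reads in the selected pool.
#' @param x_lib,n_lib motif count and total reads in the starting library.
#' @param pooled use the pooled variance estimate (default) or per-pool
#'   variances.
#' @return numeric z values (vectorized); positive when the motif is enriched
#'   in the selection.
#' @examples
#' z_obs(30, 1000, 10, 1000)  # ~ 3.19
#' @export
z_obs <- function(x_sel, n_sel, x_lib, n_lib, pooled = TRUE) {
  if (any(n_sel <= 0) || any(n_lib <= 0)) stop("pool totals must be positive")
  p1 <- x_sel / n_sel
  p2 <- x_lib / n_lib
  if (pooled) {
    ph <- (x_sel + x_lib) / (n_sel + n_lib)
    se <- sqrt(ph * (1 - ph) * (1 / n_sel + 1 / n_lib))
  } else {
    se <- sqrt(p1 * (1 - p1) / n_sel + p2 * (1 - p2) / n_lib)
  }
  z <- (p1 - p2) / se
  z[!is.finite(z)] <- 0
  z
}

#' Call privileged RNA folds from selection counts
#'
#' Computes the enrichment statistic for every (motif, compound, dose) row
#' and flags motifs with `z_obs > cutoff` as privileged -- the statistically
#' preferred RNA 3D folds of a compound. Per-dose results are always
#' returned; a compound's privileged set combines doses by union (default)
#' or can be restricted per dose downstream.
#'
#' @param counts data frame with columns `motif`, `x_sel`, `n_sel`, `x_lib`,
#'   `n_lib` and optionally `compound` and `dose` (defaulted when absent).
#' @param cutoff privileged threshold on `z_obs` (strict `>`).
#' @param pooled passed to [z_obs()].
#' @return data frame (class `enrichment_result`) with the input columns plus
#'   `p_sel`, `p_lib`, `z_obs`, `privileged`.
#' @export
call_privileged <- function(counts, cutoff = 4, pooled = TRUE) {
  need <- c("motif", "x_sel", "n_sel", "x_lib", "n_lib")
  if (!all(need %in% names(counts)))
    stop("counts needs columns: ", paste(need, collapse = ", "))
  out <- as.data.frame(counts)
  if (is.null(out$compound)) out$compound <- "c1"
  if (is.null(out$dose)) out$dose <- 1
  out$p_sel <- out$x_sel / out$n_sel
  out$p_lib <- out$x_lib / out$n_lib
  out$z_obs <- z_obs(out$x_sel, out$n_sel, out$x_lib, out$n_lib,
                     pooled = pooled)
  out$privileged <- out$z_obs > cutoff
  attr(out, "cutoff") <- cutoff
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Per-compound privileged motif sets
#'
#' @param results an `enrichment_result` from [call_privileged()].
#' @param combine `"union"` (privileged at any dose) or `"per_dose"` (a list
#'   per compound and dose).
#' @return named list of character vectors of motifs.
#' @export
privileged_sets <- function(results, combine = c("union", "per_dose")) {
  combine <- match.arg(combine)
  priv <- results[results$privileged, , drop = FALSE]
  key <- if (combine == "union") priv$compound
         else paste(priv$compound, priv$dose, sep = "@")
  lapply(split(priv$motif, key), function(m) sort(unique(m)))
}

#' Summary of privileged folds across compounds
#'
#' Descriptive summary mirroring the screen's headline numbers: per-compound
#' privileged-fold counts, their mean, standard deviation and range, the size
#' of the union over compounds, and per-compound counts of uniquely bound
#' motifs (privileged for exactly one compound).
#'
#' @param results an `enrichment_result`, or a named list of per-compound
#'   privileged motif vectors.
#' @return list with `per_compound`, `mean`, `sd` (0 for a single compound),
#'   `range`, `union_size`, `unique_per_compound`.
#' @export
compound_fold_summary <- function(results) {
  sets <- if (inherits(results, "enrichment_result")) {
    all_compounds <- unique(results$compound)
    s <- privileged_sets(results)
    missing <- setdiff(all_compounds, names(s))
    s[missing] <- replicate(length(missing), character(0), simplify = FALSE)
    s[all_compounds]
  } else results
  counts <- vapply(sets, length, integer(1))
  all_motifs <- unlist(sets, use.names = FALSE)
  tab <- table(all_motifs)
  uniq <- vapply(sets, function(m) sum(tab[m] == 1L), integer(1))
  list(per_compound = counts,
       mean = mean(counts),
       sd = if (length(counts) > 1L) stats::sd(counts) else 0,
       range = if (length(counts)) range(counts) else c(NA, NA),
       union_size = length(unique(all_motifs)),
       unique_per_compound = uniq)
}

#' Position-wise nucleotide profile and information content
#'
#' Builds the 4 x 6 frequency matrix of the six randomized positions over a
#' set of selected motifs (optionally weighted, e.g. by `z_obs`) and the
#' per-position information content in bits, `2 - H_i` with
#' `H_i = -sum_b f_ib log2 f_ib`. The small-sample correction
#' `e_n = 3 / (2 ln(2) n)` can be subtracted (floored at 0); it is off by
#' default.
#'
#' @param motifs character vector of canonical `5'XXX/3'YYY` strings or bare
#'   6-mers over A/C/G/U (top 3-mer followed by the bottom 3-mer, 3'->5').
#' @param weights optional non-negative weights, one per motif.
#' @param small_sample_correction subtract the `e_n` correction from the
#'   information content.
#' @return object of class `position_profile`: list with `freq` (4 x 6
#'   matrix, columns summing to 1), `bits` (length 6), `n_eff` (motif count).
#' @export
position_profile <- function(motifs, weights = NULL,
                             small_sample_correction = FALSE) {
  if (!length(motifs)) stop("empty motif set")
  mers <- vapply(motifs, function(m) {
    if (grepl("^5'", m)) {
      p <- parse_motif(m)
      paste0(p$top, p$bottom)
    } else m
  }, character(1), USE.NAMES = FALSE)
  if (!all(nchar(mers) == 6L) || !all(grepl("^[ACGU]{6}$", mers)))
    stop("motifs must be 6-mers over A/C/G/U")
  if (is.null(weights)) weights <- rep(1, length(mers))
  if (length(weights) != length(mers) || any(weights < 0))
    stop("weights must be non-negative, one per motif")
  m <- do.call(rbind, strsplit(mers, ""))
  freq <- matrix(0, 4L, 6L, dimnames = list(RNA_BASES, NULL))
  for (p in 1:6) {
    w <- tapply(weights, factor(m[, p], levels = RNA_BASES), sum)
    w[is.na(w)] <- 0
    freq[, p] <- w / sum(w)
  }
  H <- apply(freq, 2L, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  bits <- 2 - H
  if (small_sample_correction) {
    en <- 3 / (2 * log(2) * length(mers))
    bits <- pmax(bits - en, 0)
  }
  structure(list(freq = freq, bits = bits, n_eff = length(mers)),
            class = "position_profile")
}

#' @export
print.position_profile <- function(x, digits = 3, ...) {
  cat("Position profile over", x$n_eff, "motifs\n")
  print(round(x$freq, digits))
  cat("bits:", paste(round(x$bits, digits), collapse = " "), "\n")
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.position_profile <- function(x, ...) {
  graphics::barplot(x$bits, names.arg = seq_along(x$bits),
                    ylim = c(0, 2), xlab = "window position",
                    ylab = "information (bits)", ...)
  invisible(x)
}

#' Per-position divergence between two profiles (difference logo)
#'
#' Jensen-Shannon divergence (base 2) between the corresponding frequency
#' columns of two position profiles. Zero iff the columns are identical,
#' symmetric, bounded above by 1 bit; point masses on different nucleotides
#' attain the bound. Used to compare the RNA-fold preferences of, e.g., two
#' hub diastereomers of the same compound.
#'
#' @param a,b `position_profile` objects of equal dimensions.
#' @return numeric vector of per-position divergences (bits).
#' @export
diff_profile <- function(a, b) {
  stopifnot(inherits(a, "position_profile"), inherits(b, "position_profile"))
  if (!all(dim(a$freq) == dim(b$freq))) stop("profile dimension mismatch")
  kl <- function(p, q) {
    i <- p > 0
    sum(p[i] * log2(p[i] / q[i]))
  }
  vapply(seq_len(ncol(a$freq)), function(j) {
    p <- a$freq[, j]
    q <- b$freq[, j]
    m <- (p + q) / 2
    0.5 * kl(p, m) + 0.5 * kl(q, m)
  }, numeric(1))
}

#' Read / write selection-count tables
#'
#' TSV with columns `motif`, `compound`, `dose`, `x_sel`, `n_sel`, `x_lib`,
#' `n_lib`; `#`-prefixed header lines are ignored.
#'
#' @param path file path.
#' @param counts data frame in the same layout.
#' @param config optional list serialized into a `# config:` header.
#' @return `read_selection_counts` returns the data frame.
#' @export
read_selection_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' @rdname read_selection_counts
#' @export
write_selection_counts <- function(counts, path, config = NULL) {
  write_tsv_with_config(counts, path, config)
}
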