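# Encode residues as integers 1..4 for A,C,G,T; NA for anything that does
# not resolve to a single base (ambiguity codes and gaps). Pairwise deletion
# then reduces to dropping NA positions.
.encode_determinate <- function(chars) {
  out <- match(chars, c("A", "C", "G", "T"))
  dim(out) <- dim(chars)
  dimnames(out) <- dimnames(chars)
  out
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Computes the proportion of differing sites between two equal-length
#' aligned sequences under pairwise deletion: any column where either
#' sequence carries a gap or an IUPAC ambiguity code (anything that does
#' not resolve to exactly one base) is excluded from that comparison, and
#' `p` is the fraction of the retained columns at which the two bases
#' differ. Ambiguity codes here typically stand for electropherogram double
#' peaks, so affected comparisons are ignored rather than guessed at.
#'
#' @param seq_a,seq_b Aligned sequences: single strings or character
#'   vectors of equal length.
#' @return A list of class `pairwise_p` with `p` (proportion of differing
#'   retained sites; `NA` when no site is comparable), `n_compared`
#'   (retained columns) and `n_diff` (mismatch count).
#' @examples
#' pairwise_p("ACGT", "ACGA")  # p = 0.25 over 4 sites
#' pairwise_p("ACNT", "ACGT")  # N column dropped: p = 0 over 3 sites
#' @export
pairwise_p <- function(seq_a, seq_b) {
  a <- if (length(seq_a) == 1L) strsplit(seq_a, "", fixed = TRUE)[[1L]] else seq_a
  b <- if (length(seq_b) == 1L) strsplit(seq_b, "", fixed = TRUE)[[1L]] else seq_b
  if (length(a) != length(b)) {
    stop(sprintf("sequence length mismatch: %d vs %d", length(a), length(b)),
         call. = FALSE)
  }
  ea <- .encode_determinate(.normalise_chars(a))
  eb <- .encode_determinate(.normalise_chars(b))
  ok <- !is.na(ea) & !is.na(eb)
  n <- sum(ok)
  d <- if (n) sum(ea[ok] != eb[ok]) else 0L
  structure(list(p = if (n) d / n else NA_real_,
                 n_compared = n, n_diff = d),
            class = "pairwise_p")
}

#' Pairwise p-distance matrix for a locus
#'
#' Computes all pairwise uncorrected p-distances (pairwise deletion, see
#' [pairwise_p()]) among the sequences of one locus.
#'
#' @param locus An [aligned_locus()] with at least two sequences.
#' @return An object of class `p_distmat` with `locus_name`,
#'   `specimen_ids`, `p` (symmetric numeric matrix, zero diagonal, `NA`
#'   where no column was comparable) and `n_compared` (integer matrix of
#'   retained column counts per pair).
#' @export
distance_matrix <- function(locus) {
  stopifnot(inherits(locus, "aligned_locus"))
  n <- nrow(locus$seqs)
  if (n < 2L) stop("distance_matrix needs at least 2 sequences", call. = FALSE)
  enc <- .encode_determinate(locus$seqs)
  ids <- rownames(locus$seqs)
  p <- matrix(0, n, n, dimnames = list(ids, ids))
  nc <- matrix(0L, n, n, dimnames = list(ids, ids))
  det <- !is.na(enc)
  diag(nc) <- as.integer(rowSums(det))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- det[i, ] & det[j, ]
      m <- sum(ok)
      nc[i, j] <- nc[j, i] <- m
      p[i, j] <- p[j, i] <-
        if (m) sum(enc[i, ok] != enc[j, ok]) / m else NA_real_
    }
  }
  structure(list(locus_name = locus$locus_name, specimen_ids = ids,
                 p = p, n_compared = nc),
            class = "p_distmat")
}

#' @export
print.p_distmat <- function(x, ...) {
  cat(sprintf("<p_distmat> %s: %d specimens, %d pairs (%d undefined)\n",
              x$locus_name, length(x$specimen_ids),
              choose(length(x$specimen_ids), 2),
              sum(is.na(x$p[upper.tri(x$p)]))))
  invisible(x)
}

# ids of matrix members belonging to a group
.group_members <- function(matrix, specimens, group) {
  g <- specimens$group[match(matrix$specimen_ids, specimens$specimen_id)]
  matrix$specimen_ids[!is.na(g) & g == group]
}

#' Mean and SD of p-distances between (or within) groups
#'
#' Summarises the pairwise distances over all specimen pairs spanning two
#' groups, or over all within-group pairs when `group_a == group_b`.
#' Undefined pairs (no comparable column) are skipped and counted.
#'
#' @param matrix A `p_distmat` from [distance_matrix()].
#' @param specimens A `specimen_table` supplying group labels.
#' @param group_a,group_b Group keys; equal keys request the within-group
#'   summary.
#' @param sd_estimator `"sample"` (n-1 denominator, the default) or
#'   `"population"` (n denominator).
#' @return One-row data frame with `locus`, `group_a`, `group_b`, `type`
#'   (`"within"`/`"between"`), `mean_p`, `sd_p`, `n_pairs` (size of the
#'   defined pair set) and `n_undefined` (skipped pairs).
#' @export
group_summary <- function(matrix, specimens, group_a, group_b,
                          sd_estimator = c("sample", "population")) {
  stopifnot(inherits(matrix, "p_distmat"))
  sd_estimator <- match.arg(sd_estimator)
  ia <- .group_members(matrix, specimens, group_a)
  ib <- .group_members(matrix, specimens, group_b)
  within <- identical(group_a, group_b)
  if (within) {
    if (length(ia) < 2L) {
      stop(sprintf("within-group summary for '%s' needs >= 2 members", group_a),
           call. = FALSE)
    }
    pairs <- t(utils::combn(ia, 2L))
  } else {
    if (!length(ia) || !length(ib)) {
      stop(sprintf("empty pair set for '%s' vs '%s'", group_a, group_b),
           call. = FALSE)
    }
    pairs <- as.matrix(expand.grid(ia, ib, stringsAsFactors = FALSE))
  }
  vals <- matrix$p[cbind(pairs[, 1L], pairs[, 2L])]
  defined <- vals[!is.na(vals)]
  if (!length(defined)) {
    stop(sprintf("no defined distances for '%s' vs '%s'", group_a, group_b),
         call. = FALSE)
  }
  m <- mean(defined)
  s <- if (length(defined) > 1L) {
    if (sd_estimator == "sample") stats::sd(defined)
    else sqrt(mean((defined - m)^2))
  } else 0
  data.frame(locus = matrix$locus_name, group_a = group_a, group_b = group_b,
             type = if (within) "within" else "between",
             mean_p = m, sd_p = s, n_pairs = nrow(pairs),
             n_undefined = sum(is.na(vals)),
             stringsAsFactors = FALSE)
}

#' All group-pair distance summaries for a dataset
#'
#' For every locus, computes the between-group summary for every unordered
#' pair of groups present at that locus and the within-group summary for
#' every group with at least two members there. Loci or group pairs that
#' cannot be summarised are skipped with a warning.
#'
#' @param dataset A `barcode_dataset` (see [build_dataset()]).
#' @param specimens Optional `specimen_table` overriding
#'   `dataset$specimens` (e.g. [species_level()] groups).
#' @param sd_estimator Passed to [group_summary()].
#' @return Data frame of summaries, one row per locus x group pair.
#' @export
all_group_summaries <- function(dataset, specimens = NULL,
                                sd_estimator = c("sample", "population")) {
  stopifnot(inherits(dataset, "barcode_dataset"))
  sd_estimator <- match.arg(sd_estimator)
  if (is.null(specimens)) specimens <- dataset$specimens
  out <- list()
  for (loc in dataset$loci) {
    if (nrow(loc$seqs) < 2L) {
      warning(sprintf("locus '%s' has < 2 sequences; skipped", loc$locus_name))
      next
    }
    dm <- distance_matrix(loc)
    g <- specimens$group[match(dm$specimen_ids, specimens$specimen_id)]
    groups <- sort(unique(g))
    if (length(groups) < 2L) {
      warning(sprintf("locus '%s' covers a single group; between-group summaries skipped",
                      loc$locus_name))
    }
    for (grp in groups) {
      if (sum(g == grp) >= 2L) {
        out[[length(out) + 1L]] <-
          group_summary(dm, specimens, grp, grp, sd_estimator)
      }
    }
    if (length(groups) >= 2L) {
      cmb <- utils::combn(groups, 2L)
      for (k in seq_len(ncol(cmb))) {
        out[[length(out) + 1L]] <-
          group_summary(dm, specimens, cmb[1L, k], cmb[2L, k], sd_estimator)
      }
    }
  }
  do.call(rbind, out)
}

#' Write a distance matrix
#'
#' Writes the pairwise distances in two plain-text forms: a square
#' PHYLIP-style matrix (`<stem>.phylip.txt`) and a long-format TSV
#' (`<stem>.pairs.tsv` with columns `specimen_i`, `specimen_j`, `p`,
#' `n_compared`).
#'
#' @param matrix A `p_distmat`.
#' @param stem Output path stem (directory must exist).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_distance_matrix <- function(matrix, stem) {
  stopifnot(inherits(matrix, "p_distmat"))
  ids <- matrix$specimen_ids
  phylip <- file.path(paste0(stem, ".phylip.txt"))
  lines <- c(sprintf("%5d", length(ids)),
             vapply(seq_along(ids), function(i) {
               paste0(formatC(ids[i], width = -12),
                      paste(sprintf("%.6f", matrix$p[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, phylip)
  pairs <- which(upper.tri(matrix$p), arr.ind = TRUE)
  long <- data.frame(specimen_i = ids[pairs[, 1L]],
                     specimen_j = ids[pairs[, 2L]],
                     p = matrix$p[pairs],
                     n_compared = matrix$n_compared[pairs],
                     stringsAsFactors = FALSE)
  long_path <- paste0(stem, ".pairs.tsv")
  utils::write.table(long, long_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(phylip, long_path))
}

#' Render group summaries as a publication-style table
#'
#' Pivots [all_group_summaries()] output into a wide table with one row per
#' group pair and one `"mean (SD)"` cell per locus.
#'
#' @param summaries Data frame from [all_group_summaries()].
#' @param digits Number of decimal places in the cells.
#' @return Data frame with a `comparison` column and one column per locus.
#' @export
summary_table <- function(summaries, digits = 5L) {
  summaries$comparison <- ifelse(
    summaries$type == "within",
    paste("within", summaries$group_a),
    paste(summaries$group_a, "VS", summaries$group_b))
  loci <- unique(summaries$locus)
  rows <- unique(summaries$comparison)
  out <- data.frame(comparison = rows, stringsAsFactors = FALSE)
  fmt <- sprintf("%%.%df (%%.%df)", digits, digits)
  for (loc in loci) {
    cells <- rep(NA_character_, length(rows))
    sub <- summaries[summaries$locus == loc, ]
    idx <- match(sub$comparison, rows)
    cells[idx] <- sprintf(fmt, sub$mean_p, sub$sd_p)
    out[[loc]] <- cells
  }
  out
}
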