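# long table of defined pairs with category labels
.pair_table <- function(matrix, specimens) {
  ids <- matrix$specimen_ids
  g <- specimens$group[match(ids, specimens$specimen_id)]
  idx <- which(upper.tri(matrix$p), arr.ind = TRUE)
  ga <- g[idx[, 1L]]
  gb <- g[idx[, 2L]]
  lo <- pmin(ga, gb)
  hi <- pmax(ga, gb)
  data.frame(
    specimen_i = ids[idx[, 1L]], specimen_j = ids[idx[, 2L]],
    group_i = ga, group_j = gb,
    category = ifelse(ga == gb, paste("within", ga), paste(lo, "VS", hi)),
    p = matrix$p[idx], stringsAsFactors = FALSE)
}

#' Mismatch distribution of pairwise distances by comparison category
#'
#' Bins the pairwise p-distances of a locus into half-open intervals
#' `[k*w, (k+1)*w)` separately for each comparison category. By default a
#' category is created for every within-group comparison and every
#' unordered between-group pair. Undefined pairs (no comparable column)
#' are dropped and counted.
#'
#' @param matrix A `p_distmat` from [distance_matrix()].
#' @param specimens A `specimen_table`.
#' @param bin_width Positive bin width (default 0.005).
#' @return An object of class `mismatch_distribution`: a data frame with
#'   columns `locus`, `category`, `bin`, `bin_lo`, `bin_hi`, `count`, plus
#'   attributes `bin_width`, `n_pairs` (named total defined pairs per
#'   category) and `n_undefined`.
#' @export
mismatch_distribution <- function(matrix, specimens, bin_width = 0.005) {
  stopifnot(inherits(matrix, "p_distmat"))
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0) {
    stop("bin_width must be a positive number", call. = FALSE)
  }
  pt <- .pair_table(matrix, specimens)
  n_undef <- sum(is.na(pt$p))
  pt <- pt[!is.na(pt$p), , drop = FALSE]
  if (!nrow(pt)) warning("no defined pairs; empty mismatch distribution")
  # small epsilon so p that lies exactly on an edge lands in the upper bin
  pt$bin <- floor(pt$p / bin_width + 1e-9)
  agg <- stats::aggregate(list(count = rep(1L, nrow(pt))),
                          by = pt[c("category", "bin")], FUN = sum)
  agg <- agg[order(agg$category, agg$bin), , drop = FALSE]
  out <- data.frame(locus = matrix$locus_name,
                    category = agg$category, bin = agg$bin,
                    bin_lo = agg$bin * bin_width,
                    bin_hi = (agg$bin + 1L) * bin_width,
                    count = agg$count, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, bin_width = bin_width,
            n_pairs = tapply(pt$p, pt$category, length),
            n_undefined = n_undef,
            class = c("mismatch_distribution", "data.frame"))
}

#' Barcoding gap between two groups
#'
#' Tests whether the smallest between-group distance exceeds the largest
#' within-group distance (pooled over both groups). A positive gap means
#' every inter-group pair is more divergent than every intra-group pair,
#' which is the condition for threshold-based identification to be safe
#' for this pair of groups. The gap is computed from the raw distances,
#' never from histogram bins.
#'
#' @param matrix A `p_distmat`.
#' @param specimens A `specimen_table`.
#' @param group_a,group_b Distinct group keys, each with at least two
#'   members in the matrix.
#' @return One-row data frame: `locus`, `group_a`, `group_b`, `max_intra`,
#'   `min_inter`, `gap_size` (`min_inter - max_intra`), `has_gap`
#'   (`gap_size > 0`), `n_intra`, `n_inter`, `n_undefined`.
#' @export
barcoding_gap <- function(matrix, specimens, group_a, group_b) {
  stopifnot(inherits(matrix, "p_distmat"))
  if (identical(group_a, group_b)) {
    stop("group_a and group_b must differ", call. = FALSE)
  }
  ia <- .group_members(matrix, specimens, group_a)
  ib <- .group_members(matrix, specimens, group_b)
  if (length(ia) < 2L || length(ib) < 2L) {
    stop(sprintf(
      "barcoding_gap needs >= 2 members per group (got %d in '%s', %d in '%s')",
      length(ia), group_a, length(ib), group_b), call. = FALSE)
  }
  intra <- c(matrix$p[t(utils::combn(ia, 2L))],
             matrix$p[t(utils::combn(ib, 2L))])
  inter <- matrix$p[as.matrix(expand.grid(ia, ib, stringsAsFactors = FALSE))]
  n_undef <- sum(is.na(intra)) + sum(is.na(inter))
  intra <- intra[!is.na(intra)]
  inter <- inter[!is.na(inter)]
  if (!length(intra) || !length(inter)) {
    stop("all distances undefined for this group pair", call. = FALSE)
  }
  gap <- min(inter) - max(intra)
  data.frame(locus = matrix$locus_name, group_a = group_a, group_b = group_b,
             max_intra = max(intra), min_inter = min(inter),
             gap_size = gap, has_gap = gap > 0,
             n_intra = length(intra), n_inter = length(inter),
             n_undefined = n_undef, stringsAsFactors = FALSE)
}

#' Barcoding gaps for every group pair at a locus
#'
#' @param matrix A `p_distmat`.
#' @param specimens A `specimen_table`.
#' @return Data frame with one [barcoding_gap()] row per unordered pair of
#'   groups having at least two members each; pairs failing that are
#'   skipped with a warning.
#' @export
all_barcoding_gaps <- function(matrix, specimens) {
  g <- specimens$group[match(matrix$specimen_ids, specimens$specimen_id)]
  tab <- table(g)
  groups <- names(tab)[tab >= 2L]
  dropped <- setdiff(names(tab), groups)
  if (length(dropped)) {
    warning(sprintf("group(s) with < 2 members skipped: %s",
                    paste(dropped, collapse = ", ")))
  }
  if (length(groups) < 2L) stop("need two groups with >= 2 members", call. = FALSE)
  cmb <- utils::combn(sort(groups), 2L)
  do.call(rbind, lapply(seq_len(ncol(cmb)), function(k) {
    barcoding_gap(matrix, specimens, cmb[1L, k], cmb[2L, k])
  }))
}

#' Write a mismatch distribution as TSV
#'
#' @param hist A `mismatch_distribution`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_mismatch_distribution <- function(hist, path) {
  utils::write.table(as.data.frame(hist), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Stacked-bar plot of a mismatch distribution
#'
#' Draws the classic mismatch-distribution figure: distance bins on the x
#' axis, pair counts stacked by comparison category.
#'
#' @param x A `mismatch_distribution`.
#' @param main Plot title (defaults to the locus name).
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the matrix of stacked counts.
#' @export
plot.mismatch_distribution <- function(x, main = NULL, ...) {
  w <- attr(x, "bin_width")
  bins <- 0:max(x$bin)
  cats <- sort(unique(x$category))
  m <- matrix(0L, length(cats), length(bins),
              dimnames = list(cats, sprintf("%.3f", bins * w)))
  m[cbind(match(x$category, cats), x$bin + 1L)] <- x$count
  cols <- grDevices::hcl.colors(length(cats), "Dark 3")
  graphics::barplot(m, col = cols, border = NA, las = 2,
                    xlab = "pairwise distance (p)", ylab = "number of pairs",
                    main = if (is.null(main)) x$locus[1L] else main, ...)
  graphics::legend("topright", legend = cats, fill = cols, bty = "n",
                   cex = 0.8)
  invisible(m)
}
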