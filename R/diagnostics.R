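#' Columns excluded for ambiguity
#'
#' A column is excluded when any sequence carries a non-ACGT, non-gap
#' character there, i.e. an IUPAC ambiguity code standing for an
#' electropherogram double peak. Gaps do not trigger exclusion: a deletion
#' is not a double peak.
#'
#' @param locus An [aligned_locus()].
#' @return Sorted integer vector of excluded (1-based) column indices.
#' @export
ambiguity_filter <- function(locus) {
  stopifnot(inherits(locus, "aligned_locus"))
  amb <- !(locus$seqs %in% c("A", "C", "G", "T", "-"))
  dim(amb) <- dim(locus$seqs)
  which(colSums(amb) > 0L)
}

#' Columns showing variation in two or more individuals
#'
#' Retains a column when at least `min_variant_carriers` sequences do not
#' carry the column's modal base (gaps are ignored when counting).
#' Singleton variation — a base seen in one individual only — is thereby
#' excluded, suppressing isolated sequencing errors. When several bases tie
#' for modal, any of them minimises the non-modal count, so the rule is
#' unambiguous; tied columns are retained whenever each state is carried by
#' at least `min_variant_carriers` individuals.
#'
#' @param locus An [aligned_locus()].
#' @param min_variant_carriers Minimum number of non-modal carriers
#'   (default 2).
#' @param exclude Column indices to skip (normally the output of
#'   [ambiguity_filter()]); set to `integer(0)` to filter all columns.
#' @return Sorted integer vector of retained column indices.
#' @export
variable_site_filter <- function(locus, min_variant_carriers = 2L,
                                 exclude = ambiguity_filter(locus)) {
  stopifnot(inherits(locus, "aligned_locus"))
  cols <- setdiff(seq_len(locus$length), exclude)
  keep <- vapply(cols, function(j) {
    col <- locus$seqs[, j]
    col <- col[.is_determinate(col)]
    if (!length(col)) return(FALSE)
    counts <- table(col)
    (length(col) - max(counts)) >= min_variant_carriers
  }, logical(1))
  cols[keep]
}

#' Classify alignment columns as diagnostic characters
#'
#' Applies the two column filters (ambiguity exclusion, then the
#' two-or-more-individuals variation filter) and classifies every retained
#' column, per group, as:
#'
#' * `PURE` — all members of the group share one base there, and that base
#'   occurs in no member of any other group (a purely diagnostic site,
#'   usable for identification);
#' * `PRIVATE` — some base occurs only in this group but is not shared by
#'   all its members;
#' * `NONE` — otherwise.
#'
#' Gaps are ignored when collecting a group's observed states; a group that
#' is all-gap at a column has an empty state set and status `NONE`.
#'
#' @param locus An [aligned_locus()] covering at least two groups.
#' @param specimens A `specimen_table` with group labels.
#' @param min_variant_carriers Passed to [variable_site_filter()].
#' @param filtered If `FALSE`, classify every column instead of only the
#'   filtered ones (exclusion counts are then zero); useful for inspecting
#'   what the filters removed.
#' @return An object of class `diag_table`: `locus_name`, `groups`,
#'   `columns` (retained 1-based indices), `status` (character matrix,
#'   columns x groups), `state_sets` (list over columns of per-group base
#'   sets), `informative` (logical per column: any group PURE or PRIVATE),
#'   `n_excluded_ambiguous`, `n_excluded_rare`.
#' @export
classify_sites <- function(locus, specimens, min_variant_carriers = 2L,
                           filtered = TRUE) {
  stopifnot(inherits(locus, "aligned_locus"),
            inherits(specimens, "specimen_table"))
  g <- specimens$group[match(rownames(locus$seqs), specimens$specimen_id)]
  if (anyNA(g)) {
    stop("locus contains specimens absent from metadata", call. = FALSE)
  }
  groups <- sort(unique(g))
  if (length(groups) < 2L) {
    stop("classify_sites needs at least two groups", call. = FALSE)
  }
  if (filtered) {
    excl_amb <- ambiguity_filter(locus)
    retained <- variable_site_filter(locus, min_variant_carriers,
                                     exclude = excl_amb)
    n_rare <- locus$length - length(excl_amb) - length(retained)
  } else {
    excl_amb <- integer(0)
    retained <- seq_len(locus$length)
    n_rare <- 0L
  }
  status <- matrix("NONE", length(retained), length(groups),
                   dimnames = list(NULL, groups))
  state_sets <- vector("list", length(retained))
  for (k in seq_along(retained)) {
    col <- locus$seqs[, retained[k]]
    sets <- lapply(groups, function(grp) {
      obs <- col[g == grp]
      sort(unique(obs[.is_determinate(obs)]))
    })
    names(sets) <- groups
    state_sets[[k]] <- sets
    for (gi in seq_along(groups)) {
      own <- sets[[gi]]
      if (!length(own)) next
      others <- unique(unlist(sets[-gi]))
      exclusive <- setdiff(own, others)
      if (length(own) == 1L && length(exclusive) == 1L) {
        status[k, gi] <- "PURE"
      } else if (length(exclusive)) {
        status[k, gi] <- "PRIVATE"
      }
    }
  }
  structure(list(
    locus_name = locus$locus_name, groups = groups,
    columns = retained, status = status, state_sets = state_sets,
    informative = apply(status != "NONE", 1L, any),
    n_excluded_ambiguous = length(excl_amb),
    n_excluded_rare = n_rare),
    class = "diag_table")
}

#' @export
print.diag_table <- function(x, ...) {
  cat(sprintf(
    "<diag_table> %s: %d retained columns (%d ambiguous, %d rare-variant excluded)\n",
    x$locus_name, length(x$columns), x$n_excluded_ambiguous, x$n_excluded_rare))
  for (grp in x$groups) {
    cat(sprintf("  %s: %d PURE, %d PRIVATE\n", grp,
                sum(x$status[, grp] == "PURE"),
                sum(x$status[, grp] == "PRIVATE")))
  }
  cat(sprintf("  non-informative columns: %d\n", sum(!x$informative)))
  invisible(x)
}

#' Count pure character differences between two groups
#'
#' Number of retained columns at which the two groups' observed state sets
#' are nonempty and disjoint — fixed, non-overlapping character
#' differences usable as diagnostics between the pair.
#'
#' @param table A `diag_table` from [classify_sites()].
#' @param group_a,group_b Group keys present in the table.
#' @return Integer count.
#' @export
count_pure_differences <- function(table, group_a, group_b) {
  stopifnot(inherits(table, "diag_table"))
  for (grp in c(group_a, group_b)) {
    if (!grp %in% table$groups) {
      stop(sprintf("unknown group '%s'", grp), call. = FALSE)
    }
  }
  sum(vapply(table$state_sets, function(sets) {
    a <- sets[[group_a]]; b <- sets[[group_b]]
    length(a) > 0L && length(b) > 0L && !length(intersect(a, b))
  }, logical(1)))
}

#' Assign a query sequence to a group from pure diagnostic sites
#'
#' Votes are cast only at columns that are `PURE` for some group: the
#' query's base there (expanded through its IUPAC states) votes for each
#' group whose pure diagnostic base it is compatible with. Characters with
#' no state (gap) or with the full four-base state set (`N`) are
#' uninformative and cast no vote. The query is assigned to the group with
#' strictly the most votes; ties or zero votes give `"UNASSIGNED"`.
#' `PRIVATE` states never vote.
#'
#' @param query Aligned query sequence (string or character vector) in the
#'   same coordinate system as the table's locus.
#' @param table A `diag_table` from [classify_sites()].
#' @param locus_length Full alignment length the table was built from,
#'   used to validate the query; defaults to the largest retained column.
#' @return List with `group` (the winning group key or `"UNASSIGNED"`) and
#'   `tally` (named integer votes per group).
#' @export
assign_specimen <- function(query, table, locus_length = NULL) {
  stopifnot(inherits(table, "diag_table"))
  q <- if (length(query) == 1L) strsplit(query, "", fixed = TRUE)[[1L]] else query
  q <- .normalise_chars(q)
  if (!is.null(locus_length) && length(q) != locus_length) {
    stop(sprintf("query length %d does not match alignment length %d",
                 length(q), locus_length), call. = FALSE)
  }
  if (length(table$columns) && max(table$columns) > length(q)) {
    stop(sprintf("query length %d shorter than retained column %d",
                 length(q), max(table$columns)), call. = FALSE)
  }
  tally <- stats::setNames(integer(length(table$groups)), table$groups)
  for (k in seq_along(table$columns)) {
    pure_groups <- table$groups[table$status[k, ] == "PURE"]
    if (!length(pure_groups)) next
    states <- iupac_states(q[table$columns[k]])
    if (!length(states) || length(states) == 4L) next  # gap or N: no vote
    for (grp in pure_groups) {
      if (table$state_sets[[k]][[grp]] %in% states) {
        tally[grp] <- tally[grp] + 1L
      }
    }
  }
  best <- max(tally)
  winners <- names(tally)[tally == best]
  list(group = if (best > 0L && length(winners) == 1L) winners else "UNASSIGNED",
       tally = tally)
}

#' Write a diagnostic site table as TSV
#'
#' One row per retained column with, per group, the observed state set and
#' PURE/PRIVATE/NONE status.
#'
#' @param table A `diag_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_diag_table <- function(table, path) {
  stopifnot(inherits(table, "diag_table"))
  df <- data.frame(column = table$columns,
                   informative = table$informative,
                   stringsAsFactors = FALSE)
  for (grp in table$groups) {
    df[[paste0("states.", grp)]] <- vapply(
      table$state_sets, function(s) paste(s[[grp]], collapse = "/"),
      character(1))
    df[[paste0("status.", grp)]] <- table$status[, grp]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Text rendering of the diagnostic alignment
#'
#' Prints specimens as rows and retained columns as sites, in the style of
#' a diagnostic-character figure: a site that is PURE for the specimen's
#' group is bracketed (`[A]`), a state private to the group is marked with
#' an asterisk (`A*`), other states print bare. Column labels are 1-based,
#' zero-padded alignment coordinates.
#'
#' @param table A `diag_table`.
#' @param locus The [aligned_locus()] the table was built from.
#' @param specimens A `specimen_table`.
#' @return Character vector of lines, invisibly; also printed.
#' @export
render_diag_alignment <- function(table, locus, specimens) {
  stopifnot(inherits(table, "diag_table"), inherits(locus, "aligned_locus"))
  g <- specimens$group[match(rownames(locus$seqs), specimens$specimen_id)]
  width <- max(nchar(as.character(max(c(table$columns, 1L)))), 3L)
  header <- paste0(formatC("", width = 24),
                   paste(formatC(sprintf(paste0("%0", width, "d"),
                                         table$columns), width = 4),
                         collapse = ""))
  lines <- header
  ord <- order(g, rownames(locus$seqs))
  for (i in ord) {
    cells <- vapply(seq_along(table$columns), function(k) {
      ch <- locus$seqs[i, table$columns[k]]
      st <- table$status[k, g[i]]
      own_private <- st == "PRIVATE" &&
        ch %in% setdiff(table$state_sets[[k]][[g[i]]],
                        unlist(table$state_sets[[k]][table$groups != g[i]]))
      lab <- if (st == "PURE") paste0("[", ch, "]")
             else if (own_private) paste0(ch, "*")
             else ch
      formatC(lab, width = 4)
    }, character(1))
    lines <- c(lines, paste0(formatC(paste0(rownames(locus$seqs)[i], " (", g[i], ")"),
                                     width = -24), paste(cells, collapse = "")))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
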