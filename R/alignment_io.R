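#' Construct an aligned locus
#'
#' An `aligned_locus` holds one marker's multiple sequence alignment as a
#' character matrix (rows = specimens, columns = alignment positions) over
#' the IUPAC DNA alphabet plus gap. Input is case-insensitive and `"U"` is
#' accepted (stored as `"T"`); storage is uppercase.
#'
#' @param sequences Named character vector of aligned sequences (names are
#'   specimen ids), or a character matrix with rownames.
#' @param locus_name Name of the marker (e.g. `"COI"`).
#' @return An object of class `aligned_locus` with elements `locus_name`,
#'   `length` (number of columns) and `seqs` (character matrix).
#' @examples
#' aligned_locus(c(s1 = "ACGT", s2 = "ACGA"), "toy")
#' @export
aligned_locus <- function(sequences, locus_name) {
  stopifnot(is.character(locus_name), length(locus_name) == 1L)
  if (is.matrix(sequences)) {
    mat <- sequences
  } else {
    if (is.null(names(sequences)) || anyNA(names(sequences)) ||
        any(names(sequences) == "")) {
      stop("all sequences must be named by specimen id", call. = FALSE)
    }
    lens <- nchar(sequences)
    if (length(unique(lens)) > 1L) {
      bad <- names(sequences)[which(lens != lens[1L])[1L]]
      stop(sprintf(
        "alignment error in locus '%s': sequence '%s' has length %d, expected %d",
        locus_name, bad, nchar(sequences[[bad]]), lens[1L]), call. = FALSE)
    }
    mat <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
    rownames(mat) <- names(sequences)
  }
  if (anyDuplicated(rownames(mat))) {
    dup <- rownames(mat)[duplicated(rownames(mat))][1L]
    stop(sprintf("duplicate specimen id '%s' in locus '%s'", dup, locus_name),
         call. = FALSE)
  }
  mat[] <- .normalise_chars(mat)
  bad <- which(!(mat %in% .ALPHABET))
  if (length(bad)) {
    i <- bad[1L]
    row <- (i - 1L) %% nrow(mat) + 1L
    col <- (i - 1L) %/% nrow(mat) + 1L
    stop(sprintf(
      "alphabet error in locus '%s': illegal character '%s' in sequence '%s' at column %d",
      locus_name, mat[i], rownames(mat)[row], col), call. = FALSE)
  }
  structure(
    list(locus_name = locus_name, length = ncol(mat), seqs = mat),
    class = "aligned_locus")
}

#' @export
print.aligned_locus <- function(x, ...) {
  cat(sprintf("<aligned_locus> %s: %d sequences x %d columns\n",
              x$locus_name, nrow(x$seqs), x$length))
  invisible(x)
}

#' Sequences of an aligned locus as strings
#'
#' @param locus An [aligned_locus()].
#' @return Named character vector of sequences.
#' @export
locus_strings <- function(locus) {
  stopifnot(inherits(locus, "aligned_locus"))
  out <- apply(locus$seqs, 1L, paste, collapse = "")
  names(out) <- rownames(locus$seqs)
  out
}

#' Read one aligned FASTA file as a locus
#'
#' Parses an aligned FASTA file and validates it: all records must have the
#' same length and use only the IUPAC DNA alphabet plus gap. Record ids are
#' the first whitespace-delimited token of each header and become specimen
#' ids.
#'
#' @param path Path to an aligned FASTA file.
#' @param locus_name Marker name to attach.
#' @return An [aligned_locus()].
#' @export
read_fasta_alignment <- function(path, locus_name) {
  if (!file.exists(path)) {
    stop(sprintf("FASTA file not found: %s", path), call. = FALSE)
  }
  recs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                             as.string = TRUE, set.attributes = FALSE)
  if (!length(recs)) stop(sprintf("no sequences in %s", path), call. = FALSE)
  seqs <- vapply(recs, identity, character(1))
  names(seqs) <- vapply(strsplit(names(recs), "\\s+"), `[[`, character(1), 1L)
  aligned_locus(seqs, locus_name)
}

#' Write an aligned locus to FASTA
#'
#' @param locus An [aligned_locus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(locus, path) {
  stopifnot(inherits(locus, "aligned_locus"))
  strs <- locus_strings(locus)
  seqinr::write.fasta(as.list(strs), names = names(strs), file.out = path,
                      nbchar = 70)
  invisible(path)
}

#' Group key from species and form labels
#'
#' The group key is the species name when the form is empty, otherwise
#' `species|form`. Downstream code treats groups as opaque strings, so the
#' species-vs-form hierarchy is expressed purely through metadata.
#'
#' @param species,form Character vectors (recycled to common length); `NA`
#'   forms are treated as empty.
#' @return Character vector of group keys.
#' @export
group_key <- function(species, form) {
  form[is.na(form)] <- ""
  ifelse(form == "", species, paste(species, form, sep = "|"))
}

#' Build a specimen metadata table
#'
#' @param df Data frame with character columns `specimen_id`, `species`,
#'   `form` (empty form allowed).
#' @return Data frame with an added `group` column, class `specimen_table`.
#' @export
specimen_records <- function(df) {
  need <- c("specimen_id", "species", "form")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("metadata is missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  for (col in need) df[[col]] <- as.character(df[[col]])
  df$form[is.na(df$form)] <- ""
  if (anyDuplicated(df$specimen_id)) {
    dup <- unique(df$specimen_id[duplicated(df$specimen_id)])
    stop(sprintf("duplicate specimen id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  if (any(df$species == "" | is.na(df$species))) {
    stop("every specimen needs a nonempty species label", call. = FALSE)
  }
  df$group <- group_key(df$species, df$form)
  class(df) <- c("specimen_table", "data.frame")
  df
}

#' Read specimen metadata from TSV
#'
#' Expects a tab-separated file with header columns `specimen_id`,
#' `species` and `form` (the form may be empty for specimens without a
#' named intraspecific variant).
#'
#' @param path Path to the TSV file.
#' @return A `specimen_table` data frame with a derived `group` column.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("metadata file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, colClasses = "character", na.strings = NULL)
  specimen_records(df)
}

#' Write specimen metadata to TSV
#'
#' @param specimens A `specimen_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(specimens, path) {
  utils::write.table(
    specimens[c("specimen_id", "species", "form")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble loci and metadata into one dataset
#'
#' Cross-validates that every sequence belongs to a known specimen. A
#' specimen may be missing from some loci (partial coverage is allowed);
#' loci covering fewer than two groups are kept but flagged with a warning
#' since most analyses need at least two groups.
#'
#' @param loci List of [aligned_locus()] objects (names taken from each
#'   locus).
#' @param specimens A `specimen_table` (see [read_metadata()]).
#' @return An object of class `barcode_dataset` with elements `specimens`
#'   and `loci` (named list).
#' @export
build_dataset <- function(loci, specimens) {
  stopifnot(inherits(specimens, "specimen_table"))
  if (inherits(loci, "aligned_locus")) loci <- list(loci)
  if (!length(loci)) {
    warning("dataset has no loci")
  }
  names(loci) <- vapply(loci, function(l) l$locus_name, character(1))
  for (loc in loci) {
    orphans <- setdiff(rownames(loc$seqs), specimens$specimen_id)
    if (length(orphans)) {
      stop(sprintf(
        "locus '%s' contains specimen id(s) absent from metadata: %s",
        loc$locus_name, paste(orphans, collapse = ", ")), call. = FALSE)
    }
    groups <- specimens$group[match(rownames(loc$seqs), specimens$specimen_id)]
    if (length(unique(groups)) < 2L) {
      warning(sprintf("locus '%s' covers fewer than 2 groups", loc$locus_name))
    }
  }
  structure(list(specimens = specimens, loci = loci),
            class = "barcode_dataset")
}

#' @export
print.barcode_dataset <- function(x, ...) {
  cat(sprintf("<barcode_dataset> %d specimens, %d groups, %d loci\n",
              nrow(x$specimens), length(unique(x$specimens$group)),
              length(x$loci)))
  for (loc in x$loci) {
    groups <- x$specimens$group[match(rownames(loc$seqs),
                                      x$specimens$specimen_id)]
    tab <- table(groups)
    cat(sprintf("  %s (%d bp): %s\n", loc$locus_name, loc$length,
                paste(sprintf("%s n=%d", names(tab), tab), collapse = ", ")))
  }
  invisible(x)
}

#' Collapse form-level groups to species-level groups
#'
#' Returns a copy of the specimen table whose `group` column is the species
#' label alone, pooling any named forms. Useful for running the same
#' pipeline at species rather than form resolution.
#'
#' @param specimens A `specimen_table`.
#' @return A `specimen_table` with species-level groups.
#' @export
species_level <- function(specimens) {
  stopifnot(inherits(specimens, "specimen_table"))
  specimens$group <- specimens$species
  specimens
}
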