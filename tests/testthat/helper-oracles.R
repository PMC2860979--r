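# Independent brute-force oracles and fixture builders used across tests.
# The oracles deliberately share no code with the package implementation:
# they loop column by column over explicit state sets.

ALPHA16 <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
             "B", "D", "H", "V", "N", "-")

# naive per-column p-distance with pairwise deletion: a column counts only
# when both characters are plain A/C/G/T
naive_p <- function(a, b) {
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(av) == length(bv))
  n <- 0L; d <- 0L
  for (k in seq_along(av)) {
    x <- av[k]; y <- bv[k]
    if (x %in% c("A", "C", "G", "T") && y %in% c("A", "C", "G", "T")) {
      n <- n + 1L
      if (x != y) d <- d + 1L
    }
  }
  list(p = if (n > 0) d / n else NA_real_, n_compared = n, n_diff = d)
}

# brute-force per-column PURE/PRIVATE/NONE classification from explicit
# per-group observed base sets (gaps and ambiguity characters ignored)
brute_classify_column <- function(chars, groups) {
  gs <- sort(unique(groups))
  sets <- lapply(gs, function(g) {
    obs <- chars[groups == g]
    sort(unique(obs[obs %in% c("A", "C", "G", "T")]))
  })
  names(sets) <- gs
  status <- sapply(gs, function(g) {
    own <- sets[[g]]
    if (length(own) == 0) return("NONE")
    others <- sort(unique(unlist(sets[names(sets) != g])))
    excl <- setdiff(own, others)
    if (length(own) == 1 && length(excl) == 1) "PURE"
    else if (length(excl) > 0) "PRIVATE"
    else "NONE"
  })
  list(sets = sets, status = status)
}

# random aligned sequences with controllable IUPAC/gap content
random_alignment <- function(n_seq, n_col,
                             p_ambig = 0.1, p_gap = 0.05,
                             ids = sprintf("s%02d", seq_len(n_seq))) {
  chars <- c("A", "C", "G", "T")
  amb <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")
  m <- matrix(sample(chars, n_seq * n_col, replace = TRUE), n_seq, n_col)
  pick <- matrix(runif(n_seq * n_col), n_seq, n_col)
  m[pick < p_ambig] <- sample(amb, sum(pick < p_ambig), replace = TRUE)
  m[pick > 1 - p_gap] <- "-"
  rownames(m) <- ids
  m
}

make_locus <- function(seqs, name = "toy") {
  if (is.null(names(seqs)) && !is.matrix(seqs)) {
    names(seqs) <- sprintf("s%d", seq_along(seqs))
  }
  aligned_locus(seqs, name)
}

make_specimens <- function(ids, species, form = rep("", length(ids))) {
  specimen_records(data.frame(specimen_id = ids, species = species,
                              form = form, stringsAsFactors = FALSE))
}

# two-group toy dataset used by several modules
toy_two_groups <- function() {
  loc <- make_locus(c(a1 = "AAAACCGGTT", a2 = "AAAACCGGTT",
                      b1 = "AAAACCGGTA", b2 = "AAAACCGGTA"))
  sp <- make_specimens(c("a1", "a2", "b1", "b2"),
                       species = c("A", "A", "B", "B"))
  list(locus = loc, specimens = sp)
}

write_tmp_fasta <- function(seqs, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(seqs), function(nm) c(paste0(">", nm), seqs[[nm]])))
  writeLines(lines, path)
  path
}

write_tmp_metadata <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
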