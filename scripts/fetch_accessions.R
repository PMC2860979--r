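#!/usr/bin/env Rscript
# Helper: download the deposited Neocalanus sequences (GenBank accessions
# AB526881-AB527004: mitochondrial COI and 12S, nuclear ITS and 28S for 37
# specimens), align each marker with MAFFT, and place the per-locus
# alignments plus a metadata TSV under inst/extdata/accessions/ so the
# accession-based checks in the test suite can run.
#
# Requires network access and the `mafft` executable on PATH. The package
# itself builds and tests without this step; only the published-value
# reproduction check consumes these files.
#
# Usage: Rscript scripts/fetch_accessions.R [outdir]

args <- commandArgs(trailingOnly = TRUE)
outdir <- if (length(args)) args[[1]] else "inst/extdata/accessions"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

accessions <- sprintf("AB%06d", 526881:527004)
eutils <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi"

message("fetching ", length(accessions), " records from GenBank ...")
raw <- file.path(tempdir(), "neocalanus_raw.fasta")
url <- sprintf("%s?db=nuccore&id=%s&rettype=fasta&retmode=text",
               eutils, paste(accessions, collapse = ","))
download.file(url, raw, quiet = TRUE)

recs <- seqinr::read.fasta(raw, seqtype = "DNA", as.string = TRUE,
                           forceDNAtolower = FALSE, set.attributes = FALSE)
headers <- attr(recs, "Annot")
if (is.null(headers)) headers <- names(recs)

# GenBank definition lines carry the organism and the gene region; the
# specimen/form identity must be curated from the record features (isolate/
# specimen_voucher qualifiers). The sorting below is a starting point and
# should be reviewed against the GenBank flatfiles before use.
classify_locus <- function(h) {
  h <- tolower(h)
  if (grepl("cytochrome (c )?oxidase|coi|cox1", h)) "COI"
  else if (grepl("12s", h)) "12S"
  else if (grepl("internal transcribed spacer|its", h)) "ITS"
  else if (grepl("28s", h)) "28S"
  else NA_character_
}
loci <- vapply(names(recs), function(nm) {
  h <- headers[grep(nm, headers, fixed = TRUE)[1]]
  classify_locus(if (is.na(h)) nm else h)
}, character(1))

for (locus in c("COI", "12S", "ITS", "28S")) {
  idx <- which(loci == locus)
  if (!length(idx)) {
    warning("no records classified as ", locus)
    next
  }
  unaligned <- file.path(tempdir(), paste0(locus, "_unaligned.fasta"))
  seqinr::write.fasta(recs[idx], names = names(recs)[idx],
                      file.out = unaligned)
  aligned <- file.path(outdir, paste0(locus, ".fasta"))
  status <- system2("mafft", c("--auto", "--quiet", unaligned),
                    stdout = aligned)
  if (status != 0) stop("mafft failed for ", locus)
  message(locus, ": ", length(idx), " sequences aligned -> ", aligned)
}

message("NOTE: write ", file.path(outdir, "metadata.tsv"),
        " (specimen_id, species, form) from the GenBank isolate/voucher ",
        "qualifiers, with specimen ids matching the FASTA record ids, ",
        "before running the accession-based checks.")
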