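# On-disk artifacts: FASTQ reads, FASTA/TSV catalogs.

#' Read a FASTQ file into a tibble
#'
#' Strict 4-line-per-record Phred+33 FASTQ (the modern Illumina/BGISEQ
#' dialect; wrapped or Phred+64 files are rejected by construction). Record
#' order is preserved, so mates pair positionally across the two files of a
#' paired library.
#'
#' @param path FASTQ file.
#' @param sex_label `"male"` or `"female"`; carried on every record.
#' @return tibble with columns `id`, `sequence`, `qualities` (Phred+33
#'   string), `sex`.
#' @export
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq, "male")
read_fastq <- function(path, sex_label = c("male", "female")) {
  sex_label <- match.arg(sex_label)
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0) {
    return(tibble(id = character(), sequence = character(),
                  qualities = character(), sex = character()))
  }
  if (n %% 4 != 0) {
    stop("malformed FASTQ: ", path, " has ", n,
         " lines, truncated record begins at line ", 4 * (n %/% 4) + 1)
  }
  hdr <- lines[seq(1, n, by = 4)]
  seqs <- toupper(lines[seq(2, n, by = 4)])
  plus <- lines[seq(3, n, by = 4)]
  qual <- lines[seq(4, n, by = 4)]
  bad_hdr <- which(!startsWith(hdr, "@"))
  if (length(bad_hdr)) {
    stop("malformed FASTQ: header without '@' at line ", 4 * (bad_hdr[1] - 1) + 1)
  }
  bad_plus <- which(!startsWith(plus, "+"))
  if (length(bad_plus)) {
    stop("malformed FASTQ: separator without '+' at line ", 4 * (bad_plus[1] - 1) + 3)
  }
  bad_len <- which(nchar(seqs) != nchar(qual))
  if (length(bad_len)) {
    stop("malformed FASTQ: sequence/quality length mismatch at line ",
         4 * (bad_len[1] - 1) + 2)
  }
  tibble(
    id = sub("^@", "", sub("\\s.*$", "", hdr)),
    sequence = seqs,
    qualities = qual,
    sex = sex_label
  )
}

#' Read a paired-end library (R1/R2) with positional pairing
#'
#' @param r1,r2 mate-1 and mate-2 FASTQ paths.
#' @inheritParams read_fastq
#' @return tibble with `pair_id`, `mate` (1/2), `id`, `sequence`,
#'   `qualities`, `sex`; mates of a pair share `pair_id`.
#' @export
read_fastq_pairs <- function(r1, r2, sex_label = c("male", "female")) {
  sex_label <- match.arg(sex_label)
  m1 <- read_fastq(r1, sex_label)
  m2 <- read_fastq(r2, sex_label)
  if (nrow(m1) != nrow(m2)) {
    stop("R1 and R2 differ in record count (", nrow(m1), " vs ", nrow(m2), ")")
  }
  bind_rows(
    mutate(m1, pair_id = row_number(), mate = 1L),
    mutate(m2, pair_id = row_number(), mate = 2L)
  ) %>%
    select("pair_id", "mate", "id", "sequence", "qualities", "sex") %>%
    arrange(.data$pair_id, .data$mate)
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param reads tibble with `id`, `sequence`, `qualities`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "qualities") %in% names(reads)))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (nrow(reads)) {
    out <- rbind(paste0("@", reads$id), reads$sequence, "+", reads$qualities)
    writeLines(as.vector(out), con)
  }
  invisible(path)
}

#' Write a satellite catalog (FASTA + companion TSV)
#'
#' FASTA headers are `name|RUL|AT%`; the TSV carries one row per monomer with
#' name, repeat unit length, AT fraction, per-sex abundance, M/F ratio and
#' family/superfamily assignment. Decimal point, tab separator, UTF-8.
#'
#' @param monomers tibble with at least `name` and `sequence`; optional
#'   `abundance_male`, `abundance_female`, `mf_ratio`, `family_id`,
#'   `superfamily`.
#' @param fasta_path,tsv_path output files; either may be `NULL` to skip.
#' @return invisibly, the monomer tibble with descriptors filled.
#' @export
write_catalog <- function(monomers, fasta_path, tsv_path = NULL) {
  if (anyDuplicated(monomers$name)) {
    stop("duplicate monomer names: ",
         paste(unique(monomers$name[duplicated(monomers$name)]), collapse = ", "))
  }
  m <- mutate(monomers,
              rul = nchar(.data$sequence),
              at_fraction = at_fraction(.data$sequence))
  if (!is.null(fasta_path)) {
    hdr <- sprintf("%s|%d|%.1f", m$name, m$rul, 100 * m$at_fraction)
    x <- Biostrings::DNAStringSet(setNames(m$sequence, hdr))
    Biostrings::writeXStringSet(x, fasta_path)
  }
  if (!is.null(tsv_path)) {
    cols <- c("name", "rul", "at_fraction", "abundance_male",
              "abundance_female", "mf_ratio", "family_id", "superfamily")
    tab <- as.data.frame(m)
    for (cc in setdiff(cols, names(tab))) tab[[cc]] <- rep(NA, nrow(tab))
    write.table(tab[, cols], tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE, fileEncoding = "UTF-8", dec = ".")
  }
  invisible(m)
}

#' Read a catalog FASTA written by [write_catalog()]
#'
#' @param path FASTA file.
#' @return tibble with `name`, `sequence`, `rul`, `at_fraction` (descriptors
#'   recomputed from the sequence, not trusted from the header).
#' @export
read_catalog_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(x)
  tibble(
    name = sub("\\|.*$", "", names(x)),
    sequence = unname(seqs),
    rul = nchar(unname(seqs)),
    at_fraction = at_fraction(unname(seqs))
  )
}

# fraction of A+T bases
at_fraction <- function(seq) {
  (nchar(gsub("[^AT]", "", seq))) / nchar(seq)
}
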