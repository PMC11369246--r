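# Internal helpers: sequence primitives, seeded RNG scoping, logging.

DNA_BASES <- c("A", "C", "G", "T")

# reverse complement of a character vector of DNA strings
rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Phred+33 decode/encode
phred_to_int <- function(qual) {
  lapply(qual, function(q) utf8ToInt(q) - 33L)
}

int_to_phred <- function(q) {
  vapply(q, function(v) intToUtf8(v + 33L), character(1))
}

#' Run code with a locally fixed RNG seed
#'
#' Sets the RNG to `seed` for the duration of `code` and restores the caller's
#' RNG state on exit, so seeded package internals never perturb user-level
#' randomness.
#' @noRd
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-stage seed from the run seed
#'
#' One documented deterministic derivation so each pipeline stage can be rerun
#' in isolation with the same randomness as within a full run. Stays below
#' 2^31 - 1.
#'
#' @param seed integer run seed.
#' @param stage stage name, one of the pipeline stages.
#' @return integer seed.
#' @export
#' @examples
#' derive_seed(1, "simulate")
derive_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, discover = 2L, quantify = 3L, haplonet = 4L,
              subsample = 5L, evaluate = 6L)
  if (!stage %in% names(stages)) stop("unknown stage: ", stage)
  as.integer((as.double(seed) * 7919 + stages[[stage]] * 104729) %% 2147483647)
}

# timestamped progress line on stderr
log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_dna <- function(x) {
  all(grepl("^[ACGT]+$", x))
}

# Tandem-tiled alignment reference: at least a dimer (so alignments can cross
# the arbitrary phase boundary) and long enough that a full read fits inside
# one copy run even for monomers much shorter than the read.
tile_reference <- function(seqs, read_length) {
  m <- nchar(seqs)
  copies <- pmax(2L, as.integer(ceiling(read_length / m)) + 1L)
  vapply(seq_along(seqs), function(i) strrep(seqs[i], copies[i]), character(1))
}
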