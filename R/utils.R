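# Internal helpers shared across modules. All interval columns in exported
# tibbles are 0-based half-open ([start, end), BED convention); conversion to
# 1-based closed coordinates happens only at GTF/Bioconductor boundaries.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement a character vector of DNA sequences
#' @param x character vector over A/C/G/T/N.
#' @return character vector of the same length.
#' @keywords internal
#' @noRd
rc_chr <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# RNA motif notation (UGCAUG) to DNA (TGCATG)
rna2dna <- function(x) chartr("Uu", "Tt", toupper(x))

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Stable stage-derived sub-seed: polynomial hash of the stage name folded
# into the global seed, kept inside 32-bit integer range.
sub_seed <- function(seed, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147480000
  as.integer((h + as.numeric(seed) * 7919) %% 2147480000) + 1L
}

# Vectorised Hamming distance between the length-nchar(ref) prefix of `x`
# and a single reference string.
prefix_mismatches <- function(x, ref) {
  n <- nchar(ref)
  mm <- integer(length(x))
  for (j in seq_len(n)) {
    mm <- mm + (stringi::stri_sub(x, j, j) != substr(ref, j, j))
  }
  mm
}

# Random DNA of given lengths (vectorised), one string per element.
random_dna <- function(lengths) {
  if (length(lengths) == 0L) return(character(0))
  total <- sum(lengths)
  bases <- sample(DNA_BASES, total, replace = TRUE)
  ends <- cumsum(lengths)
  starts <- ends - lengths + 1L
  stringi::stri_sub(paste(bases, collapse = ""), starts, ends)
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  invisible(x)
}

# Contig length lookup from an artr_genome, a named vector, or a tibble.
contig_lengths <- function(genome) {
  if (inherits(genome, "artr_genome")) {
    return(setNames(genome$contigs$length, genome$contigs$chrom))
  }
  if (is.data.frame(genome)) return(setNames(genome$length, genome$chrom))
  if (is.numeric(genome) && !is.null(names(genome))) return(genome)
  abort("cannot derive contig lengths; pass an `artr_genome` or a named vector")
}

# Genome sequence lookup (DNAStringSet) from artr_genome or DNAStringSet.
genome_seq <- function(genome) {
  if (inherits(genome, "artr_genome")) return(genome$seq)
  if (methods::is(genome, "DNAStringSet")) return(genome)
  abort("expected an `artr_genome` or a DNAStringSet")
}
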