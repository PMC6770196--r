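# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical one-letter order.
AA_STANDARD20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

CONSEQUENCE_LEVELS <- c("missense", "synonymous", "stop_gained")
CATEGORY_LEVELS <- c("Not targeted", "Twilight zone", "Targeted")

#' @noRd
strip_chr <- function(x) sub("^chr", "", as.character(x))

#' @noRd
comp_base <- function(b) chartr("ACGT", "TGCA", b)

#' @noRd
revcomp <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# codon -> amino acid via the standard genetic code; stops translate to "*".
#' @noRd
translate_cds <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3 == 0)
  codons <- substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
  bad <- grepl("[^ACGT]", codons)
  if (any(bad)) {
    stop("ambiguous or non-ACGT base in codon(s): ",
         paste(unique(codons[bad]), collapse = ", "))
  }
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  paste(aa, collapse = "")
}

# amino acid -> codons lookup (includes "*" for stops)
#' @noRd
codons_for_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# All nine single-nucleotide neighbours of a codon, with the substitution
# (offset 0..2 within the codon, ref base, alt base) attached.
#' @noRd
codon_neighbours <- function(codon) {
  bases <- c("A", "C", "G", "T")
  out <- list()
  cs <- strsplit(codon, "")[[1]]
  for (off in 0:2) {
    for (b in setdiff(bases, cs[off + 1L])) {
      mt <- cs
      mt[off + 1L] <- b
      out[[length(out) + 1L]] <- list(
        codon = paste(mt, collapse = ""), offset = off,
        ref = cs[off + 1L], alt = b)
    }
  }
  out
}

# Parse "start-end;start-end" (0-based half-open) into an ascending matrix.
#' @noRd
parse_cds_segments <- function(x) {
  parts <- strsplit(trimws(x), ";", fixed = TRUE)[[1]]
  m <- do.call(rbind, lapply(parts, function(p) {
    se <- as.numeric(strsplit(p, "-", fixed = TRUE)[[1]])
    if (length(se) != 2L || anyNA(se)) stop("malformed CDS segment: ", p)
    se
  }))
  colnames(m) <- c("start", "end")
  m
}

#' @noRd
format_cds_segments <- function(m) {
  paste(sprintf("%d-%d", as.integer(m[, 1]), as.integer(m[, 2])),
        collapse = ";")
}

# Genomic positions (0-based) of the spliced CDS in coding (5'->3') order.
#' @noRd
splice_positions <- function(segments, strand) {
  pos <- unlist(lapply(seq_len(nrow(segments)), function(i) {
    seq.int(segments[i, 1], segments[i, 2] - 1L)
  }), use.names = FALSE)
  if (strand == "-") pos <- rev(pos)
  as.integer(pos)
}

# Load a genome as a named DNAStringSet with "chr" prefixes stripped.
#' @noRd
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  names(genome) <- strip_chr(names(genome))
  genome
}

# Fetch plus-strand bases at 0-based genomic positions on one chromosome.
#' @noRd
genome_base_chars <- function(genome, chrom, pos0) {
  chrom <- strip_chr(chrom)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  s <- as.character(genome[[chrom]])
  if (any(pos0 < 0L) || any(pos0 >= nchar(s))) {
    stop("genomic position outside chromosome ", chrom)
  }
  substring(s, pos0 + 1L, pos0 + 1L)
}

#' @noRd
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @noRd
read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE, ...)
}

# Deterministic sub-seed derivation (kept below 2^31).
#' @noRd
derive_seed <- function(seed, phase) {
  as.integer((as.numeric(seed) * 131L + phase * 7919) %% 2147483647)
}
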