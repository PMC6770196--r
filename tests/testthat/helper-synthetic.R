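# Fixture builders used across the suite. These deliberately re-derive
# sequences with their own independent splice/translate logic so they can act
# as oracles for the package's coordinate arithmetic.

GC_TABLE <- Biostrings::GENETIC_CODE
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

oracle_translate <- function(cds) {
  codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
  paste(unname(GC_TABLE[codons]), collapse = "")
}

# Splice a CDS out of a plus-strand chromosome string (segments are a
# matrix of 0-based half-open rows in ascending order).
oracle_splice <- function(chrom_seq, segments, strand) {
  s <- paste(substring(chrom_seq, segments[, 1] + 1, segments[, 2]),
             collapse = "")
  if (strand == "-") oracle_revcomp(s) else s
}

random_codon_for <- function(aa) {
  cands <- names(GC_TABLE)[GC_TABLE == aa]
  cands[sample.int(length(cands), 1)]
}

# Build one random transcript embedded in a random chromosome string.
# Returns the transcript-table row, the chromosome sequence, and enough
# geometry to compute oracle answers.
random_synthetic_transcript <- function(id = "TXX", gene = "GX",
                                        chrom = "1", strand = NULL,
                                        n_exons = NULL, P = NULL) {
  if (is.null(strand)) strand <- sample(c("+", "-"), 1)
  if (is.null(n_exons)) n_exons <- sample(1:4, 1)
  if (is.null(P)) P <- sample(15:40, 1)
  protein <- paste(c("M", sample(AA20, P - 1, replace = TRUE)),
                   collapse = "")
  codons <- vapply(strsplit(protein, "")[[1]], random_codon_for,
                   character(1))
  cds <- paste(c(codons, sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
  L <- nchar(cds)
  breaks <- if (n_exons > 1) sort(sample(seq_len(L - 1), n_exons - 1))
            else integer()
  lens <- diff(c(0L, breaks, L))
  glens <- if (strand == "-") rev(lens) else lens
  at <- sample(20:80, 1)
  segs <- matrix(NA_integer_, n_exons, 2)
  for (j in seq_len(n_exons)) {
    segs[j, ] <- c(at, at + glens[j])
    at <- segs[j, 2] + if (j < n_exons) sample(10:60, 1) else 0L
  }
  total_len <- at + sample(20:60, 1)
  bg <- paste(sample(c("A", "C", "G", "T"), total_len, replace = TRUE),
              collapse = "")
  plus <- if (strand == "-") oracle_revcomp(cds) else cds
  chrom_chars <- strsplit(bg, "")[[1]]
  ofs <- 0L
  for (j in seq_len(n_exons)) {
    w <- segs[j, 2] - segs[j, 1]
    chrom_chars[seq(segs[j, 1] + 1, segs[j, 2])] <-
      strsplit(substr(plus, ofs + 1, ofs + w), "")[[1]]
    ofs <- ofs + w
  }
  chrom_seq <- paste(chrom_chars, collapse = "")
  record <- data.frame(
    transcript_id = id, gene = gene, chromosome = chrom, strand = strand,
    cds_segments = paste(sprintf("%d-%d", segs[, 1], segs[, 2]),
                         collapse = ";"),
    status = "Public", protein_seq = protein, stringsAsFactors = FALSE)
  list(record = record, chrom_seq = chrom_seq, segments = segs,
       strand = strand, cds = cds, protein = protein, P = P)
}

as_genome <- function(chrom_seqs) {
  g <- Biostrings::DNAStringSet(unlist(chrom_seqs))
  names(g) <- names(chrom_seqs)
  g
}

# Oracle: apply a plus-strand substitution to the chromosome, re-splice,
# re-translate, return the full mutant protein (stop trimmed; "*" kept if
# internal).
oracle_mutant_protein <- function(tr, pos0, alt) {
  chars <- strsplit(tr$chrom_seq, "")[[1]]
  chars[pos0 + 1] <- alt
  cds <- oracle_splice(paste(chars, collapse = ""), tr$segments, tr$strand)
  aa <- oracle_translate(cds)
  sub("\\*$", "", aa)
}

# Write a minimal VCF for a table of plus-strand SNVs.
write_test_vcf <- function(df, path, contig_len = 100000L) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FILTER=<ID=PASS,Description=\"ok\">",
    "##FILTER=<ID=RF,Description=\"fail\">",
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"af\">",
    "##INFO=<ID=nhomalt,Number=A,Type=Integer,Description=\"nhom\">",
    sprintf("##contig=<ID=%s,length=%d>", unique(df$chrom), contig_len),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"))
  if (nrow(df)) {
    if (is.null(df$id)) df$id <- "."
    if (is.null(df$filter)) df$filter <- "PASS"
    if (is.null(df$info)) df$info <- "AF=0.0001;nhomalt=0"
    lines <- c(lines, paste(df$chrom, df$pos1, df$id, df$ref, df$alt, ".",
                            df$filter, df$info, sep = "\t"))
  }
  writeLines(lines, path)
  path
}

# Shared tiny scoring matrix fixture.
toy_matrix <- function() example_pts1_matrix()
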