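test_that("withdrawn records are excluded and public ones validated", {
  set.seed(101)
  t1 <- random_synthetic_transcript("TX1", "GA", chrom = "1")
  t2 <- random_synthetic_transcript("TX2", "GB", chrom = "2")
  t3 <- random_synthetic_transcript("TX3", "GC", chrom = "1")
  t3$record$status <- "Withdrawn"
  # second chromosome must be long enough for both TX2 and nothing else
  genome <- as_genome(list(`1` = paste0(t1$chrom_seq, t3$chrom_seq),
                           `2` = t2$chrom_seq))
  # shift TX3 segments onto the concatenated chromosome 1
  segs3 <- t3$segments + nchar(t1$chrom_seq)
  t3$record$cds_segments <- paste(sprintf("%d-%d", segs3[, 1], segs3[, 2]),
                                  collapse = ";")
  records <- rbind(t1$record, t2$record, t3$record)
  ts <- load_transcripts(records, genome)
  expect_equal(nrow(ts$transcripts), 2L)
  expect_setequal(ts$transcripts$transcript_id, c("TX1", "TX2"))
  expect_equal(ts$excluded$reason[ts$excluded$transcript_id == "TX3"],
               "withdrawn")
})

test_that("empty input gives an empty validated set", {
  genome <- as_genome(list(`1` = strrep("A", 100)))
  ts <- load_transcripts(read_transcript_tsv(
    write_tsv(data.frame(transcript_id = character(), gene = character(),
                         chromosome = character(), strand = character(),
                         cds_segments = character(), status = character()),
              withr::local_tempfile(fileext = ".tsv"))), genome)
  expect_equal(nrow(ts$transcripts), 0L)
  expect_equal(nrow(ts$excluded), 0L)
})

test_that("stored protein disagreeing with the translated CDS is reported", {
  set.seed(102)
  tr <- random_synthetic_transcript("TXBAD", "G1")
  # corrupt one internal residue of the stored protein
  p <- tr$record$protein_seq
  mid <- 5L
  orig <- substr(p, mid, mid)
  repl <- setdiff(AA20, orig)[1]
  substr(tr$record$protein_seq, mid, mid) <- repl
  # oracle: full splice-and-translate of the synthetic CDS
  oracle <- sub("\\*$", "", oracle_translate(
    oracle_splice(tr$chrom_seq, tr$segments, tr$strand)))
  expect_false(identical(oracle, tr$record$protein_seq))
  ts <- load_transcripts(tr$record,
                         as_genome(list(`1` = tr$chrom_seq)))
  expect_equal(nrow(ts$transcripts), 0L)
  expect_equal(ts$excluded$transcript_id, "TXBAD")
  expect_equal(ts$excluded$reason, "translation_mismatch")
})

test_that("structural defects get distinct record-level reasons", {
  set.seed(103)
  tr <- random_synthetic_transcript("TXA", "G1", n_exons = 1)
  genome <- as_genome(list(`1` = tr$chrom_seq))
  # frame break: drop one base off the single segment
  bad_frame <- tr$record
  segs <- tr$segments
  bad_frame$cds_segments <- sprintf("%d-%d", segs[1, 1], segs[1, 2] - 1L)
  ts <- load_transcripts(bad_frame, genome)
  expect_equal(ts$excluded$reason, "cds_length_not_multiple_of_3")
  # stop codon removed: trim a full codon
  no_stop <- tr$record
  no_stop$cds_segments <- sprintf("%d-%d", segs[1, 1], segs[1, 2] - 3L)
  if (tr$strand == "-") {
    no_stop$cds_segments <- sprintf("%d-%d", segs[1, 1] + 3L, segs[1, 2])
  }
  no_stop$protein_seq <- NA_character_
  ts2 <- load_transcripts(no_stop, genome)
  expect_true(ts2$excluded$reason %in%
                c("missing_stop_codon", "translation_mismatch"))
  # unknown chromosome is a hard error naming the transcript
  lost <- tr$record
  lost$chromosome <- "99"
  expect_error(load_transcripts(lost, genome), "TXA.*unknown chromosome")
})

test_that("C-terminal window arithmetic matches the strand conventions", {
  # 24-nt single-exon CDS: 7 residues + stop
  cds <- "ATGGCTGCTGCTGCTTCCAAGCTTTAA"  # 27 nt = 8 aa + stop
  # use a 24-nt CDS as in the worked example: 7 aa + stop
  cds <- "ATGGCTGCTGCTTCCAAGCTTTAA"
  chrom <- paste0(strrep("G", 100), cds, strrep("G", 50))
  rec <- data.frame(transcript_id = "T+", gene = "G", chromosome = "1",
                    strand = "+", cds_segments = "100-124",
                    status = "Public", protein_seq = NA_character_,
                    stringsAsFactors = FALSE)
  ts <- load_transcripts(rec, as_genome(list(`1` = chrom)))
  w <- cterminal_codon_intervals(ts$transcripts[1, ])
  expect_equal(sum(w$intervals$end - w$intervals$start), 9L)
  expect_equal(min(w$intervals$start), 112L)
  expect_equal(max(w$intervals$end), 121L)

  # same CDS placed on the minus strand: genomic bases are the revcomp
  chrom_m <- paste0(strrep("G", 100), oracle_revcomp(cds), strrep("G", 50))
  rec_m <- data.frame(transcript_id = "T-", gene = "G", chromosome = "1",
                      strand = "-", cds_segments = "100-124",
                      status = "Public", protein_seq = NA_character_,
                      stringsAsFactors = FALSE)
  ts_m <- load_transcripts(rec_m, as_genome(list(`1` = chrom_m)))
  w_m <- cterminal_codon_intervals(ts_m$transcripts[1, ])
  expect_equal(min(w_m$intervals$start), 103L)
  expect_equal(max(w_m$intervals$end), 112L)
  expect_equal(sum(w_m$intervals$end - w_m$intervals$start), 9L)

  # exon boundary 4 nt before the stop codon splits the window in two
  rec2 <- data.frame(transcript_id = "T2", gene = "G", chromosome = "1",
                     strand = "+", cds_segments = "100-117;150-157",
                     status = "Public", protein_seq = NA_character_,
                     stringsAsFactors = FALSE)
  chrom2 <- paste0(strrep("G", 100), substr(cds, 1, 17), strrep("A", 33),
                   substr(cds, 18, 24), strrep("G", 50))
  ts2 <- load_transcripts(rec2, as_genome(list(`1` = chrom2)))
  w2 <- cterminal_codon_intervals(ts2$transcripts[1, ])
  expect_gte(nrow(w2$intervals), 2L)
  expect_equal(sum(w2$intervals$end - w2$intervals$start), 9L)
})

test_that("window translation matches the stored tail on both strands", {
  # TCC AAG CTT -> SKL on the plus strand
  cds <- "ATGTCCAAGCTTTAA"
  chrom <- paste0(strrep("T", 50), cds, strrep("T", 30))
  rec <- data.frame(transcript_id = "T1", gene = "G", chromosome = "1",
                    strand = "+", cds_segments = "50-65", status = "Public",
                    protein_seq = NA_character_, stringsAsFactors = FALSE)
  genome <- as_genome(list(`1` = chrom))
  ts <- load_transcripts(rec, genome)
  expect_equal(ts$transcripts$protein_seq, "MSKL")
  w <- cterminal_codon_intervals(ts$transcripts[1, ])
  expect_equal(window_tripeptide(w, genome), "SKL")

  # minus strand: genomic window bases AAGCTTGGA translate to SKL
  cds_m <- "ATGTCCAAGCTTTAA"
  chrom_m <- paste0(strrep("T", 50), oracle_revcomp(cds_m), strrep("T", 30))
  rec_m <- rec
  rec_m$strand <- "-"
  ts_m <- load_transcripts(rec_m, as_genome(list(`1` = chrom_m)))
  w_m <- cterminal_codon_intervals(ts_m$transcripts[1, ])
  gb <- paste(substring(chrom_m, sort(w_m$codon_map$gpos) + 1,
                        sort(w_m$codon_map$gpos) + 1), collapse = "")
  expect_equal(gb, "AAGCTTGGA")
  expect_equal(window_tripeptide(w_m, as_genome(list(`1` = chrom_m))),
               "SKL")

  # tampering with the genome under the window is a consistency error
  broken <- chrom
  substr(broken, 54, 54) <- "A"  # TCC -> ACC: S becomes T at the tail
  expect_error(window_tripeptide(w, as_genome(list(`1` = broken))),
               "disagrees with stored protein tail")
})

test_that("proteins shorter than three residues are unsupported windows", {
  rec <- data.frame(transcript_id = "T1", gene = "G", chromosome = "1",
                    strand = "+", cds_segments = "10-19", status = "Public",
                    protein_seq = "MS", protein_length = 2L,
                    stringsAsFactors = FALSE)
  expect_error(cterminal_codon_intervals(rec[1, ]), "shorter than 3")
})

test_that("window extraction is deterministic and BED output well formed", {
  set.seed(104)
  trs <- lapply(1:5, function(i)
    random_synthetic_transcript(sprintf("TX%d", i), sprintf("G%d", i)))
  # one chromosome per transcript keeps layouts independent
  genome <- as_genome(stats::setNames(lapply(trs, `[[`, "chrom_seq"),
                                      as.character(1:5)))
  records <- do.call(rbind, lapply(trs, `[[`, "record"))
  records$chromosome <- as.character(1:5)
  ts <- load_transcripts(records, genome)
  f1 <- withr::local_tempfile(fileext = ".bed")
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_windows_bed(ts, f1)
  write_windows_bed(ts, f2)
  expect_identical(readLines(f1), readLines(f2))
  bed <- read.table(f1, header = TRUE, sep = "\t")
  lens <- tapply(bed$end - bed$start, bed$transcript_id, sum)
  expect_true(all(lens == 9L))
})

test_that("the CCDS text dialect maps onto the same transcript contract", {
  cds <- "ATGTCCAAGCTTTAA"
  chrom <- paste0(strrep("T", 50), cds, strrep("T", 30))
  lines <- c(paste("#chromosome", "nc_accession", "gene", "gene_id",
                   "ccds_id", "ccds_status", "cds_strand", "cds_from",
                   "cds_to", "cds_locations", "match_type", sep = "\t"),
             paste("chr1", "NC_1", "GENE1", "1", "CCDS1.1", "Public", "+",
                   "50", "64", "[50-64]", "Identical", sep = "\t"))
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(lines, f)
  recs <- read_ccds_text(f)
  expect_equal(recs$cds_segments, "50-65")
  ts <- load_transcripts(recs, as_genome(list(`1` = chrom)))
  expect_equal(ts$transcripts$protein_seq, "MSKL")
})
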