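#' Read a transcript table in the package's TSV dialect
#'
#' The table has one row per protein-coding transcript with columns
#' \code{transcript_id}, \code{gene}, \code{chromosome}, \code{strand}
#' (\code{+}/\code{-}), \code{cds_segments} (0-based half-open intervals
#' written \code{"start-end;start-end"} in ascending genomic order, stop codon
#' included), \code{status} (\code{Public}/\code{Withdrawn}) and an optional
#' \code{protein_seq} column holding the stored protein for cross-validation
#' against the translated CDS.
#'
#' @param path path to the TSV file.
#' @return a data.frame, one row per transcript.
#' @seealso [read_ccds_text()] for the native CCDS text dialect,
#'   [load_transcripts()] for validation against a genome.
#' @export
read_transcript_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("transcript_id", "gene", "chromosome", "strand",
            "cds_segments", "status")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("transcript table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"protein_seq" %in% names(df)) {
    df$protein_seq <- rep(NA_character_, nrow(df))
  }
  df$chromosome <- strip_chr(df$chromosome)
  df
}

#' Read transcripts from the native CCDS text dialect
#'
#' Parses the tab-delimited \code{CCDS.current.txt} layout (columns
#' \code{chromosome}, \code{nc_accession}, \code{gene}, \code{gene_id},
#' \code{ccds_id}, \code{ccds_status}, \code{cds_strand}, \code{cds_from},
#' \code{cds_to}, \code{cds_locations}, \code{match_type}) into the same
#' transcript table contract as [read_transcript_tsv()]. CCDS coordinates are
#' 0-based inclusive; they are converted to 0-based half-open on read. The
#' dialect carries no protein sequence, so \code{protein_seq} is \code{NA} and
#' the translated CDS is adopted after validation.
#'
#' @param path path to a CCDS-style text file (leading \code{#} on the header
#'   line is tolerated).
#' @return a data.frame in the [read_transcript_tsv()] layout.
#' @export
read_ccds_text <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) {
    return(data.frame(transcript_id = character(), gene = character(),
                      chromosome = character(), strand = character(),
                      cds_segments = character(), status = character(),
                      protein_seq = character(), stringsAsFactors = FALSE))
  }
  lines[1] <- sub("^#", "", lines[1])
  df <- utils::read.table(text = lines, sep = "\t", header = TRUE,
                          quote = "", comment.char = "",
                          stringsAsFactors = FALSE)
  segs <- vapply(df$cds_locations, function(x) {
    x <- gsub("\\[|\\]", "", x)
    parts <- strsplit(x, ",")[[1]]
    m <- do.call(rbind, lapply(trimws(parts), function(p) {
      as.numeric(strsplit(p, "-", fixed = TRUE)[[1]])
    }))
    # inclusive end -> half-open
    paste(sprintf("%d-%d", as.integer(m[, 1]), as.integer(m[, 2]) + 1L),
          collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  data.frame(transcript_id = df$ccds_id, gene = df$gene,
             chromosome = strip_chr(df$chromosome), strand = df$cds_strand,
             cds_segments = segs, status = df$ccds_status,
             protein_seq = NA_character_, stringsAsFactors = FALSE)
}

#' Load and validate protein-coding transcripts against a genome
#'
#' Each record is spliced from the genome, oriented by strand and translated.
#' A record is kept only if its status is \code{Public}, its CDS length is a
#' multiple of 3, its segments are strictly ascending and non-overlapping, its
#' CDS ends in a stop codon, and the translation (stop excluded) matches the
#' stored protein where one is given. Records without a stored protein adopt
#' the validated translation. Transcripts encoding proteins shorter than three
#' residues are excluded and logged rather than treated as errors. A reference
#' to a chromosome absent from the genome is a hard error naming the
#' transcript.
#'
#' @param records a transcript data.frame ([read_transcript_tsv()] /
#'   [read_ccds_text()]) or a path to a TSV in that dialect.
#' @param genome a named \code{DNAStringSet} or path to a genome FASTA.
#' @return an object of class \code{pts1_transcripts}: a list with
#'   \code{$transcripts} (validated records, with \code{protein_seq} and
#'   \code{protein_length} filled in) and \code{$excluded} (data.frame of
#'   \code{transcript_id}, \code{reason} for every record not kept).
#' @export
load_transcripts <- function(records, genome) {
  if (is.character(records) && length(records) == 1L) {
    records <- read_transcript_tsv(records)
  }
  genome <- load_genome(genome)
  records$chromosome <- strip_chr(records$chromosome)

  excl <- list()
  note <- function(id, reason) {
    excl[[length(excl) + 1L]] <<- data.frame(transcript_id = id,
                                             reason = reason,
                                             stringsAsFactors = FALSE)
  }

  keep <- logical(nrow(records))
  prot <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    id <- records$transcript_id[i]
    if (!records$chromosome[i] %in% names(genome)) {
      stop("transcript ", id, ": unknown chromosome '",
           records$chromosome[i], "'")
    }
    if (!identical(records$status[i], "Public")) {
      note(id, "withdrawn")
      next
    }
    segs <- tryCatch(parse_cds_segments(records$cds_segments[i]),
                     error = function(e) NULL)
    if (is.null(segs) || any(segs[, 2] <= segs[, 1])) {
      note(id, "malformed_segments")
      next
    }
    if (nrow(segs) > 1L &&
        any(segs[-1L, 1] < segs[-nrow(segs), 2])) {
      note(id, "segments_not_ascending")
      next
    }
    L <- sum(segs[, 2] - segs[, 1])
    if (L %% 3 != 0) {
      note(id, "cds_length_not_multiple_of_3")
      next
    }
    chrom_seq <- as.character(genome[[records$chromosome[i]]])
    if (max(segs[, 2]) > nchar(chrom_seq)) {
      note(id, "cds_outside_chromosome")
      next
    }
    cds <- paste(substring(chrom_seq, segs[, 1] + 1L, segs[, 2]),
                 collapse = "")
    if (records$strand[i] == "-") cds <- revcomp(cds)
    aa <- tryCatch(translate_cds(cds), error = function(e) NULL)
    if (is.null(aa)) {
      note(id, "ambiguous_base")
      next
    }
    last <- substr(aa, nchar(aa), nchar(aa))
    if (last != "*") {
      note(id, "missing_stop_codon")
      next
    }
    body <- substr(aa, 1L, nchar(aa) - 1L)
    if (grepl("\\*", body)) {
      note(id, "internal_stop_codon")
      next
    }
    stored <- records$protein_seq[i]
    if (!is.na(stored) && nzchar(stored) && !identical(stored, body)) {
      note(id, "translation_mismatch")
      next
    }
    if (nchar(body) < 3L) {
      note(id, "protein_too_short")
      next
    }
    keep[i] <- TRUE
    prot[i] <- body
  }

  out <- records[keep, , drop = FALSE]
  out$protein_seq <- prot[keep]
  out$protein_length <- nchar(out$protein_seq)
  rownames(out) <- NULL
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(transcript_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  structure(list(transcripts = out, excluded = excluded),
            class = "pts1_transcripts")
}

#' @export
print.pts1_transcripts <- function(x, ...) {
  cat("Validated transcript set:", nrow(x$transcripts), "kept,",
      nrow(x$excluded), "excluded\n")
  if (nrow(x$excluded)) {
    tab <- table(x$excluded$reason)
    for (r in names(tab)) cat("  -", r, ":", tab[[r]], "\n")
  }
  invisible(x)
}

#' Genomic window over the last three amino-acid codons
#'
#' Computes the genomic intervals covering the nine coding bases of the last
#' three residues preceding the stop codon, together with a complete per-base
#' codon map. Codons are indexed from the C-terminal end: \code{codon_index}
#' 1 is the C-terminal-most residue, 3 the antepenultimate; the corresponding
#' position in the tripeptide string is \code{4 - codon_index}. The window
#' never overlaps the stop codon.
#'
#' @param transcript one validated transcript row (from
#'   \code{load_transcripts()$transcripts}).
#' @return an object of class \code{pts1_window}: a list with
#'   \code{transcript_id}, \code{gene}, \code{chromosome}, \code{strand},
#'   \code{intervals} (data.frame \code{start}, \code{end},
#'   \code{codon_index}; 0-based half-open, lengths summing to 9),
#'   \code{codon_map} (data.frame \code{gpos}, \code{codon_index},
#'   \code{offset}, \code{coding_base}) and \code{tripeptide} (the stored
#'   protein's last three residues).
#' @export
cterminal_codon_intervals <- function(transcript) {
  t <- as.list(transcript)
  P <- nchar(t$protein_seq)
  if (is.na(P) || P < 3L) {
    stop("transcript ", t$transcript_id,
         ": protein shorter than 3 residues is unsupported")
  }
  segs <- parse_cds_segments(t$cds_segments)
  gmap <- splice_positions(segs, t$strand)
  # spliced CDS coordinates of the window: [3(P-3), 3P)
  idx <- seq.int(3L * (P - 3L), 3L * P - 1L)
  gpos <- gmap[idx + 1L]
  win_off <- idx - 3L * (P - 3L)
  codon_index <- 3L - win_off %/% 3L
  offset <- win_off %% 3L
  tri <- substr(t$protein_seq, P - 2L, P)
  # coding bases spelled from the protein: derive from stored CDS geometry is
  # not possible without the genome, so callers fill coding_base via
  # window_tripeptide(); here we record the window skeleton.
  cm <- data.frame(gpos = gpos, codon_index = codon_index, offset = offset,
                   stringsAsFactors = FALSE)
  ivs <- do.call(rbind, lapply(split(cm, cm$codon_index), function(d) {
    p <- sort(d$gpos)
    brk <- c(0L, which(diff(p) != 1L), length(p))
    do.call(rbind, lapply(seq_len(length(brk) - 1L), function(j) {
      data.frame(start = p[brk[j] + 1L], end = p[brk[j + 1L]] + 1L,
                 codon_index = d$codon_index[1], stringsAsFactors = FALSE)
    }))
  }))
  ivs <- ivs[order(ivs$start), , drop = FALSE]
  rownames(ivs) <- NULL
  structure(list(transcript_id = t$transcript_id, gene = t$gene,
                 chromosome = t$chromosome, strand = t$strand,
                 intervals = ivs, codon_map = cm, tripeptide = tri,
                 protein_seq = t$protein_seq),
            class = "pts1_window")
}

#' @export
print.pts1_window <- function(x, ...) {
  cat("C-terminal window for", x$transcript_id, "(", x$strand, "strand )\n")
  cat("  tripeptide:", x$tripeptide, "\n")
  for (i in seq_len(nrow(x$intervals))) {
    cat(sprintf("  %s:%d-%d codon %d\n", x$chromosome,
                x$intervals$start[i], x$intervals$end[i],
                x$intervals$codon_index[i]))
  }
  invisible(x)
}

#' Translate a C-terminal window from the genome
#'
#' Reads the nine window bases from the genome, orients them to the coding
#' strand, translates them and checks the result against the transcript's
#' stored protein tail. A disagreement is a consistency error, as is any
#' non-ACGT base inside the window.
#'
#' @param window a \code{pts1_window}.
#' @param genome a named \code{DNAStringSet} or FASTA path.
#' @return the three-residue tripeptide string.
#' @export
window_tripeptide <- function(window, genome) {
  genome <- load_genome(genome)
  cm <- window$codon_map
  plus <- genome_base_chars(genome, window$chromosome, cm$gpos)
  if (any(!plus %in% c("A", "C", "G", "T"))) {
    stop("ambiguous base in C-terminal window of ", window$transcript_id)
  }
  coding <- if (window$strand == "-") comp_base(plus) else plus
  ord <- order(-cm$codon_index, cm$offset)
  tri <- translate_cds(paste(coding[ord], collapse = ""))
  if (!identical(tri, window$tripeptide)) {
    stop("window translation '", tri, "' disagrees with stored protein tail '",
         window$tripeptide, "' for transcript ", window$transcript_id)
  }
  tri
}

#' Build a scan-ready window table for a transcript set
#'
#' Flattens the per-transcript C-terminal windows into one base-level table
#' used by [scan_variants()], validating every window translation against the
#' stored protein on the way.
#'
#' @param ts a \code{pts1_transcripts} object (or its \code{$transcripts}
#'   data.frame).
#' @param genome a named \code{DNAStringSet} or FASTA path.
#' @return an object of class \code{pts1_window_table}: a data.frame with one
#'   row per window base (\code{transcript_id}, \code{gene},
#'   \code{chromosome}, \code{strand}, \code{gpos}, \code{codon_index},
#'   \code{offset}, \code{coding_base}, \code{win9} the nine coding bases in
#'   frame, \code{wt_tri}, \code{protein_length}, \code{last12}).
#' @export
cterminal_windows <- function(ts, genome) {
  df <- if (inherits(ts, "pts1_transcripts")) ts$transcripts else ts
  genome <- load_genome(genome)
  rows <- lapply(seq_len(nrow(df)), function(i) {
    w <- cterminal_codon_intervals(df[i, ])
    tri <- window_tripeptide(w, genome)
    cm <- w$codon_map
    plus <- genome_base_chars(genome, w$chromosome, cm$gpos)
    coding <- if (w$strand == "-") comp_base(plus) else plus
    ord <- order(-cm$codon_index, cm$offset)
    win9 <- paste(coding[ord], collapse = "")
    P <- df$protein_length[i]
    last12 <- if (P >= 12L) substr(df$protein_seq[i], P - 11L, P)
              else NA_character_
    data.frame(transcript_id = w$transcript_id, gene = w$gene,
               chromosome = w$chromosome, strand = w$strand,
               gpos = cm$gpos, codon_index = cm$codon_index,
               offset = cm$offset, coding_base = coding,
               win9 = win9, wt_tri = tri, protein_length = P,
               last12 = last12, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(transcript_id = character(), gene = character(),
               chromosome = character(), strand = character(),
               gpos = integer(), codon_index = integer(), offset = integer(),
               coding_base = character(), win9 = character(),
               wt_tri = character(), protein_length = integer(),
               last12 = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pts1_window_table", "data.frame")
  out
}

#' Write C-terminal windows as a BED-like TSV
#'
#' Emits one row per (codon, contiguous genomic run) with 0-based half-open
#' coordinates: \code{chromosome}, \code{start}, \code{end},
#' \code{transcript_id}, \code{codon_index}, \code{strand}. Output row order
#' is deterministic (chromosome, start, transcript).
#'
#' @param ts a \code{pts1_transcripts} object.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_windows_bed <- function(ts, path) {
  df <- if (inherits(ts, "pts1_transcripts")) ts$transcripts else ts
  rows <- lapply(seq_len(nrow(df)), function(i) {
    w <- cterminal_codon_intervals(df[i, ])
    data.frame(chromosome = w$chromosome, start = w$intervals$start,
               end = w$intervals$end, transcript_id = w$transcript_id,
               codon_index = w$intervals$codon_index, strand = w$strand,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(), start = integer(), end = integer(),
               transcript_id = character(), codon_index = integer(),
               strand = character(), stringsAsFactors = FALSE)
  out <- out[order(out$chromosome, out$start, out$transcript_id,
                   out$codon_index), , drop = FALSE]
  write_tsv(out, path)
}
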