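#' Read per-allele variant records from a VCF
#'
#' Reads a plain or bgzipped VCF, expands multi-allelic sites into one record
#' per alternate allele, and extracts the quality filter status plus the
#' allele frequency and homozygote-count INFO fields. Coordinates are 1-based
#' in the file and stored 0-based.
#'
#' @param path VCF path.
#' @param af_key,nhom_key INFO keys for allele frequency and homozygote count
#'   (defaults \code{"AF"}, \code{"nhomalt"}); missing keys yield \code{NA}.
#' @return a data.frame with columns \code{chrom} (\code{"chr"} prefix
#'   stripped), \code{pos} (0-based), \code{ref}, \code{alt}, \code{pass}
#'   (\code{FILTER == "PASS"} literally), \code{af}, \code{nhomalt},
#'   \code{rsid}; non-SNV alleles are dropped and counted in the
#'   \code{"dropped_non_snv"} attribute.
#' @export
read_vcf_variants <- function(path, af_key = "AF", nhom_key = "nhomalt") {
  vcf <- VariantAnnotation::readVcf(path)
  site_ids <- names(SummarizedExperiment::rowRanges(vcf))
  n_alt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  if (n == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), pass = logical(), af = numeric(),
                      nhomalt = integer(), rsid = character(),
                      stringsAsFactors = FALSE)
    attr(out, "dropped_non_snv") <- 0L
    return(out)
  }
  ref <- as.character(VariantAnnotation::ref(vcf))
  alt <- as.character(VariantAnnotation::alt(vcf))
  bad_chars <- grepl("[^ACGTN*.<>]", toupper(paste0(ref, alt)))
  if (any(bad_chars)) {
    stop("malformed REF/ALT field in record(s): ",
         paste(utils::head(which(bad_chars), 5L), collapse = ", "))
  }
  filt <- as.character(VariantAnnotation::filt(vcf))
  info <- VariantAnnotation::info(vcf)
  getinfo <- function(key) {
    if (key %in% names(info)) {
      v <- info[[key]]
      if (is.list(v) || methods::is(v, "List")) {
        v <- vapply(v, function(x) if (length(x)) x[[1]] else NA, numeric(1))
      }
      as.numeric(v)
    } else rep(NA_real_, n)
  }
  rsid <- names(rr)
  if (is.null(rsid)) rsid <- rep(site_ids, n_alt)  # expand() drops names
  if (is.null(rsid)) rsid <- rep("", n)
  # readVcf names rows "chrom:pos_ref/alt" when ID is "."; keep only rs-style
  rsid <- ifelse(is.na(rsid) | rsid == "." | grepl(":", rsid), "", rsid)
  out <- data.frame(
    chrom = strip_chr(as.character(GenomicRanges::seqnames(rr))),
    pos = GenomicRanges::start(rr) - 1L,
    ref = ref, alt = alt,
    pass = filt == "PASS",
    af = getinfo(af_key),
    nhomalt = as.integer(getinfo(nhom_key)),
    rsid = rsid, stringsAsFactors = FALSE)
  snv <- nchar(out$ref) == 1L & nchar(out$alt) == 1L &
    out$ref %in% c("A", "C", "G", "T") & out$alt %in% c("A", "C", "G", "T") &
    out$ref != out$alt
  dropped <- sum(!snv)
  out <- out[snv, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_non_snv") <- dropped
  out
}

#' Normalize and merge variant call sets into per-allele SNV records
#'
#' Produces the canonical per-allele record table used downstream: one row per
#' (chromosome, position, ref, alt), with quality-pass flags kept separately
#' for the exome and genome call sets. Alleles present in both call sets are
#' merged into a single record carrying both flags; allele frequency and rsid
#' are taken from the exome record when both sources provide them. The
#' function is idempotent: feeding its own output back returns a structurally
#' identical table.
#'
#' @param exome,genome a VCF path, a [read_vcf_variants()] data.frame, or (for
#'   \code{exome} only) an already-normalized table. Either may be omitted.
#' @return a data.frame with columns \code{chrom}, \code{pos} (0-based),
#'   \code{ref}, \code{alt}, \code{pass_exome}, \code{pass_genome}, \code{af},
#'   \code{nhomalt}, \code{rsid}, sorted by allele key; the
#'   \code{"dropped_non_snv"} attribute carries the total non-SNV drop count.
#' @export
normalize_variants <- function(exome = NULL, genome = NULL) {
  dropped <- 0L
  as_source <- function(x, flag) {
    if (is.null(x)) return(NULL)
    if (is.character(x) && length(x) == 1L) x <- read_vcf_variants(x)
    d <- attr(x, "dropped_non_snv")
    if (!is.null(d)) dropped <<- dropped + d
    if (all(c("pass_exome", "pass_genome") %in% names(x))) {
      return(x[, c("chrom", "pos", "ref", "alt", "pass_exome", "pass_genome",
                   "af", "nhomalt", "rsid")])
    }
    stopifnot(all(c("chrom", "pos", "ref", "alt", "pass") %in% names(x)))
    nr <- nrow(x)
    data.frame(chrom = strip_chr(x$chrom), pos = x$pos, ref = x$ref,
               alt = x$alt,
               pass_exome = if (flag == "exome") x$pass else
                 rep(FALSE, nr),
               pass_genome = if (flag == "genome") x$pass else
                 rep(FALSE, nr),
               af = if ("af" %in% names(x)) x$af else rep(NA_real_, nr),
               nhomalt = if ("nhomalt" %in% names(x)) x$nhomalt
                         else rep(NA_integer_, nr),
               rsid = if ("rsid" %in% names(x)) x$rsid else rep("", nr),
               stringsAsFactors = FALSE)
  }
  parts <- list(as_source(exome, "exome"), as_source(genome, "genome"))
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) stop("no variant source supplied")
  all <- do.call(rbind, parts)
  ok <- nchar(all$ref) == 1L & nchar(all$alt) == 1L &
    all$ref %in% c("A", "C", "G", "T") & all$alt %in% c("A", "C", "G", "T") &
    all$ref != all$alt
  dropped <- dropped + sum(!ok)
  all <- all[ok, , drop = FALSE]
  if (!nrow(all)) {
    rownames(all) <- NULL
    attr(all, "dropped_non_snv") <- dropped
    return(all)
  }
  key <- paste(all$chrom, all$pos, all$ref, all$alt, sep = ":")
  merged <- lapply(split(all, key), function(d) {
    first_af <- d$af[!is.na(d$af)]
    first_rs <- d$rsid[nzchar(d$rsid)]
    first_nh <- d$nhomalt[!is.na(d$nhomalt)]
    data.frame(chrom = d$chrom[1], pos = d$pos[1], ref = d$ref[1],
               alt = d$alt[1],
               pass_exome = any(d$pass_exome),
               pass_genome = any(d$pass_genome),
               af = if (length(first_af)) first_af[1] else NA_real_,
               nhomalt = if (length(first_nh)) first_nh[1] else NA_integer_,
               rsid = if (length(first_rs)) first_rs[1] else "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_non_snv") <- dropped
  out
}

#' Classify the consequence of a tripeptide change
#'
#' \code{synonymous} when the mutant tripeptide equals the wild type,
#' \code{stop_gained} when the mutated codon becomes a stop, otherwise
#' \code{missense}. Downstream candidate filters consume missense records
#' only.
#'
#' @param wt_tri,mt_tri wild-type and mutant tripeptides; \code{mt_tri} uses
#'   \code{"*"} for a gained stop. Vectorized.
#' @return character vector over \code{c("missense", "synonymous",
#'   "stop_gained")}.
#' @export
classify_consequence <- function(wt_tri, mt_tri) {
  ifelse(wt_tri == mt_tri, "synonymous",
         ifelse(grepl("\\*", mt_tri, fixed = FALSE), "stop_gained",
                "missense"))
}

#' Map one normalized variant onto a C-terminal window
#'
#' Applies the alternate allele on the coding strand (complemented for minus
#' strand transcripts), rebuilds the affected codon in frame and returns both
#' tripeptides. Returns \code{NULL} when the variant does not fall inside the
#' window. A REF base that disagrees with the genome is a hard
#' reference-mismatch error naming the variant and transcript.
#'
#' @param v one normalized variant (single-row data.frame or list with
#'   \code{chrom}, \code{pos} 0-based, \code{ref}, \code{alt}).
#' @param window a \code{pts1_window}.
#' @param genome a named \code{DNAStringSet} or FASTA path.
#' @return a one-row data.frame (transcript_id, gene, chrom, pos, ref, alt,
#'   wt_tri, mt_tri, codon_index, consequence) or \code{NULL}.
#' @export
map_variant <- function(v, window, genome) {
  v <- as.list(v)
  if (strip_chr(v$chrom) != window$chromosome) return(NULL)
  cm <- window$codon_map
  hit <- which(cm$gpos == v$pos)
  if (!length(hit)) return(NULL)
  genome <- load_genome(genome)
  gbase <- genome_base_chars(genome, window$chromosome, v$pos)
  if (gbase != v$ref) {
    stop("reference mismatch for variant ", v$chrom, ":", v$pos + 1L,
         " ", v$ref, ">", v$alt, " on transcript ", window$transcript_id,
         ": genome has ", gbase)
  }
  plus <- genome_base_chars(genome, window$chromosome, cm$gpos)
  coding <- if (window$strand == "-") comp_base(plus) else plus
  ord <- order(-cm$codon_index, cm$offset)
  win9 <- coding[ord]
  ci <- cm$codon_index[hit]
  off <- cm$offset[hit]
  alt_coding <- if (window$strand == "-") comp_base(v$alt) else v$alt
  win9[(3L - ci) * 3L + off + 1L] <- alt_coding
  mt_tri <- translate_cds(paste(win9, collapse = ""))
  wt_tri <- window$tripeptide
  data.frame(transcript_id = window$transcript_id, gene = window$gene,
             chrom = window$chromosome, pos = v$pos, ref = v$ref,
             alt = v$alt, wt_tri = wt_tri, mt_tri = mt_tri,
             codon_index = ci,
             consequence = classify_consequence(wt_tri, mt_tri),
             stringsAsFactors = FALSE)
}

#' Intersect normalized variants with C-terminal windows
#'
#' Vectorized scan of a normalized variant table against a window table: every
#' (variant, transcript) pair where the variant falls inside the transcript's
#' C-terminal window yields one tripeptide-change record. REF bases are
#' checked against the window's coding bases; any disagreement aborts the scan
#' with a reference-mismatch error.
#'
#' @param variants normalized variants from [normalize_variants()].
#' @param windows a \code{pts1_window_table} from [cterminal_windows()].
#' @return a data.frame of tripeptide changes: \code{transcript_id},
#'   \code{gene}, \code{chrom}, \code{pos} (0-based), \code{ref}, \code{alt},
#'   \code{wt_tri}, \code{mt_tri}, \code{codon_index}, \code{consequence},
#'   \code{pass_exome}, \code{pass_genome}, \code{af}, \code{nhomalt},
#'   \code{rsid}, \code{protein_length}, \code{last12}.
#' @export
scan_variants <- function(variants, windows) {
  empty <- data.frame(transcript_id = character(), gene = character(),
                      chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      wt_tri = character(), mt_tri = character(),
                      codon_index = integer(), consequence = character(),
                      pass_exome = logical(), pass_genome = logical(),
                      af = numeric(), nhomalt = integer(), rsid = character(),
                      protein_length = integer(), last12 = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(variants) || !nrow(windows)) return(empty)
  wv <- merge(as.data.frame(windows), variants,
              by.x = c("chromosome", "gpos"), by.y = c("chrom", "pos"))
  if (!nrow(wv)) return(empty)
  expected_plus <- ifelse(wv$strand == "+", wv$coding_base,
                          comp_base(wv$coding_base))
  bad <- expected_plus != wv$ref
  if (any(bad)) {
    b <- wv[which(bad)[1], ]
    stop("reference mismatch for variant ", b$chromosome, ":", b$gpos + 1L,
         " ", b$ref, ">", b$alt, " on transcript ", b$transcript_id)
  }
  alt_coding <- ifelse(wv$strand == "+", wv$alt, comp_base(wv$alt))
  at <- (3L - wv$codon_index) * 3L + wv$offset + 1L
  mt9 <- wv$win9
  substr(mt9, at, at) <- alt_coding
  mt_tri <- vapply(mt9, translate_cds, character(1), USE.NAMES = FALSE)
  out <- data.frame(transcript_id = wv$transcript_id, gene = wv$gene,
                    chrom = wv$chromosome, pos = wv$gpos, ref = wv$ref,
                    alt = wv$alt, wt_tri = wv$wt_tri, mt_tri = mt_tri,
                    codon_index = wv$codon_index,
                    consequence = classify_consequence(wv$wt_tri, mt_tri),
                    pass_exome = wv$pass_exome, pass_genome = wv$pass_genome,
                    af = wv$af, nhomalt = wv$nhomalt, rsid = wv$rsid,
                    protein_length = wv$protein_length, last12 = wv$last12,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$alt, out$transcript_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write tripeptide changes as TSV (1-based positions)
#'
#' @param changes a [scan_variants()] data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_changes_tsv <- function(changes, path) {
  out <- changes
  if (nrow(out)) out$pos <- out$pos + 1L
  write_tsv(out, path)
}

#' Read a tripeptide-change TSV written by [write_changes_tsv()]
#'
#' @param path TSV path.
#' @return the change table with 0-based positions restored.
#' @export
read_changes_tsv <- function(path) {
  out <- read_tsv(path, colClasses = c(rsid = "character",
                                       last12 = "character"))
  if (nrow(out)) out$pos <- out$pos - 1L
  out$chrom <- as.character(out$chrom)
  out
}
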