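# Localization keyword sets used by the two cascades. Matching is
# exact-token and case-insensitive (so "Cytoplasmic vesicle" does not match
# "Cytoplasm"), which is deliberately stricter than free-text matching.
LOF_EXCLUDE_KEYWORDS <- c("Secreted", "Nucleus", "Mitochondrion",
                          "Endosome", "Cytoplasm")
GOF_EXCLUDE_KEYWORDS <- c("Secreted", "Nucleus", "Mitochondrion",
                          "Endosome", "Peroxisome")

#' @noRd
parse_keywords <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  lapply(strsplit(x, ";", fixed = TRUE),
         function(k) tolower(trimws(k[nzchar(trimws(k))])))
}

#' @noRd
has_keyword <- function(kwsets, keyword) {
  kw <- tolower(trimws(keyword))
  vapply(kwsets, function(s) kw %in% s, logical(1))
}

#' @noRd
has_any_keyword <- function(kwsets, keywords) {
  kws <- tolower(trimws(keywords))
  vapply(kwsets, function(s) any(kws %in% s), logical(1))
}

#' Read a subcellular localization annotation table
#'
#' TSV with columns \code{protein_id}, \code{keywords} (semicolon-separated),
#' \code{isoform_specific} (logical).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_localization_tsv <- function(path) {
  df <- read_tsv(path, colClasses = c(keywords = "character"))
  need <- c("protein_id", "keywords", "isoform_specific")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("localization table missing column(s): ",
         paste(miss, collapse = ", "))
  }
  df$isoform_specific <- as.logical(df$isoform_specific)
  df
}

#' Read a gene-context table
#'
#' TSV with columns \code{gene}, \code{omim_flag}, \code{length} (residues of
#' the gene's reference protein), \code{tmd_flag} (annotated transmembrane
#' domain) and \code{manual_include} (whitelist override for the
#' peroxisome-exclusive localization stage).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_gene_context_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("gene", "omim_flag", "length", "tmd_flag", "manual_include")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("gene context table missing column(s): ",
         paste(miss, collapse = ", "))
  }
  for (col in c("omim_flag", "tmd_flag", "manual_include")) {
    df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Propagate localization annotations across isoforms
#'
#' Isoform-specific annotations are kept untouched; a transcript with no
#' annotation of its own inherits the annotation of its gene's canonical
#' transcript (the longest protein; ties broken by the lexicographically
#' smallest transcript id). Genes whose canonical transcript is unannotated
#' stay unannotated and are excluded later by the cascades with reason
#' \code{"unannotated"}.
#'
#' @param annotations data.frame from [read_localization_tsv()] (protein ids
#'   are transcript ids).
#' @param transcripts data.frame with \code{transcript_id}, \code{gene},
#'   \code{protein_length} identifying each gene's isoforms.
#' @return the completed annotation data.frame (one row per annotated
#'   transcript).
#' @export
propagate_annotations <- function(annotations, transcripts) {
  stopifnot(all(c("transcript_id", "gene", "protein_length") %in%
                  names(transcripts)))
  tx <- transcripts[order(transcripts$gene, -transcripts$protein_length,
                          transcripts$transcript_id), , drop = FALSE]
  canonical <- tx[!duplicated(tx$gene), c("gene", "transcript_id")]
  names(canonical)[2] <- "canonical_id"
  rows <- list()
  for (i in seq_len(nrow(transcripts))) {
    id <- transcripts$transcript_id[i]
    own <- annotations[annotations$protein_id == id, , drop = FALSE]
    if (nrow(own)) {
      rows[[length(rows) + 1L]] <- own[1, , drop = FALSE]
      next
    }
    can <- canonical$canonical_id[canonical$gene == transcripts$gene[i]]
    ca <- annotations[annotations$protein_id == can[1], , drop = FALSE]
    # an isoform-specific annotation on the canonical never propagates
    ca <- ca[!(ca$isoform_specific %in% TRUE), , drop = FALSE]
    if (nrow(ca)) {
      inherited <- ca[1, , drop = FALSE]
      inherited$protein_id <- id
      rows[[length(rows) + 1L]] <- inherited
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    annotations[0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Sequential stage engine: predicates see only the records that survived the
# previous stages; each excluded record is logged at its first failing stage.
#' @noRd
run_cascade <- function(records, stages, reasons = NULL) {
  key_cols <- intersect(c("transcript_id", "gene", "chrom", "pos", "ref",
                          "alt", "rsid"), names(records))
  n <- nrow(records)
  alive <- rep(TRUE, n)
  counts <- data.frame(stage = names(stages), n_in = NA_integer_,
                       n_out = NA_integer_, stringsAsFactors = FALSE)
  log <- list()
  for (k in seq_along(stages)) {
    idx <- which(alive)
    counts$n_in[k] <- length(idx)
    if (length(idx)) {
      res <- stages[[k]](records[idx, , drop = FALSE])
      pass <- res$pass
      fail <- idx[!pass]
      if (length(fail)) {
        log[[length(log) + 1L]] <- cbind(
          records[fail, key_cols, drop = FALSE],
          data.frame(stage = names(stages)[k],
                     reason = res$reason[!pass], stringsAsFactors = FALSE))
      }
      alive[fail] <- FALSE
    }
    counts$n_out[k] <- sum(alive)
  }
  exclusion_log <- if (length(log)) do.call(rbind, log) else
    cbind(records[0, key_cols, drop = FALSE],
          data.frame(stage = character(), reason = character(),
                     stringsAsFactors = FALSE))
  rownames(exclusion_log) <- NULL
  retained <- records[alive, , drop = FALSE]
  rownames(retained) <- NULL
  structure(list(retained = retained, stage_counts = counts,
                 exclusion_log = exclusion_log),
            class = "pts1_filter_outcome")
}

#' @export
print.pts1_filter_outcome <- function(x, ...) {
  cat("Filter cascade:", x$stage_counts$n_in[1], "records in,",
      nrow(x$retained), "retained\n")
  for (k in seq_len(nrow(x$stage_counts))) {
    cat(sprintf("  %-38s %4d -> %4d\n", x$stage_counts$stage[k],
                x$stage_counts$n_in[k], x$stage_counts$n_out[k]))
  }
  invisible(x)
}

#' @noRd
stage_result <- function(pass, reason_fail, reason_override = NULL) {
  reason <- rep(reason_fail, length(pass))
  if (!is.null(reason_override)) {
    reason[!is.na(reason_override)] <-
      reason_override[!is.na(reason_override)]
  }
  list(pass = pass, reason = reason)
}

#' Loss-of-function candidate cascade
#'
#' Prioritizes missense tripeptide changes that could inactivate an existing
#' C-terminal targeting signal. Stages, applied in order with per-stage
#' accounting: (1) gene belongs to the curated list of PTS1-carrying
#' peroxisomal genes; (2) gene has a disease annotation; (3) the protein's
#' localization contains the token \code{Peroxisome} and none of
#' \code{Secreted}, \code{Nucleus}, \code{Mitochondrion}, \code{Endosome},
#' \code{Cytoplasm} — unless the gene is on the \code{manual_include}
#' whitelist; (4) the variant passed quality filters in at least one call
#' set; (5) the wild-type tripeptide matches the canonical consensus and the
#' mutant one does not. Records whose gene or protein lacks context or
#' annotation fail their stage with reason \code{"unannotated"}.
#'
#' @param changes missense tripeptide changes ([scan_variants()] rows;
#'   non-missense rows are rejected with an error).
#' @param annotations completed localization annotations
#'   ([propagate_annotations()]).
#' @param contexts gene contexts ([read_gene_context_tsv()]).
#' @param pts1_genes character vector: the curated PTS1 gene list.
#' @param consensus canonical consensus passed to [is_canonical_pts1()].
#' @return a \code{pts1_filter_outcome}: \code{$retained},
#'   \code{$stage_counts} (telescoping in/out per stage) and
#'   \code{$exclusion_log} (first failing stage per excluded record).
#' @export
lof_cascade <- function(changes, annotations, contexts, pts1_genes,
                        consensus = list(c("S", "A", "C"),
                                         c("K", "R", "H"), "L")) {
  if (nrow(changes) && any(changes$consequence != "missense")) {
    stop("lof_cascade expects missense changes only")
  }
  ann_kw <- parse_keywords(annotations$keywords)
  ctx_idx <- function(genes) match(genes, contexts$gene)
  stages <- list(
    curated_pts1_gene = function(d) {
      stage_result(d$gene %in% pts1_genes, "not_in_curated_pts1_list")
    },
    omim_disease = function(d) {
      i <- ctx_idx(d$gene)
      pass <- !is.na(i) & contexts$omim_flag[i] %in% TRUE
      stage_result(pass, "no_omim_disease",
                   ifelse(is.na(i), "unannotated", NA))
    },
    peroxisome_exclusive_localization = function(d) {
      ai <- match(d$transcript_id, annotations$protein_id)
      ci <- ctx_idx(d$gene)
      manual <- !is.na(ci) & contexts$manual_include[ci] %in% TRUE
      perox <- rep(FALSE, nrow(d))
      clean <- rep(FALSE, nrow(d))
      known <- !is.na(ai)
      if (any(known)) {
        sets <- ann_kw[ai[known]]
        perox[known] <- has_keyword(sets, "Peroxisome")
        clean[known] <- !has_any_keyword(sets, LOF_EXCLUDE_KEYWORDS)
      }
      pass <- (known & perox & clean) | (known & perox & manual)
      stage_result(pass, "not_peroxisome_exclusive",
                   ifelse(!known, "unannotated", NA))
    },
    quality_pass = function(d) {
      stage_result(d$pass_exome | d$pass_genome, "failed_quality_filters")
    },
    canonical_wt_noncanonical_mt = function(d) {
      stage_result(is_canonical_pts1(d$wt_tri, consensus) &
                     !is_canonical_pts1(d$mt_tri, consensus),
                   "tripeptide_consensus_rule")
    })
  run_cascade(changes, stages)
}

#' Gain-of-function candidate cascade
#'
#' Prioritizes missense tripeptide changes that could create a de novo
#' targeting signal on a cytosolic protein. Stages, in order: (1) variant
#' quality-passing; (2) localization contains \code{Cytoplasm} and none of
#' \code{Secreted}, \code{Nucleus}, \code{Mitochondrion}, \code{Endosome},
#' \code{Peroxisome}; (3) the predicted category changes to
#' \code{"Targeted"} from \code{"Twilight zone"} or \code{"Not targeted"};
#' (4) per gene, only the longest transcript carrying the variant is kept
#' (ties broken by smallest transcript id); (5) protein shorter than
#' \code{max_protein_length} residues and no annotated transmembrane domain.
#'
#' @param changes scored missense changes ([score_changes()] rows with
#'   \code{wt_category}/\code{mt_category}).
#' @param annotations completed localization annotations.
#' @param contexts gene contexts.
#' @param max_protein_length upper protein-length bound (default 1000,
#'   exclusive).
#' @return a \code{pts1_filter_outcome}.
#' @export
gof_cascade <- function(changes, annotations, contexts,
                        max_protein_length = 1000L) {
  if (nrow(changes) && any(changes$consequence != "missense")) {
    stop("gof_cascade expects missense changes only")
  }
  if (!all(c("wt_category", "mt_category") %in% names(changes))) {
    stop("gof_cascade needs scored changes (see score_changes())")
  }
  ann_kw <- parse_keywords(annotations$keywords)
  stages <- list(
    quality_pass = function(d) {
      stage_result(d$pass_exome | d$pass_genome, "failed_quality_filters")
    },
    cytoplasm_exclusive_localization = function(d) {
      ai <- match(d$transcript_id, annotations$protein_id)
      known <- !is.na(ai)
      cyto <- rep(FALSE, nrow(d))
      clean <- rep(FALSE, nrow(d))
      if (any(known)) {
        sets <- ann_kw[ai[known]]
        cyto[known] <- has_keyword(sets, "Cytoplasm")
        clean[known] <- !has_any_keyword(sets, GOF_EXCLUDE_KEYWORDS)
      }
      stage_result(known & cyto & clean, "not_cytoplasm_exclusive",
                   ifelse(!known, "unannotated", NA))
    },
    category_gain = function(d) {
      pass <- !is.na(d$mt_category) & d$mt_category == "Targeted" &
        d$wt_category %in% c("Twilight zone", "Not targeted")
      stage_result(pass, "no_category_gain",
                   ifelse(is.na(d$mt_category), "unscored", NA))
    },
    longest_transcript_per_gene = function(d) {
      ord <- order(d$gene, -d$protein_length, d$transcript_id)
      keep_tx <- d$transcript_id[ord][!duplicated(d$gene[ord])]
      keep_gene <- d$gene[ord][!duplicated(d$gene[ord])]
      pass <- paste(d$gene, d$transcript_id) %in%
        paste(keep_gene, keep_tx)
      stage_result(pass, "shorter_isoform_of_gene")
    },
    protein_size_and_tmd = function(d) {
      ci <- match(d$gene, contexts$gene)
      tmd <- !is.na(ci) & contexts$tmd_flag[ci] %in% TRUE
      pass <- !is.na(ci) & d$protein_length < max_protein_length & !tmd
      stage_result(pass, "too_long_or_tmd",
                   ifelse(is.na(ci), "unannotated", NA))
    })
  run_cascade(changes, stages)
}

#' Write a filter outcome's tables
#'
#' Writes the retained-candidate table (mirroring the published candidate
#' tables: rsid, gene, transcript, tripeptides, categories when present), the
#' per-stage count table and the exclusion log as three TSVs sharing a path
#' prefix (\code{<prefix>_retained.tsv}, \code{<prefix>_stages.tsv},
#' \code{<prefix>_exclusions.tsv}).
#'
#' @param outcome a \code{pts1_filter_outcome}.
#' @param prefix output path prefix.
#' @return named character vector of the three paths, invisibly.
#' @export
write_filter_outcome <- function(outcome, prefix) {
  stopifnot(inherits(outcome, "pts1_filter_outcome"))
  paths <- c(retained = paste0(prefix, "_retained.tsv"),
             stages = paste0(prefix, "_stages.tsv"),
             exclusions = paste0(prefix, "_exclusions.tsv"))
  ret <- outcome$retained
  if (nrow(ret) && "pos" %in% names(ret)) ret$pos <- ret$pos + 1L
  write_tsv(ret, paths["retained"])
  write_tsv(outcome$stage_counts, paths["stages"])
  excl <- outcome$exclusion_log
  if (nrow(excl) && "pos" %in% names(excl)) excl$pos <- excl$pos + 1L
  write_tsv(excl, paths["exclusions"])
  invisible(paths)
}
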