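#' Position-specific scoring matrix for 12-residue C-termini
#'
#' Container for the scoring model used to grade the quality of a C-terminal
#' peroxisomal targeting signal: a 12-position by 20-residue matrix of
#' additive score contributions (position 1 is the most N-terminal of the
#' window, position 12 the C-terminal residue) plus two ordered thresholds
#' that cut the score range into the three targeting categories
#' \code{"Targeted"} (score >= \code{t_targeted}), \code{"Twilight zone"}
#' (\code{t_twilight} <= score < \code{t_targeted}) and
#' \code{"Not targeted"}. A score exactly at a threshold joins the higher
#' category.
#'
#' The matrix used by the original published predictor is not distributed
#' with this package; matrices are configuration. [zero_pts1_matrix()] is a
#' neutral placeholder and [example_pts1_matrix()] a documented toy matrix
#' used by the test-suite and the synthetic pipeline.
#'
#' @param entries numeric 12 x 20 matrix; columns must be named by the 20
#'   standard residues (any order; stored alphabetically).
#' @param t_targeted,t_twilight category thresholds, \code{t_targeted >
#'   t_twilight}.
#' @param name free-text matrix name/version.
#' @return an object of class \code{pts1_matrix}.
#' @export
pts1_matrix <- function(entries, t_targeted, t_twilight, name = "unnamed") {
  entries <- as.matrix(entries)
  if (!identical(dim(entries), c(12L, 20L))) {
    stop("matrix must be 12 positions x 20 residues")
  }
  if (is.null(colnames(entries)) ||
      !setequal(colnames(entries), AA_STANDARD20)) {
    stop("matrix columns must be named by the 20 standard residues")
  }
  entries <- entries[, AA_STANDARD20, drop = FALSE]
  rownames(entries) <- as.character(1:12)
  storage.mode(entries) <- "double"
  if (anyNA(entries)) stop("matrix entries must all be defined")
  if (!(is.numeric(t_targeted) && is.numeric(t_twilight) &&
        t_targeted > t_twilight)) {
    stop("thresholds must satisfy t_targeted > t_twilight")
  }
  structure(list(entries = entries, t_targeted = as.numeric(t_targeted),
                 t_twilight = as.numeric(t_twilight), name = name),
            class = "pts1_matrix")
}

#' @export
print.pts1_matrix <- function(x, ...) {
  cat("PTS1 scoring matrix '", x$name, "' (12 x 20)\n", sep = "")
  cat("  thresholds: Targeted >= ", x$t_targeted,
      ", Twilight zone >= ", x$t_twilight, "\n", sep = "")
  invisible(x)
}

#' Read a scoring matrix file
#'
#' Strict parser for the package's matrix format: a header row of the 20
#' residue letters, exactly 12 tab-separated data rows (position 1 first),
#' and a two-line footer \code{#t_targeted<TAB>value} /
#' \code{#t_twilight<TAB>value}. Any deviation is an error; there are no
#' silent defaults.
#'
#' @param path matrix file path.
#' @return a \code{pts1_matrix}.
#' @export
read_pts1_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 15L) {
    stop("matrix file must have 1 header + 12 data + 2 threshold lines, got ",
         length(lines))
  }
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!setequal(header, AA_STANDARD20) || length(header) != 20L) {
    stop("matrix header must list the 20 standard residues")
  }
  rows <- lapply(lines[2:13], function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "\t", fixed = TRUE)[[1]]))
    if (length(v) != 20L || anyNA(v)) stop("malformed matrix data row: ", l)
    v
  })
  entries <- do.call(rbind, rows)
  colnames(entries) <- header
  th <- function(line, key) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) != 2L || f[1] != key) {
      stop("expected threshold line '", key, "<TAB>value', got: ", line)
    }
    as.numeric(f[2])
  }
  pts1_matrix(entries, t_targeted = th(lines[14], "#t_targeted"),
              t_twilight = th(lines[15], "#t_twilight"),
              name = basename(path))
}

#' Write a scoring matrix file
#'
#' @param m a \code{pts1_matrix}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pts1_matrix <- function(m, path) {
  stopifnot(inherits(m, "pts1_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(AA_STANDARD20, collapse = "\t"), con)
  for (i in 1:12) {
    writeLines(paste(format(m$entries[i, ], trim = TRUE, scientific = FALSE),
                     collapse = "\t"), con)
  }
  writeLines(sprintf("#t_targeted\t%s", format(m$t_targeted)), con)
  writeLines(sprintf("#t_twilight\t%s", format(m$t_twilight)), con)
  invisible(path)
}

#' Neutral all-zero placeholder matrix
#'
#' Scores every sequence 0; with thresholds (2, 1) every sequence is
#' \code{"Not targeted"}. Useful as a stand-in when no real matrix is
#' configured.
#'
#' @return a \code{pts1_matrix}.
#' @export
zero_pts1_matrix <- function() {
  entries <- matrix(0, 12, 20, dimnames = list(NULL, AA_STANDARD20))
  pts1_matrix(entries, t_targeted = 2, t_twilight = 1, name = "zero")
}

#' Documented example matrix rewarding the canonical tripeptide consensus
#'
#' A deliberately simple teaching/testing matrix: the three tripeptide
#' positions (window positions 10-12) reward membership in the canonical
#' consensus sets ([S/A/C], [K/R/H], L) with contributions 5 / 4.5 / 4 for
#' the first, second and third listed residue, and 5 for the terminal L; all
#' other entries are 0. With thresholds (12, 7) a fully canonical tripeptide
#' (minimum score 4 + 4 + 5 = 13) is always \code{"Targeted"}, exactly two
#' matching positions (maximum 5 + 5 = 10) land in the
#' \code{"Twilight zone"}, and at most one match is \code{"Not targeted"}.
#' This matrix is a package fixture, not a reproduction of any published
#' predictor.
#'
#' @return a \code{pts1_matrix}.
#' @export
example_pts1_matrix <- function() {
  entries <- matrix(0, 12, 20, dimnames = list(NULL, AA_STANDARD20))
  entries[10, c("S", "A", "C")] <- c(5, 4.5, 4)
  entries[11, c("K", "R", "H")] <- c(5, 4.5, 4)
  entries[12, "L"] <- 5
  pts1_matrix(entries, t_targeted = 12, t_twilight = 7,
              name = "consensus-example")
}

#' Test a tripeptide against the canonical PTS1 consensus
#'
#' The default consensus is the classical [S/A/C]-[K/R/H]-L pattern; the
#' per-position residue sets are overridable.
#'
#' @param tripeptide character vector of 3-residue uppercase strings.
#' @param consensus list of three character vectors of allowed residues.
#' @return logical vector.
#' @export
is_canonical_pts1 <- function(tripeptide,
                              consensus = list(c("S", "A", "C"),
                                               c("K", "R", "H"), "L")) {
  stopifnot(is.list(consensus), length(consensus) == 3L)
  tripeptide <- as.character(tripeptide)
  if (any(nchar(tripeptide) != 3L)) {
    stop("tripeptides must have exactly 3 residues")
  }
  chars <- do.call(rbind, strsplit(tripeptide, ""))
  if (any(!chars %in% AA_STANDARD20)) {
    stop("non-amino-acid character in tripeptide(s): ",
         paste(unique(tripeptide[rowSums(
           matrix(!chars %in% AA_STANDARD20, ncol = 3)) > 0]),
           collapse = ", "))
  }
  chars[, 1] %in% consensus[[1]] & chars[, 2] %in% consensus[[2]] &
    chars[, 3] %in% consensus[[3]]
}

#' Score a 12-residue C-terminus with a scoring matrix
#'
#' The score is the sum over the 12 aligned positions of the matrix entry for
#' the residue observed at that position. Inputs must be exactly 12 standard
#' residues; shorter proteins are not padded and must be rejected upstream.
#'
#' @param c_terminus_12aa character vector of 12-residue sequences.
#' @param m a \code{pts1_matrix}.
#' @return numeric vector of scores.
#' @export
pssm_score <- function(c_terminus_12aa, m) {
  stopifnot(inherits(m, "pts1_matrix"))
  s <- as.character(c_terminus_12aa)
  if (any(is.na(s)) || any(nchar(s) != 12L)) {
    stop("input sequences must have exactly 12 residues")
  }
  chars <- do.call(rbind, strsplit(s, ""))
  if (any(!chars %in% AA_STANDARD20)) {
    stop("unknown residue in input (only the 20 standard residues are ",
         "supported): ",
         paste(unique(chars[!chars %in% AA_STANDARD20]), collapse = ", "))
  }
  col <- match(chars, AA_STANDARD20)
  idx <- cbind(rep(1:12, each = length(s)), col)
  rowSums(matrix(m$entries[idx], nrow = length(s)))
}

#' Assign the targeting category for a score
#'
#' @param score numeric vector of scores.
#' @param m a \code{pts1_matrix} supplying the thresholds.
#' @return character vector over \code{c("Targeted", "Twilight zone",
#'   "Not targeted")}; ties at a threshold join the higher category.
#' @export
categorize <- function(score, m) {
  stopifnot(inherits(m, "pts1_matrix"))
  ifelse(score >= m$t_targeted, "Targeted",
         ifelse(score >= m$t_twilight, "Twilight zone", "Not targeted"))
}

#' Score a wild-type / mutant pair of C-termini
#'
#' @param wt_12aa,mt_12aa 12-residue sequences.
#' @param m a \code{pts1_matrix}.
#' @return an object of class \code{pts1_result}: list with \code{wt_score},
#'   \code{mt_score}, \code{wt_category}, \code{mt_category} and
#'   \code{score_difference} (= \code{mt_score - wt_score}).
#' @export
score_pair <- function(wt_12aa, mt_12aa, m) {
  wt <- pssm_score(wt_12aa, m)
  mt <- pssm_score(mt_12aa, m)
  structure(list(wt_score = wt, mt_score = mt,
                 wt_category = categorize(wt, m),
                 mt_category = categorize(mt, m),
                 score_difference = mt - wt),
            class = "pts1_result")
}

#' @export
print.pts1_result <- function(x, ...) {
  cat(sprintf("PTS1 score: WT %.3f (%s) -> MT %.3f (%s), difference %+.3f\n",
              x$wt_score, x$wt_category, x$mt_score, x$mt_category,
              x$score_difference))
  invisible(x)
}

#' Score a table of tripeptide changes
#'
#' Builds the wild-type 12-residue C-terminus from each change's
#' \code{last12} and the mutant one by substituting the mutant tripeptide at
#' positions 10-12, then scores both. Changes on proteins shorter than 12
#' residues are returned with \code{NA} scores and counted in the
#' \code{"skipped_short"} attribute.
#'
#' @param changes a [scan_variants()] data.frame (needs \code{last12} and
#'   \code{mt_tri}).
#' @param m a \code{pts1_matrix}.
#' @return \code{changes} with columns \code{wt_score}, \code{mt_score},
#'   \code{wt_category}, \code{mt_category}, \code{score_difference} added.
#' @export
score_changes <- function(changes, m) {
  out <- changes
  out$wt_score <- NA_real_
  out$mt_score <- NA_real_
  out$wt_category <- NA_character_
  out$mt_category <- NA_character_
  out$score_difference <- NA_real_
  ok <- which(!is.na(out$last12) & nchar(out$last12) == 12L)
  if (length(ok)) {
    wt12 <- out$last12[ok]
    mt12 <- wt12
    substr(mt12, 10L, 12L) <- out$mt_tri[ok]
    sp <- score_pair(wt12, mt12, m)
    out$wt_score[ok] <- sp$wt_score
    out$mt_score[ok] <- sp$mt_score
    out$wt_category[ok] <- sp$wt_category
    out$mt_category[ok] <- sp$mt_category
    out$score_difference[ok] <- sp$score_difference
  }
  attr(out, "skipped_short") <- nrow(out) - length(ok)
  out
}

#' Score C-termini from a FASTA file
#'
#' Reads protein sequences, takes the last 12 residues of each and emits a
#' TSV with columns \code{id}, \code{last12}, \code{score},
#' \code{category}. Sequences shorter than 12 residues are rejected with an
#' error naming the offending records.
#'
#' @param fasta path to a protein FASTA.
#' @param m a \code{pts1_matrix}.
#' @param path output TSV path.
#' @return the scored data.frame, invisibly.
#' @export
score_fasta <- function(fasta, m, path) {
  aa <- Biostrings::readAAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- as.character(aa)
  short <- nchar(seqs) < 12L
  if (any(short)) {
    stop("sequence(s) shorter than 12 residues: ",
         paste(ids[short], collapse = ", "))
  }
  last12 <- substr(seqs, nchar(seqs) - 11L, nchar(seqs))
  score <- pssm_score(last12, m)
  out <- data.frame(id = ids, last12 = last12, score = score,
                    category = categorize(score, m),
                    stringsAsFactors = FALSE)
  write_tsv(out, path)
  invisible(out)
}
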