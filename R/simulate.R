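#' Configuration for the synthetic dataset generator
#'
#' Describes a fully self-contained toy study: how many loss-of-function and
#' gain-of-function candidate variants to plant, how many decoys of each
#' class (each decoy violates exactly one pipeline rule), the total gene
#' count, the exon-count range and the fraction of minus-strand genes.
#' Identical configuration and seed always produce byte-identical output
#' files.
#'
#' @param seed master integer seed.
#' @param n_lof_planted,n_gof_planted planted candidate counts.
#' @param n_decoy_synonymous in-window variants that do not change the
#'   tripeptide.
#' @param n_decoy_outside_window variants upstream of the C-terminal window.
#' @param n_decoy_failqc in-window candidate-like variants failing quality
#'   filters in every call set.
#' @param n_genes total genes (must cover all planted hosts; the remainder
#'   are variant-free filler genes).
#' @param exons_per_transcript integer range \code{c(min, max)}.
#' @param strand_minus_frac fraction of genes on the minus strand.
#' @return an object of class \code{pts1_sim_config}.
#' @export
simulation_config <- function(seed = 1L, n_lof_planted = 2L,
                              n_gof_planted = 2L, n_decoy_synonymous = 1L,
                              n_decoy_outside_window = 1L,
                              n_decoy_failqc = 1L, n_genes = 12L,
                              exons_per_transcript = c(1L, 4L),
                              strand_minus_frac = 0.5) {
  counts <- c(n_lof_planted, n_gof_planted, n_decoy_synonymous,
              n_decoy_outside_window, n_decoy_failqc, n_genes)
  if (any(counts < 0)) stop("config error: counts must be non-negative")
  hosts <- sum(counts[1:5])
  if (n_genes < hosts) {
    stop("config error: n_genes (", n_genes,
         ") must cover all planted hosts (", hosts, ")")
  }
  if (length(exons_per_transcript) != 2L ||
      exons_per_transcript[1] < 1L ||
      exons_per_transcript[2] < exons_per_transcript[1] ||
      exons_per_transcript[2] > 8L) {
    stop("config error: exons_per_transcript must be an increasing range ",
         "within 1..8")
  }
  if (strand_minus_frac < 0 || strand_minus_frac > 1) {
    stop("config error: strand_minus_frac must be in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_lof_planted = n_lof_planted,
                 n_gof_planted = n_gof_planted,
                 n_decoy_synonymous = n_decoy_synonymous,
                 n_decoy_outside_window = n_decoy_outside_window,
                 n_decoy_failqc = n_decoy_failqc, n_genes = n_genes,
                 exons_per_transcript = as.integer(exons_per_transcript),
                 strand_minus_frac = strand_minus_frac),
            class = "pts1_sim_config")
}

#' @export
print.pts1_sim_config <- function(x, ...) {
  cat("Synthetic study config (seed ", x$seed, "): ",
      x$n_lof_planted, " LoF + ", x$n_gof_planted, " GoF planted, decoys ",
      x$n_decoy_synonymous, "/", x$n_decoy_outside_window, "/",
      x$n_decoy_failqc, " (syn/outside/failqc), ",
      x$n_genes, " genes\n", sep = "")
  invisible(x)
}

# Sample a codon uniformly among the synonymous codons of an amino acid.
#' @noRd
sample_codon <- function(aa, table) {
  cands <- table[[aa]]
  cands[sample.int(length(cands), 1L)]
}

# Pick a single-substitution neighbour of `codon` whose translation breaks
# (or, for direction = "into", lies outside) the consensus set at tripeptide
# string position `strpos`.
#' @noRd
pick_breaking_neighbour <- function(codon, strpos, consensus) {
  nb <- codon_neighbours(codon)
  aa <- vapply(nb, function(x) unname(Biostrings::GENETIC_CODE[x$codon]),
               character(1))
  wt_aa <- unname(Biostrings::GENETIC_CODE[codon])
  ok <- which(aa != "*" & aa != wt_aa & !(aa %in% consensus[[strpos]]))
  if (!length(ok)) return(NULL)
  nb[[ok[sample.int(length(ok), 1L)]]]
}

#' Generate a self-contained synthetic dataset with planted candidates
#'
#' Emits a toy genome, transcript table, variant call file, localization and
#' gene-context annotations and a truth table into \code{dir}. Planted
#' loss-of-function variants sit in peroxisome-exclusive, disease-flagged
#' genes on the curated gene list, with canonical wild-type tripeptides
#' mutated to non-canonical ones; planted gain-of-function variants sit in
#' cytoplasm-exclusive genes where a single base change completes a canonical
#' tripeptide. Decoy classes each violate exactly one rule: synonymous
#' in-window changes, variants upstream of the window, and quality-failing
#' variants in otherwise perfect loss-of-function genes. Running both filter
#' cascades on the bundle must retain exactly the planted candidates.
#'
#' Codons for planted tripeptides are chosen so the planted event is a true
#' single-nucleotide substitution; all other codons are sampled uniformly
#' among synonymous codons. Distinct pseudo-random streams (sub-seeds of the
#' master seed) drive sequence design, genome background and allele
#' frequencies.
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with \code{paths} (named: genome, transcripts,
#'   variants, localization, gene_context, pts1_genes, truth) and
#'   \code{truth} (the truth data.frame).
#' @export
generate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "pts1_sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()),
            add = TRUE)
  }
  consensus <- list(c("S", "A", "C"), c("K", "R", "H"), "L")
  aa_codons <- codons_for_aa()
  stops <- c("TAA", "TAG", "TGA")
  roles <- c(rep("lof", cfg$n_lof_planted), rep("gof", cfg$n_gof_planted),
             rep("decoy_synonymous", cfg$n_decoy_synonymous),
             rep("decoy_outside", cfg$n_decoy_outside_window),
             rep("decoy_failqc", cfg$n_decoy_failqc))
  roles <- c(roles, rep("filler", cfg$n_genes - length(roles)))

  set.seed(derive_seed(cfg$seed, 1L))  # design stream
  genes <- vector("list", length(roles))
  for (i in seq_along(roles)) {
    role <- roles[i]
    strand <- if (stats::runif(1) < cfg$strand_minus_frac) "-" else "+"
    k <- sample(seq(cfg$exons_per_transcript[1],
                    cfg$exons_per_transcript[2]), 1L)
    P <- sample(25:60, 1L)
    variant <- NULL

    if (role %in% c("lof", "decoy_failqc")) {
      tri <- c(sample(consensus[[1]], 1L), sample(consensus[[2]], 1L), "L")
      tri_codons <- vapply(tri, sample_codon, character(1),
                           table = aa_codons)
      strpos <- sample(1:3, 1L)
      nb <- pick_breaking_neighbour(tri_codons[strpos], strpos, consensus)
      while (is.null(nb)) {
        tri_codons[strpos] <- sample_codon(tri[strpos], aa_codons)
        nb <- pick_breaking_neighbour(tri_codons[strpos], strpos, consensus)
      }
      mt_tri <- tri
      mt_tri[strpos] <- unname(Biostrings::GENETIC_CODE[nb$codon])
      variant <- list(strpos = strpos, offset = nb$offset,
                      coding_ref = nb$ref, coding_alt = nb$alt,
                      wt_tri = paste(tri, collapse = ""),
                      mt_tri = paste(mt_tri, collapse = ""),
                      pass = role != "decoy_failqc")
    } else if (role == "gof") {
      mt <- c(sample(consensus[[1]], 1L), sample(consensus[[2]], 1L), "L")
      mt_codons <- vapply(mt, sample_codon, character(1), table = aa_codons)
      strpos <- sample(1:3, 1L)
      nb <- pick_breaking_neighbour(mt_codons[strpos], strpos, consensus)
      while (is.null(nb)) {
        mt_codons[strpos] <- sample_codon(mt[strpos], aa_codons)
        nb <- pick_breaking_neighbour(mt_codons[strpos], strpos, consensus)
      }
      tri <- mt
      tri[strpos] <- unname(Biostrings::GENETIC_CODE[nb$codon])
      tri_codons <- mt_codons
      tri_codons[strpos] <- nb$codon
      # genome carries the (non-canonical) wild type; the variant restores
      # the canonical mutant codon
      variant <- list(strpos = strpos, offset = nb$offset,
                      coding_ref = nb$alt, coding_alt = nb$ref,
                      wt_tri = paste(tri, collapse = ""),
                      mt_tri = paste(mt, collapse = ""), pass = TRUE)
    } else if (role == "decoy_synonymous") {
      tri <- c(sample(consensus[[1]], 1L), sample(consensus[[2]], 1L), "L")
      tri_codons <- vapply(tri, sample_codon, character(1),
                           table = aa_codons)
      tri_codons[3] <- "CTG"  # Leu with synonymous third-base neighbours
      alt3 <- sample(c("A", "C", "T"), 1L)
      variant <- list(strpos = 3L, offset = 2L, coding_ref = "G",
                      coding_alt = alt3,
                      wt_tri = paste(tri, collapse = ""),
                      mt_tri = paste(tri, collapse = ""), pass = TRUE)
    } else if (role == "decoy_outside") {
      tri <- c(sample(consensus[[1]], 1L), sample(consensus[[2]], 1L), "L")
      tri_codons <- vapply(tri, sample_codon, character(1),
                           table = aa_codons)
      variant <- list(outside = TRUE, pass = TRUE,
                      wt_tri = paste(tri, collapse = ""))
    } else {
      tri <- sample(AA_STANDARD20, 3L, replace = TRUE)
      tri_codons <- vapply(tri, sample_codon, character(1),
                           table = aa_codons)
    }

    body <- c("M", sample(AA_STANDARD20, P - 4L, replace = TRUE), tri)
    codons <- c(vapply(body[seq_len(P - 3L)], sample_codon, character(1),
                       table = aa_codons),
                tri_codons, sample(stops, 1L))
    cds <- paste(codons, collapse = "")
    L <- nchar(cds)
    if (!is.null(variant) && isTRUE(variant$outside)) {
      s <- sample(seq(3L, 3L * (P - 3L) - 1L), 1L)
      coding_ref <- substr(cds, s + 1L, s + 1L)
      variant$spliced_pos <- s
      variant$coding_ref <- coding_ref
      variant$coding_alt <- sample(setdiff(c("A", "C", "G", "T"),
                                           coding_ref), 1L)
      variant$mt_tri <- ""
    } else if (!is.null(variant)) {
      variant$spliced_pos <- 3L * (P - 3L) + (variant$strpos - 1L) * 3L +
        variant$offset
    }
    breaks <- if (k > 1L) sort(sample(seq_len(L - 1L), k - 1L)) else integer()
    lens <- diff(c(0L, breaks, L))
    genes[[i]] <- list(role = role, strand = strand, P = P, cds = cds,
                       protein = paste(body, collapse = ""),
                       exon_lens = lens, variant = variant)
  }

  # genomic layout: two toy chromosomes, genes placed in order with random
  # intergenic gaps and introns
  chroms <- c("1", "2")
  cursor <- stats::setNames(sample(100:300, length(chroms), replace = TRUE),
                            chroms)
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    chrom <- chroms[(i - 1L) %% length(chroms) + 1L]
    k <- length(g$exon_lens)
    # ascending genomic segments: spliced order for +, reversed for -
    glens <- if (g$strand == "-") rev(g$exon_lens) else g$exon_lens
    segs <- matrix(NA_integer_, k, 2L,
                   dimnames = list(NULL, c("start", "end")))
    at <- cursor[chrom] + sample(100:500, 1L)
    for (j in seq_len(k)) {
      segs[j, ] <- c(at, at + glens[j])
      at <- segs[j, 2L] + if (j < k) sample(30:200, 1L) else 0L
    }
    cursor[chrom] <- at
    genes[[i]]$chrom <- chrom
    genes[[i]]$segments <- segs
    genes[[i]]$gene <- sprintf("G%03d", i)
    genes[[i]]$transcript_id <- sprintf("TX%03d", i)
  }

  # chromosome backgrounds (independent stream), exon bases written on top
  set.seed(derive_seed(cfg$seed, 2L))
  chrom_len <- pmax(cursor + 200L, 10000L)
  chrom_seq <- lapply(chrom_len, function(n) {
    sample(c("A", "C", "G", "T"), n, replace = TRUE)
  })
  for (g in genes) {
    plus <- strsplit(if (g$strand == "-") revcomp(g$cds) else g$cds, "")[[1]]
    ofs <- 0L
    for (j in seq_len(nrow(g$segments))) {
      w <- g$segments[j, 2L] - g$segments[j, 1L]
      chrom_seq[[g$chrom]][seq(g$segments[j, 1L] + 1L,
                               g$segments[j, 2L])] <-
        plus[seq(ofs + 1L, ofs + w)]
      ofs <- ofs + w
    }
  }

  # variant genomic coordinates
  set.seed(derive_seed(cfg$seed, 3L))  # allele-frequency stream
  vrows <- list()
  truth <- list()
  vi <- 0L
  for (g in genes) {
    v <- g$variant
    if (is.null(v)) next
    vi <- vi + 1L
    gmap <- splice_positions(g$segments, g$strand)
    gpos <- gmap[v$spliced_pos + 1L]
    ref_plus <- if (g$strand == "-") comp_base(v$coding_ref) else
      v$coding_ref
    alt_plus <- if (g$strand == "-") comp_base(v$coding_alt) else
      v$coding_alt
    vrows[[vi]] <- data.frame(
      chrom = g$chrom, pos = gpos, id = sprintf("rs%06d", vi),
      ref = ref_plus, alt = alt_plus,
      filter = if (v$pass) "PASS" else "RF",
      af = stats::runif(1, 1e-6, 1e-4), stringsAsFactors = FALSE)
    truth[[vi]] <- data.frame(
      chrom = g$chrom, pos = gpos + 1L, ref = ref_plus, alt = alt_plus,
      gene = g$gene, transcript_id = g$transcript_id,
      planted_class = if (g$role == "decoy_synonymous") "decoy_synonymous"
        else if (g$role == "decoy_outside") "decoy_outside"
        else if (g$role == "decoy_failqc") "decoy_failqc" else g$role,
      expected_wt_tri = v$wt_tri, expected_mt_tri = v$mt_tri,
      stringsAsFactors = FALSE)
  }

  paths <- c(genome = file.path(dir, "genome.fa"),
             transcripts = file.path(dir, "transcripts.tsv"),
             variants = file.path(dir, "variants.vcf"),
             localization = file.path(dir, "localization.tsv"),
             gene_context = file.path(dir, "gene_context.tsv"),
             pts1_genes = file.path(dir, "pts1_genes.txt"),
             truth = file.path(dir, "truth.tsv"))

  gset <- Biostrings::DNAStringSet(vapply(chrom_seq, paste, character(1),
                                          collapse = ""))
  names(gset) <- names(chrom_seq)
  Biostrings::writeXStringSet(gset, paths["genome"], width = 80L)

  tx <- do.call(rbind, lapply(genes, function(g) {
    data.frame(transcript_id = g$transcript_id, gene = g$gene,
               chromosome = g$chrom, strand = g$strand,
               cds_segments = format_cds_segments(g$segments),
               status = "Public", protein_seq = g$protein,
               stringsAsFactors = FALSE)
  }))
  write_tsv(tx, paths["transcripts"])

  write_vcf_rows <- function(rows, path, contigs) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##FILTER=<ID=PASS,Description=\"All filters passed\">",
      "##FILTER=<ID=RF,Description=\"Failed random forest quality model\">",
      paste0("##INFO=<ID=AF,Number=A,Type=Float,",
             "Description=\"Allele frequency\">"),
      paste0("##INFO=<ID=nhomalt,Number=A,Type=Integer,",
             "Description=\"Homozygous alternate count\">"),
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              unname(contigs)),
      paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            sep = "\t")), con)
    if (length(rows)) {
      df <- do.call(rbind, rows)
      df <- df[order(df$chrom, df$pos, df$ref, df$alt), , drop = FALSE]
      site <- paste(df$chrom, df$pos, df$ref, sep = ":")
      for (s in unique(site)) {
        d <- df[site == s, , drop = FALSE]
        writeLines(paste(
          d$chrom[1], d$pos[1] + 1L, d$id[1], d$ref[1],
          paste(d$alt, collapse = ","), ".",
          # a multi-allelic line carries one FILTER; fail only if all fail
          if (any(d$filter == "PASS")) "PASS" else d$filter[1],
          paste0("AF=", paste(sprintf("%.6g", d$af), collapse = ","),
                 ";nhomalt=", paste(rep("0", nrow(d)), collapse = ",")),
          sep = "\t"), con)
      }
    }
    invisible(path)
  }
  write_vcf_rows(vrows, paths["variants"], vapply(chrom_seq, length,
                                                  integer(1)))

  filler_locs <- c("Nucleus", "Mitochondrion", "Secreted",
                   "Cytoplasm;Nucleus", "Cytoplasm;Cytoskeleton")
  set.seed(derive_seed(cfg$seed, 4L))  # annotation stream
  loc <- do.call(rbind, lapply(genes, function(g) {
    kw <- switch(g$role,
                 lof = , decoy_synonymous = , decoy_outside = ,
                 decoy_failqc = "Peroxisome",
                 gof = "Cytoplasm",
                 filler = sample(filler_locs, 1L))
    data.frame(protein_id = g$transcript_id, keywords = kw,
               isoform_specific = FALSE, stringsAsFactors = FALSE)
  }))
  write_tsv(loc, paths["localization"])

  ctx <- do.call(rbind, lapply(genes, function(g) {
    host <- g$role %in% c("lof", "decoy_synonymous", "decoy_outside",
                          "decoy_failqc")
    data.frame(gene = g$gene, omim_flag = host,
               length = g$P,
               tmd_flag = if (g$role == "filler") sample(c(TRUE, FALSE), 1L)
                          else FALSE,
               manual_include = FALSE, stringsAsFactors = FALSE)
  }))
  write_tsv(ctx, paths["gene_context"])

  pts1_genes <- vapply(genes[vapply(genes, function(g)
    g$role %in% c("lof", "decoy_synonymous", "decoy_outside",
                  "decoy_failqc"), logical(1))],
    function(g) g$gene, character(1))
  writeLines(pts1_genes, paths["pts1_genes"])

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gene = character(),
               transcript_id = character(), planted_class = character(),
               expected_wt_tri = character(), expected_mt_tri = character(),
               stringsAsFactors = FALSE)
  truth_df <- truth_df[order(truth_df$chrom, truth_df$pos, truth_df$alt), ,
                       drop = FALSE]
  rownames(truth_df) <- NULL
  write_tsv(truth_df, paths["truth"])

  invisible(list(paths = paths, truth = truth_df))
}

#' Packaged affinity fixture
#'
#' The eleven experimentally tested wild-type/mutant tripeptide pairs with
#' their measured apparent affinities (on the published 1e-6 scale), printed
#' log affinity ratios, predicted binding-energy changes, predictor score
#' differences and experimental outcome labels
#' (\code{loss}/\code{gain}/\code{no_change} by localization change).
#'
#' @return a data.frame of 11 affinity records ([read_affinity_tsv()]
#'   layout).
#' @export
table3_fixture <- function() {
  read_affinity_tsv(system.file("extdata", "table3_affinity.tsv",
                                package = "pts1var", mustWork = TRUE))
}
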