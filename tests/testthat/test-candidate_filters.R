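make_change <- function(gene, tx, wt, mt, pass = TRUE, plen = 400L,
                        pos = 100L) {
  data.frame(transcript_id = tx, gene = gene, chrom = "1", pos = pos,
             ref = "A", alt = "G", wt_tri = wt, mt_tri = mt,
             codon_index = 3L, consequence = "missense",
             pass_exome = pass, pass_genome = FALSE, af = 1e-5,
             nhomalt = 0L, rsid = paste0("rs", pos),
             protein_length = plen,
             last12 = paste0(strrep("A", 9), wt), stringsAsFactors = FALSE)
}

make_ann <- function(ids, kw, iso = FALSE) {
  data.frame(protein_id = ids, keywords = kw, isoform_specific = iso,
             stringsAsFactors = FALSE)
}

make_ctx <- function(genes, omim = TRUE, len = 400L, tmd = FALSE,
                     manual = FALSE) {
  data.frame(gene = genes, omim_flag = omim, length = len, tmd_flag = tmd,
             manual_include = manual, stringsAsFactors = FALSE)
}

test_that("canonical annotations propagate to unannotated isoforms", {
  tx <- data.frame(transcript_id = c("T1", "T2", "T3"),
                   gene = c("G1", "G1", "G1"),
                   protein_length = c(500L, 300L, 200L),
                   stringsAsFactors = FALSE)
  ann <- make_ann("T1", "Cytoplasm")
  out <- propagate_annotations(ann, tx)
  expect_setequal(out$protein_id, c("T1", "T2", "T3"))
  expect_true(all(out$keywords == "Cytoplasm"))
  # an isoform with its own annotation keeps it
  ann2 <- rbind(make_ann("T1", "Cytoplasm"),
                make_ann("T2", "Nucleus", iso = TRUE))
  out2 <- propagate_annotations(ann2, tx)
  expect_equal(out2$keywords[out2$protein_id == "T2"], "Nucleus")
  # empty annotation table leaves everything unannotated
  out3 <- propagate_annotations(ann[0, ], tx)
  expect_equal(nrow(out3), 0L)
  # an isoform-specific canonical annotation never propagates
  ann4 <- make_ann("T1", "Cytoplasm", iso = TRUE)
  out4 <- propagate_annotations(ann4, tx)
  expect_equal(out4$protein_id, "T1")
})

test_that("the loss-of-function cascade applies its five stages in order", {
  pts1_genes <- c("EHH", "DUAL", "NOM")
  changes <- rbind(
    make_change("EHH", "T1", "SKL", "GKL", pos = 1),     # retained
    make_change("DUAL", "T2", "SKL", "GKL", pos = 2),    # dual localization
    make_change("EHH", "T3", "SKL", "AKL", pos = 3),     # MT still canonical
    make_change("OFF", "T4", "SKL", "GKL", pos = 4),     # not curated
    make_change("NOM", "T5", "SKL", "GKL", pos = 5),     # no disease link
    make_change("EHH", "T6", "SKL", "GKL", pass = FALSE, pos = 6))
  ann <- rbind(make_ann("T1", "Peroxisome"),
               make_ann("T2", "Peroxisome;Cytoplasm"),
               make_ann("T3", "Peroxisome"),
               make_ann("T4", "Peroxisome"),
               make_ann("T5", "Peroxisome"),
               make_ann("T6", "Peroxisome"))
  ctx <- rbind(make_ctx("EHH"), make_ctx("DUAL"),
               make_ctx("NOM", omim = FALSE), make_ctx("OFF"))
  fo <- lof_cascade(changes, ann, ctx, pts1_genes)
  expect_equal(fo$retained$transcript_id, "T1")
  log <- fo$exclusion_log
  expect_equal(log$stage[log$transcript_id == "T2"],
               "peroxisome_exclusive_localization")
  expect_equal(log$stage[log$transcript_id == "T3"],
               "canonical_wt_noncanonical_mt")
  expect_equal(log$stage[log$transcript_id == "T4"], "curated_pts1_gene")
  expect_equal(log$stage[log$transcript_id == "T5"], "omim_disease")
  expect_equal(log$stage[log$transcript_id == "T6"], "quality_pass")
  # telescoping counts and conservation
  expect_equal(fo$stage_counts$n_in[-1],
               fo$stage_counts$n_out[-nrow(fo$stage_counts)])
  expect_equal(nrow(fo$retained) + nrow(log), nrow(changes))
})

test_that("a manual-include whitelist overrides the dual-localization rule", {
  changes <- make_change("AGXTlike", "T1", "SKL", "GKL")
  ann <- make_ann("T1", "Peroxisome;Mitochondrion")
  ctx_plain <- make_ctx("AGXTlike")
  fo1 <- lof_cascade(changes, ann, ctx_plain, "AGXTlike")
  expect_equal(nrow(fo1$retained), 0L)
  ctx_manual <- make_ctx("AGXTlike", manual = TRUE)
  fo2 <- lof_cascade(changes, ann, ctx_manual, "AGXTlike")
  expect_equal(nrow(fo2$retained), 1L)
})

test_that("keyword matching is exact-token and case-insensitive", {
  changes <- make_change("G1", "T1", "SKL", "GKL")
  ctx <- make_ctx("G1")
  # "Cytoplasmic vesicle" must not count as "Cytoplasm"
  fo <- lof_cascade(changes, make_ann("T1", "peroxisome;Cytoplasmic vesicle"),
                    ctx, "G1")
  expect_equal(nrow(fo$retained), 1L)
  fo2 <- lof_cascade(changes, make_ann("T1", "Peroxisome; cytoplasm "),
                     ctx, "G1")
  expect_equal(nrow(fo2$retained), 0L)
})

test_that("the gain-of-function cascade mirrors its published patterns", {
  m <- example_pts1_matrix()
  changes <- rbind(
    make_change("PPP4R4like", "T1", "SNP", "SNL", plen = 873L, pos = 1),
    make_change("GLTPlike", "T2", "YKL", "SKL", plen = 209L, pos = 2),
    make_change("BIG", "T3", "TKL", "SKL", plen = 1200L, pos = 3),
    make_change("NUC", "T4", "TKL", "SKL", plen = 300L, pos = 4))
  sc <- score_changes(changes, m)
  # the first record mirrors a published pattern whose categories come from
  # the external predictor, not the bundled example matrix: supply them
  sc$wt_category[1] <- "Not targeted"
  sc$mt_category[1] <- "Targeted"
  ann <- rbind(make_ann("T1", "Cytoplasm"), make_ann("T2", "Cytoplasm"),
               make_ann("T3", "Cytoplasm"), make_ann("T4", "Nucleus"))
  ctx <- rbind(make_ctx("PPP4R4like", len = 873L),
               make_ctx("GLTPlike", len = 209L),
               make_ctx("BIG", len = 1200L), make_ctx("NUC", len = 300L))
  fo <- gof_cascade(sc, ann, ctx)
  expect_setequal(fo$retained$gene, c("PPP4R4like", "GLTPlike"))
  log <- fo$exclusion_log
  expect_equal(log$stage[log$gene == "BIG"], "protein_size_and_tmd")
  expect_equal(log$stage[log$gene == "NUC"],
               "cytoplasm_exclusive_localization")
  # twilight-to-targeted changes pass the category stage
  expect_true(all(sc$wt_category[sc$gene == "GLTPlike"] == "Twilight zone"))
  expect_true(all(sc$mt_category[sc$gene == "GLTPlike"] == "Targeted"))
})

test_that("only the longest transcript of a gene survives, ties by id", {
  m <- example_pts1_matrix()
  changes <- rbind(
    make_change("G1", "TB", "TKL", "SKL", plen = 500L, pos = 1),
    make_change("G1", "TA", "TKL", "SKL", plen = 500L, pos = 1),
    make_change("G1", "TC", "TKL", "SKL", plen = 300L, pos = 1))
  sc <- score_changes(changes, m)
  ann <- make_ann(c("TA", "TB", "TC"), "Cytoplasm")
  ctx <- make_ctx("G1", len = 500L)
  fo <- gof_cascade(sc, ann, ctx)
  expect_equal(fo$retained$transcript_id, "TA")
  expect_equal(sort(fo$exclusion_log$stage), rep("longest_transcript_per_gene", 2))
})

test_that("retained sets are order-invariant and exclusion sets conserved", {
  set.seed(109)
  m <- example_pts1_matrix()
  changes <- do.call(rbind, lapply(1:12, function(i) {
    make_change(sprintf("G%d", i), sprintf("T%d", i),
                sample(c("SKL", "TKL", "SNP"), 1),
                sample(c("GKL", "SKL", "SNL"), 1),
                pass = sample(c(TRUE, FALSE), 1),
                plen = sample(c(300L, 1200L), 1), pos = i)
  }))
  sc <- score_changes(changes, m)
  ann <- make_ann(sprintf("T%d", 1:12),
                  sample(c("Cytoplasm", "Peroxisome", "Cytoplasm;Nucleus"),
                         12, replace = TRUE))
  ctx <- make_ctx(sprintf("G%d", 1:12),
                  omim = sample(c(TRUE, FALSE), 12, replace = TRUE))
  fo1 <- gof_cascade(sc, ann, ctx)
  shuffle <- sample(nrow(sc))
  fo2 <- gof_cascade(sc[shuffle, ], ann, ctx)
  key <- function(d) sort(paste(d$gene, d$transcript_id, d$pos))
  expect_equal(key(fo1$retained), key(fo2$retained))
  expect_equal(fo1$stage_counts, fo2$stage_counts)
  expect_equal(nrow(fo1$retained) + nrow(fo1$exclusion_log), nrow(sc))
})

test_that("growing an exclusion keyword set never increases retention", {
  changes <- rbind(make_change("G1", "T1", "SKL", "GKL"),
                   make_change("G2", "T2", "SKL", "GKL", pos = 101L))
  ann <- rbind(make_ann("T1", "Peroxisome"),
               make_ann("T2", "Peroxisome;Lysosome"))
  ctx <- rbind(make_ctx("G1"), make_ctx("G2"))
  base <- lof_cascade(changes, ann, ctx, c("G1", "G2"))
  expect_equal(nrow(base$retained), 2L)
  # simulate a wider exclusion list by adding the keyword to the records
  with_kw <- ann
  with_kw$keywords[1] <- "Peroxisome;Cytoplasm"
  narrowed <- lof_cascade(changes, with_kw, ctx, c("G1", "G2"))
  expect_lte(nrow(narrowed$retained), nrow(base$retained))
})

test_that("records lacking context or annotation fail as unannotated", {
  changes <- make_change("GHOST", "T1", "SKL", "GKL")
  ann0 <- data.frame(protein_id = character(), keywords = character(),
                     isoform_specific = logical(), stringsAsFactors = FALSE)
  ctx0 <- data.frame(gene = character(), omim_flag = logical(),
                     length = integer(), tmd_flag = logical(),
                     manual_include = logical(), stringsAsFactors = FALSE)
  fo <- lof_cascade(changes, ann0, ctx0, "GHOST")
  expect_equal(nrow(fo$retained), 0L)
  expect_equal(fo$exclusion_log$reason, "unannotated")
})
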