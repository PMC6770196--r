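#' Log10 ratio of wild-type over mutant apparent affinity
#'
#' \code{log10(ka_wt / ka_mt)}: positive values mean the mutant binds the
#' receptor more weakly than the wild type, negative values that it binds
#' more strongly. Apparent affinity values are used on whatever common scale
#' they are reported on (the ratio is scale-invariant). Non-positive or
#' missing inputs (non-analyzable fits) are a domain error, never
#' zero-filled.
#'
#' @param ka_wt,ka_mt strictly positive apparent association strengths.
#' @return numeric vector of log10 ratios.
#' @export
log_ka_ratio <- function(ka_wt, ka_mt) {
  ka_wt <- as.numeric(ka_wt)
  ka_mt <- as.numeric(ka_mt)
  if (length(ka_wt) != length(ka_mt)) stop("inputs must have equal length")
  if (anyNA(ka_wt) || anyNA(ka_mt) || any(ka_wt <= 0) || any(ka_mt <= 0)) {
    stop("affinity values must be strictly positive and present; ",
         "flag non-analyzable fits instead of passing them")
  }
  log10(ka_wt / ka_mt)
}

#' Pearson correlation with p-value and confidence interval
#'
#' Product-moment correlation with a two-sided p-value from the t-transform
#' on n - 2 degrees of freedom and a confidence interval from the Fisher
#' z-transform, as implemented by [stats::cor.test()].
#'
#' @param xs,ys equal-length numeric vectors, n >= 3, finite, each with
#'   nonzero variance.
#' @param conf_level confidence level (default 0.95).
#' @return an object of class \code{pts1_cor}: list with \code{r},
#'   \code{p_value}, \code{ci_low}, \code{ci_high}, \code{n},
#'   \code{conf_level}.
#' @export
pearson_with_ci <- function(xs, ys, conf_level = 0.95) {
  xs <- as.numeric(xs)
  ys <- as.numeric(ys)
  if (length(xs) != length(ys)) stop("xs and ys must have equal length")
  if (length(xs) < 3L) stop("need at least 3 paired observations")
  if (!all(is.finite(xs)) || !all(is.finite(ys))) {
    stop("inputs must be finite")
  }
  if (stats::var(xs) == 0 || stats::var(ys) == 0) {
    stop("undefined correlation: an input has zero variance")
  }
  ct <- stats::cor.test(xs, ys, method = "pearson",
                        conf.level = conf_level)
  structure(list(r = unname(ct$estimate), p_value = ct$p.value,
                 ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                 n = length(xs), conf_level = conf_level),
            class = "pts1_cor")
}

#' @export
print.pts1_cor <- function(x, digits = 3, ...) {
  cat(sprintf("Pearson's r = %.*f (%d%% CI %.*f to %.*f), p = %s, n = %d\n",
              digits, x$r, round(100 * x$conf_level), digits, x$ci_low,
              digits, x$ci_high, format(signif(x$p_value, 3)), x$n))
  invisible(x)
}

#' Concordance of predicted binding-energy changes with experiment
#'
#' Turns each predicted change in binding free energy into a three-way label
#' using a significance band: \code{loss} when \code{ddg >
#' significance}, \code{gain} when \code{ddg < -significance}, otherwise
#' \code{no_change}; a verdict is correct when the label equals the
#' experimental outcome. Records lacking an energy value are skipped with a
#' warning and reduce n.
#'
#' @param records data.frame with columns \code{ddg_bind} (kcal/mol,
#'   positive = weakened binding) and \code{experimental_outcome}
#'   (\code{loss}/\code{gain}/\code{no_change}); extra identifying columns
#'   are carried through to the verdict table.
#' @param significance half-width of the no-change band in kcal/mol
#'   (default 0.5).
#' @return list with \code{count_correct}, \code{n} and \code{verdicts} (the
#'   input records plus \code{predicted} and \code{correct}).
#' @export
foldx_concordance <- function(records, significance = 0.5) {
  stopifnot(all(c("ddg_bind", "experimental_outcome") %in% names(records)))
  missing_ddg <- is.na(records$ddg_bind)
  if (any(missing_ddg)) {
    warning(sum(missing_ddg), " record(s) without ddG skipped")
    records <- records[!missing_ddg, , drop = FALSE]
  }
  predicted <- ifelse(records$ddg_bind > significance, "loss",
                      ifelse(records$ddg_bind < -significance, "gain",
                             "no_change"))
  verdicts <- records
  verdicts$predicted <- predicted
  verdicts$correct <- predicted == records$experimental_outcome
  list(count_correct = sum(verdicts$correct), n = nrow(verdicts),
       verdicts = verdicts)
}

#' Concordance of categorical targeting predictions with experiment
#'
#' The predicted direction follows the category change between the wild type
#' and the mutant on the ordered scale \code{Not targeted < Twilight zone <
#' Targeted}: a rise predicts \code{gain}, a fall predicts \code{loss},
#' identical categories predict \code{no_change}. A verdict is correct when
#' the predicted direction equals the experimental outcome. Categories are
#' supplied by the caller (e.g. from a published prediction table); records
#' with a missing category are skipped with a warning.
#'
#' @param records data.frame with columns \code{wt_category},
#'   \code{mt_category} and \code{experimental_outcome}.
#' @return list with \code{count_correct}, \code{n} and \code{verdicts}.
#' @export
predictor_concordance <- function(records) {
  need <- c("wt_category", "mt_category", "experimental_outcome")
  stopifnot(all(need %in% names(records)))
  rank <- function(cat) match(cat, CATEGORY_LEVELS)
  missing <- is.na(records$wt_category) | is.na(records$mt_category)
  if (any(missing)) {
    warning(sum(missing), " record(s) without categories skipped")
    records <- records[!missing, , drop = FALSE]
  }
  delta <- rank(records$mt_category) - rank(records$wt_category)
  predicted <- ifelse(delta > 0, "gain", ifelse(delta < 0, "loss",
                                                "no_change"))
  verdicts <- records
  verdicts$predicted <- predicted
  verdicts$correct <- predicted == records$experimental_outcome
  list(count_correct = sum(verdicts$correct), n = nrow(verdicts),
       verdicts = verdicts)
}

#' Read an affinity table
#'
#' TSV with columns \code{gene}, \code{wt_tri}, \code{mt_tri}, \code{ka_wt},
#' \code{ka_mt} (apparent affinities on a common scale; \code{NA} marks a
#' non-analyzable fit), \code{log_ka_ratio} (as printed in the source),
#' \code{ddg_bind} (kcal/mol), \code{score_difference} (MT - WT predictor
#' score) and \code{experimental_outcome}.
#'
#' @param path TSV path.
#' @return data.frame of affinity records.
#' @export
read_affinity_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("gene", "wt_tri", "mt_tri", "ka_wt", "ka_mt", "log_ka_ratio",
            "ddg_bind", "score_difference", "experimental_outcome")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("affinity table missing column(s): ", paste(miss, collapse = ", "))
  }
  bad <- !is.na(df$ka_wt) & df$ka_wt <= 0 |
    !is.na(df$ka_mt) & df$ka_mt <= 0
  if (any(bad)) {
    stop("non-positive affinity value(s); use NA to flag non-analyzable ",
         "fits")
  }
  df
}

#' Write an affinity table
#'
#' @param records affinity data.frame ([read_affinity_tsv()] layout).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_affinity_tsv <- function(records, path) {
  write_tsv(records, path)
}

#' Full concordance report for an affinity table
#'
#' Recomputes the log affinity ratios from the measured affinity columns,
#' correlates them with the predicted binding-energy changes and with the
#' predictor score differences, counts band-rule concordance, and returns
#' scatter-ready tables.
#'
#' @param records affinity data.frame; rows with missing affinities are
#'   excluded from the correlations.
#' @param significance band half-width for [foldx_concordance()].
#' @return list with \code{log_ratios}, \code{cor_ddg} and \code{cor_score}
#'   (\code{pts1_cor}), \code{foldx} (concordance list), \code{scatter_ddg}
#'   and \code{scatter_score} (data.frames \code{x}, \code{y}, \code{label},
#'   \code{group}).
#' @export
concordance_report <- function(records, significance = 0.5) {
  ok <- !is.na(records$ka_wt) & !is.na(records$ka_mt)
  r <- records[ok, , drop = FALSE]
  lr <- log_ka_ratio(r$ka_wt, r$ka_mt)
  cor_ddg <- pearson_with_ci(r$ddg_bind, lr)
  cor_score <- pearson_with_ci(r$score_difference, lr)
  fx <- foldx_concordance(records, significance)
  lab <- paste0(r$gene, " ", r$wt_tri, ">", r$mt_tri)
  list(log_ratios = data.frame(gene = r$gene, wt_tri = r$wt_tri,
                               mt_tri = r$mt_tri, log_ka_ratio = lr,
                               stringsAsFactors = FALSE),
       cor_ddg = cor_ddg, cor_score = cor_score, foldx = fx,
       scatter_ddg = data.frame(x = r$ddg_bind, y = lr, label = lab,
                                group = r$experimental_outcome,
                                stringsAsFactors = FALSE),
       scatter_score = data.frame(x = r$score_difference, y = lr,
                                  label = lab,
                                  group = r$experimental_outcome,
                                  stringsAsFactors = FALSE))
}
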