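.FIXTURE_FILE <- "glycemic_bc_instruments.tsv"
.FIXTURE_MD5 <- "1cca17a256905b38ac1d2ebe77052b1d"
.FIXTURE_BLOCKS <- list(
  FG = c("OncoArray" = 19L, "ATLAS-CGEMS" = 19L, "ATLAS-GEEA" = 9L, "ATLAS-GEEAB" = 9L),
  FI = c("OncoArray" = 4L, "ATLAS-CGEMS" = 3L)
)

#' Load the packaged glycemic-traits / breast-cancer instrument fixture
#'
#' The package ships the per-variant summary associations used as genetic
#' instruments for fasting glucose (FG, mmol/L) and fasting insulin (FI,
#' ln-pmol/L) against breast cancer: MAGIC exposure effects paired with
#' outcome odds ratios from four breast-cancer sources — BCAC OncoArray and
#' ATLAS CGEMS, GEE age-adjusted (GEEA) and GEE age+BMI-adjusted (GEEAB).
#' Outcome ORs with 95% CIs are converted to log-odds and SE on load via
#' [or_ci_to_log()]; exposure standard errors, not printed in the source
#' table, are back-derived from the effect size and p-value (they are
#' carried in the data model but unused by the estimators).
#'
#' @return nested list: `fixture[[trait]][[dataset]]` is a list with
#'   elements `exposure` and `outcome`, both [assoc_panel()] objects. Block
#'   sizes are FG 19/19/9/9 and FI 4/3 (38 and 6 unique rsids).
#' @export
load_fixture <- function() {
  path <- system.file("extdata", .FIXTURE_FILE, package = "gtmr")
  if (path == "" || !file.exists(path))
    stop("integrity error: packaged fixture not found", call. = FALSE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .FIXTURE_MD5))
    stop("integrity error: fixture checksum mismatch (", md5, ")", call. = FALSE)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  out <- list()
  for (trait in names(.FIXTURE_BLOCKS)) {
    out[[trait]] <- list()
    for (ds in names(.FIXTURE_BLOCKS[[trait]])) {
      b <- raw[raw$trait == trait & raw$dataset == ds, , drop = FALSE]
      if (nrow(b) != .FIXTURE_BLOCKS[[trait]][[ds]])
        stop("integrity error: fixture block ", trait, "/", ds, " has ",
             nrow(b), " rows, expected ", .FIXTURE_BLOCKS[[trait]][[ds]],
             call. = FALSE)
      # exposure SE back-derived from |beta| and two-sided p (NOME: unused downstream)
      se_x <- abs(b$exp_beta) / stats::qnorm(b$exp_pval / 2, lower.tail = FALSE)
      exposure <- assoc_panel(data.frame(
        rsid = b$rsid, chrom = b$chrom, pos = b$pos, ref = b$ref, alt = b$alt,
        eaf = b$eaf, beta = b$exp_beta, se = se_x, pval = b$exp_pval,
        stringsAsFactors = FALSE
      ), trait = trait, dataset = ds)
      conv <- or_ci_to_log(b$out_or, b$out_ci_low, b$out_ci_high)
      outcome <- assoc_panel(data.frame(
        rsid = b$rsid, chrom = b$chrom, pos = b$pos, ref = b$ref, alt = b$alt,
        eaf = b$eaf, beta = conv$beta, se = conv$se, pval = b$out_pval,
        stringsAsFactors = FALSE
      ), trait = "BC", dataset = ds)
      out[[trait]][[ds]] <- list(exposure = exposure, outcome = outcome)
    }
  }
  out
}

#' Harmonized instruments for one fixture block
#'
#' @param trait `"FG"` or `"FI"`.
#' @param dataset one of the fixture's outcome datasets for that trait.
#' @param fixture output of [load_fixture()]; reloaded if omitted.
#' @param palindrome_policy passed to [match_instruments()]. Default
#'   `"keep"`: the source table reports exposure and outcome on one curated
#'   strand, and its instrument set includes palindromic variants (e.g.
#'   rs7944584 T/A), so the same-strand assumption is the faithful one.
#' @return an `mr_instruments` data frame.
#' @export
fixture_instruments <- function(trait, dataset, fixture = NULL,
                                palindrome_policy = "keep") {
  if (is.null(fixture)) fixture <- load_fixture()
  if (is.null(fixture[[trait]]) || is.null(fixture[[trait]][[dataset]]))
    stop("configuration error: no fixture block for ", trait, "/", dataset,
         call. = FALSE)
  blk <- fixture[[trait]][[dataset]]
  match_instruments(blk$exposure, blk$outcome,
                    palindrome_policy = palindrome_policy)
}

#' Placeholder sensitivity-exclusion lists
#'
#' Named rsid sets for the sensitivity analyses that drop instruments at
#' loci with established direct breast-cancer pathways: `t2dm` (type 2
#' diabetes loci: MTNR1B, CDKN2B-AS1, ADCY5) and `whr` (visceral
#' obesity/waist-hip-ratio locus near PPP1R3B). These are synthetic
#' placeholder defaults chosen to exercise the exclusion machinery; the
#' definitive locus lists are a user decision and should be supplied
#' explicitly for substantive use.
#'
#' @return named list of character vectors of rsids.
#' @export
default_exclusions <- function() {
  list(t2dm = c("rs10830963", "rs2383208", "rs11708067"),
       whr = c("rs4240624"))
}

.resolve_exclusions <- function(exclusions, exclusion_lists) {
  if (is.null(exclusions)) return(character(0))
  if (length(exclusions) == 1L && exclusions %in% names(exclusion_lists))
    return(exclusion_lists[[exclusions]])
  if (length(exclusions) == 1L && !grepl("^rs", exclusions))
    stop("configuration error: unknown exclusion list '", exclusions, "'",
         call. = FALSE)
  as.character(exclusions)
}

.analysis_row <- function(label, trait, instruments, level, egger_orient,
                          egger_intercept_dist) {
  ivw <- mr_ivw(instruments, level = level)
  het <- if (nrow(instruments) >= 2L) cochran_q(instruments, beta = ivw$beta) else NULL
  egg <- if (nrow(instruments) >= 3L)
    mr_egger(instruments, level = level, orient = egger_orient,
             intercept_dist = egger_intercept_dist) else NULL
  r3 <- function(x) round(x, 3)
  row <- data.frame(
    analysis = label, trait = trait,
    n_snps = ivw$n_snps, n_rows = ivw$n_rows,
    or = r3(ivw$or_scale$or_value),
    or_ci_low = r3(ivw$or_scale$ci_low), or_ci_high = r3(ivw$or_scale$ci_high),
    ivw_p = ivw$pvalue,
    egger_intercept_or = if (is.null(egg)) NA_real_ else r3(egg$intercept_or_scale$or_value),
    egger_ci_low = if (is.null(egg)) NA_real_ else r3(egg$intercept_or_scale$ci_low),
    egger_ci_high = if (is.null(egg)) NA_real_ else r3(egg$intercept_or_scale$ci_high),
    egger_p = if (is.null(egg)) NA_real_ else egg$intercept_p,
    Q = if (is.null(het)) NA_real_ else het$Q,
    Q_df = if (is.null(het)) NA_integer_ else het$df,
    Q_p = if (is.null(het)) NA_real_ else het$pvalue,
    stringsAsFactors = FALSE
  )
  if (is.null(egg)) attr(row, "egger_note") <- "fewer than 3 instruments"
  attr(row, "ivw") <- ivw
  attr(row, "egger") <- egg
  attr(row, "het") <- het
  attr(row, "instruments") <- instruments
  row
}

#' Run the MR analysis for one trait/dataset block
#'
#' Harmonizes the block's exposure and outcome panels, then computes the
#' fixed-effect IVW estimate, Cochran's Q, and MR-Egger regression. Odds
#' ratios in the returned report row are rounded to 3 decimals; the
#' unrounded `mr_result` / `mr_egger_result` / `mr_het` objects and the
#' instrument table are attached as attributes `"ivw"`, `"egger"`, `"het"`,
#' `"instruments"`.
#'
#' @param trait,dataset fixture block selector.
#' @param exclusions optional: a character vector of rsids to drop, or the
#'   name of a list in `exclusion_lists`.
#' @param fixture output of [load_fixture()]; reloaded if omitted.
#' @param exclusion_lists named list of rsid sets; default
#'   [default_exclusions()].
#' @param level confidence level.
#' @param egger_orient orientation flag for [mr_egger()]. Default FALSE:
#'   the study's published pleiotropy intercepts are reproduced by the
#'   unoriented regression (see the methods vignette).
#' @param egger_intercept_dist `"t"` or `"normal"` for the intercept test.
#' @return one-row data frame (a report row); Egger columns are NA with an
#'   `"egger_note"` attribute when fewer than 3 instruments remain.
#' @export
run_dataset_analysis <- function(trait, dataset, exclusions = NULL,
                                 fixture = NULL,
                                 exclusion_lists = default_exclusions(),
                                 level = 0.95, egger_orient = FALSE,
                                 egger_intercept_dist = "t") {
  drop_ids <- .resolve_exclusions(exclusions, exclusion_lists)
  instr <- fixture_instruments(trait, dataset, fixture = fixture)
  instr <- instr[!(instr$rsid %in% drop_ids), , drop = FALSE]
  label <- if (length(drop_ids) > 0L && !is.null(exclusions) &&
               length(exclusions) == 1L && exclusions %in% names(exclusion_lists))
    paste0(dataset, " -", exclusions) else dataset
  .analysis_row(label, trait, instr, level, egger_orient, egger_intercept_dist)
}

#' Pooled MR analysis across all of a trait's outcome datasets
#'
#' Builds harmonized instruments for every fixture dataset of the trait,
#' applies any exclusions per set, pools them with [mr_pool()] and runs
#' Cochran's Q and MR-Egger on the pooled rows.
#'
#' @inheritParams run_dataset_analysis
#' @param dedup_policy pooling policy, see [mr_pool()]. The default
#'   `per_dataset_rows` reports unique-rsid counts (38 FG, 6 FI for the
#'   fixture) while letting each dataset's row enter the meta-analysis.
#' @return one-row report data frame labelled `"Pooled"`.
#' @export
run_pooled <- function(trait, exclusions = NULL, fixture = NULL,
                       exclusion_lists = default_exclusions(),
                       dedup_policy = "per_dataset_rows",
                       level = 0.95, egger_orient = FALSE,
                       egger_intercept_dist = "t") {
  if (is.null(fixture)) fixture <- load_fixture()
  datasets <- names(fixture[[trait]])
  if (length(datasets) < 2L)
    stop("usage error: pooling needs >= 2 dataset blocks", call. = FALSE)
  drop_ids <- .resolve_exclusions(exclusions, exclusion_lists)
  sets <- lapply(datasets, function(ds) {
    s <- fixture_instruments(trait, ds, fixture = fixture)
    s[!(s$rsid %in% drop_ids), , drop = FALSE]
  })
  sets <- sets[vapply(sets, nrow, integer(1)) > 0L]
  pooled_rows <- do.call(rbind, lapply(sets, as.data.frame))
  if (identical(dedup_policy, "first_dataset"))
    pooled_rows <- pooled_rows[!duplicated(pooled_rows$rsid), , drop = FALSE]
  label <- if (length(drop_ids) > 0L) "Pooled (with exclusions)" else "Pooled"
  .analysis_row(label, trait, pooled_rows, level, egger_orient,
                egger_intercept_dist)
}

#' Leave-one-out IVW sensitivity analysis
#'
#' Recomputes the IVW estimate omitting each instrument in turn; an
#' estimate that moves materially when one variant is dropped flags that
#' variant as influential.
#'
#' @inheritParams run_dataset_analysis
#' @return data frame with one row per omitted rsid: log-scale `beta`, `se`,
#'   `pvalue` and the OR-scale triple, ordered as the fixture block.
#' @export
leave_one_out <- function(trait, dataset, fixture = NULL, level = 0.95) {
  instr <- fixture_instruments(trait, dataset, fixture = fixture)
  if (nrow(instr) < 2L)
    stop("usage error: leave-one-out needs K >= 2", call. = FALSE)
  rows <- lapply(seq_len(nrow(instr)), function(k) {
    fit <- mr_ivw(instr[-k, , drop = FALSE], level = level)
    data.frame(omitted_rsid = instr$rsid[k], beta = fit$beta, se = fit$se,
               or = fit$or_scale$or_value, or_ci_low = fit$or_scale$ci_low,
               or_ci_high = fit$or_scale$ci_high, pvalue = fit$pvalue,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Export report rows (and optional scatter data) to TSV and JSON
#'
#' @param rows report rows from [run_dataset_analysis()] / [run_pooled()],
#'   either a list of one-row data frames or an already-bound data frame.
#' @param dir output directory, created if needed.
#' @param scatter when TRUE, also write a per-instrument `(X, Y, se_Y)`
#'   table for effect-scatter plotting, taken from the rows' attached
#'   instrument tables.
#' @param prefix file-name prefix (default `"mr_report"`).
#' @return invisible character vector of the files written.
#' @export
export_report <- function(rows, dir, scatter = FALSE, prefix = "mr_report") {
  if (is.data.frame(rows)) rows <- list(rows)
  if (length(rows) == 0L) stop("no report rows to export", call. = FALSE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  tsv <- file.path(dir, paste0(prefix, ".tsv"))
  utils::write.table(tab, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  json <- file.path(dir, paste0(prefix, ".json"))
  jsonlite::write_json(tab, json, auto_unbox = TRUE, digits = NA, na = "null")
  files <- c(tsv, json)
  if (scatter) {
    pts <- do.call(rbind, lapply(rows, function(r) {
      instr <- attr(r, "instruments")
      if (is.null(instr)) return(NULL)
      data.frame(analysis = r$analysis, trait = r$trait,
                 as.data.frame(instr)[c("rsid", "dataset", "X", "Y", "se_Y")],
                 stringsAsFactors = FALSE)
    }))
    sc <- file.path(dir, paste0(prefix, "_scatter.tsv"))
    utils::write.table(pts, sc, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, sc)
  }
  invisible(files)
}

#' Reproduce the full fixture study
#'
#' Runs every per-dataset analysis plus the pooled analysis for both traits
#' against the packaged fixture: 5 fasting-glucose rows (OncoArray, three
#' ATLAS sources, pooled) and 3 fasting-insulin rows.
#'
#' @param out_dir optional directory; when given, report TSV/JSON and the
#'   pooled scatter table are written there via [export_report()].
#' @param level confidence level.
#' @return list of report rows, invisibly bound copies written if
#'   `out_dir` is set.
#' @export
reproduce_study <- function(out_dir = NULL, level = 0.95) {
  fixture <- load_fixture()
  rows <- list()
  for (trait in names(fixture)) {
    for (ds in names(fixture[[trait]]))
      rows[[paste(trait, ds)]] <-
        run_dataset_analysis(trait, ds, fixture = fixture, level = level)
    rows[[paste(trait, "Pooled")]] <-
      run_pooled(trait, fixture = fixture, level = level)
  }
  if (!is.null(out_dir)) export_report(rows, out_dir, scatter = TRUE)
  rows
}
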