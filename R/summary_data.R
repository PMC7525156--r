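#' Association panels of GWAS summary statistics
#'
#' An association panel is a data frame of per-variant summary associations
#' with one trait in one dataset, with canonical columns `rsid`, `chrom`,
#' `pos`, `ref`, `alt`, `eaf`, `beta`, `se`, `pval`. Effects are per copy of
#' the `alt` allele: trait units per allele for an exposure (mmol/L fasting
#' glucose, ln-pmol/L fasting insulin), log-odds per allele for a binary
#' outcome.
#'
#' @param x data frame carrying the canonical columns.
#' @param trait trait label, one of `"FG"`, `"FI"`, `"BC"`.
#' @param dataset free-form dataset label (e.g. `"OncoArray"`).
#' @param validate reject rows that violate the type invariants? When TRUE,
#'   offending rows are dropped with a row-indexed warning.
#' @return A data frame of class `assoc_panel` with `trait` and `dataset`
#'   attributes; `rsid` is unique within a panel.
#' @details Invariants enforced per row: `eaf` in \[0, 1\], `se >= 0`
#'   (`se > 0` for outcome panels is enforced downstream where it matters),
#'   `pval` in (0, 1\], `ref != alt`. Duplicated rsids are an error: a panel
#'   represents one association per variant.
#' @export
assoc_panel <- function(x, trait = c("FG", "FI", "BC"), dataset = "unknown",
                        validate = TRUE) {
  trait <- match.arg(trait)
  req <- c("rsid", "chrom", "pos", "ref", "alt", "eaf", "beta", "se", "pval")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0L)
    stop("configuration error: panel is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  x <- as.data.frame(x)[req]
  for (col in c("pos", "eaf", "beta", "se", "pval")) {
    v <- x[[col]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad) > 0L)
        stop("parse error: non-numeric '", col, "' at row(s) ",
             paste(bad, collapse = ", "), call. = FALSE)
      x[[col]] <- vn
    }
  }
  if (validate) {
    ok <- !is.na(x$eaf) & x$eaf >= 0 & x$eaf <= 1 &
      !is.na(x$se) & x$se >= 0 &
      !is.na(x$pval) & x$pval > 0 & x$pval <= 1 &
      !is.na(x$beta) & x$ref != x$alt
    if (any(!ok)) {
      warning("rejected ", sum(!ok), " row(s) violating panel invariants: rows ",
              paste(which(!ok), collapse = ", "), call. = FALSE)
      x <- x[ok, , drop = FALSE]
    }
  }
  if (anyDuplicated(x$rsid))
    stop("duplicated rsid(s) in panel: ",
         paste(unique(x$rsid[duplicated(x$rsid)]), collapse = ", "),
         call. = FALSE)
  rownames(x) <- NULL
  structure(x, trait = trait, dataset = dataset,
            class = c("assoc_panel", "data.frame"))
}

#' @export
print.assoc_panel <- function(x, ...) {
  cat("<assoc_panel> trait=", attr(x, "trait"),
      " dataset=", attr(x, "dataset"),
      " variants=", nrow(x), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("... (", nrow(x) - 10L, " more rows)\n", sep = "")
  invisible(x)
}

#' Read an association panel from a tab-separated file
#'
#' Reads a TSV with a header row into an [assoc_panel()]. Files reporting
#' the outcome association as an odds ratio with a 95% confidence interval
#' (columns mapped to `or`, `ci_low`, `ci_high`) are converted to log-odds
#' and standard error on read via [or_ci_to_log()].
#'
#' @param path path to a tab-separated file with a header row.
#' @param trait,dataset labels passed to [assoc_panel()].
#' @param column_map optional named character vector mapping canonical names
#'   (`rsid`, `chrom`, `pos`, `ref`, `alt`, `eaf`, `beta`, `se`, `pval`, and
#'   optionally `or`, `ci_low`, `ci_high`) to the file's column names.
#' @param level confidence level of the interval when converting OR/CI input.
#' @return An [assoc_panel()].
#' @export
read_panel <- function(path, trait = c("FG", "FI", "BC"), dataset = "unknown",
                       column_map = NULL, level = 0.95) {
  trait <- match.arg(trait)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(column_map)) {
    miss <- setdiff(unname(column_map), names(raw))
    if (length(miss) > 0L)
      stop("configuration error: mapped column(s) absent from file: ",
           paste(miss, collapse = ", "), call. = FALSE)
    for (canon in names(column_map)) names(raw)[names(raw) == column_map[[canon]]] <- canon
  }
  if (!("beta" %in% names(raw)) && all(c("or", "ci_low", "ci_high") %in% names(raw))) {
    conv <- or_ci_to_log(as.numeric(raw$or), as.numeric(raw$ci_low),
                         as.numeric(raw$ci_high), level = level)
    raw$beta <- conv$beta
    raw$se <- conv$se
  }
  assoc_panel(raw, trait = trait, dataset = dataset)
}

#' Write an association panel as canonical TSV
#'
#' @param panel an [assoc_panel()].
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(as.data.frame(panel), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert an odds ratio and confidence interval to log-odds and SE
#'
#' Uses the symmetric normal approximation on the log scale:
#' `beta = ln(OR)` and `se = (ln(hi) - ln(lo)) / (2 z)` with `z` the
#' standard-normal quantile at `(1 + level)/2`. Asymmetry of printed
#' intervals (a rounding artifact) is absorbed by the midpoint formula.
#'
#' @param or_value odds ratio(s), > 0.
#' @param ci_low,ci_high confidence bounds, `0 < ci_low <= or_value <= ci_high`.
#' @param level confidence level of the interval (default 0.95).
#' @return list with numeric `beta` (log-odds) and `se` (> 0).
#' @examples
#' or_ci_to_log(0.982, 0.969, 0.994)
#' @export
or_ci_to_log <- function(or_value, ci_low, ci_high, level = 0.95) {
  if (any(or_value <= 0 | ci_low <= 0 | ci_high <= 0))
    stop("domain error: odds ratios and bounds must be positive", call. = FALSE)
  if (any(ci_low > ci_high))
    stop("ordering error: ci_low > ci_high", call. = FALSE)
  if (any(ci_low > or_value | or_value > ci_high))
    stop("ordering error: OR outside its confidence interval", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  se <- (log(ci_high) - log(ci_low)) / (2 * z)
  if (any(se <= 0))
    stop("degenerate interval: implied se must be > 0", call. = FALSE)
  list(beta = log(or_value), se = se)
}

#' Convert log-odds and SE to an odds ratio with confidence interval
#'
#' Inverse of [or_ci_to_log()]: `exp(beta)` and `exp(beta +/- z se)`.
#'
#' @param beta log-odds.
#' @param se standard error, > 0.
#' @param level confidence level.
#' @return list with `or_value`, `ci_low`, `ci_high`.
#' @export
log_to_or <- function(beta, se, level = 0.95) {
  if (any(se <= 0)) stop("se must be > 0", call. = FALSE)
  z <- stats::qnorm((1 + level) / 2)
  list(or_value = exp(beta), ci_low = exp(beta - z * se),
       ci_high = exp(beta + z * se))
}

#' Keep genome-wide significant associations
#'
#' Retains records with `pval` strictly below the threshold (the
#' conventional genome-wide instrument rule, p < 5e-8), preserving order.
#'
#' @param panel an [assoc_panel()].
#' @param threshold p-value threshold; strict inequality.
#' @return The filtered [assoc_panel()].
#' @export
filter_genomewide <- function(panel, threshold = 5e-8) {
  stopifnot(inherits(panel, "assoc_panel"))
  keep <- panel$pval < threshold
  out <- as.data.frame(panel)[keep, , drop = FALSE]
  assoc_panel(out, trait = attr(panel, "trait"),
              dataset = attr(panel, "dataset"), validate = FALSE)
}

#' Count distinct variants across panels of one trait
#'
#' @param panels a single [assoc_panel()] or a list of panels sharing a trait.
#' @return integer count of distinct rsids.
#' @export
unique_variant_count <- function(panels) {
  if (inherits(panels, "assoc_panel")) panels <- list(panels)
  traits <- vapply(panels, function(p) attr(p, "trait"), character(1))
  if (length(unique(traits)) != 1L)
    stop("usage error: panels mix traits: ", paste(unique(traits), collapse = ", "),
         call. = FALSE)
  length(unique(unlist(lapply(panels, function(p) p$rsid))))
}
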