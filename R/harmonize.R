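.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

.check_snv <- function(...) {
  al <- c(...)
  bad <- !(al %in% names(.COMPLEMENT))
  if (any(bad))
    stop("unsupported variant: non-SNV allele(s) ",
         paste(unique(al[bad]), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Is a ref/alt allele pair palindromic?
#'
#' Palindromic (strand-ambiguous) pairs are A/T and C/G: the same two
#' letters on either strand, so allele labels alone cannot resolve strand.
#'
#' @param ref,alt single-nucleotide alleles (vectorized).
#' @return logical vector.
#' @export
is_palindromic <- function(ref, alt) {
  .check_snv(ref, alt)
  unname(.COMPLEMENT[ref] == alt)
}

#' Re-express a variant association on a chosen effect allele
#'
#' If `allele` is already the record's alt (effect) allele the record is
#' returned unchanged; if it is the ref allele, the effect is negated, the
#' allele frequency replaced by its complement, and the alleles swapped.
#' Applying the flip twice is the identity.
#'
#' @param record a one-row data frame (or list) with fields `ref`, `alt`,
#'   `eaf`, `beta`.
#' @param allele the desired effect allele; must be one of the record's.
#' @return the record with `beta`, `eaf`, `ref`, `alt` adjusted.
#' @export
flip_to_effect_allele <- function(record, allele) {
  if (identical(allele, record$alt)) return(record)
  if (!identical(allele, record$ref))
    stop("allele mismatch: '", allele, "' is neither ref (", record$ref,
         ") nor alt (", record$alt, ")", call. = FALSE)
  record$beta <- -record$beta
  record$eaf <- 1 - record$eaf
  tmp <- record$ref
  record$ref <- record$alt
  record$alt <- tmp
  record
}

#' Harmonize exposure and outcome panels into MR instruments
#'
#' Inner-joins the two panels on rsid and aligns every outcome record to the
#' exposure record's alt (effect) allele, flipping effect sign and allele
#' frequency where the outcome is encoded on the opposite allele and
#' resolving strand flips by complementing. Palindromic (A/T, C/G) variants
#' cannot be resolved from allele labels; they are handled per
#' `palindrome_policy`:
#' \describe{
#'   \item{drop}{exclude all palindromic variants;}
#'   \item{infer_by_freq}{orient by comparing outcome allele frequency with
#'     the exposure frequency and its complement; drop when either frequency
#'     is within `freq_tolerance` of 0.5 (ambiguous);}
#'   \item{keep}{assume both panels report the same strand (appropriate when
#'     both derive from one curated table).}
#' }
#' Every decision is recorded in a line-oriented audit log attached as the
#' `"audit"` attribute; unmatched and dropped rsids are never silent.
#'
#' @param exposure,outcome [assoc_panel()] objects; the outcome must be on
#'   the log-odds scale.
#' @param palindrome_policy see above; default `infer_by_freq`.
#' @param freq_tolerance ambiguity half-width around 0.5 for
#'   `infer_by_freq`; the default 0.08 drops variants with minor-allele
#'   frequency above 0.42.
#' @return data frame of class `mr_instruments` with columns `rsid`, `X`
#'   (exposure effect per effect allele), `se_X`, `Y` (outcome log-odds per
#'   effect allele), `se_Y`, `effect_allele`, `dataset`, `flipped`,
#'   `palindromic`; audit log in `attr(, "audit")`.
#' @export
match_instruments <- function(exposure, outcome,
                              palindrome_policy = c("infer_by_freq", "drop", "keep"),
                              freq_tolerance = 0.08) {
  palindrome_policy <- match.arg(palindrome_policy)
  stopifnot(inherits(exposure, "assoc_panel"), inherits(outcome, "assoc_panel"))
  audit <- character(0)
  log1 <- function(fmt, ...) audit[length(audit) + 1L] <<- sprintf(fmt, ...)

  e <- as.data.frame(exposure)
  o <- as.data.frame(outcome)
  unmatched <- setdiff(e$rsid, o$rsid)
  for (r in unmatched) log1("unmatched\t%s\texposure rsid absent from outcome panel", r)
  idx <- match(e$rsid, o$rsid)
  keep <- !is.na(idx)
  e <- e[keep, , drop = FALSE]
  o <- o[idx[keep], , drop = FALSE]

  n <- nrow(e)
  Y <- o$beta
  oeaf <- o$eaf
  oref <- o$ref
  oalt <- o$alt
  flipped <- logical(n)
  drop <- logical(n)

  .check_snv(e$ref, e$alt, oref, oalt)
  pal <- is_palindromic(e$ref, e$alt)

  same <- oref == e$ref & oalt == e$alt
  swapped <- oref == e$alt & oalt == e$ref
  comp_same <- .COMPLEMENT[oref] == e$ref & .COMPLEMENT[oalt] == e$alt
  comp_swap <- .COMPLEMENT[oref] == e$alt & .COMPLEMENT[oalt] == e$ref

  for (k in seq_len(n)) {
    if (pal[k]) {
      # same/comp and swapped/comp_swap coincide: labels cannot resolve strand
      if (palindrome_policy == "drop") {
        drop[k] <- TRUE
        log1("dropped\t%s\tpalindromic (%s/%s), policy=drop", e$rsid[k], e$ref[k], e$alt[k])
        next
      }
      if (!(same[k] || swapped[k])) {
        drop[k] <- TRUE
        log1("dropped\t%s\tirreconcilable alleles %s/%s vs %s/%s",
             e$rsid[k], e$ref[k], e$alt[k], oref[k], oalt[k])
        next
      }
      if (palindrome_policy == "keep") {
        if (swapped[k]) { Y[k] <- -Y[k]; oeaf[k] <- 1 - oeaf[k]; flipped[k] <- TRUE }
        log1("kept\t%s\tpalindromic, policy=keep (same-strand assumption)%s",
             e$rsid[k], if (swapped[k]) ", allele-swapped" else "")
        next
      }
      # infer_by_freq
      if (min(e$eaf[k], 1 - e$eaf[k]) > 0.5 - freq_tolerance ||
          min(oeaf[k], 1 - oeaf[k]) > 0.5 - freq_tolerance) {
        drop[k] <- TRUE
        log1("dropped\t%s\tpalindromic, frequency ambiguous (exp %.3f, out %.3f)",
             e$rsid[k], e$eaf[k], oeaf[k])
        next
      }
      f <- if (swapped[k]) 1 - oeaf[k] else oeaf[k]
      if (abs(f - e$eaf[k]) > abs(f - (1 - e$eaf[k]))) {
        # reported outcome allele is the strand-complement of the exposure alt
        Y[k] <- if (swapped[k]) Y[k] else -Y[k]
        flipped[k] <- !swapped[k]
        log1("kept\t%s\tpalindromic, orientation inferred by frequency (flipped)", e$rsid[k])
      } else {
        if (swapped[k]) { Y[k] <- -Y[k]; flipped[k] <- TRUE }
        log1("kept\t%s\tpalindromic, orientation inferred by frequency", e$rsid[k])
      }
    } else {
      if (same[k] || comp_same[k]) {
        if (comp_same[k]) log1("kept\t%s\tstrand-complemented outcome alleles", e$rsid[k])
      } else if (swapped[k] || comp_swap[k]) {
        Y[k] <- -Y[k]
        oeaf[k] <- 1 - oeaf[k]
        flipped[k] <- TRUE
        log1("kept\t%s\toutcome effect allele flipped to exposure alt%s", e$rsid[k],
             if (comp_swap[k]) " (strand-complemented)" else "")
      } else {
        drop[k] <- TRUE
        log1("dropped\t%s\tirreconcilable alleles %s/%s vs %s/%s",
             e$rsid[k], e$ref[k], e$alt[k], oref[k], oalt[k])
      }
    }
  }

  out <- data.frame(
    rsid = e$rsid, X = e$beta, se_X = e$se, Y = Y, se_Y = o$se,
    effect_allele = e$alt, dataset = attr(outcome, "dataset"),
    flipped = flipped, palindromic = pal,
    stringsAsFactors = FALSE
  )[!drop, , drop = FALSE]
  rownames(out) <- NULL
  if (any(out$se_Y <= 0))
    stop("outcome standard errors must be > 0 after harmonization", call. = FALSE)
  structure(out, audit = audit,
            exposure_trait = attr(exposure, "trait"),
            class = c("mr_instruments", "data.frame"))
}

#' Read an LD matrix from TSV
#'
#' Accepts either a square matrix with a header of rsids (first column =
#' rsid) or long-format triples `rsid_a`, `rsid_b`, `r2`; missing pairs in
#' long format default to r2 = 0.
#'
#' @param path TSV path.
#' @return matrix of squared correlations with unit diagonal, rsids as
#'   dimnames.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (all(c("rsid_a", "rsid_b", "r2") %in% names(raw))) {
    ids <- sort(unique(c(raw$rsid_a, raw$rsid_b)))
    m <- diag(length(ids))
    dimnames(m) <- list(ids, ids)
    m[cbind(raw$rsid_a, raw$rsid_b)] <- raw$r2
    m[cbind(raw$rsid_b, raw$rsid_a)] <- raw$r2
  } else {
    ids <- raw[[1]]
    m <- as.matrix(raw[, -1, drop = FALSE])
    dimnames(m) <- list(ids, colnames(m))
    m <- m[, ids, drop = FALSE]
  }
  storage.mode(m) <- "double"
  .validate_ld(m)
  m
}

.validate_ld <- function(m) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8)))
    stop("LD matrix must be symmetric", call. = FALSE)
  if (any(abs(diag(m) - 1) > 1e-8))
    stop("LD matrix diagonal must be 1", call. = FALSE)
  if (any(m < -1e-8 | m > 1 + 1e-8))
    stop("LD r-squared entries must lie in [0, 1]", call. = FALSE)
  invisible(m)
}

#' Greedy LD pruning of an instrument panel
#'
#' Sorts records by ascending p-value (ties broken lexicographically by
#' rsid), then iteratively keeps the most significant remaining record and
#' discards every record with squared correlation at or above the threshold
#' to any kept record. The surviving set is pairwise independent at
#' `r2 < r2_threshold`.
#'
#' @param panel an [assoc_panel()].
#' @param ld squared-correlation matrix with rsid dimnames covering the panel.
#' @param r2_threshold exclusion threshold (default 0.1, i.e. keep r2 < 0.1).
#' @return pruned [assoc_panel()] in original panel order.
#' @export
greedy_ld_prune <- function(panel, ld, r2_threshold = 0.1) {
  stopifnot(inherits(panel, "assoc_panel"))
  .validate_ld(ld)
  miss <- setdiff(panel$rsid, rownames(ld))
  if (length(miss) > 0L)
    stop("configuration error: rsid(s) absent from LD matrix: ",
         paste(miss, collapse = ", "), call. = FALSE)
  ord <- order(panel$pval, panel$rsid)
  cand <- panel$rsid[ord]
  kept <- character(0)
  while (length(cand) > 0L) {
    top <- cand[1L]
    kept <- c(kept, top)
    r2 <- ld[top, cand]
    cand <- cand[r2 < r2_threshold]
  }
  out <- as.data.frame(panel)[panel$rsid %in% kept, , drop = FALSE]
  assoc_panel(out, trait = attr(panel, "trait"),
              dataset = attr(panel, "dataset"), validate = FALSE)
}
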