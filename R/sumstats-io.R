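# Reading, validation, harmonization, and QC filtering of per-study per-sex
# GWAS summary statistics in a GWAMA-style tab-delimited dialect.

#' Default column dialect for summary-statistic files
#'
#' Maps internal field names to the column headers of the tab-delimited
#' dialect used throughout the pipeline. Override individual entries to read
#' files from studies using different headers.
#'
#' @return named character vector, internal field -> file column name
#' @export
default_column_map <- function() {
  c(marker_id = "MARKERNAME", chrom = "CHR", pos = "POS",
    effect_allele = "EA", other_allele = "NEA", eaf = "EAF",
    beta = "BETA", se = "SE", n = "N", info = "INFO", strand = "STRAND",
    call_rate = "CALLRATE", hwe_p = "HWE_P", mac = "MAC")
}

.MANDATORY_FIELDS <- c("marker_id", "effect_allele", "other_allele",
                       "eaf", "beta", "se", "n")
.NUMERIC_FIELDS <- c("chrom", "pos", "eaf", "beta", "se", "n", "info",
                     "call_rate", "hwe_p", "mac")

#' Construct a study panel
#'
#' A study panel is one study's summary statistics for one analysis stratum
#' (female, male, or combined), together with rows quarantined as malformed.
#'
#' @param records data.frame of variant records (see [read_sumstats()])
#' @param study_id study label
#' @param sex one of "female", "male", "combined"
#' @param trait trait label, e.g. "FG" or "FI"
#' @param design genotyping design: "gwas", "metabochip" or "custom"; the
#'   design selects the genomic-control subset rule
#' @param malformed data.frame of rejected rows with a REASON column
#' @return object of class `study_panel`
#' @export
study_panel <- function(records, study_id, sex = c("female", "male", "combined"),
                        trait = "FG", design = c("gwas", "metabochip", "custom"),
                        malformed = NULL) {
  sex <- match.arg(sex)
  design <- match.arg(design)
  if (anyDuplicated(records$marker_id))
    stop("duplicate marker_id in study panel '", study_id, "'")
  if (is.null(malformed)) {
    malformed <- records[0, , drop = FALSE]
    malformed$REASON <- character(0)
  }
  structure(list(study_id = study_id, sex = sex, trait = trait,
                 design = design, records = records, malformed = malformed),
            class = "study_panel")
}

#' @export
print.study_panel <- function(x, ...) {
  cat(sprintf("<study_panel> %s [%s, %s, %s]: %d records, %d malformed\n",
              x$study_id, x$sex, x$trait, x$design,
              nrow(x$records), nrow(x$malformed)))
  invisible(x)
}

#' Read a summary-statistics file into a study panel
#'
#' Parses a tab- or whitespace-delimited file with a header (gzip transparently
#' supported). Alleles are upper-cased. Rows violating the record invariants
#' (non-ACGT alleles, identical alleles, SE <= 0, EAF outside \[0,1\],
#' position < 1, non-autosomal chromosome) are routed to the panel's
#' `malformed` set with a reason code, never silently dropped.
#'
#' @param path file path
#' @param column_map see [default_column_map()]; missing optional columns are
#'   tolerated, missing mandatory columns are an error
#' @inheritParams study_panel
#' @return a `study_panel`
#' @export
read_sumstats <- function(path, column_map = default_column_map(),
                          study_id = basename(path), sex = "combined",
                          trait = "FG", design = "gwas") {
  raw <- read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "")
  missing_cols <- setdiff(column_map[.MANDATORY_FIELDS], names(raw))
  if (length(missing_cols))
    stop("mandatory column(s) missing from ", path, ": ",
         paste(missing_cols, collapse = ", "))

  rec <- data.frame(marker_id = as.character(raw[[column_map["marker_id"]]]),
                    stringsAsFactors = FALSE)
  for (f in setdiff(names(column_map), "marker_id")) {
    col <- column_map[[f]]
    if (col %in% names(raw)) {
      rec[[f]] <- if (f %in% .NUMERIC_FIELDS) as.numeric(raw[[col]])
                  else as.character(raw[[col]])
    } else {
      rec[[f]] <- if (f %in% .NUMERIC_FIELDS) NA_real_ else NA_character_
    }
  }
  rec$effect_allele <- toupper(rec$effect_allele)
  rec$other_allele <- toupper(rec$other_allele)

  reason <- rep(NA_character_, nrow(rec))
  flag <- function(bad, why) ifelse(is.na(reason) & bad, why, reason)
  acgt <- c("A", "C", "G", "T")
  reason <- flag(!(rec$effect_allele %in% acgt) | !(rec$other_allele %in% acgt),
                 "non_acgt_allele")
  reason <- flag(rec$effect_allele == rec$other_allele, "identical_alleles")
  reason <- flag(!is.finite(rec$se) | rec$se <= 0, "nonpositive_se")
  reason <- flag(!is.finite(rec$beta), "missing_beta")
  reason <- flag(!is.finite(rec$eaf) | rec$eaf < 0 | rec$eaf > 1, "eaf_out_of_range")
  reason <- flag(!is.na(rec$pos) & rec$pos < 1, "invalid_position")
  reason <- flag(!is.na(rec$chrom) & !(rec$chrom %in% 1:22), "non_autosomal")

  bad <- !is.na(reason)
  malformed <- rec[bad, , drop = FALSE]
  malformed$REASON <- reason[bad]
  rownames(malformed) <- NULL
  good <- rec[!bad, , drop = FALSE]
  rownames(good) <- NULL
  study_panel(good, study_id = study_id, sex = sex, trait = trait,
              design = design, malformed = malformed)
}

#' Write a study panel's records in the pipeline dialect
#'
#' Numeric fields are written with 17 significant digits so that a
#' read/write cycle round-trips every finite double bit-identically.
#' A path ending in `.gz` is written gzip-compressed.
#'
#' @param panel a `study_panel`
#' @param path output path
#' @param column_map see [default_column_map()]
#' @export
write_sumstats <- function(panel, path, column_map = default_column_map()) {
  out <- panel$records
  keep <- intersect(names(column_map), names(out))
  out <- out[, keep, drop = FALSE]
  for (f in intersect(keep, .NUMERIC_FIELDS))
    out[[f]] <- ifelse(is.na(out[[f]]), "NA", sprintf("%.17g", out[[f]]))
  names(out) <- column_map[keep]
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write quarantined malformed rows with their reason codes
#'
#' @inheritParams write_sumstats
#' @export
write_quarantine <- function(panel, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  write.table(panel$malformed, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default QC thresholds
#'
#' Variant-level exclusion rules: call rate < 0.95, MAF < 0.01, minor allele
#' count < 10, Hardy-Weinberg p < 1e-4, imputation info < 0.5. All rules are
#' strict inequalities; a separate, stricter info threshold of 0.7 applies to
#' panels that went through summary-statistic imputation
#' (`qc_thresholds(info = 0.7)`).
#'
#' @param call_rate,maf,mac,hwe_p,info threshold values; set one to `NA` to
#'   disable the corresponding rule
#' @return named list of thresholds
#' @export
qc_thresholds <- function(call_rate = 0.95, maf = 0.01, mac = 10,
                          hwe_p = 1e-4, info = 0.5) {
  list(call_rate = call_rate, maf = maf, mac = mac, hwe_p = hwe_p, info = info)
}

#' QC-filter a study panel
#'
#' Applies the variant-level exclusion rules in [qc_thresholds()]. A rule only
#' fires when its field is present (non-NA) in the record: study files vary in
#' which QC columns they provide, and absent fields never cause removal. The
#' report attributes each removed record to the first rule (in the order
#' call rate, MAF, MAC, HWE, info) it violates; the surviving set is
#' independent of that order.
#'
#' @param panel a `study_panel`
#' @param thresholds from [qc_thresholds()]
#' @return list with elements `panel` (filtered `study_panel`) and `report`
#'   (a `qc_report` itemizing removals by rule)
#' @export
qc_filter <- function(panel, thresholds = qc_thresholds()) {
  r <- panel$records
  n_input <- nrow(r)
  viol <- function(field, thr) {
    if (is.na(thr)) return(rep(FALSE, nrow(r)))
    v <- r[[field]]
    !is.na(v) & v < thr
  }
  maf <- pmin(r$eaf, 1 - r$eaf)
  fails <- cbind(call_rate = viol("call_rate", thresholds$call_rate),
                 maf = !is.na(maf) & maf < thresholds$maf,
                 mac = viol("mac", thresholds$mac),
                 hwe_p = viol("hwe_p", thresholds$hwe_p),
                 info = viol("info", thresholds$info))
  if (is.na(thresholds$maf)) fails[, "maf"] <- FALSE
  any_fail <- rowSums(fails) > 0
  # first violated rule, for reporting only
  first_rule <- apply(fails, 1L, function(z) if (any(z)) names(z)[which(z)[1]] else NA)
  removed_by <- table(factor(first_rule[any_fail],
                             levels = c("call_rate", "maf", "mac", "hwe_p", "info")))
  out <- panel
  out$records <- r[!any_fail, , drop = FALSE]
  rownames(out$records) <- NULL
  report <- structure(list(
    n_input = n_input,
    n_output = nrow(out$records),
    n_removed_callrate = unname(removed_by["call_rate"]),
    n_removed_maf = unname(removed_by["maf"]),
    n_removed_mac = unname(removed_by["mac"]),
    n_removed_hwe = unname(removed_by["hwe_p"]),
    n_removed_info = unname(removed_by["info"]),
    n_removed_malformed = nrow(panel$malformed),
    thresholds = thresholds), class = "qc_report")
  list(panel = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(paste0("<qc_report> %d in, %d out | callrate %d, maf %d, mac %d,",
                     " hwe %d, info %d (malformed at parse: %d)\n"),
              x$n_input, x$n_output, x$n_removed_callrate, x$n_removed_maf,
              x$n_removed_mac, x$n_removed_hwe, x$n_removed_info,
              x$n_removed_malformed))
  invisible(x)
}

#' Harmonize variant records to a reference allele pair
#'
#' Aligns each record's effect allele to `reference_ea`, trying in order:
#' identity, allele swap (beta -> -beta, eaf -> 1-eaf), strand complement,
#' and strand complement followed by swap. Palindromic pairs (A/T, C/G) are
#' aligned by allele frequency: both the record and reference frequencies
#' must be at least `palindromic_margin` away from 0.5, otherwise the record
#' is rejected with reason `"palindromic_ambiguous"`. Irreconcilable allele
#' pairs get reason `"allele_mismatch"`. Rejected rows keep their original
#' fields.
#'
#' @param records data.frame of variant records (vectorized; one row is fine)
#' @param reference_ea,reference_oa reference effect/other alleles, recycled
#' @param reference_eaf reference effect-allele frequency, needed only to
#'   resolve palindromic pairs
#' @param palindromic_margin minimum |eaf - 0.5| on both sides for
#'   frequency-based palindromic alignment (default 0.08)
#' @return `records` with `effect_allele`, `other_allele`, `beta`, `eaf`
#'   aligned and an added `harmonize_reason` column (`NA` where harmonized)
#' @export
harmonize <- function(records, reference_ea, reference_oa,
                      reference_eaf = NULL, palindromic_margin = 0.08) {
  n <- nrow(records)
  rea <- toupper(rep_len(reference_ea, n))
  roa <- toupper(rep_len(reference_oa, n))
  ref_eaf <- if (is.null(reference_eaf)) rep(NA_real_, n) else rep_len(reference_eaf, n)
  ea <- records$effect_allele
  oa <- records$other_allele
  cea <- unname(.complement[ea])
  coa <- unname(.complement[oa])

  pal <- is_palindromic(ea, oa)
  reason <- rep(NA_character_, n)
  swap <- rep(FALSE, n)

  # non-palindromic resolution
  direct <- !pal & ea == rea & oa == roa
  swapped <- !pal & ea == roa & oa == rea
  flip <- !pal & cea == rea & coa == roa
  flipswap <- !pal & cea == roa & coa == rea
  swap[swapped | flipswap] <- TRUE
  reason[!pal & !(direct | swapped | flip | flipswap)] <- "allele_mismatch"

  # palindromic: pair must match as a set (complement set is identical),
  # then frequency decides orientation
  if (any(pal)) {
    pair_ok <- pal & ((ea == rea & oa == roa) | (ea == roa & oa == rea))
    reason[pal & !pair_ok] <- "allele_mismatch"
    informative <- abs(records$eaf - 0.5) > palindromic_margin &
      !is.na(ref_eaf) & abs(ref_eaf - 0.5) > palindromic_margin
    reason[pair_ok & !informative] <- "palindromic_ambiguous"
    decidable <- pair_ok & informative & is.na(reason)
    # same side of 0.5 as the reference EAF => record's EA is the reference EA
    swap[decidable] <- (records$eaf[decidable] - 0.5) * (ref_eaf[decidable] - 0.5) < 0
  }

  ok <- is.na(reason)
  out <- records
  adj <- ok & swap
  out$beta[adj] <- -records$beta[adj]
  out$eaf[adj] <- 1 - records$eaf[adj]
  out$effect_allele[ok] <- rea[ok]
  out$other_allele[ok] <- roa[ok]
  out$harmonize_reason <- reason
  out
}
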