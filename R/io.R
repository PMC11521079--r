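#' Default column mapping for summary-statistics files
#'
#' Maps file headers to the canonical field names used by [summary_stats()].
#' GWAS summary formats are dialect-rich; the mapping is always explicit
#' configuration — headers are never guessed, because silent guessing is how
#' sign errors happen.
#'
#' @return Named character vector `c(field = header)` covering `rsid`,
#'   `effect_allele`, `other_allele`, `beta`, `se`, `pval` and the optional
#'   `eaf`, `n`.
#' @export
default_column_map <- function() {
  c(rsid = "SNP", effect_allele = "effect_allele",
    other_allele = "other_allele", beta = "beta", se = "se", pval = "pval",
    eaf = "eaf", n = "N")
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-separated text file (gzip transparently supported)
#' with one header row and one variant per row. Rows with missing or
#' non-numeric `beta`/`se` are rejected with an error naming the offending
#' variant — never silently dropped.
#'
#' @param path Path to the file.
#' @param column_map Named character vector mapping canonical field names to
#'   file headers; see [default_column_map()]. `eaf` and `n` entries may be
#'   omitted or absent from the file.
#' @param trait_label Label stored on the returned table.
#' @param sep Field separator; `NULL` (default) picks tab when the header
#'   contains one, comma otherwise.
#' @return An `mr_sumstats` table; row order follows the file and is stable
#'   under [write_summary_stats()] round trips.
#' @export
read_summary_stats <- function(path, column_map = default_column_map(),
                               trait_label = basename(path), sep = NULL) {
  if (!file.exists(path)) stop_mrscreen("io", "file not found: ", path)
  required <- c("rsid", "effect_allele", "other_allele", "beta", "se", "pval")
  missing_map <- setdiff(required, names(column_map))
  if (length(missing_map) > 0) {
    stop_mrscreen("config", "column_map lacks entries for: ",
                  paste(missing_map, collapse = ", "))
  }
  con <- gzfile(path, "rt")
  on.exit(close(con))
  header_line <- readLines(con, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", header_line)) "\t" else ","
  raw <- utils::read.table(con, header = FALSE, sep = sep,
                           col.names = strsplit(header_line, sep, fixed = TRUE)[[1]],
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  hdr <- names(raw)
  need_cols <- column_map[required]
  absent <- need_cols[!need_cols %in% hdr]
  if (length(absent) > 0) {
    stop_mrscreen("config", "mapped column(s) not in file: ",
                  paste(absent, collapse = ", "))
  }
  grab <- function(field, default = NA_character_) {
    col <- if (field %in% names(column_map)) column_map[[field]] else NA
    if (!is.na(col) && col %in% hdr) raw[[col]] else rep(default, nrow(raw))
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  summary_stats(
    rsid = grab("rsid"),
    effect_allele = grab("effect_allele"),
    other_allele = grab("other_allele"),
    beta = num(grab("beta")),
    se = num(grab("se")),
    pval = num(grab("pval")),
    eaf = num(grab("eaf")),
    n = num(grab("n")),
    trait_label = trait_label
  )
}

#' Write a summary-statistics table
#'
#' Emits the canonical TSV dialect this package reads back with
#' [read_summary_stats()] and [default_column_map()]; read -> write -> read
#' is the identity on the table.
#'
#' @param x An `mr_sumstats` table.
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "mr_sumstats"))
  out <- data.frame(
    SNP = x$rsid, effect_allele = x$effect_allele,
    other_allele = x$other_allele,
    beta = sprintf("%.17g", x$beta), se = sprintf("%.17g", x$se),
    pval = sprintf("%.17g", x$pval),
    eaf = ifelse(is.na(x$eaf), "NA", sprintf("%.17g", x$eaf)),
    N = ifelse(is.na(x$n), "NA", sprintf("%.17g", x$n)),
    stringsAsFactors = FALSE
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load the packaged 63-variant screen-time / retinopathy instrument table
#'
#' The package ships, verbatim, the published table of 63 variants used as
#' instruments for leisure screen time (LST, standard-deviation units; one
#' SD is about 2.2 h/day) together with their associations with diabetic
#' retinopathy (DR, log-odds) from FinnGen. Betas and standard errors are
#' stored exactly as printed (3 decimals) — downstream estimates computed
#' from this table inherit that rounding. The per-variant `F` column is the
#' published instrument-strength value; it is not derivable from the printed
#' beta/SE and is carried as given.
#'
#' @return A list with elements `exposure` and `outcome` (both `mr_sumstats`,
#'   63 rows, identical rsid order) and `info` (data frame with `rsid`,
#'   `nearest_gene`, `n`, `f_published`).
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "lst_dr_instruments.tsv",
                      package = "mrscreen", mustWork = TRUE)
  checksum <- unname(tools::md5sum(path))
  expected <- "9deaa8ab6c4838c0c3cae258a7ac9047"
  if (!identical(checksum, expected)) {
    stop_mrscreen("data", "instrument fixture is corrupted (md5 ", checksum,
                  ", expected ", expected, ")")
  }
  raw <- utils::read.delim(path, stringsAsFactors = FALSE)
  exposure <- summary_stats(
    rsid = raw$SNP, effect_allele = raw$EA, other_allele = raw$OA,
    beta = raw$beta_exposure, se = raw$se_exposure, pval = raw$pval_exposure,
    n = raw$N, trait_label = "leisure screen time (SD)"
  )
  outcome <- summary_stats(
    rsid = raw$SNP, effect_allele = raw$EA, other_allele = raw$OA,
    beta = raw$beta_outcome, se = raw$se_outcome, pval = raw$pval_outcome,
    trait_label = "diabetic retinopathy (log-odds)"
  )
  info <- data.frame(rsid = raw$SNP, nearest_gene = raw$nearest_gene,
                     n = raw$N, f_published = raw$F,
                     stringsAsFactors = FALSE)
  list(exposure = exposure, outcome = outcome, info = info)
}

#' Read a deny-list of variant identifiers
#'
#' Plain text, one rsid per line; `#` starts a comment; blank lines ignored.
#'
#' @param path Path to the file.
#' @return Character vector of rsids.
#' @export
read_deny_list <- function(path) {
  if (!file.exists(path)) stop_mrscreen("io", "file not found: ", path)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines[nzchar(lines)]
}

#' Write the analysis report bundle
#'
#' Emits a machine-readable JSON report carrying every estimate, diagnostic
#' and per-variant table at full double precision (17 significant digits, so
#' [read_report()] reproduces the numbers bit-identically), plus
#' human-readable TSVs: `estimates.tsv` in forest-plot layout (method, nSNP,
#' OR, CI, p), `exclusions.tsv`, and the per-variant `snps.tsv`,
#' `leave_one_out.tsv` and `funnel.tsv` tables when present.
#'
#' @param report An `mr_report` from [run_analysis()], or any list with at
#'   least an `estimates` data frame.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir) {
  est <- report$estimates
  if (is.null(est) || nrow(est) < 1) {
    stop_mrscreen("config", "report contains no estimates")
  }
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop_mrscreen("io", "cannot create output directory: ", dir)
  files <- c(json = file.path(dir, "report.json"),
             estimates = file.path(dir, "estimates.tsv"))
  json <- jsonlite::toJSON(unclass_deep(report), digits = I(17),
                           auto_unbox = TRUE, na = "null", null = "null",
                           dataframe = "columns", pretty = TRUE)
  writeLines(json, files[["json"]])
  fig <- data.frame(
    method = est$method, nSNP = est$n_snps,
    OR = sprintf("%.3f", est$or),
    CI95 = sprintf("%.3f-%.3f", est$or_low, est$or_high),
    p = sprintf("%.3g", est$p), stringsAsFactors = FALSE
  )
  utils::write.table(fig, files[["estimates"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tsv_extra <- list(exclusions = report$exclusions,
                    snps = report$snps,
                    leave_one_out = report$leave_one_out,
                    funnel = report$funnel)
  for (nm in names(tsv_extra)) {
    tab <- tsv_extra[[nm]]
    if (is.data.frame(tab)) {
      f <- file.path(dir, paste0(nm, ".tsv"))
      num <- vapply(tab, is.numeric, logical(1))
      tab[num] <- lapply(tab[num], function(v) sprintf("%.17g", v))
      utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
      files[[nm]] <- f
    }
  }
  invisible(files)
}

#' Read back a machine-readable report
#'
#' @param path Path to a `report.json` written by [write_report()].
#' @return The parsed report list; all numbers equal the written ones
#'   bit-identically.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) stop_mrscreen("io", "file not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# strip S3 classes/attributes so jsonlite serializes plain structures
unclass_deep <- function(x) {
  if (is.data.frame(x)) {
    x <- as.data.frame(x)
    class(x) <- "data.frame"
    attr(x, "trait_label") <- NULL
    return(x)
  }
  if (is.list(x)) return(lapply(x, unclass_deep))
  x
}
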