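## TSV case input, TSV/JSON report output.
##
## TSV is the native case format: a case is a handful of per-variant read
## count pairs plus an external germline detection flag, which maps onto a
## seven-column table far more naturally than onto VCF.

CASE_COLUMNS <- c("variant_id", "chrom", "vA", "wA", "vB", "wB",
                  "germline_detected")

input_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("twinlr_input_error", "error")))
}

#' Read a case table from TSV
#'
#' The file must be tab-separated with the exact header
#' `variant_id chrom vA wA vB wB germline_detected`, one row per
#' discriminating variant: non-negative integer read counts for both twins
#' and a 0/1 germline detection flag. Malformed rows are reported with their
#' line numbers.
#'
#' @param path Path to the TSV file.
#' @return A validated data frame of class `"case_table"` with the columns
#'   above (`germline_detected` as logical), suitable for [combine_case()].
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("variant_id\tchrom\tvA\twA\tvB\twB\tgermline_detected",
#'              "snv1\tchr7\t25\t50\t0\t65\t1"), tsv)
#' read_case_tsv(tsv)
#' @export
read_case_tsv <- function(path) {
  if (!file.exists(path)) input_error("case file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) input_error(path, ": empty file")
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, CASE_COLUMNS)) {
    input_error(path, ": header must be exactly '",
                paste(CASE_COLUMNS, collapse = "\\t"), "', got '",
                lines[[1L]], "'")
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) == 0L) input_error(path, ": no variant rows")

  parse_row <- function(line, lineno) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) != length(CASE_COLUMNS)) {
      input_error(path, " line ", lineno, ": expected ",
                  length(CASE_COLUMNS), " tab-separated fields, got ",
                  length(fields))
    }
    counts <- suppressWarnings(as.numeric(fields[3:6]))
    bad <- which(is.na(counts) | counts < 0 | counts != round(counts))
    if (length(bad) > 0L) {
      input_error(path, " line ", lineno, ": column '",
                  CASE_COLUMNS[2L + bad[1L]],
                  "' must be a non-negative integer, got '",
                  fields[2L + bad[1L]], "'")
    }
    if (!fields[7L] %in% c("0", "1")) {
      input_error(path, " line ", lineno,
                  ": 'germline_detected' must be 0 or 1, got '",
                  fields[7L], "'")
    }
    data.frame(variant_id = fields[1L], chrom = fields[2L],
               vA = counts[1L], wA = counts[2L],
               vB = counts[3L], wB = counts[4L],
               germline_detected = fields[7L] == "1")
  }
  rows <- mapply(parse_row, body, seq_along(body) + 1L, SIMPLIFY = FALSE)
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  dup <- unique(tab$variant_id[duplicated(tab$variant_id)])
  if (length(dup) > 0L) {
    input_error(path, ": duplicate variant_id: ", paste(dup, collapse = ", "))
  }
  structure(tab, class = c("case_table", "data.frame"), source = path)
}

#' Write a case table to TSV
#'
#' Writes observations in the canonical case-table dialect read by
#' [read_case_tsv()]; a canonical file survives a read-write cycle
#' byte-for-byte.
#'
#' @param x A case-table data frame, a list of [variant_observation()]
#'   objects, or a `"simulated_case"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_case_tsv <- function(x, path) {
  if (inherits(x, "simulated_case")) x <- x$observations
  if (is.list(x) && !is.data.frame(x) &&
      all(vapply(x, inherits, logical(1), "variant_observation"))) {
    x <- do.call(rbind, lapply(x, function(o) {
      data.frame(variant_id = o$variant_id, chrom = o$chrom,
                 vA = o$reads_A$v, wA = o$reads_A$w,
                 vB = o$reads_B$v, wB = o$reads_B$w,
                 germline_detected = o$germline_detected)
    }))
  }
  stopifnot(is.data.frame(x), all(CASE_COLUMNS %in% names(x)))
  out <- x[, CASE_COLUMNS]
  out$germline_detected <- as.integer(out$germline_detected)
  lines <- c(paste(CASE_COLUMNS, collapse = "\t"),
             vapply(seq_len(nrow(out)), function(i) {
               paste(c(out$variant_id[i], out$chrom[i],
                       format(c(out$vA[i], out$wA[i], out$vB[i], out$wB[i]),
                              trim = TRUE, scientific = FALSE),
                       out$germline_detected[i]), collapse = "\t")
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

format_lik <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (v != 0 && abs(v) < 1e-2) sprintf("%.2e", v) else sprintf("%.4f", v)
  }, character(1))
}

report_payload <- function(result) {
  list(
    metadata = list(
      package = "twinlr",
      version = as.character(utils::packageVersion("twinlr")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      scenario = result$config$scenario,
      detection_threshold = result$config$detection_threshold,
      prior_alpha = result$config$prior$alpha,
      prior_beta = result$config$prior$beta,
      prior_odds = result$config$prior_odds,
      use_absence = result$config$use_absence
    ),
    per_variant = result$per_variant,
    combined_lr = result$combined_lr,
    combined_lr_nearest_integer = round(result$combined_lr),
    posterior_odds = result$posterior_odds,
    warnings = as.list(result$warnings)
  )
}

#' Write a case report
#'
#' Serialises a [combine_case()] result. The TSV format prints a per-variant
#' block (likelihoods at display precision, full-precision columns alongside)
#' followed by a summary block; the JSON format is a lossless rendering that
#' [read_report()] restores.
#'
#' @param result A `"twin_case_result"` from [combine_case()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("tsv", "json")) {
  stopifnot(inherits(result, "twin_case_result"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_payload(result), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(path))
  }
  tab <- result$per_variant
  header <- c("variant_id", "chrom", "germline_detected",
              "alpha_A", "beta_A", "alpha_B", "beta_B",
              "lik_A", "lik_B", "lr",
              "lik_A_full", "lik_B_full", "lr_full")
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    paste(c(tab$variant_id[i], tab$chrom[i],
            as.integer(tab$germline_detected[i]),
            format(c(tab$alpha_A[i], tab$beta_A[i], tab$alpha_B[i],
                     tab$beta_B[i]), trim = TRUE),
            format_lik(c(tab$lik_A[i], tab$lik_B[i], tab$lr[i])),
            format(c(tab$lik_A[i], tab$lik_B[i], tab$lr[i]), digits = 15,
                   trim = TRUE)), collapse = "\t")
  }, character(1))
  summary_block <- c(
    paste0("# scenario\t", result$config$scenario),
    paste0("# prior\tBeta(", result$config$prior$alpha, ", ",
           result$config$prior$beta, ")"),
    paste0("# prior_odds\t", format(result$config$prior_odds)),
    paste0("# combined_lr\t", format_lik(result$combined_lr), "\t",
           format(result$combined_lr, digits = 15)),
    paste0("# combined_lr_nearest_integer\t", round(result$combined_lr)),
    paste0("# posterior_odds\t", format_lik(result$posterior_odds), "\t",
           format(result$posterior_odds, digits = 15))
  )
  lines <- c(paste(header, collapse = "\t"), rows, summary_block)
  if (length(result$warnings) > 0L) {
    lines <- c(lines, paste0("# warning\t", result$warnings))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON case report
#'
#' Restores a report written by [write_report()] with `format = "json"`.
#'
#' @param path Path to the JSON report.
#' @return A list with the report payload; `per_variant` is a data frame and
#'   numeric fields carry full precision.
#' @export
read_report <- function(path) {
  if (!file.exists(path)) input_error("report not found: ", path)
  rep <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  rep$per_variant <- as.data.frame(rep$per_variant)
  rep$warnings <- as.character(unlist(rep$warnings))
  rep
}
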