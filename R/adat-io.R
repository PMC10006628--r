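#' Plate-structured SOMAmer RFU container
#'
#' Bundles a samples x SOMAmers matrix of relative fluorescence units (RFU)
#' with per-SOMAmer and per-sample metadata. This is the in-memory form of the
#' simplified tab-delimited ADAT dialect read and written by [read_adat()] and
#' [write_adat()].
#'
#' @param rfu Numeric matrix, samples in rows and SOMAmer reagents in columns.
#'   Row names are sample ids, column names SOMAmer ids. All values must be
#'   present (no `NA`) and non-negative.
#' @param somamer_meta Data frame with one row per SOMAmer column:
#'   `somamer_id`, `protein_symbol`, `dilution_set` (1, 2 or 3),
#'   `is_hyb_control` (logical), `flagged_removed` (logical).
#' @param sample_meta Data frame with one row per sample row: `sample_id`,
#'   `sample_type` (one of `"calibrator"`, `"qc"`, `"buffer"`, `"study"`)
#'   and `plate_id`.
#'
#' @return An object of class `somamer_table`.
#' @export
somamer_table <- function(rfu, somamer_meta, sample_meta) {
  rfu <- as.matrix(rfu)
  storage.mode(rfu) <- "double"
  x <- structure(
    list(rfu = rfu,
         somamer_meta = as.data.frame(somamer_meta),
         sample_meta = as.data.frame(sample_meta)),
    class = "somamer_table"
  )
  validate_somamer_table(x)
}

validate_somamer_table <- function(x) {
  rfu <- x$rfu
  sm <- x$somamer_meta
  pm <- x$sample_meta
  need_sm <- c("somamer_id", "protein_symbol", "dilution_set",
               "is_hyb_control", "flagged_removed")
  need_pm <- c("sample_id", "sample_type", "plate_id")
  if (!all(need_sm %in% names(sm))) {
    stopf("somamer_meta is missing column(s): %s",
          paste(setdiff(need_sm, names(sm)), collapse = ", "))
  }
  if (!all(need_pm %in% names(pm))) {
    stopf("sample_meta is missing column(s): %s",
          paste(setdiff(need_pm, names(pm)), collapse = ", "))
  }
  if (nrow(sm) != ncol(rfu)) {
    stopf("somamer_meta has %d rows but the RFU matrix has %d columns",
          nrow(sm), ncol(rfu))
  }
  if (nrow(pm) != nrow(rfu)) {
    stopf("sample_meta has %d rows but the RFU matrix has %d rows",
          nrow(pm), nrow(rfu))
  }
  if (anyDuplicated(sm$somamer_id)) {
    stopf("duplicate somamer_id: %s",
          paste(unique(sm$somamer_id[duplicated(sm$somamer_id)]), collapse = ", "))
  }
  if (anyNA(rfu)) {
    idx <- which(is.na(rfu), arr.ind = TRUE)[1L, ]
    stopf("missing RFU value at sample '%s', SOMAmer '%s' (RFU matrices must be complete)",
          pm$sample_id[idx[1L]], sm$somamer_id[idx[2L]])
  }
  if (any(rfu < 0)) {
    idx <- which(rfu < 0, arr.ind = TRUE)[1L, ]
    stopf("negative RFU value at sample '%s', SOMAmer '%s'",
          pm$sample_id[idx[1L]], sm$somamer_id[idx[2L]])
  }
  bad_type <- setdiff(unique(pm$sample_type),
                      c("calibrator", "qc", "buffer", "study"))
  if (length(bad_type)) {
    stopf("unknown sample_type: %s", paste(bad_type, collapse = ", "))
  }
  if (!all(sm$dilution_set %in% c(1L, 2L, 3L))) {
    stopf("dilution_set must be 1, 2 or 3")
  }
  rownames(x$rfu) <- as.character(pm$sample_id)
  colnames(x$rfu) <- as.character(sm$somamer_id)
  x
}

#' @export
print.somamer_table <- function(x, ...) {
  cat(sprintf("somamer_table: %d samples x %d SOMAmers (%d plates)\n",
              nrow(x$rfu), ncol(x$rfu),
              length(unique(x$sample_meta$plate_id))))
  tab <- table(x$sample_meta$sample_type)
  cat("  samples:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat(sprintf("  hybridization controls: %d; flagged for removal: %d\n",
              sum(x$somamer_meta$is_hyb_control),
              sum(x$somamer_meta$flagged_removed)))
  invisible(x)
}

#' Dimensions of a somamer_table
#' @param x A `somamer_table`.
#' @return Integer vector `(samples, SOMAmers)`.
#' @export
dim.somamer_table <- function(x) dim(x$rfu)

fmt_num <- function(x) {
  # Full-precision decimal output so a write/read cycle is the identity.
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

#' Write the simplified ADAT dialect
#'
#' Serializes a [somamer_table()] as a tab-delimited ASCII file with three
#' blocks: `^SOMAMER` (reagent metadata), `^SAMPLE` (sample metadata) and
#' `^RFU` (the measurement matrix, samples in rows). Output ordering is the
#' table's ordering, numerics are written at full precision, newlines are
#' UNIX.
#'
#' @param table A `somamer_table`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_adat <- function(table, path) {
  table <- validate_somamer_table(table)
  sm <- table$somamer_meta
  pm <- table$sample_meta
  lines <- c(
    "^SOMAMER",
    paste(c("somamer_id", "protein_symbol", "dilution_set",
            "is_hyb_control", "flagged_removed"), collapse = "\t"),
    paste(sm$somamer_id, sm$protein_symbol, as.integer(sm$dilution_set),
          as.integer(sm$is_hyb_control), as.integer(sm$flagged_removed),
          sep = "\t"),
    "^SAMPLE",
    paste(c("sample_id", "sample_type", "plate_id"), collapse = "\t"),
    paste(pm$sample_id, pm$sample_type, pm$plate_id, sep = "\t"),
    "^RFU",
    paste(c("", as.character(sm$somamer_id)), collapse = "\t")
  )
  if (nrow(table$rfu) > 0) {
    body <- vapply(seq_len(nrow(table$rfu)), function(i) {
      paste(c(as.character(pm$sample_id[i]), fmt_num(table$rfu[i, ])),
            collapse = "\t")
    }, character(1))
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read the simplified ADAT dialect
#'
#' Parses a file written by [write_adat()] (or hand-written in the same
#' layout) into a validated [somamer_table()]. Metadata blocks precede the
#' matrix block; column order is preserved. Malformed content (missing block,
#' duplicate SOMAmer id, non-numeric RFU cell) raises an error naming the
#' offending line or cell.
#'
#' @param path File path.
#' @return A `somamer_table`.
#' @export
read_adat <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  marks <- c(som = match("^SOMAMER", lines),
             sam = match("^SAMPLE", lines),
             rfu = match("^RFU", lines))
  if (anyNA(marks)) {
    stopf("malformed ADAT dialect: missing block marker(s) %s",
          paste(c("^SOMAMER", "^SAMPLE", "^RFU")[is.na(marks)], collapse = ", "))
  }
  if (!(marks["som"] < marks["sam"] && marks["sam"] < marks["rfu"])) {
    stopf("malformed ADAT dialect: blocks must appear in order ^SOMAMER, ^SAMPLE, ^RFU")
  }
  parse_block <- function(from, to, need, what) {
    hdr <- strsplit(lines[from], "\t", fixed = TRUE)[[1]]
    if (!identical(hdr, need)) {
      stopf("line %d: %s header must be '%s'", from, what,
            paste(need, collapse = "\\t"))
    }
    rows <- lines[seq(from + 1L, length.out = max(0L, to - from - 1L))]
    rows <- rows[nzchar(rows)]
    if (!length(rows)) {
      df <- as.data.frame(setNames(rep(list(character(0)), length(need)), need))
      return(df)
    }
    parts <- strsplit(rows, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != length(need))) {
      stopf("line %d: expected %d tab-separated fields, found %d",
            from + which(nf != length(need))[1L], length(need),
            nf[nf != length(need)][1L])
    }
    df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
    names(df) <- need
    df
  }
  sm <- parse_block(marks["som"] + 1L, marks["sam"],
                    c("somamer_id", "protein_symbol", "dilution_set",
                      "is_hyb_control", "flagged_removed"), "^SOMAMER")
  pm <- parse_block(marks["sam"] + 1L, marks["rfu"],
                    c("sample_id", "sample_type", "plate_id"), "^SAMPLE")
  sm$dilution_set <- as.integer(sm$dilution_set)
  sm$is_hyb_control <- as.integer(sm$is_hyb_control) > 0L
  sm$flagged_removed <- as.integer(sm$flagged_removed) > 0L

  hdr_i <- marks["rfu"] + 1L
  if (hdr_i > length(lines)) stopf("malformed ADAT dialect: ^RFU block is empty")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 1L || nzchar(hdr[1L])) {
    stopf("line %d: RFU header row must start with an empty field", hdr_i)
  }
  ids <- hdr[-1L]
  if (!identical(ids, as.character(sm$somamer_id))) {
    stopf("RFU column ids do not match the ^SOMAMER block")
  }
  body <- lines[seq(hdr_i + 1L, length.out = length(lines) - hdr_i)]
  body <- body[nzchar(body)]
  n <- length(body)
  rfu <- matrix(NA_real_, nrow = n, ncol = length(ids))
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) != length(ids) + 1L) {
      stopf("line %d: expected %d fields, found %d",
            hdr_i + i, length(ids) + 1L, length(parts))
    }
    sample_ids[i] <- parts[1L]
    vals <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1L]
      stopf("line %d: non-numeric RFU value '%s' in column '%s' (sample '%s')",
            hdr_i + i, parts[j + 1L], ids[j], parts[1L])
    }
    rfu[i, ] <- vals
  }
  if (!identical(sample_ids, as.character(pm$sample_id))) {
    stopf("RFU sample ids do not match the ^SAMPLE block")
  }
  somamer_table(rfu, sm, pm)
}

#' Read/write clinical and outcome tables
#'
#' Plain TSV with a header row; `patient_id` is the join key across files.
#' Missing clinical entries are encoded as `NA`. Outcome files carry
#' `patient_id`, `time` (years, positive) and `cause`
#' (0 censored, 1 HF hospitalization, 2 all-cause death).
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_*` return a data frame; `write_*` return `path` invisibly.
#' @name clinical_io
NULL

#' @rdname clinical_io
#' @export
write_clinical <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname clinical_io
#' @export
read_clinical <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' @rdname clinical_io
#' @export
write_outcomes <- function(x, path) {
  validate_outcomes(x)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname clinical_io
#' @export
read_outcomes <- function(path) {
  validate_outcomes(utils::read.delim(path, stringsAsFactors = FALSE))
}

validate_outcomes <- function(x) {
  if (!all(c("time", "cause") %in% names(x))) {
    stopf("outcome table needs columns 'time' and 'cause'")
  }
  if (any(!is.finite(x$time)) || any(x$time <= 0)) {
    stopf("outcome times must be finite and positive")
  }
  if (!all(x$cause %in% c(0L, 1L, 2L))) {
    stopf("outcome cause codes must be 0 (censored), 1 (HF) or 2 (death)")
  }
  x
}
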