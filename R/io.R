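# Shared table readers and writers, array manifest handling and genomic
# interval resolution. All writers emit a `#`-prefixed provenance header
# (tool version and, where relevant, seed) that every reader skips.

.file_header <- function(extra = character(0)) {
  c(sprintf("# uniclock %s",
            as.character(utils::packageVersion("uniclock"))), extra)
}

.write_csv <- function(df, path, header = .file_header()) {
  body <- if (nrow(df) == 0L) character(0) else {
    fmt <- vapply(df, function(col) {
      if (is.numeric(col)) sprintf("%.17g", col) else as.character(col)
    }, FUN.VALUE = character(nrow(df)))
    if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
    apply(fmt, 1L, paste, collapse = ",")
  }
  lines <- c(header, paste(names(df), collapse = ","), body)
  writeLines(lines, path)
  invisible(path)
}

.read_csv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path,
                               call. = FALSE)
  nf <- utils::count.fields(path, sep = ",", comment.char = "#",
                            quote = "\"")
  nf <- nf[!is.na(nf)]
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop("ragged ", what, " file ", path, ": row ", bad, " has ", nf[bad],
         " fields, expected ", nf[1], call. = FALSE)
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop(what, " file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' Read a CpG-by-sample beta matrix from CSV
#'
#' The expected dialect is one header row (`cpg_id` then sample ids) and one
#' row per CpG. Values must lie in \[0, 1\]; empty cells become missing
#' (`NA`), never zero. Out-of-range values and ragged rows are rejected with
#' the offending CpG/sample named.
#'
#' @param path CSV file path.
#' @return Numeric matrix (rows CpGs, columns samples).
#' @export
read_beta_matrix <- function(path) {
  df <- .read_csv_checked(path, "cpg_id", "beta matrix")
  ids <- as.character(df$cpg_id)
  m <- as.matrix(df[, setdiff(names(df), "cpg_id"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  bad <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("beta values outside [0, 1], e.g. cpg ", rownames(m)[bad[1, 1]],
         " sample ", colnames(m)[bad[1, 2]], " = ", m[bad[1, , drop = FALSE]],
         call. = FALSE)
  }
  m
}

#' Write a beta matrix to CSV
#'
#' Inverse of [read_beta_matrix()]; full double precision, missing values as
#' empty cells. The round trip is exact.
#'
#' @param m numeric matrix (rows CpGs, columns samples, dimnames required).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path) {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  body <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  body[is.na(m)] <- ""
  lines <- c(.file_header(),
             paste(c("cpg_id", colnames(m)), collapse = ","),
             paste(rownames(m), apply(body, 1L, paste, collapse = ","),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample sheet from CSV
#'
#' Requires columns `sample_id`, `species_id`, `tissue`, `age`; an optional
#' `group` column (e.g. control/treated) is preserved.
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- .read_csv_checked(path, c("sample_id", "species_id", "tissue",
                                  "age"), "sample sheet")
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample ids in ", path, call. = FALSE)
  }
  df$age <- as.numeric(df$age)
  df
}

#' Write a sample sheet to CSV
#'
#' @param samples sample sheet data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  .write_csv(samples, path)
}

#' Write a trait table to CSV
#'
#' Records the adjustment state and exempt set in the provenance header
#' (informational; [load_trait_table()] always loads tables as unadjusted,
#' so adjusted tables should be re-derived, not round-tripped).
#'
#' @param table a [trait_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path) {
  stopifnot(inherits(table, "trait_table"))
  hdr <- .file_header(sprintf("# lifespan_adjusted: %s; exempt: %s",
                              isTRUE(attr(table, "lifespan_adjusted")),
                              paste(attr(table, "exempt"),
                                    collapse = "|")))
  .write_csv(as.data.frame(table), path, header = hdr)
}

#' Read an array manifest
#'
#' A manifest maps CpG probe ids to genomic coordinates: columns `cpg_id`,
#' `chromosome`, `position` (0-based) and optionally a gene annotation.
#'
#' @param path CSV file path.
#' @return Data frame of class `array_manifest`.
#' @export
read_array_manifest <- function(path) {
  df <- .read_csv_checked(path, c("cpg_id", "chromosome", "position"),
                          "array manifest")
  if (anyDuplicated(df$cpg_id)) {
    stop("duplicate cpg ids in manifest ", path, call. = FALSE)
  }
  df$position <- as.numeric(df$position)
  if (any(df$position < 0, na.rm = TRUE)) {
    stop("negative positions in manifest ", path, call. = FALSE)
  }
  structure(df, class = c("array_manifest", "data.frame"))
}

#' Resolve genomic intervals to CpG ids via an array manifest
#'
#' Internally all coordinates are 0-based half-open. BED-dialect intervals
#' (`bed0_halfopen`) are used as-is: a probe at position p is included when
#' `start <= p < end`. GFF-dialect intervals (`gff1_closed`, 1-based fully
#' closed) are converted by `start - 1` so both ends are included. Intervals
#' on chromosomes absent from the manifest are skipped with a warning.
#'
#' @param manifest an [read_array_manifest()] data frame.
#' @param intervals data frame with columns `chromosome`, `start`, `end`.
#' @param dialect `"bed0_halfopen"` or `"gff1_closed"`.
#' @return Character vector of unique CpG ids falling in any interval.
#' @export
resolve_intervals <- function(manifest, intervals,
                              dialect = c("bed0_halfopen", "gff1_closed")) {
  dialect <- match.arg(dialect)
  stopifnot(all(c("chromosome", "start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0L) return(character(0))
  start <- intervals$start
  end <- intervals$end
  if (dialect == "gff1_closed") {
    start <- start - 1  # closed 1-based -> half-open 0-based
  }
  unknown <- setdiff(unique(intervals$chromosome),
                     unique(manifest$chromosome))
  if (length(unknown) > 0L) {
    warning(length(unknown), " interval chromosome(s) absent from the ",
            "manifest, skipped: ", paste(unknown, collapse = ", "))
  }
  hits <- character(0)
  for (i in seq_len(nrow(intervals))) {
    sel <- manifest$chromosome == intervals$chromosome[i] &
      manifest$position >= start[i] & manifest$position < end[i]
    hits <- c(hits, manifest$cpg_id[sel])
  }
  unique(hits)
}

#' Read a plain CpG id list
#'
#' One id per line; blank lines and `#` comments ignored. The standard
#' format for annotation sets that are already expressed as probe ids.
#'
#' @param path text file path.
#' @return Character vector of unique ids.
#' @export
read_cpg_list <- function(path) {
  if (!file.exists(path)) stop("cpg list not found: ", path, call. = FALSE)
  x <- trimws(readLines(path))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read a 3-column interval file (BED-style)
#'
#' Tab- or comma-separated `chromosome, start, end`, no header required
#' (a header line is auto-detected and skipped); `#` comments ignored.
#'
#' @param path file path.
#' @return Data frame with `chromosome`, `start`, `end`.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("interval file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(chromosome = character(0), start = numeric(0),
                      end = numeric(0)))
  }
  sep <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  parts <- strsplit(lines, sep, fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    stop("interval file rows need at least 3 fields: ", path, call. = FALSE)
  }
  first <- suppressWarnings(as.numeric(parts[[1]][2]))
  if (is.na(first)) parts <- parts[-1]  # header line
  data.frame(chromosome = vapply(parts, `[[`, "", 1L),
             start = as.numeric(vapply(parts, `[[`, "", 2L)),
             end = as.numeric(vapply(parts, `[[`, "", 3L)),
             stringsAsFactors = FALSE)
}
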