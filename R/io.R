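#' Read and write progress-curve CSV files
#'
#' Traces are stored as CSV with header `time_s,abs_390nm`, optionally
#' preceded by a `# key=value` metadata block carrying the assay conditions.
#' Numbers are written with 12 significant digits, so a write/read/write
#' round trip is byte-stable.
#'
#' @param path File path.
#' @param trace A [progress_curve()].
#' @param metadata Write the assay-conditions metadata block (default TRUE).
#' @return `read_trace_csv` returns a [progress_curve()]; `write_trace_csv`
#'   returns `path` invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' tr <- closed_form_trace(assay_conditions(enzyme = 4.34e-9), n_points = 10)
#' write_trace_csv(tr, f)
#' tr2 <- read_trace_csv(f)
#' @name trace_csv
NULL

fmt12 <- function(x) formatC(x, digits = 12, format = "g")

#' @rdname trace_csv
#' @export
write_trace_csv <- function(trace, path, metadata = TRUE) {
  stopifnot(inherits(trace, "progress_curve"))
  lines <- character(0)
  if (metadata) {
    cond <- trace$conditions
    meta_fields <- c("substrate_total", "cis_fraction", "enzyme",
                     "uncat_rate", "catalytic_efficiency", "protease_rate",
                     "extinction_coeff", "path_length", "baseline_abs",
                     "temperature", "duration")
    lines <- c(
      paste0("# provenance=", trace$provenance),
      vapply(meta_fields,
             function(f) paste0("# ", f, "=", fmt12(cond[[f]])),
             character(1))
    )
  }
  lines <- c(lines, "time_s,abs_390nm",
             paste(fmt12(trace$times), fmt12(trace$absorbances), sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname trace_csv
#' @export
read_trace_csv <- function(path) {
  if (!file.exists(path)) stop("cannot open file '", path, "'", call. = FALSE)
  raw <- readLines(path)
  if (length(raw) == 0L) stop("no data rows in ", path, call. = FALSE)
  is_meta <- grepl("^#", raw)
  meta_lines <- raw[is_meta]
  body <- raw[!is_meta]
  body_lineno <- which(!is_meta)
  if (length(body) == 0L) stop("no data rows in ", path, call. = FALSE)
  if (trimws(body[1L]) != "time_s,abs_390nm") {
    stop(sprintf("malformed header at line %d: expected 'time_s,abs_390nm', got '%s'",
                 body_lineno[1L], body[1L]), call. = FALSE)
  }
  rows <- body[-1L]
  row_lineno <- body_lineno[-1L]
  rows_keep <- nzchar(trimws(rows))
  rows <- rows[rows_keep]
  row_lineno <- row_lineno[rows_keep]
  if (length(rows) == 0L) stop("no data rows in ", path, call. = FALSE)

  parts <- strsplit(rows, ",", fixed = TRUE)
  bad_shape <- which(lengths(parts) != 2L)
  if (length(bad_shape) > 0L) {
    stop(sprintf("malformed row at line %d (expected 2 comma-separated fields)",
                 row_lineno[bad_shape[1L]]), call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                ncol = 2L, byrow = TRUE)
  bad_num <- which(rowSums(!is.finite(mat)) > 0)
  if (length(bad_num) > 0L) {
    stop(sprintf("non-numeric cell at line %d", row_lineno[bad_num[1L]]),
         call. = FALSE)
  }
  non_mono <- which(diff(mat[, 1L]) <= 0)
  if (length(non_mono) > 0L) {
    stop(sprintf("times not strictly increasing at line %d",
                 row_lineno[non_mono[1L] + 1L]), call. = FALSE)
  }

  meta <- parse_metadata_block(meta_lines)
  cond_args <- meta[names(meta) != "provenance"]
  conditions <- do.call(assay_conditions,
                        lapply(cond_args, as.numeric))
  provenance <- if ("provenance" %in% names(meta)) {
    meta[["provenance"]]
  } else {
    "measured"
  }
  progress_curve(mat[, 1L], mat[, 2L], conditions, provenance = provenance)
}

parse_metadata_block <- function(meta_lines) {
  if (length(meta_lines) == 0L) return(list())
  kv <- sub("^#\\s*", "", meta_lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  known <- c("provenance", "substrate_total", "cis_fraction", "enzyme",
             "uncat_rate", "catalytic_efficiency", "protease_rate",
             "extinction_coeff", "path_length", "baseline_abs",
             "temperature", "duration")
  keep <- keys %in% known
  stats::setNames(as.list(vals[keep]), keys[keep])
}

#' Read and write inhibitor-titration CSV files
#'
#' Titrations are stored as CSV with header `inhibitor_M,k_per_s`, plus a
#' `replicate` column when the series carries replicates. A `# key=value`
#' metadata block records the inhibitor name and the `k0`/`ku` anchors.
#'
#' @param series An [inhibition_series()].
#' @param path File path.
#' @param k0,ku Rate anchors (1/s), required on read when the file carries
#'   no metadata block.
#' @return `read_titration_csv` returns an [inhibition_series()];
#'   `write_titration_csv` returns `path` invisibly.
#' @name titration_csv
NULL

#' @rdname titration_csv
#' @export
write_titration_csv <- function(series, path) {
  stopifnot(inherits(series, "inhibition_series"))
  lines <- c(
    paste0("# inhibitor_name=", series$inhibitor_name),
    paste0("# k0=", fmt12(series$k0)),
    paste0("# ku=", fmt12(series$ku))
  )
  if (is.null(series$replicate_k)) {
    lines <- c(lines, "inhibitor_M,k_per_s",
               paste(fmt12(series$points$conc), fmt12(series$points$k),
                     sep = ","))
  } else {
    rk <- series$replicate_k
    lines <- c(lines, "inhibitor_M,k_per_s,replicate")
    for (j in seq_len(ncol(rk))) {
      lines <- c(lines, paste(fmt12(series$points$conc), fmt12(rk[, j]), j,
                              sep = ","))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname titration_csv
#' @export
read_titration_csv <- function(path, k0 = NULL, ku = NULL) {
  if (!file.exists(path)) stop("cannot open file '", path, "'", call. = FALSE)
  raw <- readLines(path)
  is_meta <- grepl("^#", raw)
  meta <- parse_titration_meta(raw[is_meta])
  body <- raw[!is_meta]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2L) stop("no data rows in ", path, call. = FALSE)
  header <- trimws(body[1L])
  has_rep <- identical(header, "inhibitor_M,k_per_s,replicate")
  if (!has_rep && !identical(header, "inhibitor_M,k_per_s")) {
    stop("malformed header: expected 'inhibitor_M,k_per_s[,replicate]', got '",
         header, "'", call. = FALSE)
  }
  df <- utils::read.csv(text = body, header = TRUE)
  if (any(!is.finite(df$inhibitor_M)) || any(!is.finite(df$k_per_s))) {
    stop("non-numeric cell in ", path, call. = FALSE)
  }
  k0 <- if (!is.null(meta$k0)) as.numeric(meta$k0) else k0
  ku <- if (!is.null(meta$ku)) as.numeric(meta$ku) else ku
  if (is.null(k0) || is.null(ku)) {
    stop("k0 and ku must be supplied (no metadata block in file)",
         call. = FALSE)
  }
  name <- if (!is.null(meta$inhibitor_name)) meta$inhibitor_name else "inhibitor"
  if (has_rep) {
    concs <- sort(unique(df$inhibitor_M))
    reps <- sort(unique(df$replicate))
    rk <- matrix(NA_real_, nrow = length(concs), ncol = length(reps))
    for (j in seq_along(reps)) {
      sub <- df[df$replicate == reps[j], ]
      rk[, j] <- sub$k_per_s[match(concs, sub$inhibitor_M)]
    }
    inhibition_series(name, concs, rowMeans(rk), k0 = k0, ku = ku,
                      replicate_k = rk)
  } else {
    inhibition_series(name, df$inhibitor_M, df$k_per_s, k0 = k0, ku = ku)
  }
}

parse_titration_meta <- function(meta_lines) {
  kv <- sub("^#\\s*", "", meta_lines)
  kv <- kv[grepl("=", kv, fixed = TRUE)]
  stats::setNames(as.list(sub("^[^=]*=", "", kv)), sub("=.*$", "", kv))
}

#' Parse a molar concentration with SI prefix
#'
#' Accepts strings like `"4.34nM"`, `"11.16uM"`, `"80e-6M"`; the unit must
#' be molar with an optional SI prefix (p, n, u, m). Used by the CLI so
#' every concentration flag is explicit about units.
#'
#' @param x Character scalar.
#' @return Concentration in mol/L.
#' @examples
#' parse_molar("4.34nM")   # 4.34e-09
#' parse_molar("11.16uM")  # 1.116e-05
#' @export
parse_molar <- function(x) {
  if (is.numeric(x)) {
    stop("concentration must carry a molar unit, e.g. '4.34nM'", call. = FALSE)
  }
  m <- regmatches(x, regexec(
    "^\\s*([0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?)\\s*([pnum]?)M\\s*$", x))[[1L]]
  if (length(m) == 0L) {
    stop("cannot parse molar concentration '", x,
         "'; expected e.g. '4.34nM', '11.16uM', '80e-6M'", call. = FALSE)
  }
  mult <- c(p = 1e-12, n = 1e-9, u = 1e-6, m = 1e-3)
  pref <- m[3L]
  as.numeric(m[2L]) * if (nzchar(pref)) mult[[pref]] else 1
}
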