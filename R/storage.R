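CSV_NULL_SENTINEL <- "\\N"

#' Write a table in row-text (CSV) or columnar (Parquet) format
#'
#' The CSV dialect is pinned: UTF-8, header row, RFC-4180 quoting, nulls
#' encoded as the unquoted sentinel `\\N` (the PostgreSQL `COPY` convention)
#' so that `NA` and the empty string remain distinct under round-trip.
#' Parquet uses the arrow writer with its default compression codec, which
#' is recorded in the returned attributes. Dates serialize as ISO strings in
#' CSV and native date type in Parquet.
#'
#' @param table A data.frame / data.table.
#' @param path Output file path.
#' @param format `"csv"` or `"parquet"`.
#' @return `path`, invisibly, with a `format` attribute.
#' @export
write_table <- function(table, path, format = c("csv", "parquet")) {
  format <- match.arg(format)
  df <- as.data.frame(data.table::as.data.table(table))
  if (format == "csv") {
    # a data value equal to the null sentinel would be unrecoverable
    for (col in names(df)) {
      if (is.character(df[[col]]) && any(df[[col]] == CSV_NULL_SENTINEL, na.rm = TRUE)) {
        stop("column '", col, "' contains the literal CSV null sentinel '",
             CSV_NULL_SENTINEL, "'; refusing to write ambiguous CSV", call. = FALSE)
      }
    }
    arrow::write_csv_arrow(
      df, path,
      write_options = arrow::CsvWriteOptions$create(null_string = CSV_NULL_SENTINEL)
    )
  } else {
    arrow::write_parquet(df, path)
  }
  invisible(structure(path, format = format))
}

#' Read a table written by [write_table()]
#'
#' @param path File path.
#' @param format `"csv"` or `"parquet"`.
#' @param schema Optional named character vector of R column types
#'   (`"character"`, `"integer"`, `"double"`, `"logical"`, `"Date"`).
#'   Columns are cast to the declared types; a cast that would introduce
#'   `NA`s, or a missing declared column, fails explicitly — no silent
#'   coercion.
#' @return A `data.table`.
#' @export
read_table <- function(path, format = c("csv", "parquet"), schema = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- if (format == "csv") {
    as.data.frame(arrow::read_csv_arrow(
      path,
      convert_options = arrow::CsvConvertOptions$create(
        null_values = CSV_NULL_SENTINEL, strings_can_be_null = TRUE)
    ))
  } else {
    as.data.frame(arrow::read_parquet(path))
  }
  tab <- data.table::as.data.table(df)
  if (!is.null(schema)) {
    missing <- setdiff(names(schema), names(tab))
    if (length(missing)) {
      stop("schema mismatch: columns absent from file: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (col in names(schema)) {
      x <- tab[[col]]
      was_na <- is.na(x)
      y <- suppressWarnings(switch(schema[[col]],
        character = as.character(x),
        integer = as.integer(x),
        double = as.numeric(x),
        logical = as.logical(x),
        Date = as.Date(as.character(x)),
        stop("unknown schema type '", schema[[col]], "'", call. = FALSE)
      ))
      if (any(is.na(y) & !was_na)) {
        stop("schema mismatch: column '", col, "' cannot be cast to ",
             schema[[col]], call. = FALSE)
      }
      data.table::set(tab, j = col, value = y)
    }
  } else {
    # integer64 from arrow downcasts to double for plain-R ergonomics
    for (col in names(tab)) {
      if (inherits(tab[[col]], "integer64")) {
        data.table::set(tab, j = col, value = as.numeric(tab[[col]]))
      }
    }
  }
  tab
}

#' File-size ratio of a row-format file to a columnar file
#'
#' Instrumentation only: compression is data- and codec-dependent, so the
#' ratio is reported, never asserted.
#'
#' @param path_row,path_columnar Paths to the two files holding the same
#'   logical table.
#' @return `size(row) / size(columnar)`.
#' @export
compression_ratio <- function(path_row, path_columnar) {
  for (p in c(path_row, path_columnar)) {
    if (!file.exists(p)) stop("no such file: ", p, call. = FALSE)
  }
  as.numeric(file.size(path_row)) / as.numeric(file.size(path_columnar))
}

#' Paired-run stage timing harness
#'
#' Materializes the cohort in both storage formats, then for each run and
#' each format executes the three instrumented stages — `io` (read the
#' table), `feature_transform` (defining-code exclusion and signed feature
#' hashing), `training` (one-vs-rest boosted trees) — under identical seeds,
#' emitting paired timing records that share `run_id` across formats.
#' Timings are instrumentation for reporting; they are hardware-dependent
#' and never feed acceptance logic. Runs that fail part-way are marked
#' incomplete and excluded from pairing.
#'
#' @param table A cleansed, deduplicated encounter table.
#' @param n_runs Number of paired runs (default 20).
#' @param dir Working directory for the materialized files.
#' @param label_specs Label definitions for the modeling stage.
#' @param config [model_config()] used in the training stage.
#' @param hash_bits Feature-hash width exponent.
#' @param seed Base seed shared across formats within a run.
#' @return `data.table(run_id, format, stage, wall_seconds, peak_memory_mb,
#'   complete)`.
#' @export
run_paired_benchmark <- function(table, n_runs = 20L, dir = tempdir(),
                                 label_specs = default_label_specs(),
                                 config = model_config(), hash_bits = 18L,
                                 seed = 42L) {
  tab <- data.table::as.data.table(table)
  paths <- list(csv = file.path(dir, "bench_cohort.csv"),
                parquet = file.path(dir, "bench_cohort.parquet"))
  write_table(tab, paths$csv, "csv")
  write_table(tab, paths$parquet, "parquet")
  timed <- function(expr) {
    t0 <- proc.time()[["elapsed"]]
    force(expr)
    proc.time()[["elapsed"]] - t0
  }
  rows <- list()
  for (run in seq_len(n_runs)) {
    for (fmt in c("csv", "parquet")) {
      rec <- tryCatch({
        gc(reset = TRUE)
        t_io <- timed(cohort <- read_table(paths[[fmt]], fmt))
        t_feat <- timed({
          sets <- patient_code_multisets(cohort, exclude = label_specs)
          X <- hash_features(sets, n_bits = hash_bits)
        })
        Y <- build_label_matrix(cohort, label_specs)[rownames(X), , drop = FALSE]
        t_train <- timed(fit_ovr(X, Y, config = config))
        peak <- sum(gc()[, 6L])
        data.table::data.table(
          run_id = run, format = fmt,
          stage = c("io", "feature_transform", "training"),
          wall_seconds = c(t_io, t_feat, t_train),
          peak_memory_mb = peak, complete = TRUE)
      }, error = function(e) {
        data.table::data.table(run_id = run, format = fmt,
                               stage = "failed", wall_seconds = NA_real_,
                               peak_memory_mb = NA_real_, complete = FALSE)
      })
      rows[[length(rows) + 1L]] <- rec
    }
  }
  out <- data.table::rbindlist(rows)
  # run ids usable for paired statistics: complete under both formats
  ok <- out[, all(complete), by = run_id][V1 == TRUE][["run_id"]]
  data.table::setattr(out, "paired_run_ids", ok)
  out[]
}
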