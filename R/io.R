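#' Read and write the package's CSV formats
#'
#' Plain-CSV plumbing shared by the functions and the command-line
#' wrapper. Numbers are written at full double precision with `.` as the
#' decimal separator, so a write/read round trip is bit-identical.
#'
#' @param traj a `sir_trajectory`.
#' @param path file path.
#' @return `read_trajectory_csv()` returns a `sir_trajectory` (its
#'   `params` attribute is only present if supplied); the writers return
#'   `path` invisibly.
#' @name viralsir_io
NULL

write_full_csv <- function(df, path) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- sprintf("%.17g", out[[nm]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname viralsir_io
#' @export
write_trajectory_csv <- function(traj, path) {
  if (!inherits(traj, "sir_trajectory")) {
    stop("'traj' must be a sir_trajectory", call. = FALSE)
  }
  write_full_csv(as.data.frame(traj)[c("t", "S", "I", "R")], path)
}

#' @rdname viralsir_io
#' @param params optional [model_params()] to attach to the trajectory.
#' @export
read_trajectory_csv <- function(path, params = NULL) {
  df <- utils::read.csv(path)
  need <- c("t", "S", "I", "R")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("trajectory CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  structure(df[need], params = params, N = df$S[1L] + df$I[1L] + df$R[1L],
            class = c("sir_trajectory", "data.frame"))
}

#' Read a daily view series from CSV
#'
#' Expects a header `day,views` with integer days starting at 0 and
#' nonnegative view counts; the companion writer emits the same dialect.
#'
#' @param path file path.
#' @return A [view_series()].
#' @export
read_view_series_csv <- function(path) {
  df <- utils::read.csv(path)
  missing_cols <- setdiff(c("day", "views"), names(df))
  if (length(missing_cols) > 0) {
    stop("view-series CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  view_series(as.numeric(df$views), days = df$day)
}

#' @rdname read_view_series_csv
#' @param series a [view_series()].
#' @export
write_view_series_csv <- function(series, path) {
  if (!inherits(series, "view_series")) {
    stop("'series' must be a view_series", call. = FALSE)
  }
  write_full_csv(data.frame(day = series$day, views = series$daily), path)
}

#' @rdname viralsir_io
#' @param result an `abm_result` or the `mean` element of an
#'   [abm_ensemble()].
#' @export
write_abm_csv <- function(result, path) {
  write_full_csv(as.data.frame(result)[c("t", "O", "P", "Q", "typeA", "typeB")],
                 path)
}

#' @rdname viralsir_io
#' @export
read_abm_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("t", "O", "P", "Q", "typeA", "typeB")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("ABM CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  structure(df[need], class = c("abm_result", "data.frame"))
}
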