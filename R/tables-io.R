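# Lossless text serialisation of the result tables. Numeric columns are
# written with 17 significant digits so that read(write(x)) reproduces every
# double bit-exactly; JSON goes through jsonlite with full precision.

fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write a result table (occupancy table, interface report, mode summary)
#'
#' Dispatches on class: occupancy tables and mode summaries become CSV,
#' interface reports JSON. Round trips through the matching `read_*` function
#' are field-exact.
#'
#' @param x the object.
#' @param path output file.
#' @export
write_table <- function(x, path) UseMethod("write_table")

#' @export
write_table.occupancy_table <- function(x, path) {
  df <- as.data.frame(x)
  df$occupancy <- fmt_num(df$occupancy)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an occupancy table written by [write_table()].
#' @param path CSV file.
#' @export
read_occupancy_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(res1 = "integer", res2 = "integer",
                                       name1 = "character", name2 = "character",
                                       kind = "character",
                                       occupancy = "numeric",
                                       label = "character"))
  new_occupancy_table(df)
}

#' @export
write_table.interface_report <- function(x, path) {
  out <- x[c("chain_A", "chain_B", "interface_area", "delta_G",
             "delta_G_p_value", "in_contact")]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read an interface report written by [write_table()].
#' @param path JSON file.
#' @export
read_interface_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$delta_G_p_value)) x$delta_G_p_value <- NA_real_
  structure(x, class = "interface_report")
}

#' Mode-set summary table (eigenvalue spectrum with explained fractions).
#' @param mode_set a [pca_cartesian()] result.
#' @param n_modes rows to keep (default 10, the usual spectrum-plot depth).
#' @export
mode_summary <- function(mode_set, n_modes = 10) {
  k <- min(n_modes, length(mode_set$eigenvalues))
  df <- data.frame(mode = seq_len(k),
                   eigenvalue = mode_set$eigenvalues[seq_len(k)],
                   explained_fraction = mode_set$explained_fraction[seq_len(k)],
                   cumulative_fraction = mode_set$cumulative_fraction[seq_len(k)])
  class(df) <- c("mode_summary", "data.frame")
  df
}

#' @export
write_table.mode_summary <- function(x, path) {
  df <- as.data.frame(x)
  for (cc in c("eigenvalue", "explained_fraction", "cumulative_fraction"))
    df[[cc]] <- fmt_num(df[[cc]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a mode summary written by [write_table()].
#' @param path CSV file.
#' @export
read_mode_summary <- function(path) {
  df <- utils::read.csv(path, colClasses = c(mode = "integer",
                                             eigenvalue = "numeric",
                                             explained_fraction = "numeric",
                                             cumulative_fraction = "numeric"))
  class(df) <- c("mode_summary", "data.frame")
  df
}

#' @export
write_table.data.frame <- function(x, path) {
  df <- x
  for (cc in names(df)) if (is.double(df[[cc]])) df[[cc]] <- fmt_num(df[[cc]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a named list of result tables into a directory
#'
#' File names come from the list names with an extension by type (.json for
#' interface reports, .csv otherwise).
#'
#' @param tables named list.
#' @param dir output directory (created if missing).
#' @return named character vector of paths.
#' @export
write_tables <- function(tables, dir) {
  stopifnot(length(names(tables)) == length(tables))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vapply(names(tables), function(nm) {
    ext <- if (inherits(tables[[nm]], "interface_report")) ".json" else ".csv"
    p <- file.path(dir, paste0(nm, ext))
    write_table(tables[[nm]], p)
    p
  }, character(1))
}
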