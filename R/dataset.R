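#' Read a dose dataset from CSV
#'
#' Reads a CSV of H/D records with (at least) the columns `x_cm`, `y_cm`,
#' `z_cm`, `energy_MeV`, `environment`, `hd_Sv_per_Gy`. Missing columns,
#' non-positive H/D values and unknown environment tokens are reported with
#' the offending column or line.
#'
#' @param path Path to a CSV file.
#' @return A dose-dataset tibble (provenance `"file"`).
#' @seealso [write_dataset()]
#' @export
read_dataset <- function(path) {
  stop_unless(file.exists(path), paste0("dataset file not found: ", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("x_cm", "y_cm", "z_cm", "energy_MeV", "environment", "hd_Sv_per_Gy")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("parse error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_hd <- which(!is.finite(df$hd_Sv_per_Gy) | df$hd_Sv_per_Gy <= 0)
  if (length(bad_hd)) {
    stop("parse error in ", path, " line ", bad_hd[1] + 1L,
         ": hd_Sv_per_Gy must be a positive number", call. = FALSE)
  }
  bad_env <- which(!df$environment %in% c("in_water", "in_air"))
  if (length(bad_env)) {
    stop("parse error in ", path, " line ", bad_env[1] + 1L,
         ": unknown environment token \"", df$environment[bad_env[1]], "\"",
         call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  attr(out, "provenance") <- "file"
  out
}

#' Write a dose dataset to CSV
#'
#' Numeric values are written with full double precision, so a write/read
#' round trip reproduces every record exactly.
#'
#' @param data A dose-dataset data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  data <- check_dataset(data)
  df <- as.data.frame(data)
  num <- vapply(df, is.numeric, logical(1))
  # format(digits = 17) is the shortest round-trippable decimal form
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, scientific = TRUE,
                                                trim = TRUE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Validation report of model accuracy against a dataset
#'
#' Tabulates the average and maximum local relative error of a model
#' configuration against a dose dataset, per proton beam energy and overall:
#' one row per distinct energy (descending) plus an `"All"` row. Optionally
#' writes the table as CSV and as human-readable text.
#'
#' @inheritParams predict_hd
#' @param csv,txt Optional output paths for a CSV and a plain-text rendering.
#' @return A tibble with columns `energy` (character; `"All"` for the overall
#'   row), `n`, `mean_pct`, `max_pct`.
#' @export
validate_report <- function(config, data, csv = NULL, txt = NULL) {
  stats <- error_statistics(config, data)
  tab <- dplyr::bind_rows(
    tibble::tibble(energy = "All", n = nrow(data),
                   mean_pct = stats$mean_pct, max_pct = stats$max_pct),
    dplyr::mutate(stats$per_energy, energy = format(.data$energy_MeV)) |>
      dplyr::select("energy", "n", "mean_pct", "max_pct")
  )
  if (!is.null(csv)) utils::write.csv(as.data.frame(tab), csv, row.names = FALSE)
  if (!is.null(txt)) {
    lines <- c(
      sprintf("Local relative error of configuration \"%s\" (%d records)",
              config$name, nrow(data)),
      sprintf("%-10s %6s %12s %12s", "Energy", "n", "mean (%)", "max (%)"),
      sprintf("%-10s %6d %12.2f %12.2f", tab$energy, tab$n, tab$mean_pct,
              tab$max_pct)
    )
    writeLines(lines, txt)
  }
  tab
}
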