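#' Packaged covalent-compound records
#'
#' Reads the packaged compound table (id, lab code, molecular formula,
#' leaving-group formula, warhead class) and returns validated
#' [compound_record()] objects. Compound-number-to-lab-code pairings
#' that are not certain are left blank rather than guessed.
#'
#' @return Named list of `compound_record` objects (named by id where
#'   present, else by lab code).
#' @export
load_fixture_compounds <- function() {
  path <- system.file("extdata", "compounds.csv", package = "covalentCA",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("id", "code", "formula", "leaving_group_formula",
            "warhead_class")
  if (!all(need %in% names(tab))) {
    stop("malformed compound fixture: expected columns ",
         paste(need, collapse = ", "))
  }
  recs <- lapply(seq_len(nrow(tab)), function(i) {
    lg <- tab$leaving_group_formula[i]
    compound_record(
      id = if (nzchar(tab$id[i])) tab$id[i] else tab$code[i],
      code = if (nzchar(tab$code[i])) tab$code[i] else NA_character_,
      formula = tab$formula[i],
      leaving_group = if (nzchar(lg)) lg else NULL,
      warhead_class = tab$warhead_class[i])
  })
  names(recs) <- vapply(recs, `[[`, "", "id")
  recs
}

#' Packaged high-resolution MS reference values
#'
#' The printed exact-mass calibration set: molecular formula, ion
#' species and the published calculated m/z for every synthesis-series
#' compound, used as the oracle suite for [ion_mz()].
#'
#' @return Data frame with columns `formula`, `species`, `calc_mz`,
#'   `note`.
#' @export
load_hrms_reference <- function() {
  path <- system.file("extdata", "hrms_reference.csv",
                      package = "covalentCA", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a deconvoluted peak list CSV
#'
#' Two columns required: `mass_da`, `intensity`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_peaks <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("mass_da", "intensity") %in% names(df))) {
    stop("peak list must have columns mass_da, intensity")
  }
  stopifnot(all(df$mass_da > 0), all(df$intensity >= 0))
  df
}

#' Read a per-well Tm table CSV
#'
#' Columns: `well_id`, `Lt_M`, `Tm_C`, `Pt_M` (temperatures Celsius in
#' files, kelvin internally; a `Tm_K` column is added).
#'
#' @param path CSV path.
#' @return Data frame with an added `Tm_K` column.
#' @export
read_tm_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("well_id", "Lt_M", "Tm_C", "Pt_M")
  if (!all(need %in% names(df))) {
    stop("Tm table must have columns ", paste(need, collapse = ", "))
  }
  df$Tm_K <- celsius_to_kelvin(df$Tm_C)
  df
}

#' Read long-format melt curves CSV
#'
#' Columns: `well_id`, `temperature_C`, `fluorescence`.
#'
#' @param path CSV path.
#' @return Data frame with an added `temperature_K` column.
#' @export
read_melt_curves <- function(path) {
  df <- utils::read.csv(path)
  need <- c("well_id", "temperature_C", "fluorescence")
  if (!all(need %in% names(df))) {
    stop("melt curves must have columns ", paste(need, collapse = ", "))
  }
  df$temperature_K <- celsius_to_kelvin(df$temperature_C)
  df
}

#' Read a competition dose-response CSV
#'
#' Columns: `well_id`, `competitor_total_M`, `signal` (optional
#' `replicate`).
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_competition_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("well_id", "competitor_total_M", "signal")
  if (!all(need %in% names(df))) {
    stop("competition table must have columns ",
         paste(need, collapse = ", "))
  }
  stopifnot(all(df$competitor_total_M >= 0))
  df
}

#' Write an analysis result as JSON with config echo
#'
#' Every analysis output embeds the resolved configuration and the
#' package version so numbers are reproducible from the file alone.
#'
#' @param result Named list of results.
#' @param path Output path.
#' @param config Named list of resolved parameters.
#' @return The path, invisibly.
#' @export
write_result_json <- function(result, path, config = list()) {
  payload <- c(result,
               list(config = config,
                    package_version =
                      as.character(utils::packageVersion("covalentCA"))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
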