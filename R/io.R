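# Table schemas, versioned. Each entry maps column name -> readr type code
# (c = character, d = double, i = integer, l = logical). Written tables carry
# the schema name and version in a header comment line and are validated
# strictly on read.
.phyto_schema_version <- "v1"
.phyto_schemas <- list(
  cultures = c(culture_id = "c", culture_type = "c", regime = "c", co2 = "c",
               replicate = "i", chamber = "c", day = "d", species = "c",
               true_density = "d", count = "d", frequency = "d",
               density_cells_per_ml = "d"),
  species_truth = c(name = "c", taxon = "c", r_ambient = "d",
                    delta_r_co2 = "d", counting_instrument = "c"),
  growth_fits = c(culture_id = "c", species = "c", co2 = "c", regime = "c",
                  replicate = "i", chamber = "c", r = "d",
                  standard_error = "d", n_points = "i", method = "c"),
  growth_responses = c(species = "c", regime = "c", delta_r = "d",
                       uncertainty = "d", n_high = "i", n_ambient = "i"),
  coefficients = c(focal = "c", opponent = "c", kind = "c", level = "c",
                   co2 = "c", regime = "c", replicate = "i",
                   g_community = "d", value = "d"),
  responses = c(focal = "c", opponent = "c", kind = "c", level = "c",
                regime = "c", replicate = "i", response = "d",
                reversal = "l"),
  prediction_summary = c(level = "c", predictor = "c", regime = "c",
                         slope = "d", intercept = "d", r_squared = "d",
                         n = "i"),
  prediction_points = c(species = "c", regime = "c", x = "d", y = "d",
                        n = "i", dispersion = "d", level = "c"),
  carbonate_samples = c(sample_id = "c", ph = "d", ta_umol_kg = "d",
                        temp_c = "d", salinity = "d"),
  carbonate_solved = c(sample_id = "c", ph = "d", ta_umol_kg = "d",
                       temp_c = "d", salinity = "d", dic_umol_kg = "d",
                       pco2_uatm = "d", co2_aq_umol_kg = "d"),
  recovery = c(species = "c", regime = "c", r_ambient_true = "d",
               r_ambient_est = "d", r_high_true = "d", r_high_est = "d",
               delta_r_true = "d", delta_r_est = "d", r_ambient_error = "d",
               r_high_error = "d", delta_r_error = "d")
)

#' List the table schemas the package reads and writes
#'
#' @return Named list: schema name -> named character vector of column
#'   `readr` type codes.
#' @export
phyto_schemas <- function() .phyto_schemas

#' Write a pipeline table with a schema header
#'
#' Writes CSV preceded by one comment line
#' `# phytocomp-table <name> <version>` identifying the schema, so readers can
#' validate strictly. Doubles are written in shortest round-trip
#' representation (readr), so write/read round trips are lossless.
#'
#' @param df the table; must have exactly the schema's columns.
#' @param path output file.
#' @param name schema name, one of `names(phyto_schemas())`.
#' @return `path`, invisibly.
#' @export
write_phyto_table <- function(df, path, name) {
  # shortest decimal representation that parses back to the identical double
  fmt_double <- function(x) {
    s <- sprintf("%.15g", x)
    widen <- is.finite(x)
    widen[widen] <- as.numeric(s[widen]) != x[widen]
    s[widen] <- sprintf("%.17g", x[widen])
    s[is.na(x)] <- NA_character_
    s
  }
  schema <- .phyto_schemas[[name]]
  if (is.null(schema)) {
    stop("unknown table schema `", name, "`; see phyto_schemas()",
         call. = FALSE)
  }
  if (!setequal(names(df), names(schema))) {
    stop("table does not match schema `", name, "`: expected columns {",
         paste(names(schema), collapse = ", "), "}, got {",
         paste(names(df), collapse = ", "), "}", call. = FALSE)
  }
  df <- df[, names(schema)]
  for (col in names(schema)[schema == "d"]) df[[col]] <- fmt_double(df[[col]])
  writeLines(sprintf("# phytocomp-table %s %s", name, .phyto_schema_version),
             path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read a pipeline table, validating its schema
#'
#' @param path file written by [write_phyto_table()].
#' @param name expected schema name; if `NULL`, taken from the file header.
#' @return A tibble with the schema's columns and types.
#' @export
read_phyto_table <- function(path, name = NULL) {
  header <- readLines(path, n = 1)
  m <- regmatches(header,
                  regexec("^# phytocomp-table (\\S+) (\\S+)$", header))[[1]]
  if (length(m) != 3) {
    stop("`", path, "` lacks a phytocomp schema header line", call. = FALSE)
  }
  file_name <- m[2]; file_version <- m[3]
  if (!is.null(name) && file_name != name) {
    stop("expected schema `", name, "` but file declares `", file_name, "`",
         call. = FALSE)
  }
  if (file_version != .phyto_schema_version) {
    stop("unsupported table version `", file_version, "` (supported: ",
         .phyto_schema_version, ")", call. = FALSE)
  }
  schema <- .phyto_schemas[[file_name]]
  if (is.null(schema)) {
    stop("file declares unknown schema `", file_name, "`", call. = FALSE)
  }
  # doubles come in as text and through R's correctly rounded parser, so a
  # write/read round trip reproduces them bit for bit
  read_types <- ifelse(schema == "d", "c", schema)
  df <- readr::read_csv(path, skip = 1,
                        col_types = paste(read_types, collapse = ""),
                        progress = FALSE, show_col_types = FALSE)
  for (col in names(schema)[schema == "d"]) df[[col]] <- as.numeric(df[[col]])
  if (!identical(names(df), names(schema))) {
    stop("columns of `", path, "` do not match schema `", file_name, "`",
         call. = FALSE)
  }
  df
}
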