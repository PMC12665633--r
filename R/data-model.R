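#' @name dataset
#' @title The mesocosm dataset container
#'
#' @description A `mesotox_dataset` is a list of tidy tables keyed by
#' `tank_id`:
#' \describe{
#'   \item{tanks}{tank_id, block, nominal_conc (ug/L), initial_measured_conc
#'     (treatment-group mean 1-h measured concentration, ug/L)}
#'   \item{chemistry}{tank_id, day, analyte, value, below_detection,
#'     detection_limit; censored values are stored at the detection limit
#'     with the flag set, never as zero}
#'   \item{amphipods}{tank_id, cage_id, week, n_atrisk, n_alive,
#'     n_juveniles, growth_mg (mg wet weight per surviving amphipod,
#'     week 6 only)}
#'   \item{tadpoles}{tank_id, tadpole_id, survived, gosner, days_elapsed,
#'     mass_g, liver_g, sex (F / M / unknown)}
#'   \item{algae}{tank_id, day, taxon, count, biomass_mg_m3}
#'   \item{chlorophyll}{tank_id, day, chl_ug_l}
#'   \item{stress}{tank_id, hne_ug_g, protein_carbonyl_nmol_mg}
#' }
#' Models use the treatment-group mean measured 1-h concentration by
#' default; `conc_from()` switches between that and nominal.
NULL

.table_schemas <- list(
  tanks = c("tank_id", "nominal_conc", "initial_measured_conc"),
  chemistry = c("tank_id", "day", "analyte", "value", "below_detection"),
  amphipods = c("tank_id", "cage_id", "week", "n_atrisk", "n_alive"),
  tadpoles = c("tank_id", "tadpole_id", "survived", "gosner",
               "days_elapsed", "mass_g", "liver_g", "sex"),
  algae = c("tank_id", "day", "taxon", "count", "biomass_mg_m3"),
  chlorophyll = c("tank_id", "day", "chl_ug_l"),
  stress = c("tank_id", "hne_ug_g", "protein_carbonyl_nmol_mg")
)

.table_files <- c(tanks = "tanks.csv", chemistry = "chemistry.csv",
                  amphipods = "amphipods.csv", tadpoles = "tadpoles.csv",
                  algae = "algae_counts.csv",
                  chlorophyll = "chlorophyll.csv", stress = "stress.csv")

.empty_table <- function(name) {
  cols <- .table_schemas[[name]]
  df <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
  df
}

#' Read a mesocosm experiment dataset
#'
#' @param path directory of tidy CSV tables (`tanks.csv`, `chemistry.csv`,
#'   `amphipods.csv`, `tadpoles.csv`, `algae_counts.csv`,
#'   `chlorophyll.csv`, `stress.csv`), or an XLSX workbook.
#' @param layout `"csv_dir"` or `"supplementary_xlsx"`.
#' @param sheet_map for the XLSX layout, a named list mapping table names
#'   (as above) to sheet names, since workbook sheet naming varies.
#' @return a `mesotox_dataset`. Missing non-mandatory tables yield empty
#'   tables with a warning; missing mandatory columns are an error naming
#'   the column.
#' @export
read_dataset <- function(path, layout = c("csv_dir", "supplementary_xlsx"),
                         sheet_map = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("path does not exist: ", path)
  ds <- list()
  for (name in names(.table_schemas)) {
    tab <- switch(layout,
      csv_dir = {
        f <- file.path(path, .table_files[[name]])
        if (!file.exists(f)) NULL
        else read.csv(f, stringsAsFactors = FALSE)
      },
      supplementary_xlsx = {
        if (is.null(sheet_map) || is.null(sheet_map[[name]])) NULL
        else {
          if (!requireNamespace("readxl", quietly = TRUE))
            stop("reading XLSX requires the readxl package")
          as.data.frame(readxl::read_excel(path, sheet = sheet_map[[name]]))
        }
      })
    if (is.null(tab)) {
      if (name == "tanks") stop("mandatory table 'tanks' not found")
      warning("table '", name, "' not found; using an empty table")
      tab <- .empty_table(name)
    }
    missing <- setdiff(.table_schemas[[name]], names(tab))
    if (length(missing) > 0 && nrow(tab) > 0)
      stop("table '", name, "' is missing mandatory column(s): ",
           paste(missing, collapse = ", "))
    ds[[name]] <- tab
  }
  if (nrow(ds$chemistry) > 0) {
    ds$chemistry$below_detection <- as.logical(ds$chemistry$below_detection)
    if (!"detection_limit" %in% names(ds$chemistry))
      ds$chemistry$detection_limit <- 5
  }
  if (nrow(ds$amphipods) > 0 && !"n_juveniles" %in% names(ds$amphipods))
    ds$amphipods$n_juveniles <- NA_real_
  if (nrow(ds$amphipods) > 0 && !"growth_mg" %in% names(ds$amphipods))
    ds$amphipods$growth_mg <- NA_real_
  if (nrow(ds$tanks) > 0 && !"block" %in% names(ds$tanks))
    ds$tanks$block <- NA_character_
  if (nrow(ds$tanks) > 0) ds$tanks$block <- as.character(ds$tanks$block)
  if (nrow(ds$amphipods) == 0)
    warning("empty amphipod table: zero survival observations")
  structure(ds, class = "mesotox_dataset")
}

#' Validate a dataset against its invariants
#'
#' Pure function: applies every type invariant and reports violations as
#' data, never as exceptions.
#'
#' @param ds a `mesotox_dataset`.
#' @return a `mesotox_validation` list: `errors` and `warnings` data frames
#'   (table, row, rule), and `n_records` per table. The dataset is accepted
#'   iff `errors` is empty.
#' @export
validate_dataset <- function(ds) {
  errors <- list()
  warnings <- list()
  err <- function(table, row, rule)
    errors[[length(errors) + 1]] <<- data.frame(table = table, row = row,
                                                rule = rule)
  tk <- ds$tanks
  if (anyDuplicated(tk$tank_id))
    err("tanks", which(duplicated(tk$tank_id))[1], "duplicate tank_id")
  if (nrow(tk) > 0) for (i in which(tk$nominal_conc < 0))
    err("tanks", i, "nominal_conc<0")
  known <- tk$tank_id
  for (name in c("chemistry", "amphipods", "tadpoles", "algae",
                 "chlorophyll", "stress")) {
    t <- ds[[name]]
    if (nrow(t) == 0) next
    for (i in which(!t$tank_id %in% known))
      err(name, i, "tank_id not in tanks table")
  }
  am <- ds$amphipods
  if (nrow(am) > 0) {
    for (i in which(am$n_alive > am$n_atrisk)) err("amphipods", i,
                                                   "alive>at_risk")
    for (i in which(am$n_alive < 0 | am$n_atrisk < 0))
      err("amphipods", i, "negative count")
  }
  td <- ds$tadpoles
  if (nrow(td) > 0) {
    for (i in which(!is.na(td$mass_g) & td$mass_g < 0))
      err("tadpoles", i, "negative mass")
    for (i in which(!is.na(td$liver_g) & td$liver_g < 0))
      err("tadpoles", i, "negative liver mass")
    for (i in which(!td$sex %in% c("F", "M", "unknown")))
      err("tadpoles", i, "sex not in {F, M, unknown}")
  }
  al <- ds$algae
  if (nrow(al) > 0) for (i in which(al$count < 0))
    err("algae", i, "negative count")
  ch <- ds$chemistry
  if (nrow(ch) > 0) {
    for (i in which(ch$value < 0)) err("chemistry", i, "negative value")
    bad <- ch$below_detection & abs(ch$value - ch$detection_limit) > 1e-9
    for (i in which(bad))
      err("chemistry", i, "censored value not stored at detection limit")
  }
  structure(list(
    errors = if (length(errors)) do.call(rbind, errors)
             else data.frame(table = character(0), row = integer(0),
                             rule = character(0)),
    warnings = if (length(warnings)) do.call(rbind, warnings)
               else data.frame(table = character(0), row = integer(0),
                               rule = character(0)),
    n_records = vapply(ds, nrow, 0)),
    class = "mesotox_validation")
}

#' @export
print.mesotox_validation <- function(x, ...) {
  cat("Dataset validation:", nrow(x$errors), "error(s),",
      nrow(x$warnings), "warning(s)\n")
  if (nrow(x$errors) > 0) print(x$errors, row.names = FALSE)
  invisible(x)
}

#' Write a dataset to a directory of tidy CSV tables
#'
#' Inverse of [read_dataset()] under the `csv_dir` layout; a dataset
#' written and re-read reproduces all values.
#'
#' @param ds a `mesotox_dataset`.
#' @param out_dir output directory (created if needed).
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (name in names(.table_files))
    write.csv(ds[[name]], file.path(out_dir, .table_files[[name]]),
              row.names = FALSE)
  invisible(out_dir)
}

#' Write result tables with a run manifest
#'
#' One tab-delimited text file per result table plus a JSON manifest with
#' the table names, file checksums, the seed and configuration used, and
#' software versions. Re-running with the same configuration and seed
#' reproduces byte-identical numeric tables.
#'
#' @param bundle named list of data frames.
#' @param out_dir writable output directory.
#' @param seed seed recorded in the manifest.
#' @param config configuration list recorded (hashed) in the manifest.
#' @return the manifest, invisibly.
#' @export
write_results <- function(bundle, out_dir, seed = NULL, config = NULL) {
  stopifnot(is.list(bundle))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (name in names(bundle)) {
    f <- file.path(out_dir, paste0(name, ".tsv"))
    write.table(bundle[[name]], f, sep = "\t", row.names = FALSE,
                quote = FALSE)
    files[name] <- f
  }
  manifest <- list(
    tables = names(bundle),
    files = as.list(setNames(basename(files), names(files))),
    md5 = as.list(setNames(unname(tools::md5sum(files)), names(files))),
    seed = seed,
    config_hash = if (is.null(config)) NULL else
      unname(tools::md5sum(.serialize_config(config))),
    r_version = as.character(getRversion()),
    package_version = as.character(packageVersion("mesotox")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

.serialize_config <- function(config) {
  f <- tempfile(fileext = ".json")
  jsonlite::write_json(config, f, auto_unbox = TRUE, digits = NA)
  f
}

#' Tank-by-taxon community matrix for one sampling day
#'
#' @param ds a `mesotox_dataset`.
#' @param at_day sampling day.
#' @param value `"count"` (cells) or `"biomass_mg_m3"`.
#' @return matrix with tank ids as rows, taxa as columns, and attributes
#'   `day` and `treatment` (per-row nominal concentration).
#' @export
community_matrix <- function(ds, at_day, value = c("count", "biomass_mg_m3")) {
  value <- match.arg(value)
  al <- ds$algae[ds$algae$day == at_day, ]
  if (nrow(al) == 0) stop("no algae records at day ", at_day)
  m <- tapply(al[[value]], list(al$tank_id, al$taxon), sum, default = 0)
  m <- m[order(rownames(m)), , drop = FALSE]
  trt <- ds$tanks$nominal_conc[match(rownames(m), ds$tanks$tank_id)]
  attr(m, "day") <- at_day
  attr(m, "treatment") <- trt
  m
}

#' Model concentration per tank
#'
#' @param ds a `mesotox_dataset`.
#' @param scale `"measured_group_mean"` (default: the treatment-group mean
#'   1-h measured concentration) or `"nominal"`.
#' @return named vector of concentrations keyed by tank_id.
#' @export
conc_from <- function(ds, scale = c("measured_group_mean", "nominal")) {
  scale <- match.arg(scale)
  v <- switch(scale, measured_group_mean = ds$tanks$initial_measured_conc,
              nominal = ds$tanks$nominal_conc)
  setNames(v, ds$tanks$tank_id)
}

#' @export
print.mesotox_dataset <- function(x, ...) {
  cat("Mesocosm dataset:", nrow(x$tanks), "tanks,",
      length(unique(x$tanks$nominal_conc)), "treatment levels\n")
  for (name in names(.table_schemas))
    cat(sprintf("  %-12s %d records\n", name, nrow(x[[name]])))
  invisible(x)
}
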