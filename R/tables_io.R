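# Canonical tabular dialects
#
# The pipeline consumes post-search quantification tables in one canonical
# TSV dialect per experiment type (Census/DTASelect-style exports vary by
# version; third-party layouts are ingested through a column-mapping
# config).  All readers are strict: every cell is parsed under C-locale
# rules (decimal point only) and invariant violations are reported with the
# offending row number.

PEPTIDE_COLUMNS <- c(
  "peptide", "protein", "heavy_area", "light_area",
  "chase_time", "genotype", "replicate"
)

SPECCOUNT_COLUMNS <- c("protein", "bait", "genotype", "replicate", "spec_count")

# -- column-mapping config -----------------------------------------------

#' Read a column-mapping configuration
#'
#' Maps source column names of a third-party export onto the canonical
#' column names of the peptide or spectral-count dialect.  Accepts a named
#' character vector / list (`c(source = "canonical", ...)`) or a path to a
#' YAML or JSON file with the same structure.
#'
#' @param col_map Named character vector, named list, or file path.
#' @return Named character vector (names = source columns, values =
#'   canonical columns), or `NULL` if `col_map` is `NULL`.
#' @export
read_column_map <- function(col_map) {
  if (is.null(col_map)) return(NULL)
  if (is.character(col_map) && length(col_map) == 1 && is.null(names(col_map)) &&
      file.exists(col_map)) {
    col_map <- if (grepl("\\.ya?ml$", col_map)) {
      yaml::read_yaml(col_map)
    } else {
      jsonlite::read_json(col_map, simplifyVector = TRUE)
    }
  }
  map <- unlist(col_map)
  if (is.null(names(map)) || any(names(map) == "")) {
    stop_config("column map must be fully named (source = canonical)")
  }
  storage.mode(map) <- "character"
  map
}

apply_column_map <- function(header, col_map) {
  if (is.null(col_map)) return(header)
  hit <- header %in% names(col_map)
  header[hit] <- unname(col_map[header[hit]])
  header
}

# -- generic strict TSV reading ------------------------------------------

read_raw_tsv <- function(path, expected, col_map = NULL) {
  if (!file.exists(path)) stop_silac(paste0("file not found: ", path), "silac_io_error")
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character()
  )
  names(raw) <- apply_column_map(names(raw), read_column_map(col_map))
  missing <- setdiff(expected, names(raw))
  if (length(missing)) {
    stop_schema(paste0(
      "missing required column(s): ", paste(missing, collapse = ", ")
    ))
  }
  raw[expected]
}

parse_column <- function(raw, column, type = c("double", "integer", "character")) {
  type <- match.arg(type)
  x <- raw[[column]]
  if (type == "character") return(x)
  parsed <- if (type == "double") strict_double(x) else strict_integer(x)
  bad <- which(is.na(parsed))
  if (length(bad)) {
    stop_parse(
      paste0("malformed ", type, " value '", x[bad[1]], "'"),
      row = bad[1], column = column
    )
  }
  parsed
}

# -- peptide dialect ------------------------------------------------------

#' Validate a peptide quantification table
#'
#' Checks the invariants of the canonical peptide dialect: nonnegative
#' heavy/light MS1 areas that are not both zero, nonnegative chase time,
#' known genotype labels, positive replicate indices, and uniqueness of the
#' (peptide, protein, chase_time, genotype, replicate) key.
#'
#' @param records Data frame with the canonical peptide columns.
#' @return The validated records as a tibble (invisibly usable in pipes).
#' @export
validate_peptide_records <- function(records) {
  records <- as_tibble(records)[PEPTIDE_COLUMNS]
  bad <- which(records$heavy_area < 0)
  if (length(bad)) stop_validation("heavy_area must be >= 0", row = bad[1])
  bad <- which(records$light_area < 0)
  if (length(bad)) stop_validation("light_area must be >= 0", row = bad[1])
  bad <- which(records$heavy_area == 0 & records$light_area == 0)
  if (length(bad)) {
    stop_validation("heavy_area and light_area must not both be zero", row = bad[1])
  }
  bad <- which(records$chase_time < 0)
  if (length(bad)) stop_validation("chase_time must be >= 0", row = bad[1])
  bad <- which(!records$genotype %in% GENOTYPES)
  if (length(bad)) {
    stop_validation(
      paste0("unknown genotype label '", records$genotype[bad[1]], "'"),
      row = bad[1]
    )
  }
  bad <- which(records$replicate < 1)
  if (length(bad)) stop_validation("replicate must be a positive integer", row = bad[1])
  key <- paste(records$peptide, records$protein, records$chase_time,
               records$genotype, records$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[which(duplicated(key))[1], ]
    stop_duplicate(paste0(
      "duplicate peptide observation within one run: peptide '", d$peptide,
      "', protein '", d$protein, "', chase_time ", d$chase_time,
      ", genotype ", d$genotype, ", replicate ", d$replicate
    ))
  }
  records
}

#' Read a peptide quantification table
#'
#' Reads the canonical TSV dialect (columns `peptide`, `protein`,
#' `heavy_area`, `light_area`, `chase_time`, `genotype`, `replicate`) and
#' validates it.  Third-party exports are ingested by supplying `col_map`.
#' Row order is preserved.
#'
#' @param path Path to a TSV file.
#' @param col_map Optional column mapping (see [read_column_map()]).
#' @return Tibble of validated peptide records.
#' @export
#' @examples
#' sim <- simulate_turnover(turnover_sim_config(n_proteins = 3, seed = 1))
#' f <- tempfile(fileext = ".tsv")
#' write_peptide_table(sim$records, f)
#' pep <- read_peptide_table(f)
read_peptide_table <- function(path, col_map = NULL) {
  raw <- read_raw_tsv(path, PEPTIDE_COLUMNS, col_map)
  records <- tibble(
    peptide    = parse_column(raw, "peptide", "character"),
    protein    = parse_column(raw, "protein", "character"),
    heavy_area = parse_column(raw, "heavy_area", "double"),
    light_area = parse_column(raw, "light_area", "double"),
    chase_time = parse_column(raw, "chase_time", "double"),
    genotype   = parse_column(raw, "genotype", "character"),
    replicate  = parse_column(raw, "replicate", "integer")
  )
  validate_peptide_records(records)
}

#' Write a peptide quantification table
#'
#' Writes the canonical TSV dialect with the canonical row sort (protein,
#' peptide, genotype, replicate, chase_time), UTF-8, LF line endings.
#' `write_peptide_table()` then `read_peptide_table()` round-trips exactly;
#' reading then re-writing a canonically sorted file reproduces it byte for
#' byte.
#'
#' @param records Peptide records (validated before writing).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(records, path) {
  records <- validate_peptide_records(records)
  records <- dplyr::arrange(
    records, .data$protein, .data$peptide, .data$genotype,
    .data$replicate, .data$chase_time
  )
  readr::write_tsv(records, path, eol = "\n", progress = FALSE)
  invisible(path)
}

# -- spectral-count dialect ----------------------------------------------

#' Validate a spectral-count table
#'
#' Invariants: known bait (`VCP`/`IGG`) and genotype labels, replicate in
#' 1..3, nonnegative integer counts, and uniqueness of
#' (bait, genotype, replicate, protein).
#'
#' @param records Data frame with the canonical spectral-count columns.
#' @return Validated tibble.
#' @export
validate_speccount_records <- function(records) {
  records <- as_tibble(records)[SPECCOUNT_COLUMNS]
  bad <- which(!records$bait %in% BAITS)
  if (length(bad)) {
    stop_validation(paste0("unknown bait label '", records$bait[bad[1]], "'"),
                    row = bad[1])
  }
  bad <- which(!records$genotype %in% GENOTYPES)
  if (length(bad)) {
    stop_validation(paste0("unknown genotype label '", records$genotype[bad[1]], "'"),
                    row = bad[1])
  }
  bad <- which(records$replicate < 1 | records$replicate > 3)
  if (length(bad)) stop_validation("replicate must be in 1..3", row = bad[1])
  bad <- which(records$spec_count < 0)
  if (length(bad)) stop_validation("spec_count must be >= 0", row = bad[1])
  key <- paste(records$bait, records$genotype, records$replicate,
               records$protein, sep = "\r")
  if (anyDuplicated(key)) {
    d <- records[which(duplicated(key))[1], ]
    stop_duplicate(paste0(
      "duplicate spectral-count record: protein '", d$protein, "', bait ",
      d$bait, ", genotype ", d$genotype, ", replicate ", d$replicate
    ))
  }
  records
}

#' Read a spectral-count table
#'
#' Canonical TSV dialect: columns `protein`, `bait`, `genotype`,
#' `replicate`, `spec_count`.  Absent proteins are implicit zero counts;
#' rows record observed counts only.
#'
#' @inheritParams read_peptide_table
#' @return Tibble of validated spectral-count records.
#' @export
read_speccount_table <- function(path, col_map = NULL) {
  raw <- read_raw_tsv(path, SPECCOUNT_COLUMNS, col_map)
  records <- tibble(
    protein    = parse_column(raw, "protein", "character"),
    bait       = parse_column(raw, "bait", "character"),
    genotype   = parse_column(raw, "genotype", "character"),
    replicate  = parse_column(raw, "replicate", "integer"),
    spec_count = parse_column(raw, "spec_count", "integer")
  )
  validate_speccount_records(records)
}

#' Write a spectral-count table
#'
#' Canonical row sort: genotype, bait, replicate, protein.
#'
#' @param records Spectral-count records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_speccount_table <- function(records, path) {
  records <- validate_speccount_records(records)
  records <- dplyr::arrange(
    records, .data$genotype, .data$bait, .data$replicate, .data$protein
  )
  readr::write_tsv(records, path, eol = "\n", progress = FALSE)
  invisible(path)
}

# -- result writing with manifest ----------------------------------------

#' Write result tables with a digest manifest
#'
#' Writes every table in `tables` as `<name>.tsv` under `out_dir` (TSV,
#' UTF-8, LF line endings), with rows sorted lexicographically by all
#' columns left to right so output bytes are deterministic, then writes a
#' `manifest.json` recording file names, row counts and SHA-256 digests.
#' Identical inputs produce identical digests.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if absent).
#' @return Tibble manifest (file, rows, sha256), invisibly.
#' @export
write_results <- function(tables, out_dir) {
  if (is.null(tables) || !length(names(tables)) || any(names(tables) == "")) {
    stop_config("'tables' must be a non-empty named list of data frames")
  }
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop_silac(paste0("cannot create output directory: ", out_dir), "silac_io_error")
  entries <- lapply(names(tables), function(nm) {
    tab <- as_tibble(tables[[nm]])
    if (nrow(tab) > 1) {
      tab <- tab[do.call(order, c(unname(as.list(tab)), list(method = "radix"))), ]
    }
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tab, path, eol = "\n", progress = FALSE)
    tibble(
      file = paste0(nm, ".tsv"),
      rows = nrow(tab),
      sha256 = digest::digest(path, algo = "sha256", file = TRUE)
    )
  })
  manifest <- dplyr::bind_rows(entries)
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(manifest)
}
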