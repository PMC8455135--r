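# Table I/O with named schemas. The dialect is plain CSV: comma-separated,
# UTF-8, header row required, '.' decimal separator. Headers are matched
# case-insensitively; unrecognized extra columns are kept with a warning
# (tolerant-reader contract).

.SCHEMAS <- list(
  growth_curve = list(cols = c("time_h", "od", "strain", "replicate"),
                      numeric = c("time_h", "od")),
  viability = list(cols = c("day", "cfu", "dilution", "strain", "replicate"),
                   numeric = c("day", "cfu", "dilution")),
  lifespan = list(cols = c("strain", "divisions"), numeric = "divisions"),
  competition = list(cols = c("generation", "resistant", "total", "mix_id"),
                     numeric = c("generation", "resistant", "total")),
  cell_area = list(cols = c("cell_id", "area_um2", "strain", "replicate"),
                   numeric = "area_um2"),
  polysome = list(cols = c("position", "a260"), numeric = c("position", "a260")),
  luciferase = list(cols = c("well", "genotype", "variant", "firefly", "renilla", "od600"),
                    numeric = c("firefly", "renilla", "od600")),
  screen = list(cols = c("protein", "background", "replicate", "gfp", "od600"),
                numeric = c("gfp", "od600")),
  codon_weights = list(cols = c("codon", "weight"), numeric = "weight"))

#' Table schemas recognized by [load_table()]
#' @return Named list; each entry lists required (`cols`) and numeric
#'   (`numeric`) columns.
#' @export
table_schemas <- function() .SCHEMAS

#' Load and validate a delimited data table
#'
#' Reads a CSV file and validates it against a named schema: required
#' columns must be present (matched case-insensitively), numeric columns
#' must parse as numbers. Extra columns are accepted with a warning and
#' preserved on round trip.
#'
#' @param path Path to a CSV file.
#' @param schema One of `names(table_schemas())`.
#' @return A validated data frame with canonical (lower-case) required
#'   column names.
#' @export
load_table <- function(path, schema) {
  schema <- match.arg(schema, names(.SCHEMAS))
  spec <- .SCHEMAS[[schema]]
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop(sprintf("empty table: %s", path))
  lc <- tolower(names(df))
  missing <- setdiff(spec$cols, lc)
  if (length(missing))
    stop(sprintf("schema '%s' violation in %s: missing column(s) %s",
                 schema, path, paste(missing, collapse = ", ")))
  names(df)[match(spec$cols, lc)] <- spec$cols
  extra <- setdiff(names(df), spec$cols)
  if (length(extra))
    warning(sprintf("unrecognized column(s) preserved: %s", paste(extra, collapse = ", ")))
  for (cn in spec$numeric) {
    v <- df[[cn]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      bad <- which(is.na(num) & !is.na(v) & v != "")
      if (length(bad))
        stop(sprintf("schema '%s' violation: non-numeric value in column '%s' (row %d)",
                     schema, cn, bad[1]))
      df[[cn]] <- num
    }
  }
  df
}

#' Write a data table as CSV
#' @param df Data frame. @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read plate-reader growth curves (long or wide dialect)
#'
#' Long tables must match the `growth_curve` schema. Wide plate-reader
#' exports -- a time-like first column (`time`, `time_h`, `t`, `hours`)
#' followed by one numeric column per well -- are auto-detected and melted
#' to the long layout, with the well name as strain and replicate 1.
#'
#' @param path Path to a CSV file.
#' @return Long-format data frame: `time_h`, `od`, `strain`, `replicate`.
#' @export
read_growth_curves <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  hdr <- tolower(names(utils::read.csv(path, nrows = 1)))
  if (all(c("od", "strain") %in% hdr)) return(load_table(path, "growth_curve"))
  if (!hdr[1] %in% c("time", "time_h", "t", "hours", "time_hours"))
    stop("not a growth-curve table: need long schema columns or a time-like first column")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  wells <- names(df)[-1]
  out <- do.call(rbind, lapply(wells, function(w) {
    data.frame(time_h = as.numeric(df[[1]]), od = as.numeric(df[[w]]),
               strain = w, replicate = 1L)
  }))
  rownames(out) <- NULL
  out
}
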