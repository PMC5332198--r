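# Gridded field serialization: a dense CSV dialect (always available) and
# NetCDF (when the ncdf4 package is installed).
#
# CSV dialect: first line
#   # run_id=...,month=...,precursor=...,pollutant=...,n_rows=...,n_cols=...,cell_size_km=...
# followed by n_rows lines of n_cols comma-separated reals, row 1 (the
# southernmost row) first.  Values are written with 17 significant digits so
# a write/read round trip preserves doubles exactly.

FIELD_HEADER_KEYS <- c("run_id", "month", "precursor", "pollutant",
                       "n_rows", "n_cols", "cell_size_km")

#' Write a sensitivity field
#'
#' @param field A [sensitivity_field()].
#' @param path Output file path.
#' @param format `"csv"`, `"netcdf"`, or `"auto"` (chosen from the file
#'   extension: `.nc` means NetCDF).  NetCDF requires the `ncdf4` package.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path, format = c("auto", "csv", "netcdf")) {
  stopifnot(inherits(field, "sensitivity_field"))
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") write_field_csv(field, path) else
    write_field_nc(field, path)
  invisible(path)
}

#' Read a sensitivity field
#'
#' @param path File path.
#' @param format `"csv"`, `"netcdf"`, or `"auto"`.
#' @param origin_xy Grid origin to attach (the CSV/NetCDF header does not
#'   carry it); defaults to `c(0, 0)`.
#' @return A [sensitivity_field()].
#' @export
read_field <- function(path, format = c("auto", "csv", "netcdf"),
                       origin_xy = c(0, 0)) {
  format <- resolve_format(match.arg(format), path)
  if (format == "csv") read_field_csv(path, origin_xy) else
    read_field_nc(path, origin_xy)
}

resolve_format <- function(format, path) {
  if (format != "auto") return(format)
  if (grepl("\\.nc$", path, ignore.case = TRUE)) "netcdf" else "csv"
}

write_field_csv <- function(field, path) {
  hdr <- sprintf(
    "# run_id=%s,month=%s,precursor=%s,pollutant=%s,n_rows=%d,n_cols=%d,cell_size_km=%s",
    field$run_id, field$month, field$pair$precursor, field$pair$pollutant,
    field$grid$n_rows, field$grid$n_cols,
    format(field$grid$cell_size_km, digits = 17))
  rows <- apply(field$values, 1L, function(r)
    paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(hdr, rows), path)
}

parse_field_header <- function(line) {
  if (!startsWith(line, "# "))
    stop("missing '# key=value' metadata header line", call. = FALSE)
  kv <- strsplit(sub("^# ", "", line), ",", fixed = TRUE)[[1L]]
  kv <- strsplit(kv, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  missing <- setdiff(FIELD_HEADER_KEYS, keys)
  if (length(missing))
    stop(sprintf("field header is missing attribute(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  stats::setNames(as.list(vals), keys)
}

read_field_csv <- function(path, origin_xy = c(0, 0)) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty field file", call. = FALSE)
  meta <- parse_field_header(lines[[1L]])
  n_rows <- as.integer(meta$n_rows)
  n_cols <- as.integer(meta$n_cols)
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (length(body) != n_rows)
    stop(sprintf("expected %d data rows, found %d (attribute: n_rows)",
                 n_rows, length(body)), call. = FALSE)
  vals <- t(vapply(strsplit(body, ",", fixed = TRUE), function(r) {
    if (length(r) != n_cols)
      stop(sprintf("expected %d columns, found %d (attribute: n_cols)",
                   n_cols, length(r)), call. = FALSE)
    as.numeric(r)
  }, numeric(n_cols)))
  if (n_cols == 1L) vals <- matrix(vals, ncol = 1L)
  grid <- model_grid(n_rows, n_cols, as.numeric(meta$cell_size_km), origin_xy)
  sensitivity_field(grid, vals, meta$run_id, meta$month,
                    pp_pair(meta$precursor, meta$pollutant))
}

require_ncdf4 <- function() {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("NetCDF support requires the 'ncdf4' package; use format = \"csv\"",
         call. = FALSE)
}

write_field_nc <- function(field, path) {
  require_ncdf4()
  dim_row <- ncdf4::ncdim_def("row", "index", seq_len(field$grid$n_rows))
  dim_col <- ncdf4::ncdim_def("col", "index", seq_len(field$grid$n_cols))
  units <- if (field$pair$pollutant == "PM25") "ug/m3" else "ppb"
  var <- ncdf4::ncvar_def("delta_x", units, list(dim_row, dim_col),
                          prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc))
  ncdf4::ncvar_put(nc, var, field$values)
  ncdf4::ncatt_put(nc, 0, "run_id", field$run_id)
  ncdf4::ncatt_put(nc, 0, "month", field$month)
  ncdf4::ncatt_put(nc, 0, "precursor", field$pair$precursor)
  ncdf4::ncatt_put(nc, 0, "pollutant", field$pair$pollutant)
  ncdf4::ncatt_put(nc, 0, "cell_size_km", field$grid$cell_size_km,
                   prec = "double")
}

read_field_nc <- function(path, origin_xy = c(0, 0)) {
  require_ncdf4()
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc))
  vals <- ncdf4::ncvar_get(nc, "delta_x", collapse_degen = FALSE)
  att <- function(name) {
    a <- ncdf4::ncatt_get(nc, 0, name)
    if (!a$hasatt)
      stop(sprintf("NetCDF file is missing attribute: %s", name),
           call. = FALSE)
    a$value
  }
  grid <- model_grid(nrow(vals), ncol(vals), as.numeric(att("cell_size_km")),
                     origin_xy)
  sensitivity_field(grid, vals, att("run_id"), att("month"),
                    pp_pair(att("precursor"), att("pollutant")))
}
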