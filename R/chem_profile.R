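# GC-MS component table handling and Kovats retention indices.

#' Construct an n-alkane calibration ladder
#'
#' The ladder records the retention time of each n-alkane standard and anchors
#' the Kovats retention-index scale: an alkane with Z carbons sits at RI =
#' 100 * Z by definition, and analytes are placed by linear interpolation of
#' retention time between the bracketing alkanes.
#'
#' @param carbon_number integer vector of alkane carbon numbers, strictly
#'   increasing.
#' @param retention_time numeric vector of retention times in minutes,
#'   strictly increasing and positive.
#' @return a data.frame of class `alkane_ladder` with columns
#'   `carbon_number` and `retention_time`.
#' @export
alkane_ladder <- function(carbon_number, retention_time) {
  carbon_number <- as.numeric(carbon_number)
  retention_time <- as.numeric(retention_time)
  if (length(carbon_number) != length(retention_time))
    validation_error("carbon_number and retention_time lengths differ")
  if (length(carbon_number) < 2)
    validation_error("alkane ladder needs at least 2 entries")
  if (anyNA(carbon_number) || anyNA(retention_time))
    validation_error("alkane ladder contains missing values")
  if (any(carbon_number <= 0) || any(carbon_number != round(carbon_number)))
    validation_error("carbon numbers must be positive integers")
  if (any(retention_time <= 0))
    validation_error("retention times must be positive")
  if (any(diff(carbon_number) <= 0))
    validation_error("carbon numbers must be strictly increasing")
  if (any(diff(retention_time) <= 0))
    validation_error("retention times must be strictly increasing with carbon number")
  structure(
    data.frame(carbon_number = as.integer(carbon_number),
               retention_time = retention_time),
    class = c("alkane_ladder", "data.frame")
  )
}

#' Read an n-alkane ladder from CSV/TSV
#'
#' Expects a header `carbon_number,retention_time`; the separator is taken
#' from the file extension (`.csv` comma, otherwise tab).
#'
#' @param path file path.
#' @return an [alkane_ladder()].
#' @export
read_alkane_ladder <- function(path) {
  df <- read_flat(path, sep = sep_for(path))
  need <- c("carbon_number", "retention_time")
  if (!all(need %in% names(df)))
    validation_error("ladder file must have columns: ", paste(need, collapse = ", "))
  alkane_ladder(df$carbon_number, df$retention_time)
}

#' Compute Kovats retention indices
#'
#' Linear interpolation between bracketing n-alkanes:
#' `RI = 100 * Z + 100 * (Z' - Z) * (t_x - tR(Z)) / (tR(Z') - tR(Z))`,
#' where Z is the largest ladder carbon number with `tR(Z) <= t_x` and Z' the
#' next one. For consecutive alkanes (`Z' = Z + 1`) this is the classical
#' formula; ladders with skipped carbons interpolate across the gap. A ladder
#' member maps exactly to `100 * Z`. Retention times outside the ladder range
#' are an error: the formula is an interpolation, not an extrapolation.
#'
#' @param t_x numeric vector of analyte retention times (minutes).
#' @param ladder an [alkane_ladder()].
#' @return numeric vector of retention indices.
#' @export
#' @examples
#' lad <- alkane_ladder(10:12, c(10, 12, 15))
#' compute_retention_index(11, lad)  # 1050
compute_retention_index <- function(t_x, ladder) {
  if (!inherits(ladder, "alkane_ladder"))
    ladder <- alkane_ladder(ladder$carbon_number, ladder$retention_time)
  t_x <- as.numeric(t_x)
  tr <- ladder$retention_time
  z <- as.numeric(ladder$carbon_number)
  bad <- !is.na(t_x) & (t_x < tr[1] | t_x > tr[length(tr)])
  if (anyNA(t_x))
    validation_error("retention time is missing")
  if (any(bad))
    stop_wcnp("retention time(s) outside ladder range [", tr[1], ", ",
              tr[length(tr)], "]: ", paste(t_x[bad], collapse = ", "),
              class = "wcnp_range_error")
  # findInterval gives the bracket index i with tr[i] <= t_x < tr[i + 1];
  # the right endpoint collapses onto the last bracket.
  i <- findInterval(t_x, tr, rightmost.closed = TRUE)
  i <- pmin(i, length(tr) - 1L)
  frac <- (t_x - tr[i]) / (tr[i + 1L] - tr[i])
  ri <- 100 * (z[i] + (z[i + 1L] - z[i]) * frac)
  # exact identity at ladder members, immune to roundoff in frac
  at_member <- match(t_x, tr)
  hit <- !is.na(at_member)
  ri[hit] <- 100 * z[at_member[hit]]
  ri
}

#' Construct a validated component table
#'
#' Holds one row per essential-oil constituent from a GC-MS run: name, CAS
#' registry id (free-form, may be empty), retention time and/or retention
#' index, relative content as peak-area percent (`area_pct`, column I of the
#' weighting cascade) and oral bioavailability (`ob`, a fraction in 0-1).
#' Row identity is the (normalized name, CAS) pair: the same compound name may
#' legitimately recur under different CAS numbers (isomers resolved by the
#' spectral library), and each such row keeps its own content.
#'
#' @param df data.frame with columns `name`, `cas`, `retention_time`,
#'   `retention_index`, `area_pct`, `ob` (missing cells `NA`; `cas` may be
#'   empty strings).
#' @param content_scale `"percent"` (default; values on the 0-100 scale as
#'   printed in GC-MS reports) or `"fraction"` (0-1 values, converted to
#'   percent on ingestion).
#' @return data.frame of class `component_table`; attribute
#'   `total_area_pct` carries the content sum.
#' @export
component_table <- function(df, content_scale = c("percent", "fraction")) {
  content_scale <- match.arg(content_scale)
  need <- c("name", "area_pct", "ob")
  if (!all(need %in% names(df)))
    validation_error("component table must have columns: ",
                     paste(need, collapse = ", "))
  out <- data.frame(
    name = squish(df$name),
    cas = if ("cas" %in% names(df)) squish(df$cas) else "",
    retention_time = if ("retention_time" %in% names(df))
      as.numeric(df$retention_time) else NA_real_,
    retention_index = if ("retention_index" %in% names(df))
      as.numeric(df$retention_index) else NA_real_,
    area_pct = as.numeric(df$area_pct),
    ob = as.numeric(df$ob),
    stringsAsFactors = FALSE
  )
  if (content_scale == "fraction") out$area_pct <- out$area_pct * 100
  if (nrow(out) > 0) {
    key <- paste(norm_key(out$name), norm_key(out$cas), sep = "\r")
    if (anyDuplicated(key))
      validation_error("duplicate (name, CAS) pairs: ",
                       paste(unique(out$name[duplicated(key)]), collapse = ", "))
    if (anyNA(out$area_pct) || any(out$area_pct < 0))
      validation_error("area_pct must be >= 0 for every component")
    if (anyNA(out$ob) || any(out$ob < 0 | out$ob > 1))
      validation_error("ob must be within [0, 1] for every component ",
                       "(no oral-bioavailability values are imputed)")
    no_pos <- is.na(out$retention_time) & is.na(out$retention_index)
    if (any(no_pos))
      validation_error("components lacking both retention_time and ",
                       "retention_index: ",
                       paste(out$name[no_pos], collapse = ", "))
    if (any(!is.na(out$retention_time) & out$retention_time <= 0))
      validation_error("retention times must be positive")
  }
  structure(out, total_area_pct = sum(out$area_pct),
            class = c("component_table", "data.frame"))
}

#' Read a component table from CSV/TSV
#'
#' Expects the header
#' `name,cas,retention_time,retention_index,area_pct,ob` with missing cells
#' left empty.
#'
#' @inheritParams component_table
#' @param path file path.
#' @return a [component_table()].
#' @export
read_component_table <- function(path, content_scale = c("percent", "fraction")) {
  df <- read_flat(path, sep = sep_for(path), na.strings = c("NA", ""),
                  colClasses = c(name = "character"))
  if ("cas" %in% names(df)) {
    df$cas <- as.character(df$cas)
    df$cas[is.na(df$cas)] <- ""
  }
  component_table(df, content_scale = content_scale)
}

#' Write a component table to CSV/TSV
#'
#' @param table a [component_table()].
#' @param path output path; extension selects the separator.
#' @export
write_component_table <- function(table, path) {
  df <- as.data.frame(table)[, c("name", "cas", "retention_time",
                                 "retention_index", "area_pct", "ob")]
  write_flat(df, path, sep = sep_for(path))
}

#' Fill in retention indices for a component table
#'
#' Applies [compute_retention_index()] to every component whose
#' `retention_index` is missing; indices supplied in the input are preserved
#' untouched. Components that cannot be placed (no retention time, or one
#' outside the ladder range) are reported together in a single error.
#'
#' @param table a [component_table()].
#' @param ladder an [alkane_ladder()].
#' @return the table with `retention_index` populated for every row.
#' @export
annotate_retention_index <- function(table, ladder) {
  out <- table
  todo <- which(is.na(out$retention_index))
  if (length(todo) == 0) return(out)
  tr <- ladder$retention_time
  t_x <- out$retention_time[todo]
  bad <- is.na(t_x) | t_x < tr[1] | t_x > tr[length(tr)]
  if (any(bad))
    validation_error("cannot compute retention index for component(s): ",
                     paste(out$name[todo[bad]], collapse = ", "),
                     " (retention time missing or outside ladder range)")
  out$retention_index[todo] <- compute_retention_index(t_x, ladder)
  out
}
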