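# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Normalize free-text identifiers: trim, collapse internal whitespace.
# Case-folding is applied on top for matching keys; the display string keeps
# its original case.
squish <- function(x) {
  x <- gsub("^\\s+|\\s+$", "", as.character(x))
  gsub("\\s+", " ", x)
}

norm_key <- function(x) toupper(squish(x))

#' Normalize gene symbols
#'
#' Trims surrounding whitespace, collapses internal whitespace and upper-cases
#' symbols so that sets from different sources intersect on a common
#' convention. No alias or ortholog mapping is attempted.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized symbols.
#' @export
normalize_genes <- function(x) norm_key(x)

# Evaluate `code` under a local, fully specified RNG state; the caller's
# .Random.seed is restored afterwards. RNG kinds are pinned so the same seed
# yields the same stream across R versions.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

# write.table with the conventions used for every text artifact the package
# emits: tab/comma separated, no quoting, no row names, LF line endings.
write_flat <- function(df, path, sep = "\t") {
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_flat <- function(path, sep = "\t", ...) {
  utils::read.table(path, sep = sep, header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

# Pick the separator from a file extension: .csv -> comma, otherwise tab.
sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

stop_wcnp <- function(..., class = "wcnp_error") {
  stop(errorCondition(paste0(...), class = c(class, "wcnp_error")))
}

validation_error <- function(...) stop_wcnp(..., class = "wcnp_validation_error")
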