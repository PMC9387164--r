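# Gene-identifier handling, DEG threshold filtering, three-way intersection.

#' Construct a gene set
#'
#' @param label non-empty label for the set.
#' @param genes character vector of gene symbols; normalized
#'   (trimmed, upper-cased) and deduplicated.
#' @return object of class `gene_set`: a list with `label` and sorted
#'   `genes`.
#' @export
gene_set <- function(label, genes) {
  label <- squish(label)
  if (!nzchar(label)) validation_error("gene set label must be non-empty")
  genes <- normalize_genes(genes)
  genes <- sort(unique(genes[nzchar(genes)]))
  structure(list(label = label, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s': %d genes>\n", x$label, length(x$genes)))
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Read a gene list file
#'
#' One symbol per line, or a TSV whose first column holds the symbols.
#' Lines starting with `#` are comments.
#'
#' @param path file path.
#' @param label set label; defaults to the file name.
#' @return a [gene_set()].
#' @export
read_gene_list <- function(path, label = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  first <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  gene_set(label, first)
}

#' Write a gene list file
#'
#' @param set a [gene_set()].
#' @param path output path.
#' @export
write_gene_list <- function(set, path) {
  writeLines(set$genes, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' TSV with header `gene`, `log2fc`, `fdr`. One row per gene (after symbol
#' normalization); duplicate genes are an error because silently keeping one
#' row would hide an upstream merge problem.
#'
#' @param path file path.
#' @return data.frame of class `de_table` with normalized `gene`, numeric
#'   `log2fc` and `fdr`.
#' @export
read_de_table <- function(path) {
  df <- read_flat(path, sep = sep_for(path))
  de_table(df)
}

#' Validate a differential-expression table
#'
#' @param df data.frame with columns `gene`, `log2fc`, `fdr`.
#' @return data.frame of class `de_table`.
#' @export
de_table <- function(df) {
  need <- c("gene", "log2fc", "fdr")
  if (!all(need %in% names(df)))
    stop_wcnp("DE table must have columns: ", paste(need, collapse = ", "),
              class = "wcnp_parse_error")
  out <- data.frame(gene = normalize_genes(df$gene),
                    log2fc = as.numeric(df$log2fc),
                    fdr = as.numeric(df$fdr),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene))
    validation_error("duplicate gene rows in DE table: ",
                     paste(unique(out$gene[duplicated(out$gene)]), collapse = ", "))
  if (anyNA(out$fdr) || any(out$fdr < 0 | out$fdr > 1))
    validation_error("fdr must be within [0, 1]")
  if (anyNA(out$log2fc))
    validation_error("log2fc contains missing values")
  structure(out, class = c("de_table", "data.frame"))
}

#' Select differentially expressed genes by threshold
#'
#' Keeps genes with `fdr` below `fdr_max` and `|log2fc|` at least `lfc_min`.
#' The FDR comparison is strict (`<`) and the fold-change comparison
#' inclusive (`>=`) by default; both boundaries are explicit switches because
#' published threshold statements are often ambiguous on this point. A gene
#' with `log2fc == 0` is neither up- nor down-regulated and is excluded from
#' the selection (with a warning) even when `lfc_min = 0`.
#'
#' @param table a [de_table()] (or data.frame coercible to one).
#' @param fdr_max FDR threshold in (0, 1]; default 0.05.
#' @param lfc_min minimum absolute log2 fold change; default 1.
#' @param fdr_strict if `TRUE` (default) require `fdr < fdr_max`, else `<=`.
#' @param lfc_inclusive if `TRUE` (default) require `|log2fc| >= lfc_min`,
#'   else `>`.
#' @return object of class `deg_result`: list with `selected` ([gene_set()]),
#'   `n_up`, `n_down`, and `thresholds`.
#' @export
select_degs <- function(table, fdr_max = 0.05, lfc_min = 1,
                        fdr_strict = TRUE, lfc_inclusive = TRUE) {
  if (!inherits(table, "de_table")) table <- de_table(table)
  if (!is.numeric(fdr_max) || fdr_max <= 0 || fdr_max > 1)
    validation_error("fdr_max must be in (0, 1]")
  if (!is.numeric(lfc_min) || lfc_min < 0)
    validation_error("lfc_min must be >= 0")
  pass_fdr <- if (fdr_strict) table$fdr < fdr_max else table$fdr <= fdr_max
  pass_lfc <- if (lfc_inclusive) abs(table$log2fc) >= lfc_min
              else abs(table$log2fc) > lfc_min
  keep <- pass_fdr & pass_lfc
  zero <- keep & table$log2fc == 0
  if (any(zero)) {
    warning(sum(zero), " gene(s) passing thresholds with log2fc == 0 ",
            "excluded (direction undefined)")
    keep <- keep & table$log2fc != 0
  }
  sel <- table[keep, , drop = FALSE]
  structure(list(
    selected = gene_set("degs", sel$gene),
    n_up = sum(sel$log2fc > 0),
    n_down = sum(sel$log2fc < 0),
    thresholds = c(fdr_max = fdr_max, lfc_min = lfc_min)
  ), class = "deg_result")
}

#' @export
print.deg_result <- function(x, ...) {
  cat(sprintf("<deg_result: %d genes (%d up, %d down) at fdr < %g, |log2FC| >= %g>\n",
              length(x$selected), x$n_up, x$n_down,
              x$thresholds[["fdr_max"]], x$thresholds[["lfc_min"]]))
  invisible(x)
}

as_gene_set <- function(x, label = "set") {
  if (inherits(x, "gene_set")) x else gene_set(label, x)
}

#' Three-way gene-set intersection
#'
#' The set-theoretic intersection of component targets, disease genes and
#' DEGs, yielding the key-target set of the pipeline. All inputs are
#' normalized with the same symbol convention before intersecting.
#'
#' @param component_targets,disease_genes,degs [gene_set()]s (or character
#'   vectors).
#' @return a [gene_set()] labelled `"key_targets"`.
#' @export
three_way_intersection <- function(component_targets, disease_genes, degs) {
  a <- as_gene_set(component_targets, "targets")$genes
  b <- as_gene_set(disease_genes, "disease")$genes
  c_ <- as_gene_set(degs, "degs")$genes
  gene_set("key_targets", intersect(intersect(a, b), c_))
}

#' Exclusive Venn region counts for three gene sets
#'
#' @param a,b,c [gene_set()]s (or character vectors).
#' @return named integer vector with the 7 exclusive region counts
#'   (`a_only`, `b_only`, `c_only`, `ab`, `ac`, `bc`, `abc`); they sum to
#'   the size of the union.
#' @export
venn_counts <- function(a, b, c) {
  ga <- as_gene_set(a, "a")$genes
  gb <- as_gene_set(b, "b")$genes
  gc_ <- as_gene_set(c, "c")$genes
  u <- union(union(ga, gb), gc_)
  ina <- u %in% ga; inb <- u %in% gb; inc <- u %in% gc_
  c(a_only = sum(ina & !inb & !inc),
    b_only = sum(!ina & inb & !inc),
    c_only = sum(!ina & !inb & inc),
    ab = sum(ina & inb & !inc),
    ac = sum(ina & !inb & inc),
    bc = sum(!ina & inb & inc),
    abc = sum(ina & inb & inc))
}
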