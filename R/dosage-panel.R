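#' Dosage panel: subjects-by-variants genotype container
#'
#' A light container holding a numeric dosage matrix (subjects in rows,
#' variants in columns, values in [0,2] counting the A1 allele), a variant
#' metadata table, and optionally the two phased haplotype matrices the
#' gene-dropping simulator needs.
#'
#' @param dosage Numeric matrix, subjects x variants, dosages in [0,2].
#' @param variants data.frame with columns `variant_id`, `chr`, `bp`,
#'   `a1`, `a2`, `maf` (frequency of `a1`).
#' @param h1,h2 Optional 0/1 matrices of the same shape as `dosage`
#'   counting the A1 allele on each haplotype.
#' @return An object of class `dosage_panel`.
#' @export
dosage_panel <- function(dosage, variants, h1 = NULL, h2 = NULL) {
  dosage <- as.matrix(dosage)
  if (ncol(dosage) != nrow(variants))
    stop_famprs("dosage columns must match variant rows")
  if (anyNA(dosage) || any(dosage < 0 | dosage > 2))
    stop_famprs("dosages must lie in [0,2]")
  colnames(dosage) <- variants$variant_id
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  structure(list(dosage = dosage, variants = variants, h1 = h1, h2 = h2),
            class = "dosage_panel")
}

#' @export
print.dosage_panel <- function(x, ...) {
  cat("dosage_panel:", nrow(x$dosage), "subjects x", ncol(x$dosage),
      "variants", if (!is.null(x$h1)) "(phased)" else "", "\n")
  invisible(x)
}

#' @export
dim.dosage_panel <- function(x) dim(x$dosage)

#' Subset a dosage panel by subjects and/or variants
#'
#' @param panel A `dosage_panel`.
#' @param subjects Subject ids or indices to keep (default all).
#' @param variants Variant ids or indices to keep (default all).
#' @return A `dosage_panel` restricted to the requested rows/columns.
#' @export
subset_panel <- function(panel, subjects = NULL, variants = NULL) {
  i <- subjects %||% seq_len(nrow(panel$dosage))
  j <- variants %||% seq_len(ncol(panel$dosage))
  if (is.character(j)) j <- match(j, panel$variants$variant_id)
  dosage_panel(panel$dosage[i, j, drop = FALSE],
               panel$variants[j, , drop = FALSE],
               h1 = if (!is.null(panel$h1)) panel$h1[i, j, drop = FALSE],
               h2 = if (!is.null(panel$h2)) panel$h2[i, j, drop = FALSE])
}

#' Combine two dosage panels over the same variant set
#'
#' @param a,b `dosage_panel` objects sharing an identical variant table.
#' @return A `dosage_panel` with the subjects of both (haplotypes kept only
#'   if both inputs are phased).
#' @export
bind_panels <- function(a, b) {
  if (!identical(a$variants$variant_id, b$variants$variant_id))
    stop_famprs("panels must share the same variants")
  phased <- !is.null(a$h1) && !is.null(b$h1)
  dosage_panel(rbind(a$dosage, b$dosage), a$variants,
               h1 = if (phased) rbind(a$h1, b$h1),
               h2 = if (phased) rbind(a$h2, b$h2))
}

#' Write / read a dosage panel as a TSV matrix
#'
#' The text format is variants in rows (id, chr, bp, a1, a2, maf) followed
#' by one dosage column per subject.
#'
#' @param panel A `dosage_panel`.
#' @param path Output file.
#' @return `read_dosage_tsv` returns a `dosage_panel` (unphased).
#' @export
write_dosage_tsv <- function(panel, path) {
  dt <- data.table::as.data.table(panel$variants)
  dos <- t(panel$dosage)
  colnames(dos) <- rownames(panel$dosage)
  data.table::fwrite(cbind(dt, data.table::as.data.table(dos)),
                     path, sep = "\t")
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  meta_cols <- c("variant_id", "chr", "bp", "a1", "a2", "maf")
  variants <- dt[meta_cols]
  dos <- t(as.matrix(dt[setdiff(names(dt), meta_cols)]))
  dosage_panel(dos, variants)
}
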