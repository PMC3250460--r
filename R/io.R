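#' Compute Beta values from methylated/unmethylated signal intensities
#'
#' Converts per-probe methylated (M) and unmethylated (U) intensities into
#' methylation Beta values with the Illumina stabilising offset:
#' \deqn{\beta = M / (U + M + 100)}
#' The +100 in the denominator guarantees \eqn{0 \le \beta < 1} for all
#' finite non-negative signals and damps the noise of low-intensity probes.
#'
#' @param M numeric matrix of methylated intensities (probes x samples).
#' @param U numeric matrix of unmethylated intensities, same dimensions
#'   and dimnames as `M`.
#' @return numeric matrix of Beta values in `[0, 1)` with the dimnames of `M`.
#' @examples
#' compute_beta(matrix(c(0, 100, 900), 3, 1), matrix(0, 3, 1))
#' @export
compute_beta <- function(M, U) {
  M <- as.matrix(M)
  U <- as.matrix(U)
  if (!identical(dim(M), dim(U)))
    stop("M and U matrices must have identical dimensions")
  bad <- !is.finite(M) | !is.finite(U) | M < 0 | U < 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, , drop = TRUE]
    stop(sprintf(
      "invalid signal (negative or non-finite) at probe '%s', sample '%s'",
      if (is.null(rownames(M))) idx[1] else rownames(M)[idx[1]],
      if (is.null(colnames(M))) idx[2] else colnames(M)[idx[2]]))
  }
  M / (U + M + 100)
}

#' Validate a sample sheet
#'
#' A sample sheet describes one sample per row: `sample_id` (unique),
#' `group` (`"tumour"` or `"normal"`), `batch`, and optionally
#' `laboratory` and `patient_id` (for tumour/normal pairing).
#'
#' @param sheet data.frame to validate.
#' @param require_pairing if TRUE, additionally require each `patient_id`
#'   to appear exactly once per group.
#' @return the sheet, invisibly, with character columns.
#' @export
validate_sample_sheet <- function(sheet, require_pairing = FALSE) {
  needed <- c("sample_id", "group", "batch")
  missing_cols <- setdiff(needed, names(sheet))
  if (length(missing_cols))
    stop("sample sheet missing column(s): ", paste(missing_cols, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$group <- as.character(sheet$group)
  sheet$batch <- as.character(sheet$batch)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet: ",
         sheet$sample_id[duplicated(sheet$sample_id)][1])
  if (any(is.na(sheet$group) | !nzchar(sheet$group)))
    stop("every sample must have a group")
  if (any(is.na(sheet$batch) | !nzchar(sheet$batch)))
    stop("every sample must have a batch")
  bad_grp <- setdiff(unique(sheet$group), c("tumour", "normal"))
  if (length(bad_grp))
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "))
  if (require_pairing) {
    if (is.null(sheet$patient_id) || any(is.na(sheet$patient_id)))
      stop("paired analysis requires a complete patient_id column")
    tab <- table(sheet$patient_id, sheet$group)
    if (any(tab != 1))
      stop("paired analysis requires each patient_id exactly once per group")
  }
  invisible(sheet)
}

#' Collapse probe-level results to gene level
#'
#' Promoter arrays report per probe but downstream comparisons are per gene.
#' Each gene is represented by its minimum-p probe (ties broken by larger
#' absolute effect, then lexicographic probe_id).  If a gene's probes
#' disagree in direction, the representative's direction is kept and the
#' gene is flagged `discordant_probes`.  Unmapped probes are dropped; the
#' dropped count is attached as attribute `n_unmapped`.
#'
#' @param results data.frame of probe-level results with columns `id`
#'   (probe), `p`, `effect`, `direction`, and any others (carried over).
#' @param annotation data.frame with columns `probe_id`, `gene_id`.
#' @param method collapsing rule; only `"min_p"` is implemented.
#' @return gene-level data.frame with `gene_id` first, one row per gene,
#'   plus columns `n_probes` and `discordant_probes`.
#' @export
collapse_probes_to_genes <- function(results, annotation, method = "min_p") {
  method <- match.arg(method, "min_p")
  if (anyDuplicated(annotation$probe_id))
    stop("annotation maps a probe_id more than once")
  idx <- match(results$id, annotation$probe_id)
  n_unmapped <- sum(is.na(idx))
  keep <- !is.na(idx)
  if (!any(keep))
    stop("no probe in the results is present in the annotation")
  res <- results[keep, , drop = FALSE]
  res$gene_id <- as.character(annotation$gene_id[idx[keep]])
  # deterministic representative: min p, then max |effect|, then probe_id
  ord <- order(res$gene_id, res$p, -abs(res$effect), res$id,
               method = "radix")
  res <- res[ord, , drop = FALSE]
  first <- !duplicated(res$gene_id)
  n_probes <- as.vector(table(res$gene_id)[res$gene_id[first]])
  discord <- tapply(res$direction, res$gene_id,
                    function(d) length(unique(d[d != "none"])) > 1)
  out <- res[first, , drop = FALSE]
  out$n_probes <- n_probes
  out$discordant_probes <- as.logical(discord[out$gene_id])
  rownames(out) <- NULL
  out <- out[, c("gene_id", setdiff(names(out), "gene_id")), drop = FALSE]
  attr(out, "n_unmapped") <- n_unmapped
  out
}

# ---- TSV readers/writers ---------------------------------------------------
# All matrices are TSV with a header row of sample ids and the feature id in
# the first column; missing values are written "NA".

#' Write a feature-by-sample matrix as TSV
#' @param mat numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @param path output file.
#' @param id_col header name of the feature-id column.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "feature_id") {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature-by-sample matrix from TSV
#' @param path TSV file: first column feature ids, header row sample ids.
#' @return numeric matrix with feature rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("matrix TSV needs a feature column plus >=1 sample")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate feature id in ", path, ": ", ids[duplicated(ids)][1])
  mat <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(mat)) stop("non-numeric values in matrix ", path)
  rownames(mat) <- ids
  mat
}

#' Write / read a sample sheet TSV
#' @param sheet data.frame (see [validate_sample_sheet()]).
#' @param path file path.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
  validate_sample_sheet(sheet)
  sheet
}

#' Write / read a probe-to-gene annotation TSV
#' @param annotation data.frame with columns `probe_id`, `gene_id`.
#' @param path file path.
#' @export
write_annotation <- function(annotation, path) {
  utils::write.table(annotation[, c("probe_id", "gene_id")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (!all(c("probe_id", "gene_id") %in% names(ann)))
    stop("annotation needs probe_id and gene_id columns")
  if (anyDuplicated(ann$probe_id))
    stop("duplicate probe_id in annotation")
  ann
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors of gene ids; descriptions kept
#'   in attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad))
    stop("malformed GMT line (fewer than 3 fields): line ", which(bad)[1])
  sets <- lapply(parts, function(x) unique(x[-c(1, 2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set name in GMT")
  attr(sets, "descriptions") <-
    stats::setNames(vapply(parts, `[[`, "", 2L), names(sets))
  sets
}

#' Write a GMT gene-set file
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional named character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions))
    descriptions <- stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, descriptions[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a differential-result table TSV
#' @param results data.frame as produced by [dm_ttest()] or [sam_de()].
#' @param path file path.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_tsv
#' @export
read_results_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
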