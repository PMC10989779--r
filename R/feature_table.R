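#' Sample-by-taxon feature table
#'
#' The central container of the pipeline: a numeric samples x taxa matrix
#' together with per-sample metadata, optional taxon lineage strings, and a
#' mode flag recording what the values mean.
#'
#' Modes:
#' \describe{
#'   \item{counts}{raw integer read counts}
#'   \item{RMP}{relative microbiome profile; rows sum to 1}
#'   \item{QMP}{quantitative microbiome profile; rows are marker-gene
#'     copies per gram and row sums equal the per-sample microbial load}
#' }
#'
#' @param mat numeric matrix, samples in rows, taxa in columns, with
#'   dimnames. No negative values.
#' @param metadata data.frame with one row per sample; must contain a
#'   `sample_id` column matching `rownames(mat)`. Conventional columns are
#'   `bird`, `segment`, `dph` (days posthatch) and `domain`
#'   (bacteria/fungi).
#' @param taxonomy optional character vector of lineage strings (one per
#'   taxon, `;`-separated ranks with `d__/p__/c__/o__/f__/g__` prefixes).
#' @param mode one of "counts", "RMP", "QMP".
#' @param loads named numeric vector of per-sample loads (copies/g);
#'   required when `mode = "QMP"`.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(mat, metadata, taxonomy = NULL,
                          mode = c("counts", "RMP", "QMP"), loads = NULL) {
  mode <- match.arg(mode)
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("`mat` must be a numeric matrix (samples x taxa)")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("`mat` must have sample rownames and taxon colnames")
  if (any(mat < 0)) {
    bad <- which(mat < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative value at sample '%s', taxon '%s'",
                 rownames(mat)[bad[1]], colnames(mat)[bad[2]]))
  }
  if (!is.data.frame(metadata) || !"sample_id" %in% names(metadata))
    stop("`metadata` must be a data.frame with a sample_id column")
  if (anyDuplicated(metadata$sample_id))
    stop("duplicate sample ids in metadata")
  if (!setequal(metadata$sample_id, rownames(mat)))
    stop("metadata sample_id set does not match matrix rownames")
  metadata <- metadata[match(rownames(mat), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  if (!is.null(taxonomy)) {
    if (length(taxonomy) != ncol(mat))
      stop("taxonomy length must equal number of taxa")
    taxonomy <- as.character(taxonomy)
    names(taxonomy) <- colnames(mat)
  }
  if (mode == "RMP") {
    rs <- rowSums(mat)
    if (any(abs(rs - 1) > 1e-9))
      stop("RMP rows must sum to 1 (max deviation ",
           format(max(abs(rs - 1))), ")")
  }
  if (mode == "QMP") {
    if (is.null(loads))
      stop("QMP mode requires per-sample `loads`")
    loads <- loads[rownames(mat)]
    if (any(is.na(loads)))
      stop("missing load for samples: ",
           paste(rownames(mat)[is.na(loads)], collapse = ", "))
    rs <- rowSums(mat)
    rel <- abs(rs - loads) / pmax(loads, .Machine$double.eps)
    if (any(rel > 1e-6))
      stop("QMP row sums must equal loads (max relative deviation ",
           format(max(rel)), ")")
  }
  structure(
    list(mat = mat, metadata = metadata, taxonomy = taxonomy,
         mode = mode, loads = if (mode == "QMP") loads else NULL),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table [%s]: %d samples x %d taxa\n",
              x$mode, nrow(x$mat), ncol(x$mat)))
  if (!is.null(x$metadata$domain))
    cat("  domains:", paste(unique(x$metadata$domain), collapse = ", "), "\n")
  if (!is.null(x$metadata$segment))
    cat("  segments:", paste(unique(x$metadata$segment), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / taxa
#' @param x a feature_table
#' @return integer
#' @export
n_samples <- function(x) nrow(x$mat)

#' @rdname n_samples
#' @export
n_taxa <- function(x) ncol(x$mat)

#' Subset a feature table by samples and/or taxa
#'
#' @param x feature_table
#' @param samples logical/integer/character index of samples to keep
#' @param taxa logical/integer/character index of taxa to keep
#' @return feature_table with the same mode
#' @export
ft_subset <- function(x, samples = NULL, taxa = NULL) {
  mat <- x$mat
  if (!is.null(samples)) mat <- mat[samples, , drop = FALSE]
  if (!is.null(taxa)) mat <- mat[, taxa, drop = FALSE]
  md <- x$metadata[match(rownames(mat), x$metadata$sample_id), , drop = FALSE]
  tax <- if (!is.null(x$taxonomy)) x$taxonomy[colnames(mat)] else NULL
  loads <- if (!is.null(x$loads)) x$loads[rownames(mat)] else NULL
  feature_table(mat, md, taxonomy = tax, mode = x$mode, loads = loads)
}

#' Convert a table to relative abundances (RMP)
#'
#' Rows are renormalised to sum to one. Samples with zero total are dropped
#' with a message (they carry no compositional information).
#'
#' @param x feature_table in any mode
#' @return feature_table in RMP mode
#' @export
to_relative <- function(x) {
  rs <- rowSums(x$mat)
  if (any(rs == 0)) {
    message("dropping ", sum(rs == 0), " zero-total sample(s): ",
            paste(rownames(x$mat)[rs == 0], collapse = ", "))
    x <- ft_subset(x, samples = rs > 0)
    rs <- rowSums(x$mat)
  }
  feature_table(x$mat / rs, x$metadata, taxonomy = x$taxonomy, mode = "RMP")
}

#' Write / read a feature table as TSV
#'
#' The matrix is written samples-as-rows with a leading `sample_id` column;
#' metadata and taxonomy travel in sidecar files next to the matrix when
#' `sidecars = TRUE`.
#'
#' @param x feature_table
#' @param path output TSV path for the matrix
#' @param sidecars write `<path>.metadata.tsv` (and `.taxonomy.tsv` when
#'   lineages are present)
#' @return `path`, invisibly
#' @export
write_feature_table <- function(x, path, sidecars = TRUE) {
  df <- data.frame(sample_id = rownames(x$mat), x$mat,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (sidecars) {
    utils::write.table(x$metadata, paste0(path, ".metadata.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(x$taxonomy))
      utils::write.table(
        data.frame(taxon = names(x$taxonomy), lineage = x$taxonomy),
        paste0(path, ".taxonomy.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_feature_table
#' @param mode mode flag to stamp on the table read back
#' @param metadata optional data.frame; when NULL the sidecar written by
#'   [write_feature_table()] is read
#' @param loads per-sample loads, required to read back a QMP table
#' @export
read_feature_table <- function(path, mode = c("counts", "RMP", "QMP"),
                               metadata = NULL, loads = NULL) {
  mode <- match.arg(mode)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "sample_id") {
    # orientation guess: taxa-as-rows with sample columns; transpose
    mat <- t(as.matrix(df[, -1, drop = FALSE]))
    colnames(mat) <- df[[1]]
  } else {
    mat <- as.matrix(df[, -1, drop = FALSE])
    rownames(mat) <- df$sample_id
  }
  storage.mode(mat) <- "double"
  if (is.null(metadata)) {
    mpath <- paste0(path, ".metadata.tsv")
    if (file.exists(mpath))
      metadata <- utils::read.table(mpath, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)
    else
      metadata <- data.frame(sample_id = rownames(mat),
                             stringsAsFactors = FALSE)
  }
  taxonomy <- NULL
  tpath <- paste0(path, ".taxonomy.tsv")
  if (file.exists(tpath)) {
    td <- utils::read.table(tpath, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    taxonomy <- stats::setNames(td$lineage, td$taxon)[colnames(mat)]
  }
  feature_table(mat, metadata, taxonomy = taxonomy, mode = mode, loads = loads)
}

#' Write / read a feature table in BIOM format
#'
#' Uses the biomformat package (JSON flavour). Taxonomy lineages are stored
#' as observation metadata. BIOM is observation-major; the matrix is
#' transposed on the way in and out so the in-memory orientation stays
#' samples-as-rows.
#'
#' @param x feature_table
#' @param path output .biom path
#' @return `path` invisibly / a feature_table
#' @export
write_feature_table_biom <- function(x, path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required for BIOM output")
  obs_md <- NULL
  if (!is.null(x$taxonomy))
    obs_md <- lapply(unname(x$taxonomy), function(l)
      list(taxonomy = strsplit(l, ";\\s*")[[1]]))
  b <- biomformat::make_biom(t(x$mat),
                             observation_metadata = obs_md)
  biomformat::write_biom(b, path)
  invisible(path)
}

#' @rdname write_feature_table_biom
#' @param metadata data.frame of sample metadata (sample_id column)
#' @param mode mode flag for the table read back
#' @param loads per-sample loads when mode = "QMP"
#' @export
read_feature_table_biom <- function(path, metadata = NULL,
                                    mode = c("counts", "RMP", "QMP"),
                                    loads = NULL) {
  mode <- match.arg(mode)
  if (!requireNamespace("biomformat", quietly = TRUE))
    stop("the biomformat package is required for BIOM input")
  b <- biomformat::read_biom(path)
  mat <- t(as(biomformat::biom_data(b), "matrix"))
  taxonomy <- NULL
  om <- tryCatch(biomformat::observation_metadata(b), error = function(e) NULL)
  if (!is.null(om)) {
    if (is.data.frame(om))
      taxonomy <- apply(om, 1, paste, collapse = ";")
    else if (is.list(om))
      taxonomy <- vapply(om, function(r)
        paste(unlist(r$taxonomy), collapse = ";"), character(1))
    taxonomy <- taxonomy[colnames(mat)]
  }
  if (is.null(metadata))
    metadata <- data.frame(sample_id = rownames(mat),
                           stringsAsFactors = FALSE)
  feature_table(mat, metadata, taxonomy = taxonomy, mode = mode, loads = loads)
}
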