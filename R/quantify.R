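#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 template copies, the calibration
#' that turns Ct values into absolute marker-gene copy numbers. A perfectly
#' efficient reaction doubles template each cycle, giving a slope of
#' -1/log10(2) = -3.3219 and amplification efficiency
#' E = (10^(-1/slope) - 1) * 100 = 100%.
#'
#' @param log10_copies numeric vector of log10 template copies of the
#'   standards (e.g. 3:8 for a 10^3..10^8 dilution series)
#' @param ct numeric vector of measured Ct values, same length
#' @param domain label carried through ("bacteria" or "fungi")
#' @return object of class `standard_curve` with slope (Ct per
#'   log10-copies), intercept (Ct at 1 copy), r_squared, efficiency (%),
#'   and the calibrated range of log10 copies and Ct.
#' @export
fit_standard_curve <- function(log10_copies, ct, domain = "bacteria") {
  if (length(log10_copies) != length(ct))
    stop("log10_copies and ct must have the same length")
  ok <- is.finite(log10_copies) & is.finite(ct)
  log10_copies <- log10_copies[ok]; ct <- ct[ok]
  if (length(unique(log10_copies)) < 3)
    stop("calibration needs at least 3 distinct concentration points")
  fit <- stats::lm(ct ~ log10_copies)
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0) stop("zero slope: Ct does not respond to concentration")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((ct - mean(ct))^2)
  structure(list(
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
    efficiency = (10^(-1 / slope) - 1) * 100,
    domain = domain,
    range_log10 = range(log10_copies),
    range_ct = range(stats::fitted(fit))
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard_curve [%s]: Ct = %.4f + %.4f * log10(copies)\n  r2 = %.4f, efficiency = %.1f%%, calibrated 10^%g..10^%g copies\n",
    x$domain, x$intercept, x$slope, x$r_squared, x$efficiency,
    x$range_log10[1], x$range_log10[2]))
  invisible(x)
}

#' Back-calculate microbial load from Ct
#'
#' Inverts the standard curve (copies = 10^((ct - intercept)/slope)) and
#' scales reaction copies to copies per gram of luminal content. Ct values
#' outside the calibrated range are still converted but flagged as
#' extrapolated with a warning.
#'
#' @param curve a `standard_curve`
#' @param ct numeric vector of sample Ct values
#' @param dilution_factor scalar or vector: total copies in the DNA extract
#'   per copy in the reaction (elution volume / template volume, times any
#'   predilution). No default: extraction volumes are protocol-specific.
#' @param sample_weight grams of luminal content extracted (scalar or
#'   vector, > 0)
#' @return data.frame with copies (per reaction-equivalent extract), load
#'   (copies per gram), and an `extrapolated` flag
#' @export
ct_to_load <- function(curve, ct, dilution_factor, sample_weight) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(sample_weight <= 0)) stop("sample_weight must be positive")
  if (missing(dilution_factor)) stop("dilution_factor is required")
  copies_rxn <- 10^((ct - curve$intercept) / curve$slope)
  lo <- min(curve$range_ct); hi <- max(curve$range_ct)
  extrap <- ct < lo - 1e-9 | ct > hi + 1e-9
  if (any(extrap))
    warning(sum(extrap), " Ct value(s) outside the calibrated range [",
            round(lo, 2), ", ", round(hi, 2), "]; loads flagged as extrapolated")
  data.frame(ct = ct,
             copies = copies_rxn * dilution_factor,
             load = copies_rxn * dilution_factor / sample_weight,
             extrapolated = extrap)
}

#' QMP transform: scale relative abundances by measured loads
#'
#' The defining step of quantitative microbiome profiling: each sample's
#' compositional profile is multiplied by its measured total microbial load
#' so that values become marker-gene copies per gram and changes in total
#' biomass are no longer aliased into every taxon's apparent abundance.
#'
#' @param table feature_table in counts or RMP mode
#' @param loads named numeric vector (copies/g) covering every sample, or a
#'   data.frame with sample_id and load columns
#' @param copy_number optional per-taxon marker-gene copy numbers; when
#'   given, each taxon's abundance is divided by its copy number and rows
#'   are renormalised before scaling (off by default: loads are copies,
#'   not cells, and most assays report uncorrected copies)
#' @param rarefy subsample counts to the minimum sampling depth before
#'   computing proportions (counts input only; off by default — the
#'   default protocol scales raw proportions directly)
#' @param impute_missing impute a missing load as the geometric mean of
#'   loads in the sample's segment x dph group (requires segment/dph
#'   metadata); the default is to fail, listing the affected samples
#' @param seed RNG seed used only when `rarefy = TRUE`
#' @return feature_table in QMP mode
#' @export
qmp_transform <- function(table, loads, copy_number = NULL, rarefy = FALSE,
                          impute_missing = FALSE, seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (is.data.frame(loads))
    loads <- stats::setNames(loads$load, loads$sample_id)
  if (rarefy) {
    if (table$mode != "counts")
      stop("rarefaction needs a counts-mode table")
    set.seed(seed)
    depth <- min(rowSums(table$mat))
    table$mat <- vegan::rrarefy(round(table$mat), depth)
  }
  if (table$mode == "counts") table <- to_relative(table)
  if (table$mode != "RMP") stop("input must be counts or RMP")
  missing_ids <- setdiff(rownames(table$mat), names(loads))
  if (length(missing_ids)) {
    if (!impute_missing)
      stop("missing load for sample(s): ",
           paste(missing_ids, collapse = ", "))
    md <- table$metadata
    if (!all(c("segment", "dph") %in% names(md)))
      stop("load imputation needs segment and dph metadata")
    for (id in missing_ids) {
      grp <- md$sample_id[md$segment == md$segment[md$sample_id == id] &
                            md$dph == md$dph[md$sample_id == id]]
      grp_loads <- loads[intersect(grp, names(loads))]
      if (!length(grp_loads))
        stop("cannot impute load for ", id, ": empty segment x dph group")
      loads[id] <- exp(mean(log(grp_loads)))
      message("imputed load for ", id, " as the geometric mean of its ",
              "segment x dph group")
    }
  }
  mat <- table$mat
  if (!is.null(copy_number)) {
    cn <- copy_number[colnames(mat)]
    if (any(is.na(cn) | cn <= 0))
      stop("copy_number must cover every taxon with positive values")
    mat <- sweep(mat, 2, cn, "/")
    mat <- mat / rowSums(mat)
  }
  loads <- loads[rownames(mat)]
  feature_table(mat * loads, table$metadata, taxonomy = table$taxonomy,
                mode = "QMP", loads = loads)
}

rank_prefixes <- c(domain = "d__", phylum = "p__", class = "c__",
                   order = "o__", family = "f__", genus = "g__")

#' Collapse taxa to a taxonomic rank
#'
#' Columns are summed within the named rank parsed from lineage strings.
#' Lineages with no name at the requested rank are pooled under their
#' deepest named ancestor, labelled with that ancestor's rank prefix (e.g.
#' `f_Nectriaceae` for a genus-level collapse of a family-only lineage),
#' matching common amplicon-pipeline labelling.
#'
#' @param table feature_table with taxonomy lineages
#' @param rank one of domain, phylum, class, order, family, genus
#' @return feature_table at the requested rank (same mode; per-sample
#'   totals are preserved exactly)
#' @export
collapse_taxa <- function(table, rank = "genus") {
  stopifnot(inherits(table, "feature_table"))
  rank <- match.arg(rank, names(rank_prefixes))
  if (is.null(table$taxonomy)) stop("table has no taxonomy lineages")
  depth <- match(rank, names(rank_prefixes))
  labels <- vapply(seq_along(table$taxonomy), function(i) {
    lin <- table$taxonomy[i]
    parts <- trimws(strsplit(lin, ";")[[1]])
    parts <- parts[parts != ""]
    if (!length(parts)) {
      warning("malformed lineage for taxon '", names(table$taxonomy)[i],
              "'; kept as its own label")
      return(names(table$taxonomy)[i])
    }
    # strip rank prefixes, keep names; find deepest named rank <= requested
    nm <- sub("^[a-z]__", "", parts)
    named <- which(nzchar(nm))
    named <- named[named <= depth]
    if (!length(named)) {
      warning("lineage has no named rank at or above ", rank, " for taxon '",
              names(table$taxonomy)[i], "'; kept as its own label")
      return(names(table$taxonomy)[i])
    }
    j <- max(named)
    if (j == depth) nm[j]
    else paste0(substr(names(rank_prefixes)[j], 1, 1), "_", nm[j])
  }, character(1))
  groups <- factor(labels, levels = unique(labels))
  collapsed <- t(rowsum(t(table$mat), groups))
  colnames(collapsed) <- levels(groups)
  feature_table(collapsed, table$metadata, taxonomy = NULL,
                mode = table$mode, loads = table$loads)
}
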