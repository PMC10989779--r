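#' Per-day detection counts for one genus in one segment
#'
#' Counts, at every sampling day, how many birds carry the genus above the
#' detection threshold (default: any nonzero abundance after the QMP
#' transform, i.e. > 0 copies/g).
#'
#' @param table feature_table (QMP recommended) with bird/segment/dph
#'   metadata
#' @param genus column name in the table
#' @param segment segment to analyse
#' @param threshold detection threshold on the table's values (default 0,
#'   i.e. strictly positive abundance counts as detected)
#' @return data.frame: dph, detected, n_birds
#' @export
detection_matrix <- function(table, genus, segment, threshold = 0) {
  if (!genus %in% colnames(table$mat))
    stop("genus '", genus, "' absent from table")
  md <- table$metadata
  keep <- md$segment == segment
  if (!any(keep)) stop("no samples in segment ", segment)
  md <- md[keep, , drop = FALSE]
  v <- table$mat[md$sample_id, genus]
  days <- sort(unique(md$dph))
  data.frame(
    dph = days,
    detected = vapply(days, function(t)
      sum(v[md$dph == t] > threshold), integer(1)),
    n_birds = vapply(days, function(t)
      sum(md$dph == t), integer(1)))
}

#' Presence/absence/transition states from detection counts
#'
#' A genus is "present" at a day when detected in at least `presence_min`
#' of the birds, "absent" when detected in at most `absence_max`, and in
#' "transition" otherwise. Defaults follow a 10-bird design: present when
#' n >= 9, absent when n <= 1.
#'
#' @param counts integer detection counts per day
#' @param n_birds birds sampled per day (scalar or vector)
#' @param presence_min,absence_max state thresholds (presence_min >
#'   absence_max)
#' @return character vector of states per day
#' @export
states_from_counts <- function(counts, n_birds, presence_min = 9,
                               absence_max = 1) {
  if (presence_min <= absence_max)
    stop("presence_min must exceed absence_max")
  if (any(counts > n_birds)) stop("detection count exceeds n_birds")
  ifelse(counts >= presence_min, "present",
         ifelse(counts <= absence_max, "absent", "transition"))
}

#' Classify an ordered state trajectory into an occurrence category
#'
#' Categories (total over all inputs):
#' \describe{
#'   \item{core}{present at every day}
#'   \item{colonization}{absent at the first day, absent up to some onset,
#'     present at the onset and at every later day}
#'   \item{disappearance}{present at the first day, present up to some
#'     offset, absent from the offset onward}
#'   \item{irregular}{anything else, including any trajectory containing a
#'     transition state (configurable via `transitions`)}
#' }
#'
#' @param states ordered character vector of
#'   present/absent/transition states (>= 2 days)
#' @param transitions how to treat transition states: "irregular" (any
#'   transition makes the trajectory irregular, the default), "absent" or
#'   "present" (recode and classify)
#' @return list: category, onset (first present day index, colonization),
#'   offset (first absent day index, disappearance)
#' @export
classify_pattern <- function(states,
                             transitions = c("irregular", "absent",
                                             "present")) {
  transitions <- match.arg(transitions)
  if (length(states) < 2) stop("need at least two time points")
  if (any(states == "transition")) {
    if (transitions == "irregular")
      return(list(category = "irregular", onset = NA, offset = NA))
    states[states == "transition"] <- transitions
  }
  p <- states == "present"
  if (all(p)) return(list(category = "core", onset = 1, offset = NA))
  if (!p[1]) {
    # absent at hatch: colonization iff a single absent->present switch
    r <- rle(p)
    if (length(r$values) == 2 && identical(r$values, c(FALSE, TRUE)))
      return(list(category = "colonization",
                  onset = r$lengths[1] + 1, offset = NA))
  } else {
    r <- rle(p)
    if (length(r$values) == 2 && identical(r$values, c(TRUE, FALSE)))
      return(list(category = "disappearance", onset = NA,
                  offset = r$lengths[1] + 1))
  }
  list(category = "irregular", onset = NA, offset = NA)
}

#' Occurrence-pattern census across segments
#'
#' Builds every genus's state trajectory per segment, classifies it, and
#' reports per-segment category counts plus the cross-segment intersection
#' sets of genera per category (which genera share a category across all
#' four segments, etc.).
#'
#' @param table feature_table (QMP) covering all segments of one domain
#' @param segments segments to include (default: all in the metadata)
#' @param presence_min,absence_max passed to [states_from_counts()]
#' @param threshold detection threshold
#' @param transitions passed to [classify_pattern()]
#' @return list with `trajectories` (data.frame: segment, genus, category,
#'   onset_dph, offset_dph, states string), `census` (counts per segment x
#'   category), `intersections` (per category: named list mapping each
#'   segment-combination to its genus set)
#' @export
pattern_census <- function(table, segments = NULL, presence_min = 9,
                           absence_max = 1, threshold = 0,
                           transitions = "irregular") {
  md <- table$metadata
  if (is.null(segments)) segments <- unique(md$segment)
  genera <- colnames(table$mat)
  rows <- list()
  for (sg in segments) {
    sub_md <- md[md$segment == sg, , drop = FALSE]
    days <- sort(unique(sub_md$dph))
    sub <- table$mat[sub_md$sample_id, , drop = FALSE]
    det <- vapply(days, function(t)
      colSums(sub[sub_md$dph == t, , drop = FALSE] > threshold),
      numeric(length(genera)))
    nb <- vapply(days, function(t) sum(sub_md$dph == t), integer(1))
    for (gi in seq_along(genera)) {
      st <- states_from_counts(det[gi, ], nb, presence_min, absence_max)
      cl <- classify_pattern(st, transitions = transitions)
      rows[[length(rows) + 1]] <- data.frame(
        segment = sg, genus = genera[gi], category = cl$category,
        onset_dph = if (is.na(cl$onset)) NA else days[cl$onset],
        offset_dph = if (is.na(cl$offset)) NA else days[cl$offset],
        states = paste(substr(st, 1, 1), collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  traj <- do.call(rbind, rows)
  census <- as.data.frame.matrix(table(traj$segment, traj$category))
  cats <- c("colonization", "disappearance", "core")
  intersections <- lapply(stats::setNames(cats, cats), function(cat) {
    sets <- lapply(stats::setNames(segments, segments), function(sg)
      traj$genus[traj$segment == sg & traj$category == cat])
    combos <- list()
    for (k in rev(seq_along(segments))) {
      for (cmb in utils::combn(segments, k, simplify = FALSE)) {
        shared <- Reduce(intersect, sets[cmb])
        # exclusive intersection: drop genera also in a larger combo
        others <- setdiff(segments, cmb)
        if (length(others))
          shared <- shared[!vapply(shared, function(g)
            any(vapply(others, function(o) g %in% sets[[o]], logical(1))),
            logical(1))]
        combos[[paste(cmb, collapse = "&")]] <- shared
      }
    }
    combos
  })
  list(trajectories = traj, census = census, intersections = intersections)
}
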