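# Annotation tiers: one annotator's ordered, timestamped label segments for
# one recording.  Times are integer milliseconds; intervals are half-open
# [start, end) so that adjacent segments tile without double counting.

#' Construct an annotation tier
#'
#' @param start,end Segment boundaries in milliseconds (`0 <= start < end`).
#' @param label Ground labels.
#' @param run_id Recording identifier.
#' @param annotator_id Annotator identifier.
#' @return An object of class `annotation_tier`: a list with `run_id`,
#'   `annotator_id` and a `segments` data.frame sorted by start time.
#'   Overlaps between segments are recorded in attribute `"overlapping"`
#'   (with a warning), not repaired: they are fatal for plan conversion but
#'   tolerated for reliability slicing.
#' @export
annotation_tier <- function(start, end, label, run_id = "run",
                            annotator_id = "A") {
  stopifnot(length(start) == length(end), length(start) == length(label))
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start < 0)) stop("segment start before 0 ms", call. = FALSE)
  if (any(end <= start))
    stop("segment end must be after start (row ",
         which(end <= start)[1], ")", call. = FALSE)
  ord <- order(start, end)
  seg <- data.frame(start = start[ord], end = end[ord],
                    label = as.character(label)[ord],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(seg))
    stop("duplicate segment rows", call. = FALSE)
  overlapping <- nrow(seg) > 1 &&
    any(seg$start[-1] < seg$end[-nrow(seg)])
  if (overlapping)
    warning("tier has overlapping segments; plan conversion will refuse it",
            call. = FALSE)
  structure(list(run_id = run_id, annotator_id = annotator_id,
                 segments = seg),
            class = "annotation_tier", overlapping = overlapping)
}

#' Tier coverage helpers
#'
#' `tier_is_gap_free()` is true when each segment's end equals the next
#' segment's start (the precondition for [tier_to_plan()]);
#' `tier_horizon()` is the end of the last segment in ms (0 for an empty
#' tier).
#'
#' @param tier An [annotation_tier()].
#' @return A logical / a number of milliseconds.
#' @export
tier_is_gap_free <- function(tier) {
  seg <- tier$segments
  nrow(seg) == 0 ||
    (!isTRUE(attr(tier, "overlapping")) &&
     all(seg$start[-1] == seg$end[-nrow(seg)]))
}

#' @rdname tier_is_gap_free
#' @export
tier_horizon <- function(tier) {
  if (nrow(tier$segments) == 0) 0 else max(tier$segments$end)
}

#' @export
print.annotation_tier <- function(x, ...) {
  cat("annotation tier: run '", x$run_id, "', annotator '", x$annotator_id,
      "', ", nrow(x$segments), " segment(s)", sep = "")
  if (nrow(x$segments) > 0)
    cat(", ", format_msec(tier_horizon(x)), " total", sep = "")
  cat("\n")
  invisible(x)
}

# ---- time codes -------------------------------------------------------------

#' Convert between milliseconds and `MM:SS.mmm` time codes
#'
#' `parse_msec()` accepts `MM:SS.mmm`, `HH:MM:SS.mmm` or a bare integer
#' millisecond count; `format_msec()` renders `MM:SS.mmm` (minutes may
#' exceed 59).
#'
#' @param x Character time codes, or numeric milliseconds.
#' @return Numeric milliseconds / character time codes.
#' @export
parse_msec <- function(x) {
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    if (grepl("^[0-9]+$", s)) return(as.numeric(s))
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    if (!(length(parts) %in% c(2, 3)) || anyNA(suppressWarnings(as.numeric(parts))))
      stop("malformed time code '", s, "'", call. = FALSE)
    secs <- as.numeric(parts[length(parts)])
    mins <- as.numeric(parts[length(parts) - 1])
    hrs <- if (length(parts) == 3) as.numeric(parts[1]) else 0
    round(((hrs * 60 + mins) * 60 + secs) * 1000)
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname parse_msec
#' @export
format_msec <- function(x) {
  x <- round(as.numeric(x))
  mins <- x %/% 60000
  rest <- x %% 60000
  sprintf("%02d:%06.3f", mins, rest / 1000)
}

# ---- reading and writing ----------------------------------------------------

#' Read an annotation tier
#'
#' Supported formats:
#' \describe{
#'   \item{`elan-tsv`}{the ELAN tab-delimited export: four tab-separated
#'     columns `tier-name`, start, end, label, times as `MM:SS.mmm` (or
#'     `HH:MM:SS.mmm`, or integer milliseconds).  The tier name becomes the
#'     annotator id.}
#'   \item{`csv`}{columns `run,annotator,start_ms,end_ms,label` with a
#'     header row and integer millisecond times.}
#' }
#' Rows are sorted by start time; overlaps and gaps are recorded, never
#' repaired.
#'
#' @param file Path, or the file content as a character vector of lines.
#' @param format `"elan-tsv"` or `"csv"`.
#' @param run_id Run identifier for `elan-tsv` input (which does not carry
#'   one).
#' @return An [annotation_tier()].
#' @export
read_tier <- function(file, format = c("elan-tsv", "csv"), run_id = "run") {
  format <- match.arg(format)
  lines <- if (length(file) == 1 && !grepl("\n", file) && file.exists(file))
    readLines(file, warn = FALSE) else unlist(strsplit(file, "\n"))
  lines <- lines[nzchar(trimws(lines))]
  if (format == "elan-tsv") {
    if (length(lines) == 0)
      return(annotation_tier(numeric(0), numeric(0), character(0),
                             run_id = run_id, annotator_id = "A"))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 4)
    if (length(bad) > 0)
      stop("malformed elan-tsv row ", bad[1], ": expected 4 tab-separated ",
           "columns", call. = FALSE)
    m <- do.call(rbind, lapply(parts, `[`, 1:4))
    annotation_tier(parse_msec(m[, 2]), parse_msec(m[, 3]), trimws(m[, 4]),
                    run_id = run_id, annotator_id = m[1, 1])
  } else {
    con <- textConnection(lines)
    on.exit(close(con))
    df <- utils::read.csv(con, stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "numeric", "numeric", "character"))
    need <- c("run", "annotator", "start_ms", "end_ms", "label")
    if (!all(need %in% names(df)))
      stop("csv tier must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    if (nrow(df) == 0)
      return(annotation_tier(numeric(0), numeric(0), character(0),
                             run_id = run_id, annotator_id = "A"))
    annotation_tier(df$start_ms, df$end_ms, df$label,
                    run_id = df$run[1], annotator_id = df$annotator[1])
  }
}

#' Write an annotation tier
#'
#' Inverse of [read_tier()]: `read_tier(write_tier(tier, ...))` returns an
#' identical tier in either format.
#'
#' @param tier An [annotation_tier()].
#' @param file Optional output path; if `NULL` the lines are returned.
#' @param format `"elan-tsv"` or `"csv"`.
#' @return Character vector of lines, invisibly when written to `file`.
#' @export
write_tier <- function(tier, file = NULL, format = c("elan-tsv", "csv")) {
  format <- match.arg(format)
  seg <- tier$segments
  lines <- if (format == "elan-tsv") {
    if (nrow(seg) == 0) character(0) else
      paste(tier$annotator_id, format_msec(seg$start), format_msec(seg$end),
            seg$label, sep = "\t")
  } else {
    c("run,annotator,start_ms,end_ms,label",
      if (nrow(seg) > 0)
        paste(tier$run_id, tier$annotator_id, seg$start, seg$end, seg$label,
              sep = ","))
  }
  if (!is.null(file)) { writeLines(lines, file); return(invisible(lines)) }
  lines
}

#' Convert a gap-free tier to a plan
#'
#' Each segment becomes one plan step at the segment's start time
#' (instantaneous-action reading: the state between actions is constant).
#' The tier must be gap-free -- every segment's end equal to the next
#' segment's start -- and every label must belong to the domain's label
#' set; all unresolvable labels are reported together with their segment
#' index, which is the information an annotator needs to repair the tier.
#'
#' @param tier An [annotation_tier()].
#' @param domain A `semannot_domain`.
#' @return A `semannot_plan` (see [plan_steps()]).
#' @export
tier_to_plan <- function(tier, domain) {
  if (!tier_is_gap_free(tier))
    stop("tier is not gap-free: plan conversion needs contiguous segments",
         call. = FALSE)
  labels <- enumerate_labels(domain)
  bad <- which(!(tier$segments$label %in% labels))
  if (length(bad) > 0)
    stop("label(s) not in the domain's label set: ",
         paste(sprintf("'%s' (segment %d)", tier$segments$label[bad], bad),
               collapse = ", "), call. = FALSE)
  plan_steps(tier$segments$start, tier$segments$label)
}
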