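# Interrater reliability between two annotators on a common time base.
#
# Both tiers are resampled onto fixed-resolution time slices (default
# 10 ms); each slice carries the ground label of the segment covering the
# slice start, or the reserved label NONE where the tier leaves the time
# uncovered.  Raw agreement, Cohen's kappa and Krippendorff's alpha
# (nominal, two observers, no missing data) are then computed over the
# slice pairs, so long disagreements weigh more than short ones.

NONE_LABEL <- "NONE"

#' Resample a tier onto fixed time slices
#'
#' Slice `i` (1-based) covers `[(i-1)*resolution, i*resolution)` and
#' carries the label of the segment containing its start point; `"NONE"`
#' where no segment covers it.  Within a tier, overlapping segments are
#' resolved last-writer-wins (the later-starting segment).
#'
#' @param tier An [annotation_tier()].
#' @param resolution Slice width in ms (>= 1).
#' @param horizon Total span in ms; defaults to the tier's last segment
#'   end.
#' @return Character vector of length `ceiling(horizon / resolution)`.
#' @export
slice_tier <- function(tier, resolution = 10, horizon = NULL) {
  stopifnot(resolution >= 1)
  if (is.null(horizon)) horizon <- tier_horizon(tier)
  n <- ceiling(horizon / resolution)
  out <- rep(NONE_LABEL, n)
  if (n == 0) return(out)
  starts <- (seq_len(n) - 1) * resolution
  seg <- tier$segments
  for (i in seq_len(nrow(seg))) {   # segments sorted by start: later wins
    cover <- starts >= seg$start[i] & starts < seg$end[i]
    out[cover] <- seg$label[i]
  }
  out
}

#' Agreement metrics for two parallel label series
#'
#' The core computation behind [interrater()], usable directly on two
#' equal-length label vectors (one element per unit of analysis).
#'
#' Raw agreement is the fraction of units with equal labels.  Cohen's
#' kappa is `(p_o - p_e) / (1 - p_e)` with chance agreement
#' `p_e = sum_k p_a(k) p_b(k)`.  Krippendorff's alpha is `1 - D_o / D_e`
#' for nominal data with two observers and no missing values, computed
#' from the coincidence matrix.
#'
#' @param a,b Character vectors of equal positive length.
#' @return A list of class `reliability_result`: `agreement`, `kappa`,
#'   `alpha`, `n_slices`, and `confusion` (a label-by-label contingency
#'   table, `a` in rows).
#' @export
agreement_stats <- function(a, b) {
  if (length(a) == 0 || length(a) != length(b))
    stop("need two equal-length non-empty label series", call. = FALSE)
  levs <- sort(unique(c(a, b)), method = "radix")
  fa <- factor(a, levels = levs)
  fb <- factor(b, levels = levs)
  confusion <- table(a = fa, b = fb)
  n <- length(a)
  p_o <- sum(diag(confusion)) / n
  p_e <- sum((rowSums(confusion) / n) * (colSums(confusion) / n))
  kappa <- if (p_e == 1) 1 else (p_o - p_e) / (1 - p_e)

  # coincidence matrix: each unit contributes its (a,b) and (b,a) pair
  coin <- confusion + t(confusion)
  nc <- rowSums(coin)
  ntot <- sum(nc)                       # 2n pairable values
  d_o <- (ntot - sum(diag(coin))) / ntot
  d_e <- (ntot^2 - sum(nc^2)) / (ntot * (ntot - 1))
  alpha <- if (d_e == 0) 1 else 1 - d_o / d_e

  structure(list(agreement = p_o, kappa = kappa, alpha = alpha,
                 n_slices = n, confusion = confusion),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("interrater reliability over %d slices:\n", x$n_slices))
  cat(sprintf("  agreement %.4f   Cohen's kappa %.4f   Krippendorff's alpha %.4f\n",
              x$agreement, x$kappa, x$alpha))
  invisible(x)
}

#' Interrater reliability between two tiers
#'
#' Slices both tiers of one run onto a common time base (the horizon is the
#' later of the two tiers' ends) and scores the slice pairs.  By default
#' full ground labels are compared -- `take-bowl-cupboard` and
#' `take-bowl-counter` count as disagreement -- and uncovered (`NONE`)
#' slices are included, a missing label being a real disagreement.
#'
#' @param a,b Two [annotation_tier()]s with the same `run_id`.
#' @param resolution Slice width in ms; default 10.
#' @param level `"ground"` compares full labels, `"class"` compares only
#'   the action class (the first hyphen-separated token).
#' @param ignore_none Drop slices where either tier is uncovered.
#' @return A `reliability_result` (see [agreement_stats()]).
#' @examples
#' t1 <- annotation_tier(c(0, 100), c(100, 200), c("take-a-b", "put-a-b"))
#' interrater(t1, t1)$kappa
#' @export
interrater <- function(a, b, resolution = 10,
                       level = c("ground", "class"), ignore_none = FALSE) {
  level <- match.arg(level)
  if (!identical(a$run_id, b$run_id))
    stop("tiers belong to different runs ('", a$run_id, "' vs '", b$run_id,
         "')", call. = FALSE)
  horizon <- max(tier_horizon(a), tier_horizon(b))
  if (horizon == 0)
    stop("both tiers are empty: reliability metrics are undefined",
         call. = FALSE)
  sa <- slice_tier(a, resolution, horizon)
  sb <- slice_tier(b, resolution, horizon)
  if (level == "class") {
    sa <- label_class(sa)
    sb <- label_class(sb)
  }
  if (ignore_none) {
    keep <- sa != NONE_LABEL & sb != NONE_LABEL
    if (!any(keep))
      stop("no jointly covered slices: metrics are undefined", call. = FALSE)
    sa <- sa[keep]; sb <- sb[keep]
  }
  agreement_stats(sa, sb)
}

#' Action class of a ground label
#'
#' The class is the leading hyphen-separated token (entity names may
#' contain underscores but never hyphens); `"NONE"` maps to itself.
#'
#' @param label Character vector of ground labels.
#' @return Character vector of action classes.
#' @export
label_class <- function(label) {
  ifelse(label == NONE_LABEL, NONE_LABEL, sub("-.*$", "", label))
}

#' Disagreement intervals between two tiers
#'
#' Returns the maximal time intervals on which the two tiers disagree,
#' with both labels, and classifies each as `"boundary-shift"` (both
#' labels also occur in the other tier within `window` ms of the interval
#' -- the annotators saw the same actions but placed a boundary
#' differently) or `"substitution"`.
#'
#' @param a,b Two [annotation_tier()]s with the same `run_id`.
#' @param window Boundary-shift tolerance in ms (default 1000); purely
#'   diagnostic.
#' @return A data.frame with columns `start`, `end`, `label_a`, `label_b`,
#'   `kind`; zero rows when the tiers agree everywhere.
#' @export
diff_segments <- function(a, b, window = 1000) {
  if (!identical(a$run_id, b$run_id))
    stop("tiers belong to different runs", call. = FALSE)
  horizon <- max(tier_horizon(a), tier_horizon(b))
  bounds <- sort(unique(c(0, horizon,
                          a$segments$start, a$segments$end,
                          b$segments$start, b$segments$end)))
  bounds <- bounds[bounds <= horizon]
  if (length(bounds) < 2)
    return(data.frame(start = numeric(0), end = numeric(0),
                      label_a = character(0), label_b = character(0),
                      kind = character(0), stringsAsFactors = FALSE))
  s <- bounds[-length(bounds)]
  e <- bounds[-1]
  lab_at <- function(tier, t) {
    seg <- tier$segments
    hit <- which(seg$start <= t & t < seg$end)
    if (length(hit) == 0) NONE_LABEL else seg$label[max(hit)]
  }
  la <- vapply(s, lab_at, character(1), tier = a)
  lb <- vapply(s, lab_at, character(1), tier = b)
  keep <- la != lb
  s <- s[keep]; e <- e[keep]; la <- la[keep]; lb <- lb[keep]
  # merge adjacent intervals carrying the same disagreement
  if (length(s) > 1) {
    new_run <- c(TRUE, s[-1] != e[-length(e)] |
                   la[-1] != la[-length(la)] | lb[-1] != lb[-length(lb)])
    grp <- cumsum(new_run)
    s <- tapply(s, grp, min)
    e <- tapply(e, grp, max)
    la <- tapply(la, grp, `[`, 1)
    lb <- tapply(lb, grp, `[`, 1)
  }
  occurs_near <- function(tier, label, lo, hi) {
    if (label == NONE_LABEL) return(TRUE)
    seg <- tier$segments
    any(seg$label == label & seg$start < hi & seg$end > lo)
  }
  kind <- vapply(seq_along(s), function(i) {
    lo <- s[[i]] - window; hi <- e[[i]] + window
    if (occurs_near(b, la[[i]], lo, hi) && occurs_near(a, lb[[i]], lo, hi))
      "boundary-shift" else "substitution"
  }, character(1))
  data.frame(start = as.numeric(s), end = as.numeric(e),
             label_a = as.character(la), label_b = as.character(lb),
             kind = kind, row.names = NULL, stringsAsFactors = FALSE)
}

#' Reliability learning curve over an annotation sequence
#'
#' Scores each (annotator A, annotator B) tier pair in order -- e.g. the
#' successive videos of a training phase -- and summarises the trend: the
#' per-step change in raw agreement and the slope of a least-squares
#' straight line of agreement against pair index.
#'
#' @param pairs List of two-element lists/pairs of [annotation_tier()]s.
#' @param ... Passed to [interrater()] (resolution, level, ignore_none).
#' @return A list of class `learning_curve`: `results` (one
#'   `reliability_result` per pair), `agreement`, `kappa`, `alpha`
#'   (vectors), `diffs` (successive agreement differences) and `slope`.
#' @export
learning_curve <- function(pairs, ...) {
  if (length(pairs) < 1) stop("need at least one tier pair", call. = FALSE)
  results <- lapply(pairs, function(p) interrater(p[[1]], p[[2]], ...))
  agreement <- vapply(results, `[[`, numeric(1), "agreement")
  idx <- seq_along(agreement)
  slope <- if (length(idx) > 1)
    unname(stats::coef(stats::lm(agreement ~ idx))[2]) else 0
  structure(list(results = results,
                 agreement = agreement,
                 kappa = vapply(results, `[[`, numeric(1), "kappa"),
                 alpha = vapply(results, `[[`, numeric(1), "alpha"),
                 diffs = diff(agreement),
                 slope = slope),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("learning curve over", length(x$agreement), "pair(s)\n")
  cat("  agreement:", paste(sprintf("%.3f", x$agreement), collapse = " "), "\n")
  cat(sprintf("  trend slope: %+.4f per pair\n", x$slope))
  invisible(x)
}

#' Serialise a reliability result as JSON
#'
#' @param result A `reliability_result`.
#' @param path Optional output path.
#' @return JSON string.
#' @export
reliability_json <- function(result, path = NULL) {
  payload <- list(agreement = result$agreement, kappa = result$kappa,
                  alpha = result$alpha, n_slices = result$n_slices,
                  labels = rownames(result$confusion),
                  confusion = unclass(unname(as.matrix(result$confusion))))
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
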