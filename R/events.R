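#' Build the z-score event set for a biomarker panel
#'
#' Each biomarker contributes one event per z-threshold: the moment its
#' control-referenced atrophy z-score crosses that threshold. With 13
#' biomarkers and thresholds 1, 2, 3 the event set has 39 events and the
#' stage axis runs from 0 (no events) to 39 (all events occurred).
#'
#' @param biomarkers character vector of biomarker names (unique).
#' @param z_thresholds strictly increasing positive z thresholds shared by
#'   all biomarkers (default `c(1, 2, 3)`).
#' @return An object of class `event_set`: a list with the per-event
#'   biomarker index and threshold, biomarker labels, and counts.
#' @export
make_events <- function(biomarkers, z_thresholds = c(1, 2, 3)) {
  if (anyDuplicated(biomarkers)) stop_arg("biomarker names must be unique")
  if (length(z_thresholds) < 1 || any(diff(z_thresholds) <= 0) || any(z_thresholds <= 0))
    stop_arg("z_thresholds must be strictly increasing and positive")
  B <- length(biomarkers)
  Tn <- length(z_thresholds)
  ev <- list(
    biomarker    = rep(seq_len(B), each = Tn),
    z            = rep(as.numeric(z_thresholds), times = B),
    labels       = as.character(biomarkers),
    z_thresholds = as.numeric(z_thresholds),
    n_biomarkers = B,
    n_events     = B * Tn,
    by_biomarker = split(seq_len(B * Tn), rep(seq_len(B), each = Tn))
  )
  class(ev) <- "event_set"
  ev
}

# A sequence is an integer permutation of event ids; validity requires each
# biomarker's thresholds to appear in increasing order along the sequence.
is_valid_sequence <- function(ord, events) {
  if (length(ord) != events$n_events || anyDuplicated(ord)) return(FALSE)
  pos <- integer(events$n_events)
  pos[ord] <- seq_along(ord)
  for (ids in events$by_biomarker) {
    if (is.unsorted(pos[ids], strictly = TRUE)) return(FALSE)
  }
  TRUE
}

# validity check restricted to one biomarker (used inside the hill climb)
valid_for_biomarker <- function(ord, events, b) {
  pos <- match(events$by_biomarker[[b]], ord)
  !is.unsorted(pos, strictly = TRUE)
}

# Random valid sequence: draw a random permutation of positions, then place
# each biomarker's events at its allotted positions in threshold order.
random_valid_sequence <- function(events) {
  perm <- sample.int(events$n_events)
  ord <- integer(events$n_events)
  for (ids in events$by_biomarker) {
    slots <- sort(match(ids, perm))
    ord[slots] <- ids  # ids are already in increasing threshold order
  }
  ord
}

# Wave-like staggered sequence: biomarkers become abnormal in the given
# onset order and climb their thresholds progressively, with successive
# thresholds of one biomarker separated by `stagger` onset ranks. Early
# regions reach severe atrophy while late regions are just starting, as in
# a spatial progression wave; distinct onset orders give expected-z
# profiles that differ at every interior stage.
staggered_sequence <- function(events, biomarker_order = seq_len(events$n_biomarkers),
                               stagger = events$n_biomarkers / length(events$z_thresholds)) {
  Tn <- length(events$z_thresholds)
  onset <- match(seq_len(events$n_biomarkers), biomarker_order)
  key_b <- rep(onset, each = Tn)          # onset rank of each event's biomarker
  key_t <- rep(seq_len(Tn), times = events$n_biomarkers)
  key <- key_b + stagger * (key_t - 1)
  order(key, key_t, key_b)                # event ids sorted by progression time
}

# Exported tidy representation of an ordering.
as_event_sequence <- function(ord, events) {
  out <- data.frame(
    position  = seq_along(ord),
    biomarker = events$labels[events$biomarker[ord]],
    z         = events$z[ord],
    stringsAsFactors = FALSE
  )
  class(out) <- c("event_sequence", "data.frame")
  attr(out, "events") <- events
  out
}

# Recover the integer ordering from an event_sequence data frame.
sequence_ordering <- function(sequence, events = NULL) {
  if (is.numeric(sequence) && is.null(dim(sequence))) return(as.integer(sequence))
  if (is.null(events)) events <- attr(sequence, "events")
  if (is.null(events)) {
    events <- make_events(unique(sequence$biomarker), sort(unique(sequence$z)))
  }
  b <- match(sequence$biomarker, events$labels)
  t <- match(sequence$z, events$z_thresholds)
  if (anyNA(b) || anyNA(t)) stop_arg("sequence references unknown biomarkers or thresholds")
  ord <- as.integer((b - 1L) * length(events$z_thresholds) + t)
  if (!is_valid_sequence(ord, events))
    stop_arg("sequence violates within-biomarker threshold ordering")
  ord
}

# Expected z of every biomarker at every integer stage 0..N under a
# sequence: piecewise-linear through (0, 0), each of the biomarker's event
# positions at its threshold, and (N, z_max) when the last event precedes N.
expected_z_matrix <- function(ord, events, z_max) {
  K <- length(ord)
  B <- events$n_biomarkers
  zmax <- rep_len(z_max, B)
  pos <- integer(events$n_events)
  pos[ord] <- seq_along(ord)
  E <- matrix(0, B, K + 1L)
  xout <- 0:K
  for (b in seq_len(B)) {
    ids <- events$by_biomarker[[b]]
    x <- c(0, pos[ids])
    y <- c(0, events$z[ids])
    if (x[length(x)] < K) {
      x <- c(x, K)
      y <- c(y, zmax[b])
    }
    E[b, ] <- stats::approx(x, y, xout = xout)$y
  }
  rownames(E) <- events$labels
  colnames(E) <- as.character(xout)
  E
}

#' Expected z-score of a biomarker at a given stage
#'
#' The z-score event model assumes each biomarker's expected z follows a
#' piecewise-linear trajectory over the stage axis: 0 at stage 0, exactly
#' its threshold value at the stage where the corresponding event sits in
#' the sequence, and rising towards `z_max` at the final stage.
#'
#' @param sequence an `event_sequence` data frame (see [as_event_sequence()])
#'   giving the full ordering of (biomarker, threshold) events.
#' @param biomarker biomarker name (or index into the panel).
#' @param stage integer stage(s) in `[0, N_events]`.
#' @param z_max asymptotic z reached at the final stage (default 5).
#' @return numeric vector of expected z values, one per stage.
#' @export
expected_z_at_stage <- function(sequence, biomarker, stage, z_max = 5) {
  events <- attr(sequence, "events")
  if (is.null(events)) {
    events <- make_events(unique(sequence$biomarker), sort(unique(sequence$z)))
  }
  ord <- sequence_ordering(sequence, events)
  K <- length(ord)
  if (any(stage < 0 | stage > K)) stop_arg("stage must lie in [0, ", K, "]")
  b <- if (is.character(biomarker)) match(biomarker, events$labels) else as.integer(biomarker)
  if (is.na(b) || b < 1 || b > events$n_biomarkers) stop_arg("unknown biomarker")
  E <- expected_z_matrix(ord, events, z_max)
  unname(E[b, as.character(as.integer(stage))])
}

#' @export
print.event_sequence <- function(x, ...) {
  cat("Event sequence over", length(unique(x$biomarker)), "biomarkers,",
      nrow(x), "events\n")
  print.data.frame(utils::head(as.data.frame(x), 12), row.names = FALSE)
  if (nrow(x) > 12) cat("  ... (", nrow(x) - 12, " more events)\n", sep = "")
  invisible(x)
}

#' Kendall rank agreement between two event sequences
#'
#' Kendall tau between the event-position vectors of two orderings of the
#' same event set; 1 for identical sequences, -1 for full reversal.
#'
#' @param ord1,ord2 integer orderings (event ids in sequence order) or
#'   `event_sequence` data frames over the same event set.
#' @return Kendall tau in `[-1, 1]`.
#' @export
sequence_kendall <- function(ord1, ord2) {
  if (!is.numeric(ord1)) ord1 <- sequence_ordering(ord1)
  if (!is.numeric(ord2)) ord2 <- sequence_ordering(ord2)
  p1 <- integer(length(ord1)); p1[ord1] <- seq_along(ord1)
  p2 <- integer(length(ord2)); p2[ord2] <- seq_along(ord2)
  stats::cor(p1, p2, method = "kendall")
}
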