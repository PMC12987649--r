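# Detection of somatic action potentials and dendritic spikes from
# recorded traces, per the operational criteria:
#   AP    : somatic V crosses -10 mV with positive slope
#   Na+   : activated Na+ conductance density exceeds 0.3 mS/cm2, unless
#           within the bAP-exclusion window after a somatic AP
#   NMDA  : V above -40 mV for >= 26 ms AND the NMDA current magnitude
#           rises to 130% of its value at the -40 mV crossing; the event
#           ends when the current falls back to 115% of that reference
#   Ca2+  : same joint rule with the summed (HVA + LVA) calcium current

#' Event series container
#'
#' @param comp Compartment id.
#' @param kind One of `"AP"`, `"Na"`, `"NMDA"`, `"Ca"`.
#' @param onsets Event onset times, ms (strictly increasing).
#' @param offsets Offset times (plateau events) or `NA` (point events).
#' @param peaks Optional peak times (APs), ms.
#' @return Object of class `event_series`.
#' @export
event_series <- function(comp, kind, onsets, offsets = NULL, peaks = NULL) {
  kind <- match.arg(kind, c("AP", "Na", "NMDA", "Ca"))
  if (length(onsets) > 1 && is.unsorted(onsets, strictly = TRUE)) {
    stop("onsets must be strictly increasing")
  }
  if (is.null(offsets)) offsets <- rep(NA_real_, length(onsets))
  if (length(offsets) != length(onsets)) stop("onset/offset length mismatch")
  if (any(!is.na(offsets) & offsets <= onsets)) {
    stop("offsets must follow onsets")
  }
  structure(list(comp = comp, kind = kind, onsets = as.numeric(onsets),
                 offsets = as.numeric(offsets), peaks = peaks),
            class = "event_series")
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> %s, comp %s: %d events\n", x$kind,
              as.character(x$comp), length(x$onsets)))
  invisible(x)
}

# internal: indices where x crosses `thr` upward
.up_crossings <- function(x, thr) {
  n <- length(x)
  if (n < 2) return(integer())
  which(x[-1] >= thr & x[-n] < thr) + 1L
}

#' Detect somatic action potentials
#'
#' One event per upward crossing of the threshold (default -10 mV); the
#' peak time (sample of maximum V between the crossing and the next
#' downward crossing) is recorded for threshold analysis. A sustained
#' plateau above threshold yields exactly one event.
#'
#' @param v Somatic membrane potential, mV (uniform sampling).
#' @param dt Sample interval, ms.
#' @param t0 Time of the first sample, ms.
#' @param threshold Crossing threshold, mV.
#' @param comp Compartment id stored on the result.
#' @return An `event_series` of kind `"AP"` with `peaks`.
#' @export
detect_aps <- function(v, dt, t0 = dt, threshold = -10, comp = NA_integer_) {
  up <- .up_crossings(v, threshold)
  peaks <- numeric(length(up))
  n <- length(v)
  for (k in seq_along(up)) {
    i0 <- up[k]
    down <- which(v[i0:n] < threshold)
    i1 <- if (length(down)) i0 + down[1] - 2L else n
    peaks[k] <- t0 + (i0 - 1L + which.max(v[i0:i1]) - 1L) * dt
  }
  event_series(comp, "AP", t0 + (up - 1L) * dt, peaks = peaks)
}

#' Detect dendritic Na+ spikes
#'
#' Upward crossings of the activated Na+ conductance density threshold
#' (0.3 mS/cm2). Crossings within `exclusion` ms after a somatic action
#' potential are attributed to the backpropagating AP and discarded.
#'
#' @param gna Na+ conductance density trace, mS/cm2.
#' @param dt Sample interval, ms.
#' @param ap_times Somatic AP times, ms.
#' @param t0 Time of the first sample, ms.
#' @param threshold Conductance threshold, mS/cm2.
#' @param exclusion bAP-exclusion window after each AP, ms (default 2).
#' @param comp Compartment id stored on the result.
#' @return An `event_series` of kind `"Na"`.
#' @export
detect_na_spikes <- function(gna, dt, ap_times = numeric(), t0 = dt,
                             threshold = 0.3, exclusion = 2,
                             comp = NA_integer_) {
  up <- .up_crossings(gna, threshold)
  t <- t0 + (up - 1L) * dt
  if (length(ap_times) && length(t)) {
    near <- vapply(t, function(ti) {
      d <- ti - ap_times
      any(d >= -dt / 2 & d <= exclusion)
    }, logical(1))
    t <- t[!near]
  }
  event_series(comp, "Na", t)
}

#' Detect plateau events (NMDA or Ca2+ spikes) by joint voltage and
#' current criteria
#'
#' Candidate excursions are contiguous periods with V above `v_thresh`
#' lasting at least `min_dur`. Within an excursion the reference current is
#' the magnitude of `i_drive` at the upward voltage crossing (t_v); the
#' event begins when the current magnitude reaches `on_frac` times the
#' reference and ends when it falls back to `off_frac` times the reference
#' (or at the end of the excursion). Use the NMDA current for NMDA spikes
#' and the summed HVA + LVA calcium current for Ca2+ spikes.
#'
#' @param v Membrane potential trace, mV.
#' @param i_drive Driving current trace (same time base); its magnitude is
#'   used, so inward (negative) currents may be passed directly.
#' @param dt Sample interval, ms.
#' @param t0 Time of the first sample, ms.
#' @param v_thresh Voltage threshold, mV (default -40).
#' @param min_dur Minimum excursion duration, ms (default 26).
#' @param on_frac Current onset ratio (default 1.30).
#' @param off_frac Current offset ratio (default 1.15).
#' @param kind `"NMDA"` or `"Ca"`.
#' @param comp Compartment id stored on the result.
#' @return An `event_series` with onsets and offsets.
#' @export
detect_plateau <- function(v, i_drive, dt, t0 = dt, v_thresh = -40,
                           min_dur = 26, on_frac = 1.30, off_frac = 1.15,
                           kind = c("NMDA", "Ca"), comp = NA_integer_) {
  kind <- match.arg(kind)
  if (length(v) != length(i_drive)) stop("v and i_drive length mismatch")
  n <- length(v)
  above <- v >= v_thresh
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  onsets <- numeric(0)
  offsets <- numeric(0)
  mag <- abs(i_drive)
  for (k in which(r$values)) {
    i0 <- starts[k]
    i1 <- ends[k]
    if ((i1 - i0 + 1L) * dt < min_dur) next
    ref <- mag[i0]
    if (!is.finite(ref) || ref <= 0) next
    hit <- which(mag[i0:i1] >= on_frac * ref)
    if (!length(hit)) next
    on_i <- i0 + hit[1] - 1L
    fall <- which(mag[on_i:n] <= off_frac * ref)
    off_i <- if (length(fall)) on_i + fall[1] - 1L else min(i1 + 1L, n)
    off_i <- min(off_i, i1 + 1L) # an excursion's event ends with it
    if (off_i <= on_i) off_i <- on_i + 1L
    onsets <- c(onsets, t0 + (on_i - 1L) * dt)
    offsets <- c(offsets, t0 + (off_i - 1L) * dt)
  }
  event_series(comp, kind, onsets, offsets)
}

#' Binary presence series of events at fixed bins
#'
#' A bin (default width 2 ms) is true iff an event interval overlaps it;
#' point events (APs, Na+ spikes) mark the bin containing them.
#'
#' @param events An `event_series`.
#' @param duration Series duration, ms.
#' @param bin Bin width, ms (default 2).
#' @return Logical vector of length `ceiling(duration / bin)`.
#' @export
events_to_binary <- function(events, duration, bin = 2) {
  stopifnot(inherits(events, "event_series"))
  nb <- as.integer(ceiling(duration / bin))
  out <- logical(nb)
  if (!length(events$onsets)) return(out)
  on <- events$onsets
  off <- ifelse(is.na(events$offsets), events$onsets, events$offsets)
  b0 <- pmax(1L, pmin(nb, floor(on / bin) + 1L))
  # interval [on, off) overlaps bins strictly before off
  b1 <- pmax(b0, pmin(nb, ceiling(off / bin)))
  for (k in seq_along(b0)) out[b0[k]:b1[k]] <- TRUE
  out
}

#' Detect all event kinds across a trace set
#'
#' Runs [detect_aps()] on the soma and the dendritic detectors on every
#' recorded dendritic compartment. Ca2+ detection uses the calcium current;
#' NMDA detection the NMDA current.
#'
#' @param ts A `trace_set` with `v`, `gna`, `inmda`, `ica` recorded.
#' @param morph The `morphology` the traces came from.
#' @param exclusion bAP-exclusion window for Na+ spikes, ms.
#' @return List with `ap` (an `event_series`) and `dend`: a list (indexed by
#'   compartment id as character) of lists with `Na`, `NMDA`, `Ca` event
#'   series.
#' @export
detect_all_events <- function(ts, morph, exclusion = 2) {
  stopifnot(inherits(ts, "trace_set"))
  ap <- detect_aps(trace_of(ts, ts$soma, "v"), ts$dt, t0 = ts$t0,
                   comp = ts$soma)
  dend <- list()
  dids <- intersect(dendritic_ids(morph), ts$comps)
  for (id in dids) {
    v <- trace_of(ts, id, "v")
    res <- list(
      Na = detect_na_spikes(trace_of(ts, id, "gna"), ts$dt, ap$onsets,
                            t0 = ts$t0, exclusion = exclusion, comp = id),
      NMDA = detect_plateau(v, trace_of(ts, id, "inmda"), ts$dt, t0 = ts$t0,
                            kind = "NMDA", comp = id),
      Ca = detect_plateau(v, trace_of(ts, id, "ica"), ts$dt, t0 = ts$t0,
                          kind = "Ca", comp = id)
    )
    dend[[as.character(id)]] <- res
  }
  list(ap = ap, dend = dend)
}

#' Write detected events as delimited text
#'
#' Columns: compartment_id, kind, onset_ms, offset_ms.
#'
#' @param events List of `event_series` objects.
#' @param path File path.
#' @export
write_events <- function(events, path) {
  df <- do.call(rbind, lapply(events, function(e) {
    if (!length(e$onsets)) return(NULL)
    data.frame(compartment_id = e$comp, kind = e$kind,
               onset_ms = e$onsets, offset_ms = e$offsets)
  }))
  if (is.null(df)) {
    df <- data.frame(compartment_id = integer(), kind = character(),
                     onset_ms = numeric(), offset_ms = numeric())
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  keys <- unique(df[, c("compartment_id", "kind")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$compartment_id == keys$compartment_id[i] &
                df$kind == keys$kind[i], ]
    event_series(keys$compartment_id[i], keys$kind[i], sub$onset_ms,
                 offsets = sub$offset_ms)
  })
}
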