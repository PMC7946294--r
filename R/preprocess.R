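#' Continuous multichannel recording
#'
#' Light container for a continuous voltage recording: a numeric matrix
#' (samples by electrodes/channels) with its sampling rate.
#'
#' @param data Numeric matrix, samples by electrodes.
#' @param sampling_rate Sampling rate in Hz.
#' @return The matrix with class `lfp_recording` and a `sampling_rate`
#'   attribute.
#' @export
lfp_recording <- function(data, sampling_rate) {
  data <- as.matrix(data)
  if (nrow(data) < 1 || ncol(data) < 1) stop("recording must be non-empty")
  structure(data, sampling_rate = sampling_rate,
            class = c("lfp_recording", "matrix", "array"))
}

sampling_rate <- function(rec, default = NULL) {
  attr(rec, "sampling_rate") %||% default %||%
    stop("recording carries no sampling rate; use lfp_recording()")
}

#' Bipolar re-referencing
#'
#' Subtracts neighbouring electrodes: channel `i` is electrode `i` minus
#' electrode `i + 1`, so an m-electrode recording yields m - 1 channels
#' (16 electrodes give the 15 working channels). Channel 1 remains the most
#' central channel under the probe's electrode ordering.
#'
#' @param rec Numeric matrix (samples by electrodes) or [lfp_recording()].
#' @return Same container type with one fewer column.
#' @export
bipolar_rereference <- function(rec) {
  m <- ncol(rec)
  if (m < 2) stop("bipolar re-referencing needs at least 2 electrodes")
  out <- rec[, -m, drop = FALSE] - rec[, -1, drop = FALSE]
  if (inherits(rec, "lfp_recording")) {
    lfp_recording(out, sampling_rate(rec))
  } else {
    as.matrix(out)
  }
}

#' Split a recording into fixed-length epochs
#'
#' Cuts the recording into non-overlapping consecutive segments of
#' `epoch_seconds`; a trailing partial segment is discarded. An 18 s
#' recording at 1000 Hz with 2.25 s epochs yields 8 epochs of 2250 samples.
#'
#' @param rec [lfp_recording()] (or matrix plus `sampling_rate`).
#' @param epoch_seconds Epoch duration; `epoch_seconds * sampling_rate` must
#'   be a whole number of samples.
#' @param sampling_rate Required when `rec` is a plain matrix.
#' @return A tibble with columns `epoch` and `data` (list of matrices).
#' @export
segment_epochs <- function(rec, epoch_seconds = 2.25, sampling_rate = NULL) {
  sr <- attr(rec, "sampling_rate") %||% sampling_rate
  if (is.null(sr)) stop("supply `sampling_rate` or an lfp_recording")
  len <- epoch_seconds * sr
  if (abs(len - round(len)) > 1e-9) {
    stop("`epoch_seconds` must correspond to a whole number of samples")
  }
  len <- as.integer(round(len))
  n_ep <- nrow(rec) %/% len
  if (n_ep < 1) {
    stop("recording shorter than one epoch (", nrow(rec), " < ", len, " samples)")
  }
  tibble::tibble(
    epoch = seq_len(n_ep),
    data = lapply(seq_len(n_ep), function(e) {
      as.matrix(rec)[((e - 1L) * len + 1L):(e * len), , drop = FALSE]
    })
  )
}

#' Median-split binarization of an epoch
#'
#' Converts each channel to 'on' (1) for samples strictly greater than that
#' channel's within-epoch threshold voltage and 'off' (0) otherwise. The
#' default threshold is the median (quantile 0.5), computed per channel per
#' epoch, giving a balanced split — and hence maximal entropy — on tie-free
#' continuous data; other quantiles support threshold sweeps. Samples
#' exactly at the threshold go to 'off' (the strictly-greater rule). A
#' constant channel binarizes to all zeros and triggers a warning, since its
#' entropy is degenerate.
#'
#' @param epoch Numeric matrix, samples by channels.
#' @param quantile_prob Threshold quantile, default 0.5 (the median).
#' @return Integer 0/1 matrix with attribute `thresholds` (the per-channel
#'   threshold voltages).
#' @examples
#' binarize_median(cbind(1:5))  # median 3 -> 0 0 0 1 1
#' @export
binarize_median <- function(epoch, quantile_prob = 0.5) {
  epoch <- as.matrix(epoch)
  thr <- apply(epoch, 2, stats::quantile, probs = quantile_prob, names = FALSE)
  if (any(apply(epoch, 2, function(x) max(x) == min(x)))) {
    warning("constant channel(s): binarized to all zeros (degenerate entropy)")
  }
  out <- matrix(0L, nrow(epoch), ncol(epoch))
  out[] <- as.integer(sweep(epoch, 2, thr, ">"))
  structure(out, thresholds = thr)
}

#' Binarize every epoch of a study
#'
#' Maps [binarize_median()] over the `lfp` list-column of a generated or
#' loaded study table, adding a `bin` list-column of 0/1 matrices. The
#' threshold is computed per channel per epoch; epochs are never pooled.
#'
#' @param study Tibble with an `lfp` list-column ([generate_pseudo_lfp()]).
#' @param quantile_prob Threshold quantile, default the median.
#' @return The study tibble with a `bin` list-column added.
#' @export
preprocess_study <- function(study, quantile_prob = 0.5) {
  stopifnot("lfp" %in% names(study))
  study$bin <- lapply(study$lfp, binarize_median, quantile_prob = quantile_prob)
  study
}
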