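#' All k-channel subsets of a channel montage
#'
#' @param n_channels Total number of channels.
#' @param k Subset size (the study default is 4: 15 choose 4 = 1365 sets).
#' @return List of integer channel-label vectors in lexicographic order.
#' @examples
#' length(channel_sets(15, 4))  # 1365
#' @export
channel_sets <- function(n_channels, k) {
  if (k < 1 || k > n_channels) stop("`k` must lie in 1..n_channels")
  sets <- combn(n_channels, k)
  lapply(seq_len(ncol(sets)), function(i) sets[, i])
}

#' State-weighted average
#'
#' Averages a per-state quantity over system states, weighting each state by
#' its occurrence count in the epoch. Unobserved states carry zero weight,
#' so skipping them cannot change the average.
#'
#' @param values Numeric vector over the `2^n` states.
#' @param counts Occurrence counts over the same states ([state_counts()]).
#' @return Scalar weighted mean.
#' @examples
#' state_weighted_average(c(0.1, 0.5), c(3, 1))  # 0.2
#' @export
state_weighted_average <- function(values, counts) {
  if (length(values) != length(counts)) {
    stop("`values` and `counts` must cover the same state space")
  }
  tot <- sum(counts)
  if (tot == 0) stop("all-zero state counts: average undefined")
  sum(values * counts) / tot
}

#' Average across epochs
#'
#' @param per_epoch Non-empty numeric vector of per-epoch values.
#' @return Arithmetic mean.
#' @export
epoch_average <- function(per_epoch) {
  if (length(per_epoch) == 0) stop("no epochs to average")
  mean(per_epoch)
}

#' Spatial features of a channel set
#'
#' Two scalar descriptors of where a channel set sits on the linear probe:
#' the average location of its channels relative to channel 1 (the most
#' central channel) and the total path distance, the sum of pairwise
#' absolute differences between channel labels.
#'
#' @param channel_set Sorted distinct integer channel labels.
#' @return A tibble with `location` and `total_path_distance`.
#' @examples
#' spatial_features(c(1, 2, 3, 4))  # location 1.5, distance 10
#' @export
spatial_features <- function(channel_set) {
  if (anyDuplicated(channel_set)) stop("channel labels must be distinct")
  if (is.unsorted(channel_set)) stop("channel labels must be sorted")
  d <- 0
  k <- length(channel_set)
  if (k > 1) {
    for (i in seq_len(k - 1)) {
      d <- d + sum(abs(channel_set[i] - channel_set[(i + 1):k]))
    }
  }
  tibble::tibble(location = mean(channel_set - 1), total_path_distance = d)
}

#' Integrated information analysis of one binarized epoch
#'
#' Estimates the state-by-node TPM of the chosen channels at lag
#' `tau_samples`, runs the system-level engine for every observed state, and
#' returns state-weighted averages: one Phi value and one phi value per
#' mechanism (the epoch's IIS).
#'
#' @param bin Binary matrix (samples by channels).
#' @param channels Channel columns forming the system (ascending).
#' @param tau_samples Lag in samples (default 4, i.e. 4 ms at 1000 Hz).
#' @return A list with `big_phi`, `iis` (named numeric, canonical mechanism
#'   order), `counts`, and `tpm`.
#' @export
epoch_iis <- function(bin, channels, tau_samples = 4L) {
  tpm <- estimate_tpm(bin, nodes = channels, tau_samples = tau_samples)
  counts <- state_counts(tpm)
  res <- system_phi_by_state(tpm)
  big_phi <- state_weighted_average(res$big_phi, counts)
  iis <- apply(res$phi_matrix, 1, state_weighted_average, counts = counts)
  list(big_phi = big_phi, iis = iis, counts = counts, tpm = tpm)
}

#' Run the full integrated-information study
#'
#' For every subject, condition, epoch and k-channel set: estimate the TPM,
#' compute per-state system-level integrated information and the mechanism
#' phi values, average over states weighted by state occurrences, and attach
#' the channel set's spatial features. This is the composition of the whole
#' processing figure over the study grid.
#'
#' @param study Tibble with `subject`, `condition`, `epoch` and a `bin`
#'   list-column of binarized epochs ([preprocess_study()]).
#' @param k Channel-set size, 2 to 5 (default 4).
#' @param tau_samples Lag in samples (default 4).
#' @param sets Optional list of channel sets to restrict to (default: all
#'   k-subsets of the montage).
#' @return A tibble with one row per (subject, condition, epoch, channel
#'   set): `set_id`, `channel_set` (list), `big_phi`, `iis` (list of named
#'   numeric vectors), `location`, `total_path_distance`, `tau_samples`.
#' @export
run_study <- function(study, k = 4, tau_samples = 4L, sets = NULL) {
  stopifnot(all(c("subject", "condition", "epoch", "bin") %in% names(study)))
  if (k < 2 || k > 5) stop("`k` must lie in 2..5")
  nch <- ncol(study$bin[[1]])
  if (is.null(sets)) sets <- channel_sets(nch, k)
  feats <- dplyr::bind_rows(lapply(sets, spatial_features))
  rows <- vector("list", nrow(study))
  for (r in seq_len(nrow(study))) {
    per_set <- lapply(seq_along(sets), function(i) {
      ep <- epoch_iis(study$bin[[r]], sets[[i]], tau_samples = tau_samples)
      tibble::tibble(set_id = i,
                     channel_set = list(sets[[i]]),
                     big_phi = ep$big_phi,
                     iis = list(ep$iis))
    })
    tab <- dplyr::bind_rows(per_set)
    tab$location <- feats$location
    tab$total_path_distance <- feats$total_path_distance
    tab$subject <- study$subject[r]
    tab$condition <- study$condition[r]
    tab$epoch <- study$epoch[r]
    rows[[r]] <- tab
  }
  out <- dplyr::bind_rows(rows)
  out$tau_samples <- as.integer(tau_samples)
  cls <- c("subject", "condition", "epoch", "set_id", "channel_set",
           "big_phi", "iis", "location", "total_path_distance", "tau_samples")
  structure(out[, cls], class = c("iis_study_result", class(out)))
}

#' Condition-level summary of a study result
#'
#' Epoch-averages Phi per subject, condition and channel set — the
#' comparison underlying the wake versus anesthesia contrast.
#'
#' @param results An `iis_study_result` from [run_study()].
#' @return Tibble with one row per (subject, condition, set_id) and column
#'   `big_phi` (epoch-averaged).
#' @export
summarize_phi <- function(results) {
  dplyr::summarise(
    dplyr::group_by(results, .data$subject, .data$condition, .data$set_id),
    big_phi = epoch_average(.data$big_phi),
    .groups = "drop"
  )
}
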