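#' ROI time-series container
#'
#' Wraps a T x N numeric matrix of ROI signals (time points in rows, regions
#' in columns) together with ROI names and an optional subject identifier.
#'
#' @param values numeric matrix, T x N, no missing values, T >= 2, N >= 2.
#' @param roi_names character vector of length N; defaults to column names or
#'   `ROI1..ROIN`.
#' @param subject_id optional subject identifier.
#' @return An object of class `roi_ts`.
#' @export
roi_timeseries <- function(values, roi_names = NULL, subject_id = NA_character_) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("ROI time series must not contain missing values")
  if (nrow(values) < 2L) stop("need at least 2 time points")
  if (ncol(values) < 2L) stop("need at least 2 ROIs")
  if (is.null(roi_names)) {
    roi_names <- colnames(values)
    if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(ncol(values)))
  }
  if (length(roi_names) != ncol(values)) stop("roi_names length must match column count")
  if (anyDuplicated(roi_names)) stop("duplicated ROI names")
  colnames(values) <- roi_names
  structure(list(values = values, roi_names = roi_names, subject_id = subject_id),
            class = "roi_ts")
}

#' @export
print.roi_ts <- function(x, ...) {
  cat(sprintf("ROI time series: %d time points x %d ROIs (subject %s)\n",
              nrow(x$values), ncol(x$values), x$subject_id))
  invisible(x)
}

#' Read / write ROI time series as delimited text
#'
#' Files are CSV with a header row of ROI names, one row per time point.
#'
#' @param path file path.
#' @param subject_id subject identifier attached to the result.
#' @return `read_roi_timeseries` returns an `roi_ts`.
#' @export
read_roi_timeseries <- function(path, subject_id = NA_character_) {
  df <- utils::read.csv(path, check.names = FALSE)
  roi_timeseries(as.matrix(df), roi_names = colnames(df), subject_id = subject_id)
}

#' @rdname read_roi_timeseries
#' @param ts an `roi_ts` object.
#' @export
write_roi_timeseries <- function(ts, path) {
  utils::write.csv(as.data.frame(ts$values), path, row.names = FALSE)
  invisible(path)
}

#' Extract mean ROI time series from a 4D image and an integer label volume
#'
#' Column r of the output is, at each time point, the mean signal over all
#' voxels whose label equals the r-th smallest nonzero label. Label 0 is
#' background. Inputs can be in-memory arrays or NIfTI file paths.
#'
#' @param image4d 4D numeric array (x, y, z, t) or a NIfTI file path.
#' @param labels 3D integer array on the same spatial grid, or a NIfTI path.
#' @param subject_id optional subject identifier.
#' @return An `roi_ts` with one column per nonzero label, ascending label order.
#' @export
extract_roi_timeseries <- function(image4d, labels, subject_id = NA_character_) {
  if (is.character(image4d)) image4d <- as.array(RNifti::readNifti(image4d))
  if (is.character(labels)) labels <- as.array(RNifti::readNifti(labels))
  image4d <- as.array(image4d)
  labels <- as.array(labels)
  d <- dim(image4d)
  if (length(d) != 4L) stop("image4d must be a 4D array")
  if (!identical(dim(labels), d[1:3])) stop("label volume grid does not match the image grid")
  labs <- sort(unique(as.integer(labels[labels != 0])))
  if (length(labs) == 0L) stop("label volume contains no nonzero labels")
  vox <- matrix(image4d, nrow = prod(d[1:3]), ncol = d[4])
  lab_vec <- as.integer(labels)
  ts <- vapply(labs, function(l) {
    idx <- which(lab_vec == l)
    if (length(idx) == 1L) vox[idx, ] else colMeans(vox[idx, , drop = FALSE])
  }, numeric(d[4]))
  roi_timeseries(ts, roi_names = paste0("ROI", labs), subject_id = subject_id)
}

#' Restrict and reorder an ROI time series to a set of named ROIs
#'
#' @param ts an `roi_ts`.
#' @param roi_names ROIs to keep, in the requested order; duplicates and
#'   unknown names are errors.
#' @return An `roi_ts` with columns restricted and reordered.
#' @export
select_rois <- function(ts, roi_names) {
  stopifnot(inherits(ts, "roi_ts"))
  if (anyDuplicated(roi_names)) stop("duplicated ROI name in selection")
  miss <- setdiff(roi_names, ts$roi_names)
  if (length(miss)) stop("unknown ROI name(s): ", paste(miss, collapse = ", "))
  roi_timeseries(ts$values[, roi_names, drop = FALSE], roi_names = roi_names,
                 subject_id = ts$subject_id)
}

#' Zero-phase Butterworth band-pass filter per ROI
#'
#' Applies a forward-backward (zero-phase) Butterworth filter column-wise.
#' With `low_hz = 0` a pure low-pass is applied.
#'
#' @param ts an `roi_ts`.
#' @param low_hz,high_hz band edges in Hz; `0 <= low_hz < high_hz < Nyquist`.
#' @param tr_seconds sampling interval (repetition time) in seconds.
#' @param order filter order (default 4).
#' @return A filtered `roi_ts`.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.1, tr_seconds, order = 4L) {
  stopifnot(inherits(ts, "roi_ts"))
  nyq <- 1 / (2 * tr_seconds)
  if (low_hz < 0 || low_hz >= high_hz || high_hz >= nyq)
    stop(sprintf("band [%g, %g] Hz must satisfy 0 <= low < high < Nyquist (%g Hz)",
                 low_hz, high_hz, nyq))
  flt <- if (low_hz > 0) {
    signal::butter(order, c(low_hz, high_hz) / nyq, type = "pass")
  } else {
    signal::butter(order, high_hz / nyq, type = "low")
  }
  # demean first so the DC offset is removed exactly rather than through the
  # filter's slow low-frequency transient
  vals <- sweep(ts$values, 2L, colMeans(ts$values))
  out <- apply(vals, 2L, function(col) signal::filtfilt(flt, col))
  roi_timeseries(out, roi_names = ts$roi_names, subject_id = ts$subject_id)
}

#' Binarize ROI signals into active / inactive spin patterns
#'
#' Each ROI is thresholded at its own time-series mean (default) or median:
#' spin +1 (active) where the signal exceeds the threshold, -1 otherwise.
#'
#' @param ts an `roi_ts`; every column must have nonzero variance.
#' @param rule `"mean"` or `"median"` threshold.
#' @return A `binary_patterns` object: `spins` (T x N matrix of -1/+1),
#'   `state_index` (length-T integers in `[0, 2^N - 1]`), `roi_names`.
#' @export
binarize <- function(ts, rule = c("mean", "median")) {
  stopifnot(inherits(ts, "roi_ts"))
  rule <- match.arg(rule)
  v <- apply(ts$values, 2L, stats::var)
  if (any(v == 0))
    stop("zero-variance ROI(s): ", paste(ts$roi_names[v == 0], collapse = ", "))
  thr <- switch(rule,
                mean = colMeans(ts$values),
                median = apply(ts$values, 2L, stats::median))
  spins <- ifelse(sweep(ts$values, 2L, thr, `-`) > 0, 1L, -1L)
  binary_patterns(spins, roi_names = ts$roi_names)
}

#' Binary pattern series container
#'
#' @param spins T x N matrix with entries in \{-1, +1\}.
#' @param roi_names optional ROI names.
#' @return A `binary_patterns` object with the encoded `state_index`
#'   (ROI 1 = least significant bit, active = binary 1).
#' @export
binary_patterns <- function(spins, roi_names = NULL) {
  spins <- as.matrix(spins)
  if (!all(spins %in% c(-1L, 1L))) stop("spins must be -1 or +1")
  storage.mode(spins) <- "integer"
  dimnames(spins) <- NULL
  n <- ncol(spins)
  if (n > 20L) stop("at most 20 ROIs supported for state encoding")
  if (is.null(roi_names)) roi_names <- paste0("ROI", seq_len(n))
  structure(list(spins = spins,
                 state_index = encode_states(spins),
                 roi_names = roi_names),
            class = "binary_patterns")
}

#' Encode spin patterns as state indices
#'
#' ROI 1 maps to the least significant bit; spin +1 encodes binary 1.
#'
#' @param spins T x N matrix of -1/+1 spins.
#' @return Integer vector of state indices in `[0, 2^N - 1]`.
#' @export
encode_states <- function(spins) {
  spins <- as.matrix(spins)
  bits <- (spins + 1L) / 2L
  as.integer(bits %*% 2^(seq_len(ncol(spins)) - 1L))
}

#' Decode a state index into its activation map
#'
#' @param k state index in `[0, 2^N - 1]`.
#' @param n_rois number of ROIs N.
#' @return Logical vector of length N; element i is `TRUE` when ROI i is active.
#' @export
state_to_activation_map <- function(k, n_rois) {
  if (k < 0 || k > 2^n_rois - 1) stop("state index out of range")
  bitwAnd(as.integer(k), as.integer(2^(seq_len(n_rois) - 1L))) > 0L
}

#' Label a state by its active ROI positions
#'
#' State 6 over 8 ROIs (ROIs 2 and 3 active) gets label `"23"`; the all-inactive
#' state gets `"-"`. Positions are concatenated, so labels are only unambiguous
#' for N <= 9.
#'
#' @inheritParams state_to_activation_map
#' @return Character label.
#' @export
state_label <- function(k, n_rois) {
  act <- which(state_to_activation_map(k, n_rois))
  if (length(act) == 0L) "-" else paste(act, collapse = "")
}

#' Full spin matrix over all states
#'
#' Row k + 1 holds the -1/+1 spin vector of state index k under the package's
#' bit convention.
#'
#' @param n_rois number of ROIs N (<= 20).
#' @return `2^N x N` matrix.
#' @export
state_spins <- function(n_rois) {
  if (n_rois > 20L) stop("state enumeration limited to N <= 20")
  k <- 0:(2^n_rois - 1)
  m <- vapply(seq_len(n_rois),
              function(i) ifelse(bitwAnd(k, 2^(i - 1)) > 0L, 1, -1),
              numeric(length(k)))
  matrix(m, nrow = length(k), ncol = n_rois)
}

#' State probability distribution container
#'
#' @param probs nonnegative vector of length `2^N` summing to 1 (within 1e-12).
#' @param n_observations number of observations behind an empirical
#'   distribution; 0 for model distributions.
#' @return A `state_distribution` object.
#' @export
state_distribution <- function(probs, n_observations = 0L) {
  if (any(probs < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(probs) - 1) > 1e-12) stop("probabilities must sum to 1")
  n <- log2(length(probs))
  if (n != round(n)) stop("length must be a power of 2")
  structure(list(probs = as.numeric(probs),
                 n_observations = as.integer(n_observations),
                 n_rois = as.integer(round(n))),
            class = "state_distribution")
}

#' Empirical state distribution of a binary pattern series
#'
#' `probs[k + 1]` is the fraction of time points spent in state k.
#'
#' @param bps a `binary_patterns` object.
#' @return A `state_distribution` with `n_observations = T`.
#' @export
empirical_distribution <- function(bps) {
  stopifnot(inherits(bps, "binary_patterns"))
  n <- ncol(bps$spins)
  counts <- tabulate(bps$state_index + 1L, nbins = 2^n)
  state_distribution(counts / length(bps$state_index),
                     n_observations = length(bps$state_index))
}
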