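#' Design complementary ring filters over the rFFT grid
#'
#' Builds a bank of nonnegative, zero-phase frequency responses that
#' partition the spectrum: response `j` passes the band between consecutive
#' edges, with raised-cosine crossfades of width `rolloff` centered at each
#' edge. By construction the responses sum to exactly 1 at every frequency
#' bin, so the filtered components of any signal add back to the original
#' (perfect reconstruction).
#'
#' @param fs Sampling rate in Hz.
#' @param signal_length Number of samples `T`; the responses live on the
#'   rFFT grid of length `floor(T/2) + 1`.
#' @param band_edges Increasing vector of edge frequencies in `(0, fs/2)`;
#'   `length(band_edges) + 1` responses are produced. The default single
#'   edge at `fs/8` with rolloff `fs/50` yields the two-filter low/high bank
#'   used by a three-member partitioned ensemble.
#' @param rolloff Transition width in Hz (>= 0); `0` gives ideal brick-wall
#'   indicators. With `rolloff > 0`, both filters equal 0.5 exactly at each
#'   edge frequency.
#' @return An object of class `filter_bank`: responses (list of numeric
#'   vectors in `[0, 1]`), `fs`, `band_edges`, `rolloff`, `signal_length`.
#' @export
design_ring_filters <- function(fs, signal_length, band_edges = fs / 8,
                                rolloff = fs / 50) {
  check_domain(all(band_edges > 0) && all(band_edges < fs / 2),
               "`band_edges` must lie strictly inside (0, fs/2)")
  check_domain(!is.unsorted(band_edges, strictly = TRUE),
               "`band_edges` must be strictly increasing")
  check_domain(rolloff >= 0, "`rolloff` must be >= 0")
  l <- floor(signal_length / 2) + 1L
  freqs <- (seq_len(l) - 1) * fs / signal_length

  # Raised-cosine low-side step: 1 below the edge, 0 above, 0.5 at the edge.
  low_step <- function(f, edge, w) {
    if (w == 0) return(as.numeric(f <= edge))
    out <- numeric(length(f))
    out[f <= edge - w / 2] <- 1
    ramp <- f > edge - w / 2 & f < edge + w / 2
    out[ramp] <- 0.5 * (1 + cos(pi * (f[ramp] - (edge - w / 2)) / w))
    out
  }

  n_bands <- length(band_edges) + 1L
  responses <- vector("list", n_bands)
  upper <- lapply(band_edges, function(e) low_step(freqs, e, rolloff))
  for (j in seq_len(n_bands)) {
    hi <- if (j <= length(band_edges)) upper[[j]] else rep(1, l)
    lo <- if (j >= 2L) upper[[j - 1L]] else rep(0, l)
    responses[[j]] <- hi - lo
  }
  structure(list(responses = responses, fs = fs, band_edges = band_edges,
                 rolloff = rolloff, signal_length = as.integer(signal_length)),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat(sprintf("<filter_bank> %d band(s), edges %s Hz, rolloff %g Hz, T=%d @ %g Hz\n",
              length(x$responses), paste(x$band_edges, collapse = "/"),
              x$rolloff, x$signal_length, x$fs))
  invisible(x)
}

#' Serialize / restore a filter bank as JSON
#'
#' Only the design parameters are stored; responses are regenerated on read,
#' never stored raw.
#'
#' @param bank A `filter_bank`.
#' @param path JSON file path.
#' @return `write_filter_bank` returns `path` invisibly; `read_filter_bank`
#'   returns the regenerated `filter_bank`.
#' @export
write_filter_bank <- function(bank, path) {
  jsonlite::write_json(list(fs = bank$fs, band_edges = bank$band_edges,
                            rolloff = bank$rolloff,
                            signal_length = bank$signal_length),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_bank
#' @export
read_filter_bank <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  design_ring_filters(x$fs, x$signal_length, x$band_edges, x$rolloff)
}

# Mirror an rFFT-grid response onto the full FFT grid (Hermitian symmetry).
full_response <- function(response, t_len) {
  l <- floor(t_len / 2) + 1L
  check_that(length(response) == l,
             "response length must match the rFFT grid of T")
  full <- numeric(t_len)
  full[seq_len(l)] <- response
  if (t_len > l) full[t_len:(l + 1L)] <- response[2:(t_len - l + 1L)]
  full
}

#' Apply a zero-phase frequency response to signals
#'
#' Filtering is point-wise multiplication in the Fourier domain: each
#' channel is transformed, multiplied by the (real, nonnegative) response,
#' and inverse transformed. The operation is linear and, because the
#' response is real and even, self-adjoint — a property the attack gradients
#' rely on.
#'
#' @param x A `channels x T` matrix or an `N x channels x T` array.
#' @param response Nonnegative response vector over the rFFT grid
#'   (`floor(T/2) + 1` values).
#' @return Filtered signals with the same shape as `x`.
#' @export
apply_filter <- function(x, response) {
  mat_in <- is.matrix(x)
  if (mat_in) {
    d <- c(1L, dim(x))
    x <- array(x, c(1L, dim(x)))
  }
  d <- dim(x)
  t_len <- d[3L]
  full <- full_response(response, t_len)
  m <- x
  dim(m) <- c(d[1L] * d[2L], t_len)
  spec <- mvfft(t(m))
  filt <- Re(mvfft(spec * full, inverse = TRUE)) / t_len
  out <- t(filt)
  dim(out) <- d
  if (mat_in) out <- out[1L, , , drop = TRUE]
  if (is.null(dim(out))) out <- matrix(out, d[2L], t_len)
  out
}

# A serializable per-member input transform wrapping one bank response.
band_transform <- function(response, fs = NULL, label = NULL) {
  structure(list(response = response, fs = fs, label = label),
            class = "band_transform")
}

apply_transform <- function(transform, x) {
  if (is.null(transform)) return(x)
  apply_filter(x, transform$response)
}

#' Wire a filter bank into an ensemble as per-member input transforms
#'
#' Member 0 (the first member) receives the raw input; member `j >= 1`
#' receives the input filtered by response `j` of the bank. The transforms
#' apply identically during training, inference, and inside attack
#' gradients (attacks differentiate through the filter).
#'
#' @param members List of `K >= 2` classifiers in training order.
#' @param bank A `filter_bank` with exactly `K - 1` responses.
#' @return An `ecg_ensemble` with the partition transforms installed.
#' @export
partition_ensemble <- function(members, bank) {
  k <- length(members)
  check_that(k >= 2, "a partitioned ensemble needs at least two members")
  check_that(length(bank$responses) == k - 1L,
             sprintf("bank has %d response(s); need K - 1 = %d",
                     length(bank$responses), k - 1L))
  transforms <- c(list(NULL),
                  lapply(seq_len(k - 1L), function(j)
                    band_transform(bank$responses[[j]], fs = bank$fs,
                                   label = sprintf("band%d", j))))
  new_ensemble(members, input_transforms = transforms)
}
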