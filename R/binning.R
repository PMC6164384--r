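# Fixed-width chemical-shift binning of 1D NMR peak lists.
#
# A "bin_scheme" partitions a nucleus' shift axis into contiguous half-open
# intervals [lo, hi) of constant width.  1H and 13C schemes are concatenated
# into one joint descriptor index: 1H bins come first, then 13C bins.

.NUCLEI <- c("1H", "13C")

# Default bin origins, reverse-engineered from published bin edges
# (H bin 14 = [1.3019, 1.4019) at 0.1 ppm; C bin 271 of a 120-bin 1H block
# = [74.9927, 75.4927) at 0.5 ppm).  Use origin = 0 for plain axis-aligned
# bins.
.DEFAULT_ORIGIN <- c("1H" = 0.0019, "13C" = -0.0073)
.DEFAULT_SPAN <- list("1H" = c(0, 12), "13C" = c(0, 200))

#' Create a fixed-width NMR binning scheme
#'
#' Defines a partition of a chemical-shift axis into contiguous, half-open
#' bins `[lo, hi)` of constant `width`.  Bin `k` covers
#' `[origin + (k-1)*width, origin + k*width)`.
#'
#' @param nucleus `"1H"` or `"13C"`.
#' @param width Bin width in ppm; must be positive.
#' @param origin Lower edge of bin 1, in ppm.  Defaults to 0.0019 ppm for
#'   1H and -0.0073 ppm for 13C (the published bin-edge offsets); pass 0
#'   for axis-aligned bins.
#' @param span Numeric length-2 nominal shift range in ppm; defaults to
#'   0--12 ppm (1H) or 0--200 ppm (13C).
#' @param n_bins Number of bins.  Defaults to `floor(diff(span) / width)`;
#'   an explicit value overrides that arithmetic (some published counts,
#'   e.g. 61 bins of 0.2 ppm over 0--12 ppm, include one extra bin).
#' @return An object of class `bin_scheme`.
#' @examples
#' make_scheme("13C", 0.5)        # 400 bins over 0-200 ppm
#' make_scheme("1H", 0.1)$n_bins  # 120
#' @export
make_scheme <- function(nucleus = c("1H", "13C"), width, origin = NULL,
                        span = NULL, n_bins = NULL) {
  nucleus <- match.arg(nucleus)
  stopifnot(is.numeric(width), length(width) == 1L, is.finite(width))
  if (width <= 0) stop("bin width must be positive", call. = FALSE)
  if (is.null(origin)) origin <- .DEFAULT_ORIGIN[[nucleus]]
  if (is.null(span)) span <- .DEFAULT_SPAN[[nucleus]]
  stopifnot(is.numeric(span), length(span) == 2L, all(is.finite(span)))
  span <- sort(span)
  if (diff(span) < width) {
    stop("span (", span[1], ", ", span[2], ") is shorter than one bin",
         call. = FALSE)
  }
  if (is.null(n_bins)) n_bins <- floor(diff(span) / width + 1e-9)
  n_bins <- as.integer(n_bins)
  if (n_bins < 1L) stop("scheme must have at least one bin", call. = FALSE)
  structure(
    list(nucleus = nucleus, width = width, origin = origin,
         span_lo = span[1], span_hi = span[2], n_bins = n_bins),
    class = "bin_scheme")
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme> %s, %g ppm bins, origin %g ppm, %d bins over [%g, %g] ppm\n",
              x$nucleus, x$width, x$origin, x$n_bins, x$span_lo, x$span_hi))
  invisible(x)
}

#' Locate the bin of a chemical shift
#'
#' Maps shifts (ppm) to 1-based bin numbers of a scheme.  Bins are half-open
#' `[lo, hi)`, so a shift exactly on an edge belongs to the upper bin.
#' Shifts outside `[origin, origin + n_bins*width)` return `NA`.
#'
#' @param scheme A [make_scheme()] object.
#' @param shift Numeric vector of chemical shifts in ppm (finite).
#' @return Integer vector of bin numbers (`NA` where out of range).
#' @examples
#' sh <- make_scheme("1H", 0.1)
#' bin_index(sh, 1.35)  # 14
#' @export
bin_index <- function(scheme, shift) {
  stopifnot(inherits(scheme, "bin_scheme"), is.numeric(shift))
  if (any(!is.finite(shift))) stop("shifts must be finite", call. = FALSE)
  # relative epsilon so a shift written as the printed upper edge lands in
  # the upper bin despite floating-point representation error
  k <- as.integer(floor((shift - scheme$origin) / scheme$width + 1e-9)) + 1L
  k[k < 1L | k > scheme$n_bins] <- NA_integer_
  k
}

#' Chemical-shift bounds of a joint descriptor index
#'
#' The joint index concatenates the 1H block (indices `1..n_H`) and the
#' 13C block (`n_H+1 .. n_H+n_C`).
#'
#' @param scheme_h,scheme_c The 1H and 13C [make_scheme()] objects.
#' @param joint_index 1-based joint descriptor index.
#' @return A list with `nucleus`, `lo` and `hi` (ppm).
#' @examples
#' b <- joint_bounds(make_scheme("1H", 0.1), make_scheme("13C", 0.5), 271)
#' b$lo  # 74.9927
#' @export
joint_bounds <- function(scheme_h, scheme_c, joint_index) {
  stopifnot(inherits(scheme_h, "bin_scheme"), inherits(scheme_c, "bin_scheme"),
            scheme_h$nucleus == "1H", scheme_c$nucleus == "13C")
  j <- as.integer(joint_index)
  n_total <- scheme_h$n_bins + scheme_c$n_bins
  if (length(j) != 1L || is.na(j) || j < 1L || j > n_total) {
    stop("joint index must lie in 1..", n_total, call. = FALSE)
  }
  if (j <= scheme_h$n_bins) {
    s <- scheme_h; k <- j
  } else {
    s <- scheme_c; k <- j - scheme_h$n_bins
  }
  list(nucleus = s$nucleus,
       lo = s$origin + (k - 1L) * s$width,
       hi = s$origin + k * s$width)
}

#' Joint descriptor names for a pair of schemes
#'
#' Names follow the pattern `H_0014[1.3019,1.4019)` /
#' `C_0151[74.9927,75.4927)`, with the per-nucleus bin number and its ppm
#' interval.
#'
#' @inheritParams joint_bounds
#' @return Character vector of length `n_H + n_C`.
#' @export
descriptor_names <- function(scheme_h, scheme_c) {
  nm <- function(s, tag) {
    k <- seq_len(s$n_bins)
    sprintf("%s_%04d[%.4f,%.4f)", tag, k,
            s$origin + (k - 1) * s$width, s$origin + k * s$width)
  }
  c(nm(scheme_h, "H"), nm(scheme_c, "C"))
}

#' Construct a peak list
#'
#' @param sample_id Sample identifier.
#' @param nucleus Character vector, `"1H"` or `"13C"`, one per peak.
#' @param shift Chemical shifts in ppm (finite).
#' @param intensity Non-negative peak intensities (arbitrary units);
#'   defaults to 1.
#' @return A `peak_list` object.
#' @export
peak_list <- function(sample_id, nucleus = character(), shift = numeric(),
                      intensity = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  if (is.null(intensity)) intensity <- rep(1, length(shift))
  stopifnot(length(nucleus) == length(shift),
            length(intensity) == length(shift))
  bad <- setdiff(unique(nucleus), .NUCLEI)
  if (length(bad)) {
    stop("unknown nucleus label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(shift))) stop("peak shifts must be finite", call. = FALSE)
  if (any(intensity < 0)) stop("intensities must be >= 0", call. = FALSE)
  structure(
    list(sample_id = sample_id,
         peaks = data.frame(nucleus = as.character(nucleus),
                            shift = as.numeric(shift),
                            intensity = as.numeric(intensity))),
    class = "peak_list")
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %s: %d peaks (%d 1H, %d 13C)\n", x$sample_id,
              nrow(x$peaks), sum(x$peaks$nucleus == "1H"),
              sum(x$peaks$nucleus == "13C")))
  invisible(x)
}

# drop peaks falling in excluded shift windows (e.g. residual solvent)
.apply_mask <- function(peaks, mask) {
  if (is.null(mask) || !nrow(peaks)) return(peaks)
  keep <- rep(TRUE, nrow(peaks))
  for (w in mask) {
    keep <- keep & !(peaks$nucleus == w$nucleus &
                       peaks$shift >= w$lo & peaks$shift < w$hi)
  }
  peaks[keep, , drop = FALSE]
}

#' Convert one peak list to a joint descriptor vector
#'
#' Each peak is assigned to a bin of its nucleus' scheme; the joint vector
#' holds the 1H block followed by the 13C block.  Peaks outside the scheme
#' range are dropped with a warning.
#'
#' @param peaklist A [peak_list()].
#' @param scheme_h,scheme_c 1H and 13C [make_scheme()] objects.
#' @param mode `"binary"` (1 if any peak falls in the bin — the default,
#'   robust to the unreliable absolute intensities of crude-extract
#'   spectra), `"count"` (number of peaks) or `"intensity"` (summed
#'   intensity).
#' @param mask Optional list of exclusion windows, each a list with
#'   `nucleus`, `lo`, `hi` (e.g. [solvent_mask()]); peaks inside a window
#'   are discarded before binning.
#' @return Named numeric vector of length `n_H + n_C`.
#' @examples
#' pl <- peak_list("s1", c("1H", "13C"), c(1.35, 75.2))
#' v <- vectorize_peaks(pl, make_scheme("1H", 0.1), make_scheme("13C", 0.5))
#' which(v == 1)  # joint indices 14 and 271
#' @export
vectorize_peaks <- function(peaklist, scheme_h, scheme_c,
                            mode = c("binary", "count", "intensity"),
                            mask = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(peaklist, "peak_list"),
            inherits(scheme_h, "bin_scheme"), scheme_h$nucleus == "1H",
            inherits(scheme_c, "bin_scheme"), scheme_c$nucleus == "13C")
  n_h <- scheme_h$n_bins
  out <- numeric(n_h + scheme_c$n_bins)
  names(out) <- descriptor_names(scheme_h, scheme_c)
  peaks <- .apply_mask(peaklist$peaks, mask)
  if (!nrow(peaks)) return(out)

  joint <- integer(nrow(peaks))
  is_h <- peaks$nucleus == "1H"
  joint[is_h] <- bin_index(scheme_h, peaks$shift[is_h])
  kc <- bin_index(scheme_c, peaks$shift[!is_h])
  joint[!is_h] <- kc + n_h  # NA propagates
  oor <- is.na(joint)
  if (any(oor)) {
    warning(sprintf("%s: dropped %d peak(s) outside the scheme range",
                    peaklist$sample_id, sum(oor)), call. = FALSE)
    joint <- joint[!oor]
    peaks <- peaks[!oor, , drop = FALSE]
  }
  if (!length(joint)) return(out)
  agg <- switch(mode,
    binary = tapply(rep(1, length(joint)), joint, function(z) 1),
    count = tapply(rep(1, length(joint)), joint, sum),
    intensity = tapply(peaks$intensity, joint, sum))
  out[as.integer(names(agg))] <- as.numeric(agg)
  out
}

#' Standard residual-solvent exclusion windows
#'
#' Exclusion windows (default +/- 0.05 ppm for 1H, +/- 0.5 ppm for 13C)
#' around residual CDCl3 signals (7.26 ppm 1H, 77.0 ppm 13C).  Off by
#' default in all binning functions; pass the result as `mask` to enable.
#'
#' @param h_center,c_center Window centers in ppm.
#' @param h_halfwidth,c_halfwidth Window half-widths in ppm.
#' @return A list of exclusion windows for [vectorize_peaks()].
#' @export
solvent_mask <- function(h_center = 7.26, c_center = 77.0,
                         h_halfwidth = 0.05, c_halfwidth = 0.5) {
  list(list(nucleus = "1H", lo = h_center - h_halfwidth,
            hi = h_center + h_halfwidth),
       list(nucleus = "13C", lo = c_center - c_halfwidth,
            hi = c_center + c_halfwidth))
}

#' Assemble a sample-by-descriptor matrix from peak lists
#'
#' @param peaklists List of [peak_list()] objects with unique sample ids.
#' @inheritParams vectorize_peaks
#' @return A `descriptor_matrix`: list with `values` (numeric matrix, rows
#'   = samples in input order, columns = joint descriptors), `mode`,
#'   `scheme_h`, `scheme_c`.
#' @examples
#' pls <- list(peak_list("a", "1H", 1.35), peak_list("b", "13C", 75.2))
#' dm <- build_matrix(pls, make_scheme("1H", 0.1), make_scheme("13C", 0.5))
#' ncol(dm$values)  # 520
#' @export
build_matrix <- function(peaklists, scheme_h, scheme_c,
                         mode = c("binary", "count", "intensity"),
                         mask = NULL) {
  mode <- match.arg(mode)
  ids <- unname(vapply(peaklists, function(p) p$sample_id, character(1)))
  if (anyDuplicated(ids)) {
    stop("duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  nms <- descriptor_names(scheme_h, scheme_c)
  values <- matrix(0, nrow = length(peaklists), ncol = length(nms),
                   dimnames = list(ids, nms))
  for (i in seq_along(peaklists)) {
    values[i, ] <- vectorize_peaks(peaklists[[i]], scheme_h, scheme_c,
                                   mode = mode, mask = mask)
  }
  structure(list(values = values, mode = mode,
                 scheme_h = scheme_h, scheme_c = scheme_c),
            class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d samples x %d descriptors (%s mode; %g ppm 1H + %g ppm 13C)\n",
              nrow(x$values), ncol(x$values), x$mode,
              x$scheme_h$width, x$scheme_c$width))
  invisible(x)
}
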