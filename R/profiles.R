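#' Construct a fluorescence line-scan profile
#'
#' A line scan is the intensity profile sampled along a microtubule at a
#' uniform pixel spacing (default 133.35 nm, so that 2 pixels equal the
#' 266.7 nm length-bin width). The mCherry channel carries the
#' spindle-pole-body (minus-end) marker; the GFP channel carries the motor.
#'
#' @param position_nm strictly increasing, uniformly spaced positions (nm).
#' @param gfp_au GFP intensity per pixel (a.u.).
#' @param mcherry_au mCherry intensity per pixel (a.u.).
#' @param cell_id identifier for the source cell.
#' @return A `line_scan_profile` (a data frame with metadata attributes).
#' @export
line_scan_profile <- function(position_nm, gfp_au,
                              mcherry_au = rep(NA_real_, length(gfp_au)),
                              cell_id = NA_character_) {
  n <- length(position_nm)
  if (n < 2) stop("a line scan needs at least 2 pixels")
  if (length(gfp_au) != n || length(mcherry_au) != n)
    stop("channel lengths must match position_nm")
  d <- diff(position_nm)
  if (any(d <= 0)) stop("positions must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * max(d))
    stop("positions must be uniformly spaced")
  if (any(!is.finite(gfp_au))) stop("gfp_au must be finite")
  x <- data.frame(position_nm = as.numeric(position_nm),
                  gfp_au = as.numeric(gfp_au),
                  mcherry_au = as.numeric(mcherry_au))
  structure(x, class = c("line_scan_profile", "data.frame"),
            cell_id = cell_id, pixel_nm = mean(d), aligned = FALSE,
            profile_length_nm = NA_real_)
}

#' Align a line scan to the spindle pole body
#'
#' Shifts the position axis so that the mCherry (SPB marker) intensity peak
#' sits at 0. The GFP intensity peak then marks the plus-end, and the
#' profile length is defined as the peak-to-peak distance. Ties in the
#' mCherry maximum are broken toward the scan start; a flat mCherry channel
#' is an alignment error. Aligning twice equals aligning once.
#'
#' @param profile a [line_scan_profile()].
#' @return The profile with shifted positions; attributes `aligned`,
#'   `profile_length_nm` and `gfp_peak_nm` are set.
#' @export
align_to_reference_peak <- function(profile) {
  stopifnot(inherits(profile, "line_scan_profile"))
  mch <- profile$mcherry_au
  if (all(is.na(mch))) stop("alignment error: mCherry channel missing")
  if (diff(range(mch, na.rm = TRUE)) == 0)
    stop("alignment error: flat mCherry channel")
  peak <- which.max(mch) # which.max takes the first maximum (scan start)
  at <- attributes(profile)
  profile$position_nm <- profile$position_nm - profile$position_nm[peak]
  gfp_peak <- profile$position_nm[which.max(profile$gfp_au)]
  attr(profile, "aligned") <- TRUE
  attr(profile, "profile_length_nm") <- gfp_peak
  attr(profile, "gfp_peak_nm") <- gfp_peak
  attr(profile, "cell_id") <- at$cell_id
  profile
}

#' Bin aligned line scans by microtubule length
#'
#' Groups aligned profiles into length bins of width 266.7 nm (2 pixels) by
#' their peak-to-peak profile length, and computes the per-bin, per-position
#' mean GFP intensity with its 95% confidence interval. Bin edges are fixed
#' multiples of the bin width, so the bins match the canonical
#' 0.80-1.06 um, 1.06-1.33 um, ... series. Empty bins are omitted; each
#' profile falls in exactly one bin.
#'
#' @param profiles list of aligned [line_scan_profile()]s.
#' @param bin_width_nm bin width in nm (> 0), default 266.7.
#' @return A `profile_dataset`: a list with one entry per occupied bin,
#'   each holding the bin `edges_nm`, `centre_nm`, `n_profiles`, member
#'   `lengths_nm`, and a data frame `summary` with columns `position_nm`,
#'   `mean_gfp`, `sd`, `sem`, `ci95` (half-width), `n`.
#' @export
bin_by_length <- function(profiles, bin_width_nm = 266.7) {
  if (!is.finite(bin_width_nm) || bin_width_nm <= 0)
    stop("bin_width_nm must be > 0")
  if (!length(profiles)) stop("no profiles to bin")
  ok <- vapply(profiles, function(p) isTRUE(attr(p, "aligned")), logical(1))
  if (!all(ok)) stop("all profiles must be aligned first")
  px <- attr(profiles[[1]], "pixel_nm")
  lengths_nm <- vapply(profiles, attr, numeric(1),
                       which = "profile_length_nm")
  idx <- floor(lengths_nm / bin_width_nm)
  bins <- list()
  for (j in sort(unique(idx))) {
    members <- profiles[idx == j]
    mlen <- lengths_nm[idx == j]
    # group on the integer pixel index so member grids align exactly
    keys <- lapply(members, function(p) as.integer(round(p$position_nm / px)))
    all_keys <- sort(unique(unlist(keys)))
    mat <- matrix(NA_real_, nrow = length(members), ncol = length(all_keys))
    for (m in seq_along(members))
      mat[m, match(keys[[m]], all_keys)] <- members[[m]]$gfp_au
    n <- colSums(!is.na(mat))
    mu <- colMeans(mat, na.rm = TRUE)
    s <- apply(mat, 2, sd, na.rm = TRUE)
    s[n < 2] <- NA_real_
    sem <- s / sqrt(n)
    bins[[length(bins) + 1]] <- list(
      edges_nm = c(j, j + 1) * bin_width_nm,
      centre_nm = (j + 0.5) * bin_width_nm,
      n_profiles = length(members),
      lengths_nm = mlen,
      cell_ids = vapply(members, function(p)
        as.character(attr(p, "cell_id") %||% NA_character_), character(1)),
      summary = data.frame(position_nm = all_keys * px, mean_gfp = mu,
                           sd = s, sem = sem, ci95 = qnorm(0.975) * sem,
                           n = n))
  }
  structure(list(bins = bins, bin_width_nm = bin_width_nm, pixel_nm = px,
                 n_profiles = length(profiles)),
            class = "profile_dataset")
}

#' @export
print.profile_dataset <- function(x, ...) {
  cat(sprintf("Length-binned profile dataset: %d profiles in %d bins (width %.1f nm)\n",
              x$n_profiles, length(x$bins), x$bin_width_nm))
  for (b in x$bins)
    cat(sprintf("  %.2f-%.2f um: n = %d\n", b$edges_nm[1] / 1000,
                b$edges_nm[2] / 1000, b$n_profiles))
  invisible(x)
}

#' Map a model occupancy profile to a fluorescence line scan
#'
#' Converts per-site expected motor occupancy into pixel intensities:
#' site-level motor mass is optionally blurred with a Gaussian point-spread
#' function, summed into pixel windows, multiplied by the intensity per
#' motor, and offset by a background. The pixel grid is anchored at the
#' plus-end, mirroring line scans drawn from the plus-end toward the SPB:
#' the tip pixel covers a full pixel of polymer and the partial window
#' falls at the minus-end. Positions land on the aligned integer-pixel
#' grid; the sub-pixel offset of the SPB from pixel 0 is returned in
#' attribute `spb_offset_nm`. The map is linear in the occupancy for fixed
#' scale and background, and the blur preserves total motor mass (the grid
#' is extended to catch the tails).
#'
#' @param profile an `occupancy_profile` (minus-end at position 0).
#' @param scale intensity per motor, a.u. (> 0).
#' @param background additive background, a.u.
#' @param psf_sigma Gaussian PSF standard deviation in nm (0 disables).
#' @param pixel_size_nm imaging pixel size, nm (> 0).
#' @return An aligned `line_scan_profile` whose `profile_length_nm` is the
#'   position of the tip pixel on the aligned grid.
#' @export
occupancy_to_profile <- function(profile, scale = 1, background = 0,
                                 psf_sigma = 0, pixel_size_nm = 133.35) {
  stopifnot(inherits(profile, "occupancy_profile"))
  if (!is.finite(scale) || scale <= 0) stop("scale must be > 0")
  if (!is.finite(pixel_size_nm) || pixel_size_nm <= 0)
    stop("pixel_size_nm must be > 0")
  if (!is.finite(psf_sigma) || psf_sigma < 0)
    stop("psf_sigma must be >= 0")
  ss <- profile$site_size
  occ <- profile$mean_occupancy
  centers <- (seq_along(occ) - 0.5) * ss
  if (psf_sigma > 0) {
    half <- ceiling(5 * psf_sigma / ss)
    kern <- dnorm(seq(-half, half) * ss, sd = psf_sigma)
    kern <- kern / sum(kern)
    # full (open) convolution so mass spilling past either end is kept
    occ <- stats::convolve(occ, rev(kern), type = "open")
    centers <- (seq_along(occ) - 0.5 - half) * ss
  }
  px <- pixel_size_nm
  L <- length(profile$mean_occupancy) * ss
  # pixel windows anchored at the plus-end (scans run from the tip toward
  # the SPB): window j from the tip covers (L-(j+1)px, L-j*px], so the tip
  # pixel holds a full pixel of polymer and the partial window sits at the
  # minus-end; positions land on the aligned integer-pixel grid
  q <- round((L - px / 2) / px)
  delta <- (L - px / 2) - q * px # sub-pixel SPB offset, |delta| <= px/2
  k <- q - floor((L - centers) / px)
  lo <- min(k, 0L); hi <- max(k, as.integer(q))
  mass <- vapply(lo:hi, function(kk) sum(occ[k == kk]), numeric(1))
  out <- line_scan_profile((lo:hi) * px, background + scale * mass,
                           cell_id = "model")
  attr(out, "aligned") <- TRUE
  attr(out, "profile_length_nm") <- q * px
  attr(out, "gfp_peak_nm") <- out$position_nm[which.max(out$gfp_au)]
  attr(out, "spb_offset_nm") <- -delta
  out
}

#' Weighted regression of plus-end fluorescence against microtubule length
#'
#' For each length bin, the plus-end fluorescence is the mean GFP intensity
#' at the GFP-peak position of the bin's mean profile, with the squared
#' standard error of that mean as its variance. A weighted least-squares
#' line (weights = inverse variance) is fitted against the bin-centre
#' length.
#'
#' @param dataset a `profile_dataset` from [bin_by_length()].
#' @return A `plus_end_regression` list: `slope` (a.u. per um),
#'   `intercept` (a.u.), per-bin `points` data frame, `weights`, and the
#'   underlying `lm` fit.
#' @export
plus_end_regression <- function(dataset) {
  stopifnot(inherits(dataset, "profile_dataset"))
  pts <- do.call(rbind, lapply(dataset$bins, function(b) {
    s <- b$summary
    i <- which.max(s$mean_gfp)
    data.frame(length_um = b$centre_nm / 1000, plus_end_gfp = s$mean_gfp[i],
               sem = s$sem[i], n = b$n_profiles)
  }))
  pts <- pts[is.finite(pts$plus_end_gfp), , drop = FALSE]
  if (nrow(pts) < 2)
    stop("insufficient data: need >= 2 bins with a defined plus-end mean")
  w <- 1 / pts$sem^2
  if (any(!is.finite(w)) || any(w <= 0)) w <- rep(1, nrow(pts))
  fit <- lm(plus_end_gfp ~ length_um, data = pts, weights = w)
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 points = pts, weights = w, fit = fit),
            class = "plus_end_regression")
}

#' @export
print.plus_end_regression <- function(x, ...) {
  cat(sprintf("Plus-end regression over %d bins: slope %.4g a.u./um, intercept %.4g a.u.\n",
              nrow(x$points), x$slope, x$intercept))
  invisible(x)
}

#' Read and write line-scan CSV files
#'
#' The on-disk dialect is one CSV per cell with a header row and columns
#' `position_nm`, `gfp_au`, `mcherry_au` (a Fiji line-scan export with
#' renamed columns). Malformed files raise errors naming the offending
#' column or row.
#'
#' @param path CSV file path.
#' @param profile a [line_scan_profile()] (for writing).
#' @return `read_line_scan_csv` returns a `line_scan_profile`;
#'   `write_line_scan_csv` returns `path` invisibly.
#' @export
read_line_scan_csv <- function(path) {
  x <- read.csv(path, check.names = TRUE)
  need <- c("position_nm", "gfp_au", "mcherry_au")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(sprintf("%s: missing required column(s): %s", basename(path),
                 paste(miss, collapse = ", ")))
  for (col in need) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    bad <- which(is.na(v) & !is.na(x[[col]]) & col != "mcherry_au")
    if (length(bad))
      stop(sprintf("%s: non-numeric value in column '%s', row %d",
                   basename(path), col, bad[1]))
    x[[col]] <- v
  }
  line_scan_profile(x$position_nm, x$gfp_au, x$mcherry_au,
                    cell_id = sub("\\.csv$", "", basename(path)))
}

#' @rdname read_line_scan_csv
#' @export
write_line_scan_csv <- function(profile, path) {
  stopifnot(inherits(profile, "line_scan_profile"))
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
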