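#' Members nearest a group's mean morphology
#'
#' Ranks a group's records by Euclidean distance (standardised feature
#' subset) to the group mean and returns the indices of the `n` nearest,
#' restricted to rows flagged as having a linked outline.
#'
#' @param records Group's track-table rows (z-scored features present).
#' @param feature_subset Feature columns.
#' @param n Number of members to keep (default 30).
#' @param has_outline Logical vector marking rows with a linked outline
#'   (default: all).
#' @return Integer row indices into `records`, nearest first.
#' @export
nearest_members <- function(records, feature_subset, n = 30,
                            has_outline = rep(TRUE, nrow(records))) {
  if (nrow(records) == 0) stop("empty group")
  X <- feature_matrix(records, feature_subset)
  mu <- colMeans(X, na.rm = TRUE)
  d <- sqrt(rowSums(sweep(X, 2, mu)^2))
  cand <- which(has_outline & !is.na(d))
  if (length(cand) < n) {
    warning("only ", length(cand), " outlined member(s) available (need ", n, ")")
  }
  cand[order(d[cand])][seq_len(min(n, length(cand)))]
}

# resample a closed polygon to P points at equal arc-length spacing
resample_boundary <- function(vertices, P) {
  v <- vertices
  if (nrow(v) < 3) stop("degenerate polygon: fewer than 3 vertices")
  if (!all(v[1, ] == v[nrow(v), ])) v <- rbind(v, v[1, ])   # close the ring
  seg <- sqrt(rowSums(diff(v)^2))
  per <- sum(seg)
  if (per <= 0) stop("degenerate polygon: zero perimeter")
  s <- c(0, cumsum(seg))
  target <- seq(0, per, length.out = P + 1)[seq_len(P)]
  x <- approx(s, v[, 1], xout = target, ties = "ordered")$y
  y <- approx(s, v[, 2], xout = target, ties = "ordered")$y
  cbind(x, y)
}

#' Boundary power spectrum of an outline
#'
#' Resamples the closed boundary to `P` points at equal arc length,
#' expresses it as the complex function z = x + iy of arc position, takes
#' the discrete Fourier transform, and returns the squared-modulus power
#' spectrum scaled so its maximum is 1. The zero-frequency (centroid) term
#' is excluded before scaling by default, making the descriptor invariant
#' to translation and, through the max-scaling, to uniform size.
#'
#' @param vertices n x 2 matrix of boundary vertices in order (closed
#'   explicitly or implicitly).
#' @param P Number of resampled boundary points (default 128).
#' @param drop_dc Exclude the zero-frequency term (default TRUE).
#' @return Numeric vector of scaled power (length `P - 1` when `drop_dc`),
#'   with attributes `boundary` (the resampled points) and `P`.
#' @export
shape_spectrum <- function(vertices, P = 128, drop_dc = TRUE) {
  b <- resample_boundary(vertices, P)
  z <- complex(real = b[, 1], imaginary = b[, 2])
  pw <- Mod(fft(z))^2
  if (drop_dc) pw <- pw[-1]
  m <- max(pw)
  if (m <= 0) stop("degenerate polygon: zero spectral power")
  out <- pw / m
  attr(out, "boundary") <- b
  attr(out, "P") <- P
  out
}

#' Select the representative outline of a group
#'
#' Performs PCA on the members' scaled power spectra, estimates a 2-D
#' Gaussian kernel density over the first two components, locates the
#' density's global maximum on a grid, and returns the member nearest that
#' maximum — the most typical shape of the group. With fewer than 3
#' members the member nearest the spectral mean is returned with a
#' warning. Tied density maxima resolve to the first grid cell in scan
#' order; tied member distances to the lower index.
#'
#' @param spectra List of scaled power spectra ([shape_spectrum()]), all of
#'   equal length.
#' @param grid_n KDE grid resolution per axis (default 100).
#' @return Index of the selected member; attribute `"pc"` carries the PC
#'   coordinates.
#' @export
representative_outline <- function(spectra, grid_n = 100) {
  lens <- vapply(spectra, length, 0L)
  if (length(unique(lens)) != 1) stop("spectra differ in length")
  S <- do.call(rbind, lapply(spectra, as.numeric))
  n <- nrow(S)
  if (n < 3) {
    warning("fewer than 3 members: returning the member nearest the spectral mean")
    mu <- colMeans(S)
    return(which.min(rowSums(sweep(S, 2, mu)^2)))
  }
  pc <- prcomp(S, center = TRUE, scale. = FALSE)$x
  xy <- cbind(pc[, 1], if (ncol(pc) >= 2) pc[, 2] else rep(0, n))
  # Scott's-rule bandwidth per axis; kde2d treats h/4 as the kernel sd
  sdev <- pmax(apply(xy, 2, sd), 1e-9)
  h <- 4 * sdev * n^(-1 / 6)
  pad <- 0.1 * pmax(apply(xy, 2, function(v) diff(range(v))), 1e-9)
  lims <- c(range(xy[, 1]) + c(-1, 1) * pad[1],
            range(xy[, 2]) + c(-1, 1) * pad[2])
  kd <- MASS::kde2d(xy[, 1], xy[, 2], h = h, n = grid_n, lims = lims)
  peak <- which.max(kd$z)                # first maximum in scan order
  px <- kd$x[(peak - 1) %% grid_n + 1]
  py <- kd$y[(peak - 1) %/% grid_n + 1]
  d <- (xy[, 1] - px)^2 + (xy[, 2] - py)^2
  out <- which.min(d)
  attr(out, "pc") <- xy
  out
}
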