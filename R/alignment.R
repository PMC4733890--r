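#' Fit a landmark-based deformable warp
#'
#' Fits a smooth interpolating 2-D mapping from penetration coordinates in
#' the cortex-photograph frame to the stained-flatmount frame, from pairs of
#' control landmarks (marker lesions). The warp is a global affine part plus
#' a radially symmetric kernel centered on each control, solved with moment
#' side conditions so that the kernel weights carry no affine component.
#' It interpolates every control pair exactly; when the controls are drawn
#' from an affine map the kernel weights vanish and that affine is recovered
#' exactly; far from all controls the Gaussian kernels decay and the mapping
#' approaches its global affine part.
#'
#' With a single control the warp degenerates to a pure translation, and with
#' two controls to a similarity transform (rotation + isotropic scale +
#' translation), avoiding an under-determined affine.
#'
#' @param source,target n x 2 matrices (or 2-column data frames) of control
#'   coordinates in mm: `source` in the photo frame, `target` in the
#'   flatmount frame. Alternatively pass a single 4-column object
#'   (`xs ys xt yt`) as `source`.
#' @param kernel `"gaussian"` (default; `exp(-d^2 / (2 sigma^2))`) or
#'   `"tps"` (thin-plate `d^2 log d`; exact interpolation and affine
#'   recovery, but its displacements do not decay far from the controls).
#' @param bandwidth Gaussian kernel bandwidth `sigma` in mm; default is the
#'   median inter-control distance.
#' @return A `landmark_warp` object: list with the affine part (`affine`,
#'   3 x 2, rows intercept/x/y), kernel weights, control sources, residuals
#'   at the controls, and the per-control Jacobian anisotropy diagnostic
#'   (ratio of local singular values; 1 means locally shape-preserving).
#' @seealso [apply_warp()], [read_control_pairs()]
#' @export
fit_warp <- function(source, target = NULL, kernel = c("gaussian", "tps"),
                     bandwidth = NULL) {
  kernel <- match.arg(kernel)
  if (is.null(target)) {
    m <- as.matrix(source)
    if (ncol(m) != 4) stop("expected a 4-column control table (xs ys xt yt)")
    source <- m[, 1:2, drop = FALSE]
    target <- m[, 3:4, drop = FALSE]
  }
  src <- as.matrix(source); dst <- as.matrix(target)
  storage.mode(src) <- storage.mode(dst) <- "double"
  n <- nrow(src)
  if (n < 1) stop("need at least one control pair")
  if (nrow(dst) != n) stop("source/target control counts differ")
  if (any(!is.finite(src)) || any(!is.finite(dst)))
    stop("control coordinates must be finite")
  if (anyDuplicated(round(src, 12)))
    stop("duplicate control sources")

  weights <- matrix(0, n, 2)
  sigma <- NA_real_
  if (n == 1) {
    affine <- rbind(dst[1, ] - src[1, ], c(1, 0), c(0, 1))
  } else if (n == 2) {
    # similarity transform via the complex linear map z -> a z + b
    zs <- complex(real = src[, 1], imaginary = src[, 2])
    zt <- complex(real = dst[, 1], imaginary = dst[, 2])
    a <- (zt[2] - zt[1]) / (zs[2] - zs[1])
    b <- zt[1] - a * zs[1]
    affine <- rbind(c(Re(b), Im(b)), c(Re(a), Im(a)), c(-Im(a), Re(a)))
  } else {
    P <- cbind(1, src)
    if (qr(scale(src, scale = FALSE))$rank < 2)
      stop("control sources are collinear: affine part is rank deficient")
    d <- as.matrix(stats::dist(src))
    if (kernel == "gaussian") {
      sigma <- if (is.null(bandwidth)) stats::median(d[upper.tri(d)]) else bandwidth
      if (!is.finite(sigma) || sigma <= 0) stop("invalid kernel bandwidth")
      K <- exp(-d^2 / (2 * sigma^2))
    } else {
      K <- warp_kernel_tps(d)
    }
    M <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
    rhs <- rbind(dst, matrix(0, 3, 2))
    sol <- solve(M, rhs)
    weights <- sol[seq_len(n), , drop = FALSE]
    affine <- sol[n + 1:3, , drop = FALSE]
  }
  warp <- structure(list(kernel = kernel, sigma = sigma, sources = src,
                         weights = weights, affine = affine),
                    class = "landmark_warp")
  warp$residuals <- apply_warp(warp, src) - dst
  warp$anisotropy <- warp_anisotropy(warp, src)
  warp
}

warp_kernel_tps <- function(d) {
  k <- d^2 * log(d)
  k[!is.finite(k)] <- 0
  k
}

warp_kernel_eval <- function(warp, pts) {
  dx <- outer(pts[, 1], warp$sources[, 1], "-")
  dy <- outer(pts[, 2], warp$sources[, 2], "-")
  d2 <- dx^2 + dy^2
  if (warp$kernel == "gaussian") exp(-d2 / (2 * warp$sigma^2))
  else warp_kernel_tps(sqrt(d2))
}

#' Apply a fitted landmark warp to points
#'
#' @param warp a [fit_warp()] result.
#' @param points m x 2 matrix (or 2-column data frame) of photo-frame
#'   coordinates, mm.
#' @return m x 2 matrix of flatmount-frame coordinates.
#' @export
apply_warp <- function(warp, points) {
  stopifnot(inherits(warp, "landmark_warp"))
  pts <- as.matrix(points)
  if (is.null(dim(pts)) || ncol(pts) != 2) pts <- matrix(pts, ncol = 2)
  storage.mode(pts) <- "double"
  out <- cbind(1, pts) %*% warp$affine
  if (any(warp$weights != 0))
    out <- out + warp_kernel_eval(warp, pts) %*% warp$weights
  dimnames(out) <- list(NULL, c("x", "y"))
  out
}

#' @export
print.landmark_warp <- function(x, ...) {
  cat(sprintf("landmark_warp: %d controls, kernel=%s, max residual %.3g mm\n",
              nrow(x$sources), x$kernel, max(abs(x$residuals))))
  cat(sprintf("  Jacobian anisotropy at controls: %.4g - %.4g\n",
              min(x$anisotropy), max(x$anisotropy)))
  invisible(x)
}

#' Local distortion of a warp
#'
#' Numerically evaluates the warp Jacobian at the given points and returns
#' the ratio of its singular values (1 = locally shape preserving,
#' larger = anisotropic local stretch).
#'
#' @param warp a [fit_warp()] result.
#' @param points m x 2 matrix of evaluation points, mm.
#' @param h finite-difference step, mm.
#' @return numeric vector of anisotropy ratios.
#' @export
warp_anisotropy <- function(warp, points, h = 1e-4) {
  pts <- as.matrix(points)
  vapply(seq_len(nrow(pts)), function(i) {
    p <- pts[i, ]
    jx <- (apply_warp(warp, rbind(p + c(h, 0))) -
           apply_warp(warp, rbind(p - c(h, 0)))) / (2 * h)
    jy <- (apply_warp(warp, rbind(p + c(0, h))) -
           apply_warp(warp, rbind(p - c(0, h)))) / (2 * h)
    sv <- svd(rbind(jx, jy))$d
    sv[1] / sv[2]
  }, numeric(1))
}

#' Read landmark control pairs from a 4-column table
#'
#' Plain-text dialect: whitespace-separated columns `xs ys xt yt` (photo
#' frame then flatmount frame, mm), `#` comments ignored.
#'
#' @param path file path.
#' @return data frame with columns `xs, ys, xt, yt`.
#' @export
read_control_pairs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.table(path, col.names = c("xs", "ys", "xt", "yt"),
                          comment.char = "#")
  df
}

#' Serialize a landmark warp to a plain-text sidecar
#'
#' @param warp a [fit_warp()] result.
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_warp <- function(warp, path) {
  stopifnot(inherits(warp, "landmark_warp"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("# landmark_warp",
               paste("kernel", warp$kernel),
               paste("sigma", sprintf("%.15g", warp$sigma)),
               paste("n", nrow(warp$sources))), con)
  writeLines("# affine (rows: 1 x y; cols: x' y')", con)
  writeLines(apply(warp$affine, 1, function(r) paste(sprintf("%.15g", r),
                                                     collapse = " ")), con)
  writeLines("# controls: xs ys wx wy", con)
  writeLines(paste(sprintf("%.15g", warp$sources[, 1]),
                   sprintf("%.15g", warp$sources[, 2]),
                   sprintf("%.15g", warp$weights[, 1]),
                   sprintf("%.15g", warp$weights[, 2])), con)
  invisible(path)
}

#' Read a landmark warp written by [write_warp()]
#' @param path file path.
#' @return a `landmark_warp` object.
#' @export
read_warp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kernel <- strsplit(lines[1], "\\s+")[[1]][2]
  sigma <- as.numeric(strsplit(lines[2], "\\s+")[[1]][2])
  n <- as.integer(strsplit(lines[3], "\\s+")[[1]][2])
  num <- function(s) as.numeric(strsplit(trimws(s), "\\s+")[[1]])
  affine <- t(vapply(lines[4:6], num, numeric(2)))
  ctl <- t(vapply(lines[6 + seq_len(n)], num, numeric(4)))
  dimnames(affine) <- NULL; dimnames(ctl) <- NULL
  warp <- structure(list(kernel = kernel, sigma = sigma,
                         sources = ctl[, 1:2, drop = FALSE],
                         weights = ctl[, 3:4, drop = FALSE],
                         affine = affine),
                    class = "landmark_warp")
  warp$residuals <- matrix(0, n, 2)
  warp$anisotropy <- warp_anisotropy(warp, warp$sources)
  warp
}
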