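# Internal numeric / geometric helpers shared across modules.

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Axis-aligned rectangular pixel region (1-based, inclusive bounds)
#'
#' Rows/columns follow R matrix indexing: row 1 is the top of the image.
#'
#' @param row1,row2 first and last row (inclusive)
#' @param col1,col2 first and last column (inclusive)
#' @return an object of class `roi_rect`
#' @export
roi_rect <- function(row1, row2, col1, col2) {
  row1 <- as.integer(round(row1)); row2 <- as.integer(round(row2))
  col1 <- as.integer(round(col1)); col2 <- as.integer(round(col2))
  if (row2 < row1 || col2 < col1)
    stop("roi_rect: empty region (row2 < row1 or col2 < col1)")
  structure(list(row1 = row1, row2 = row2, col1 = col1, col2 = col2),
            class = "roi_rect")
}

#' @export
print.roi_rect <- function(x, ...) {
  cat(sprintf("<roi_rect rows %d..%d cols %d..%d (%d x %d px)>\n",
              x$row1, x$row2, x$col1, x$col2,
              x$row2 - x$row1 + 1L, x$col2 - x$col1 + 1L))
  invisible(x)
}

roi_center <- function(r) c((r$row1 + r$row2) / 2, (r$col1 + r$col2) / 2)
roi_npix   <- function(r) (r$row2 - r$row1 + 1L) * (r$col2 - r$col1 + 1L)

roi_shift <- function(r, drow, dcol) {
  roi_rect(r$row1 + drow, r$row2 + drow, r$col1 + dcol, r$col2 + dcol)
}

roi_overlaps <- function(a, b) {
  a$row1 <= b$row2 && b$row1 <= a$row2 && a$col1 <= b$col2 && b$col1 <= a$col2
}

roi_inside <- function(r, dim) {
  r$row1 >= 1L && r$col1 >= 1L && r$row2 <= dim[1] && r$col2 <= dim[2]
}

#' Square region of a given physical size centered at a pixel position
#' @noRd
roi_square_mm <- function(center_px, side_mm, spacing_mm) {
  half <- max(1, round(side_mm / spacing_mm / 2))
  roi_rect(round(center_px[1]) - half, round(center_px[1]) + half - 1,
           round(center_px[2]) - half, round(center_px[2]) + half - 1)
}

extract_roi <- function(pixels, r) {
  if (!roi_inside(r, dim(pixels)))
    stop("region out of image bounds: rows ", r$row1, "..", r$row2,
         " cols ", r$col1, "..", r$col2)
  pixels[r$row1:r$row2, r$col1:r$col2, drop = FALSE]
}

#' Otsu's threshold on a numeric vector (256-bin histogram)
#' @noRd
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  rng <- range(x)
  if (diff(rng) == 0) return(rng[1])
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((x - rng[1]) / diff(rng) * nb)), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  rng[1] + k / nb * diff(rng)
}

#' Means of all h x w windows of a matrix via an integral image.
#' Returns a (nrow-h+1) x (ncol-w+1) matrix; element [i,j] is the mean of
#' m[i:(i+h-1), j:(j+w-1)].
#' @noRd
window_means <- function(m, h, w) {
  ii <- apply(apply(m, 2, cumsum), 1, cumsum)  # transposed integral image
  ii <- t(ii)
  ii <- rbind(0, cbind(0, ii))
  nr <- nrow(m); nc <- ncol(m)
  i1 <- 1:(nr - h + 1); j1 <- 1:(nc - w + 1)
  (ii[i1 + h, j1 + w, drop = FALSE] - ii[i1, j1 + w, drop = FALSE] -
     ii[i1 + h, j1, drop = FALSE] + ii[i1, j1, drop = FALSE]) / (h * w)
}

#' Separable Gaussian blur with renormalized (replicate-equivalent) borders
#' @noRd
blur_gaussian <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  half <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(-half:half, sd = sigma_px)
  k <- k / sum(k)
  n <- length(k)
  conv1 <- function(x) {
    # banded Toeplitz multiply; border rows renormalized so a constant
    # input stays constant (no dark frame around the image)
    nr <- nrow(x)
    out <- matrix(0, nr, ncol(x))
    wsum <- numeric(nr)
    for (t in seq_len(n)) {
      off <- t - half - 1L
      src <- (1:nr) + off
      ok <- src >= 1L & src <= nr
      out[ok, ] <- out[ok, ] + k[t] * x[src[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + k[t]
    }
    out / wsum
  }
  t(conv1(t(conv1(m))))
}

#' Connected components of a logical mask (4-connectivity, row-run union-find)
#'
#' Fast when the mask consists of a few compact blobs; guarded by callers
#' against pathological speckle masks.
#'
#' @return list of components, each a list(area, centroid = c(row, col),
#'   rows = range, cols = range, label_runs = data.frame)
#' @noRd
mask_components <- function(mask, max_runs = 100000L) {
  nr <- nrow(mask); nc <- ncol(mask)
  runs <- vector("list", nr)
  nrun <- 0L
  for (i in seq_len(nr)) {
    r <- rle(as.vector(mask[i, ]))
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    sel <- which(r$values)
    runs[[i]] <- cbind(row = i, c1 = starts[sel], c2 = ends[sel])
    nrun <- nrun + length(sel)
    if (nrun > max_runs) stop("mask too fragmented for component labeling")
  }
  runs <- do.call(rbind, runs)
  if (is.null(runs)) return(list())
  n <- nrow(runs)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  # union vertically adjacent, column-overlapping runs
  by_row <- split(seq_len(n), runs[, "row"])
  rows_present <- as.integer(names(by_row))
  for (ri in seq_along(rows_present)[-1]) {
    if (rows_present[ri] - rows_present[ri - 1] != 1L) next
    a <- by_row[[ri - 1]]; b <- by_row[[ri]]
    for (ib in b) {
      for (ia in a) {
        if (runs[ia, "c1"] <= runs[ib, "c2"] && runs[ib, "c1"] <= runs[ia, "c2"]) {
          ra <- find(ia); rb <- find(ib)
          if (ra != rb) parent[ra] <- rb
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), root)
  lapply(comps, function(idx) {
    rr <- runs[idx, , drop = FALSE]
    len <- rr[, "c2"] - rr[, "c1"] + 1L
    area <- sum(len)
    crow <- sum(rr[, "row"] * len) / area
    ccol <- sum((rr[, "c1"] + rr[, "c2"]) / 2 * len) / area
    list(area = area, centroid = c(crow, ccol),
         rows = range(rr[, "row"]), cols = range(rr[, "c1"], rr[, "c2"]))
  })
}

#' Linear interpolation of a curve onto new x values (rule 2 at the ends)
#' @noRd
interp1 <- function(x, y, xout) {
  stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
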