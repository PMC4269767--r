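## Box-sum quantification of gridded 2D spectral planes: peak intensities
## (partial peak volumes) are obtained by summing a fixed odd-sized box of
## grid points centred on the peak maximum. No interpolation, no overlap
## correction: volumes are raw sums, exactly as acquired-data pipelines in
## this field report them.

#' Construct a gridded 2D spectral plane
#'
#' @param intensity numeric matrix, rows = 1H points, columns = 15N points.
#' @param h_ppm,n_ppm axis calibrations: ppm value of each grid point;
#'   strictly monotone.
#' @param meta plane metadata, e.g. `list(kind = "nu_cpmg_hz", value = 600)`
#'   tagging what varies across a series (relaxation delay, gradient
#'   strength, CPMG frequency or ligand ratio).
#' @return object of class `"gridded_plane"`.
#' @export
gridded_plane <- function(intensity, h_ppm, n_ppm, meta = list()) {
  stopifnot(is.matrix(intensity),
            nrow(intensity) == length(h_ppm),
            ncol(intensity) == length(n_ppm))
  dh <- diff(h_ppm); dn <- diff(n_ppm)
  if (!(all(dh > 0) || all(dh < 0)) || !(all(dn > 0) || all(dn < 0))) {
    stop("axis calibrations must be strictly monotone")
  }
  structure(list(intensity = intensity, h_ppm = h_ppm, n_ppm = n_ppm,
                 meta = meta),
            class = "gridded_plane")
}

#' @export
print.gridded_plane <- function(x, ...) {
  cat(sprintf("Gridded plane: %d x %d points, 1H %.2f..%.2f ppm, 15N %.1f..%.1f ppm\n",
              nrow(x$intensity), ncol(x$intensity),
              min(x$h_ppm), max(x$h_ppm), min(x$n_ppm), max(x$n_ppm)))
  if (length(x$meta)) {
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  }
  invisible(x)
}

.nearest_index <- function(axis, ppm) which.min(abs(axis - ppm))

#' Box-sum volume of one peak
#'
#' Sums `box x box` grid intensities centred on the grid point nearest the
#' nominal peak position, after refining the centre to the local maximum
#' within +/- 1 grid point in each dimension (peak maxima drift slightly
#' between planes of a series). A box extending past the grid edge is an
#' explicit error: volumes near edges are never silently truncated.
#'
#' @param plane a [gridded_plane()].
#' @param h_ppm,n_ppm nominal peak position, ppm.
#' @param box odd box size in points (default 5).
#' @return the partial peak volume (sum of intensities).
#' @export
box_sum_volume <- function(plane, h_ppm, n_ppm, box = 5) {
  stopifnot(inherits(plane, "gridded_plane"), box %% 2 == 1, box >= 1)
  z <- plane$intensity
  i <- .nearest_index(plane$h_ppm, h_ppm)
  j <- .nearest_index(plane$n_ppm, n_ppm)
  ## local-maximum refinement within +/- 1 point
  ii <- max(1, i - 1):min(nrow(z), i + 1)
  jj <- max(1, j - 1):min(ncol(z), j + 1)
  sub <- z[ii, jj, drop = FALSE]
  k <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  i <- ii[k[1]]; j <- jj[k[2]]
  half <- (box - 1) / 2
  if (i - half < 1 || i + half > nrow(z) ||
      j - half < 1 || j + half > ncol(z)) {
    stop("box of ", box, "x", box, " points around (", h_ppm, ", ", n_ppm,
         ") ppm extends past the grid edge")
  }
  sum(z[(i - half):(i + half), (j - half):(j + half)])
}

#' Quantify a peak list across a series of planes
#'
#' Extracts one volume per plane per residue by box summation and orders
#' them by the plane metadata value, yielding a decay series per residue.
#' All planes must share axis calibrations. Residues whose box does not fit
#' inside the grid of every plane are excluded with a message.
#'
#' @param planes list of [gridded_plane()] objects with identical axes and
#'   a numeric `meta$value` each.
#' @param peaks data.frame with columns `residue`, `h_ppm`, `n_ppm` (and
#'   optionally `aa`).
#' @param box odd box size (default 5).
#' @return data.frame (`residue`, `x`, `intensity`) ordered by `x` within
#'   residue, where `x` is the plane metadata value; attribute `excluded`
#'   lists dropped residues.
#' @export
quantify_series <- function(planes, peaks, box = 5) {
  stopifnot(length(planes) >= 1,
            all(c("residue", "h_ppm", "n_ppm") %in% names(peaks)))
  ref <- planes[[1]]
  for (p in planes[-1]) {
    if (!isTRUE(all.equal(ref$h_ppm, p$h_ppm)) ||
        !isTRUE(all.equal(ref$n_ppm, p$n_ppm))) {
      stop("planes have mismatching axis calibrations")
    }
  }
  xs <- vapply(planes, function(p) as.numeric(p$meta$value %||% NA_real_),
               numeric(1))
  if (any(is.na(xs))) stop("every plane needs a numeric meta$value")
  rows <- list(); excluded <- c()
  for (k in seq_len(nrow(peaks))) {
    vols <- tryCatch(
      vapply(planes, function(p) {
        box_sum_volume(p, peaks$h_ppm[k], peaks$n_ppm[k], box)
      }, numeric(1)),
      error = function(e) NULL)
    if (is.null(vols)) {
      excluded <- c(excluded, peaks$residue[k])
      next
    }
    o <- order(xs)
    rows[[length(rows) + 1]] <- data.frame(residue = peaks$residue[k],
                                           x = xs[o], intensity = vols[o])
  }
  if (length(excluded)) {
    message("excluded (grid coverage): residue ",
            paste(excluded, collapse = ", "))
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(residue = numeric(), x = numeric(), intensity = numeric())
  }
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Write / read a gridded plane as plain text
#'
#' The intensity matrix is written as a dense whitespace-separated text
#' matrix; axis calibrations and metadata go to a `<path>.cal` sidecar.
#'
#' @param plane a [gridded_plane()].
#' @param path file path for the matrix.
#' @return `read_plane` returns a [gridded_plane()].
#' @export
write_plane <- function(plane, path) {
  stopifnot(inherits(plane, "gridded_plane"))
  utils::write.table(plane$intensity, path, row.names = FALSE,
                     col.names = FALSE)
  cal <- c(paste("h_ppm", paste(format(plane$h_ppm, digits = 10),
                                collapse = " ")),
           paste("n_ppm", paste(format(plane$n_ppm, digits = 10),
                                collapse = " ")),
           paste("meta_kind", plane$meta$kind %||% ""),
           paste("meta_value", plane$meta$value %||% ""))
  writeLines(cal, paste0(path, ".cal"))
  invisible(path)
}

#' @rdname write_plane
#' @export
read_plane <- function(path) {
  z <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(z) <- NULL
  cal <- readLines(paste0(path, ".cal"))
  grab <- function(key) {
    line <- grep(paste0("^", key, " "), cal, value = TRUE)
    strsplit(sub(paste0("^", key, " "), "", line), " +")[[1]]
  }
  meta <- list(kind = grab("meta_kind"))
  v <- suppressWarnings(as.numeric(grab("meta_value")))
  if (length(v) && is.finite(v)) meta$value <- v
  gridded_plane(z, as.numeric(grab("h_ppm")), as.numeric(grab("n_ppm")),
                meta = meta)
}

#' Read a peak list from TSV
#'
#' Expected columns: `residue`, `aa`, `h_ppm`, `n_ppm`.
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_peaks <- function(path) {
  p <- .read_tsv(path)
  stopifnot(all(c("residue", "h_ppm", "n_ppm") %in% names(p)))
  if (anyDuplicated(p$residue)) stop("residue ids must be unique")
  if (!all(is.finite(p$h_ppm)) || !all(is.finite(p$n_ppm))) {
    stop("peak positions must be finite")
  }
  p
}
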