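# Movie containers and on-disk access.
#
# A movie is represented as a d x T matrix (pixels by frames) with row-major
# FOV flattening: pixel index = (row - 1) * cols + col.  The on-disk ".pmap"
# format stores this matrix pixel-major (each pixel's full time series is a
# contiguous byte range), which makes spatial patch access cheap: reading a
# patch touches one contiguous range per pixel instead of T scattered reads.

PMAP_MAGIC <- "PMAPMOV1"
PMAP_HEADER_BYTES <- 128L

#' Construct an in-memory movie
#'
#' @param data d x T numeric matrix of fluorescence values (pixels by
#'   frames, row-major FOV flattening) or a rows x cols x T array.
#' @param fov_dims integer(2) (rows, cols); required when \code{data} is a
#'   matrix.
#' @param frame_rate imaging rate in Hz.
#' @param source_path optional provenance path.
#' @return an object of class \code{movie} with fields \code{data},
#'   \code{fov_dims}, \code{frame_rate}, \code{source_path}.
#' @export
movie <- function(data, fov_dims = NULL, frame_rate = 30, source_path = NULL) {
  if (length(dim(data)) == 3L) {
    dims <- dim(data)
    fov_dims <- dims[1:2]
    data <- matrix(aperm(data, c(2L, 1L, 3L)), dims[1] * dims[2], dims[3])
  }
  stopifnot(is.matrix(data), !is.null(fov_dims),
            nrow(data) == prod(fov_dims), all(is.finite(data)))
  structure(list(data = data, fov_dims = as.integer(fov_dims),
                 frame_rate = frame_rate, source_path = source_path),
            class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  cat(sprintf("movie: %d x %d FOV, %d frames at %g Hz\n",
              x$fov_dims[1], x$fov_dims[2], ncol(x$data), x$frame_rate))
  invisible(x)
}

#' Extract one frame of a movie as a rows x cols image
#' @param mov a \code{movie}.
#' @param t frame index (1-based).
#' @return numeric matrix rows x cols.
#' @export
movie_frame <- function(mov, t) {
  matrix(mov$data[, t], mov$fov_dims[1], mov$fov_dims[2], byrow = TRUE)
}

#' Read a multi-page TIFF movie
#'
#' Pages are read frame by frame; 16-bit integer samples are returned at
#' their native integer scale.
#'
#' @param path TIFF file path.
#' @param frame_rate frame rate to attach, Hz.
#' @return a \code{movie}.
#' @export
read_movie_tiff <- function(path, frame_rate = 30) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  dims <- dim(pages[[1]])
  data <- vapply(pages, function(fr) {
    if (!identical(dim(fr), dims)) stop("inconsistent frame shapes in ", path)
    as.vector(t(fr))
  }, numeric(prod(dims)))
  movie(matrix(data, prod(dims), length(pages)), fov_dims = dims,
        frame_rate = frame_rate, source_path = path)
}

#' Write a movie as a multi-page 16-bit TIFF
#'
#' Values must be non-negative; they are rounded to integers and must not
#' exceed 65535. Integer-valued movies round-trip exactly through
#' \code{\link{read_movie_tiff}}.
#'
#' @param mov a \code{movie}.
#' @param path output path.
#' @export
write_movie_tiff <- function(mov, path) {
  mx <- max(mov$data)
  if (min(mov$data) < 0 || mx > 65535) {
    stop("16-bit TIFF output requires values in [0, 65535]")
  }
  frames <- lapply(seq_len(ncol(mov$data)), function(t) {
    movie_frame(mov, t) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  invisible(path)
}

#' Quantize a float movie into the 16-bit integer range
#'
#' Affine map of the value range onto 0..65535 with rounding; used to store
#' synthetic float movies in TIFF form.
#' @param mov a \code{movie}.
#' @return a list with the quantized \code{movie} plus \code{offset} and
#'   \code{scale} such that original ~= quantized * scale + offset.
#' @export
quantize_movie <- function(mov) {
  lo <- min(mov$data); hi <- max(mov$data)
  scale <- if (hi > lo) (hi - lo) / 65535 else 1
  q <- round((mov$data - lo) / scale)
  list(movie = movie(q, mov$fov_dims, mov$frame_rate, mov$source_path),
       offset = lo, scale = scale)
}

write_pmap_header <- function(con, rows, cols, Tt) {
  writeChar(PMAP_MAGIC, con, nchars = 8L, eos = NULL)
  writeBin(as.integer(c(rows, cols, Tt, 4L)), con, size = 4L, endian = "little")
  writeBin(raw(PMAP_HEADER_BYTES - 8L - 16L), con)
}

read_pmap_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- suppressWarnings(readChar(con, 8L, useBytes = TRUE))
  if (!identical(magic, PMAP_MAGIC)) stop("not a .pmap file: ", path)
  hdr <- readBin(con, "integer", 4L, size = 4L, endian = "little")
  list(rows = hdr[1], cols = hdr[2], n_frames = hdr[3], dtype = hdr[4])
}

#' Write a movie to the pixel-major ".pmap" memory-mapped format
#'
#' The file layout is a 128-byte header (magic \code{"PMAPMOV1"}, then
#' int32 rows, cols, T, dtype code 4 = float32, zero padding) followed by
#' the d x T matrix in pixel-major order as little-endian 32-bit floats.
#' Writing proceeds in two phases as chunks of frames arrive: each chunk is
#' written to a pixel-major temporary, then the temporaries are concatenated
#' pixel block by pixel block. The result is bit-identical regardless of the
#' chunking.
#'
#' @param frame_source a \code{movie}, a d x T matrix plus \code{fov_dims},
#'   or a character vector of TIFF paths read frame by frame.
#' @param out_path output \code{.pmap} path.
#' @param chunk_size frames per chunk during the first phase.
#' @param fov_dims required when \code{frame_source} is a bare matrix.
#' @param frame_rate frame rate recorded alongside (not stored in the file).
#' @return a \code{memmap_movie} handle (class with \code{path},
#'   \code{dims}, \code{frame_rate}).
#' @export
write_memmap <- function(frame_source, out_path, chunk_size = 500L,
                         fov_dims = NULL, frame_rate = 30) {
  if (is.character(frame_source)) {
    movs <- lapply(frame_source, read_movie_tiff, frame_rate = frame_rate)
    dims <- movs[[1]]$fov_dims
    for (m in movs) {
      if (!identical(m$fov_dims, dims)) {
        stop("inconsistent frame shapes in input file ", m$source_path)
      }
    }
    Y <- do.call(cbind, lapply(movs, function(m) m$data))
  } else if (inherits(frame_source, "movie")) {
    Y <- frame_source$data
    dims <- frame_source$fov_dims
    frame_rate <- frame_source$frame_rate
  } else {
    stopifnot(is.matrix(frame_source), !is.null(fov_dims))
    Y <- frame_source
    dims <- as.integer(fov_dims)
  }
  d <- nrow(Y); Tt <- ncol(Y)
  starts <- seq(1L, Tt, by = as.integer(chunk_size))
  tmp_files <- character(length(starts))
  # phase 1: each chunk saved pixel-major on its own
  for (k in seq_along(starts)) {
    t0 <- starts[k]; t1 <- min(Tt, t0 + chunk_size - 1L)
    tmp_files[k] <- paste0(out_path, ".chunk", k)
    con <- file(tmp_files[k], "wb")
    writeBin(as.numeric(t(Y[, t0:t1, drop = FALSE])), con, size = 4L,
             endian = "little")
    close(con)
  }
  # phase 2: concatenate chunk temporaries by pixel block
  con_out <- file(out_path, "wb")
  write_pmap_header(con_out, dims[1], dims[2], Tt)
  cons <- lapply(tmp_files, file, open = "rb")
  block <- 4096L
  chunk_len <- vapply(seq_along(starts), function(k) {
    min(Tt, starts[k] + chunk_size - 1L) - starts[k] + 1L
  }, integer(1))
  for (p0 in seq(1L, d, by = block)) {
    np <- min(block, d - p0 + 1L)
    parts <- lapply(seq_along(cons), function(k) {
      matrix(readBin(cons[[k]], "numeric", np * chunk_len[k], size = 4L,
                     endian = "little"), nrow = chunk_len[k])
    })
    out <- do.call(rbind, parts)     # (sum chunk_len = T) x np, pixel cols
    writeBin(as.numeric(out), con_out, size = 4L, endian = "little")
  }
  for (cn in cons) close(cn)
  close(con_out)
  unlink(tmp_files)
  structure(list(path = out_path, dims = c(dims, Tt), layout = "pixel-major",
                 frame_rate = frame_rate),
            class = "memmap_movie")
}

#' Open an existing ".pmap" file
#' @param path file path.
#' @param frame_rate frame rate to attach, Hz.
#' @return a \code{memmap_movie} handle.
#' @export
open_memmap <- function(path, frame_rate = 30) {
  hdr <- read_pmap_header(path)
  expect_size <- PMAP_HEADER_BYTES +
    as.numeric(hdr$rows) * hdr$cols * hdr$n_frames * 4
  if (file.info(path)$size != expect_size) {
    stop("corrupt .pmap file: size mismatch")
  }
  structure(list(path = path, dims = c(hdr$rows, hdr$cols, hdr$n_frames),
                 layout = "pixel-major", frame_rate = frame_rate),
            class = "memmap_movie")
}

#' Read a spatiotemporal patch from a ".pmap" file
#'
#' Returns the sub-tensor for pixel rows \code{rows[1]:rows[2]}, pixel
#' columns \code{cols[1]:cols[2]} and frames \code{frames[1]:frames[2]}
#' (1-based, inclusive), flattened row-major over the patch pixels, without
#' loading the rest of the file. Memory use is proportional to the patch.
#'
#' @param mm a \code{memmap_movie}.
#' @param rows,cols,frames integer(2) inclusive index ranges; \code{NULL}
#'   means the full extent.
#' @return numeric matrix (patch pixels) x (frames).
#' @export
read_patch <- function(mm, rows = NULL, cols = NULL, frames = NULL) {
  stopifnot(inherits(mm, "memmap_movie"))
  R <- mm$dims[1]; Cc <- mm$dims[2]; Tt <- mm$dims[3]
  if (is.null(rows)) rows <- c(1L, R)
  if (is.null(cols)) cols <- c(1L, Cc)
  if (is.null(frames)) frames <- c(1L, Tt)
  chk <- function(rng, lim, what) {
    if (rng[1] < 1L || rng[2] > lim || rng[1] > rng[2]) {
      stop("read_patch: ", what, " range [", rng[1], ", ", rng[2],
           "] outside 1..", lim)
    }
  }
  chk(rows, R, "row"); chk(cols, Cc, "col"); chk(frames, Tt, "frame")
  nr <- rows[2] - rows[1] + 1L
  nc <- cols[2] - cols[1] + 1L
  nt <- frames[2] - frames[1] + 1L
  out <- matrix(0, nr * nc, nt)
  con <- file(mm$path, "rb")
  on.exit(close(con))
  k <- 0L
  for (r in rows[1]:rows[2]) {
    for (cl in cols[1]:cols[2]) {
      k <- k + 1L
      p <- (r - 1L) * Cc + cl              # row-major pixel index, 1-based
      off <- PMAP_HEADER_BYTES +
        (as.numeric(p) - 1) * Tt * 4 + (frames[1] - 1) * 4
      seek(con, off)
      out[k, ] <- readBin(con, "numeric", nt, size = 4L, endian = "little")
    }
  }
  out
}

#' Load a full ".pmap" file as an in-memory movie
#' @param mm a \code{memmap_movie}.
#' @return a \code{movie}.
#' @export
memmap_to_movie <- function(mm) {
  Y <- read_patch(mm)
  movie(Y, fov_dims = mm$dims[1:2], frame_rate = mm$frame_rate,
        source_path = mm$path)
}
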