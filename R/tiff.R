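# Minimal baseline TIFF I/O (little-endian, uncompressed, one plane of
# interleaved samples).  Covers the formats the pipeline needs: 8/16-bit
# unsigned grayscale label/intensity maps and 32-bit float stacks used to
# cache encoded targets.  No external image package is required.

.tiff_type_size <- c(`1` = 1, `2` = 1, `3` = 2, `4` = 4, `5` = 8,
                     `11` = 4, `12` = 8)

.tiff_write <- function(path, data_raw, W, H, bits, spp, format) {
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeBin(charToRaw("II"), con); wr2(42)
  data_off <- 8L
  ifd_off <- data_off + length(data_raw)
  if (ifd_off %% 2 == 1) ifd_off <- ifd_off + 1L
  wr4(ifd_off)
  writeBin(data_raw, con)
  if ((data_off + length(data_raw)) %% 2 == 1) writeBin(as.raw(0), con)
  tags <- list(
    c(256, 4, 1, W), c(257, 4, 1, H), c(259, 3, 1, 1), c(262, 3, 1, 1),
    c(273, 4, 1, data_off), c(277, 3, 1, spp), c(278, 4, 1, H),
    c(279, 4, 1, length(data_raw)), c(339, 3, 1, format))
  extra_off <- ifd_off + 2L + 12L * (length(tags) + 1L) + 4L
  if (spp <= 2) {
    bps_val <- sum(bits * 65536^(seq_len(spp) - 1))  # packed shorts
    tags <- c(tags, list(c(258, 3, spp, bps_val)))
    extra <- integer(0)
  } else {
    tags <- c(tags, list(c(258, 3, spp, extra_off)))
    extra <- rep(bits, spp)
  }
  tags <- tags[order(vapply(tags, `[`, 0, 1))]
  wr2(length(tags))
  for (tg in tags) { wr2(tg[1]); wr2(tg[2]); wr4(tg[3]); wr4(tg[4]) }
  wr4(0)
  if (length(extra)) wr2(extra)
  invisible(path)
}

.tiff_read_ifd <- function(raw) {
  if (!(raw[1] == charToRaw("I") && raw[2] == charToRaw("I")))
    stop("only little-endian TIFF is supported")
  rd <- function(off, size, n = 1)
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = "little", signed = size > 2)
  ifd_off <- rd(4, 4)
  n_tags <- rd(ifd_off, 2)
  tags <- list()
  for (k in seq_len(n_tags)) {
    e <- ifd_off + 2 + 12 * (k - 1)
    tag <- rd(e, 2); typ <- rd(e + 2, 2); cnt <- rd(e + 4, 4)
    sz <- .tiff_type_size[[as.character(typ)]]
    vsize <- if (typ == 3) 2 else 4
    if (sz * cnt <= 4) {
      val <- rd(e + 8, vsize, n = min(cnt, 4 %/% vsize))
    } else {
      off <- rd(e + 8, 4)
      val <- rd(off, sz, n = cnt)
    }
    tags[[as.character(tag)]] <- val
  }
  tags
}

.tiff_read <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  tags <- .tiff_read_ifd(raw)
  need <- function(t, default = NULL) {
    v <- tags[[as.character(t)]]
    if (is.null(v)) { if (is.null(default)) stop("missing TIFF tag ", t); default }
    else v
  }
  W <- need(256); H <- need(257)
  if (need(259, 1) != 1) stop("compressed TIFF is not supported")
  bits <- need(258, 8)[1]
  spp <- need(277, 1)
  fmt <- need(339, 1)[1]
  offs <- need(273); cnts <- need(279, H * W * spp * bits / 8)
  data <- do.call(c, lapply(seq_along(offs), function(i)
    raw[(offs[i] + 1):(offs[i] + cnts[i])]))
  n <- H * W * spp
  vals <- if (fmt == 3) {
    readBin(data, "double", n = n, size = bits / 8, endian = "little")
  } else if (bits == 8) {
    as.integer(data[seq_len(n)])
  } else {
    v <- readBin(data, "integer", n = n, size = bits / 8, endian = "little",
                 signed = FALSE)
    as.integer(v)
  }
  # TIFF is row-major with interleaved samples -> (H, W, spp) array
  arr <- aperm(array(vals, c(spp, W, H)), c(3, 2, 1))
  list(data = arr, bits = bits, format = fmt)
}

#' Label map TIFF I/O
#'
#' Instance label maps are stored as single-channel uncompressed 16-bit
#' TIFF: 0 is background, positive integers are instance ids.
#'
#' @param labels integer matrix of instance ids.
#' @param path file path.
#' @export
write_label_tiff <- function(labels, path) {
  stopifnot(is.matrix(labels), all(labels >= 0), all(labels < 65536))
  H <- nrow(labels); W <- ncol(labels)
  v <- as.integer(t(labels))  # row-major
  raw <- writeBin(v, raw(), size = 2, endian = "little")
  .tiff_write(path, raw, W, H, 16L, 1L, 1L)
}

#' @rdname write_label_tiff
#' @return `read_label_tiff` returns an integer matrix.
#' @export
read_label_tiff <- function(path) {
  r <- .tiff_read(path)
  matrix(as.integer(r$data[, , 1]), nrow = dim(r$data)[1])
}

#' Grayscale image TIFF I/O
#'
#' Images are exchanged as single-channel uncompressed 8-bit TIFF.
#' `write_image_tiff` expects intensities in `[0, 1]`; `read_image_tiff`
#' rescales unsigned data back to `[0, 1]`.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param path file path.
#' @export
write_image_tiff <- function(img, path) {
  stopifnot(is.matrix(img))
  v <- as.integer(round(pmin(pmax(t(img), 0), 1) * 255))
  .tiff_write(path, as.raw(v), ncol(img), nrow(img), 8L, 1L, 1L)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path) {
  r <- .tiff_read(path)
  m <- matrix(as.numeric(r$data[, , 1]), nrow = dim(r$data)[1])
  if (r$format != 3) m <- m / (2^r$bits - 1)
  m
}

#' Multi-channel float stack TIFF I/O
#'
#' Caches probability/distance target stacks as uncompressed 32-bit float
#' TIFF with one sample per channel.
#'
#' @param arr numeric `H x W x C` array.
#' @param path file path.
#' @export
write_stack_tiff <- function(arr, path) {
  stopifnot(length(dim(arr)) == 3)
  H <- dim(arr)[1]; W <- dim(arr)[2]; C <- dim(arr)[3]
  v <- as.numeric(aperm(arr, c(3, 2, 1)))
  raw <- writeBin(v, raw(), size = 4, endian = "little")
  .tiff_write(path, raw, W, H, 32L, C, 3L)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  r <- .tiff_read(path)
  r$data
}
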