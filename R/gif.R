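# Minimal animated GIF89a writer.
#
# Frames are encoded with the fixed-width LZW "clear-code" technique: every
# pixel is emitted as a literal code and a Clear code is inserted before the
# decoder's dictionary would force a code-width increase. Larger files than
# true LZW, but simple, fast and bit-reproducible.

u16 <- function(x) as.raw(c(bitwAnd(x, 255), bitwAnd(bitwShiftR(x, 8), 255)))

# Quantize an h x w x 3 array in [0, 1] to <= 256 colors.
# Returns list(index = h x w integer matrix (0-based), palette = n x 3 0..255)
quantize_frame <- function(img) {
  for (bits in c(8, 7, 6, 5, 4, 3, 2)) {
    lev <- 2^bits - 1
    base <- lev + 1
    q <- round(img * lev)
    code <- q[, , 1] * base^2 + q[, , 2] * base + q[, , 3]
    pal_codes <- sort(unique(as.vector(code)))
    if (length(pal_codes) <= 256) {
      idx <- matrix(match(code, pal_codes) - 1L, nrow = dim(img)[1])
      palette <- cbind(
        round((pal_codes %/% base^2) * 255 / lev),
        round(((pal_codes %/% base) %% base) * 255 / lev),
        round((pal_codes %% base) * 255 / lev)
      )
      return(list(index = idx, palette = palette))
    }
  }
  stop("could not quantize frame to 256 colors")
}

lzw_uncompressed <- function(indices, code_bits) {
  clear <- 2^code_bits
  eoi <- clear + 1
  width <- code_bits + 1
  run <- 2^code_bits - 2
  n <- length(indices)
  starts <- seq(1, n, by = run)
  codes <- integer(0)
  chunks <- purrr::map(starts, function(s) {
    c(clear, indices[s:min(s + run - 1, n)])
  })
  codes <- c(unlist(chunks), eoi)
  bits <- outer(codes, 0:(width - 1), function(cc, b) bitwAnd(bitwShiftR(cc, b), 1L))
  bitvec <- as.integer(t(bits))
  pad <- (8 - length(bitvec) %% 8) %% 8
  packBits(c(bitvec, rep(0L, pad)), "raw")
}

sub_blocks <- function(bytes) {
  n <- length(bytes)
  starts <- seq(1, n, by = 255)
  out <- purrr::map(starts, function(s) {
    chunk <- bytes[s:min(s + 254, n)]
    c(as.raw(length(chunk)), chunk)
  })
  c(do.call(c, out), as.raw(0))
}

#' Write an animated GIF
#'
#' Assembles RGB frames (arrays `h x w x 3` with values in `[0, 1]`, e.g.
#' from [png::readPNG()]) into a looping animated GIF. Each frame is
#' quantized independently to at most 256 colours by uniform channel
#' rounding.
#'
#' @param frames List of `h x w x 3` arrays, identical dimensions.
#' @param path Output file.
#' @param delay_cs Delay between frames, centiseconds.
#' @return `path`, invisibly.
#' @export
write_gif <- function(frames, path, delay_cs = 5) {
  stopifnot(length(frames) >= 1)
  h <- dim(frames[[1]])[1]
  w <- dim(frames[[1]])[2]
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GIF89a"), con)
  # logical screen descriptor with a trivial 4-entry global table
  writeBin(c(u16(w), u16(h), as.raw(c(0x91, 0, 0))), con)
  writeBin(as.raw(c(0, 0, 0, 85, 85, 85, 170, 170, 170, 255, 255, 255)), con)
  # NETSCAPE loop-forever extension
  writeBin(c(as.raw(c(0x21, 0xFF, 0x0B)), charToRaw("NETSCAPE2.0"),
             as.raw(c(3, 1, 0, 0, 0))), con)
  for (fr in frames) {
    stopifnot(dim(fr)[1] == h, dim(fr)[2] == w)
    q <- quantize_frame(fr[, , 1:3, drop = FALSE])
    n_pal <- nrow(q$palette)
    tbl_bits <- max(2, ceiling(log2(n_pal)))
    pal <- rbind(q$palette, matrix(0, nrow = 2^tbl_bits - n_pal, ncol = 3))
    # graphic control extension
    writeBin(c(as.raw(c(0x21, 0xF9, 4, 0)), u16(delay_cs), as.raw(c(0, 0))), con)
    # image descriptor with local color table
    packed <- bitwOr(0x80, tbl_bits - 1)
    writeBin(c(as.raw(0x2C), u16(0), u16(0), u16(w), u16(h), as.raw(packed)), con)
    writeBin(as.raw(as.vector(t(pal))), con)
    code_bits <- max(2, tbl_bits)
    writeBin(as.raw(code_bits), con)
    # row-major pixel stream, top row first
    writeBin(sub_blocks(lzw_uncompressed(as.vector(t(q$index)), code_bits)), con)
  }
  writeBin(as.raw(0x3B), con)
  invisible(path)
}
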