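#' Assemble rendered frames into an animated GIF
#'
#' Reads the PNG frames in the order given, builds one shared color table
#' (quantizing if the pooled frames exceed 256 colors), and writes a looping
#' GIF89a in which each map plays for `spec$frame_duration_s` seconds. The
#' PNG frames remain on disk so any external video tool can consume them
#' instead. Output is written atomically.
#'
#' @param frame_paths character vector of PNG paths, in window order (the
#'   output follows this order).
#' @param spec a [render_spec()] (only `frame_duration_s` is used).
#' @param path output GIF path.
#' @return `path`, invisibly.
#' @export
assemble_animation <- function(frame_paths, spec = render_spec(), path) {
  if (!length(frame_paths)) stop("no frames", call. = FALSE)
  missing <- frame_paths[!file.exists(frame_paths)]
  if (length(missing))
    stop("missing frame file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  frames <- lapply(frame_paths, function(p) {
    a <- png::readPNG(p)
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    if (dim(a)[3] == 4) {           # composite alpha over white
      al <- a[, , 4]
      a <- a[, , 1:3] * rep(al, 3) + (1 - rep(al, 3))
      dim(a) <- c(dim(al), 3)
    }
    round(a[, , 1:3] * 255)
  })
  dm <- dim(frames[[1]])
  for (f in frames) if (!identical(dim(f), dm))
    stop("frames differ in size", call. = FALSE)

  keys <- lapply(frames, function(f)
    f[, , 1] * 65536 + f[, , 2] * 256 + f[, , 3])
  pal_keys <- sort(unique(unlist(lapply(keys, unique))))
  if (length(pal_keys) > 256) {     # 5 bits/channel quantization
    q <- function(k) {
      r <- k %/% 65536; g <- (k %/% 256) %% 256; b <- k %% 256
      (r %/% 8 * 8 + 4) * 65536 + (g %/% 8 * 8 + 4) * 256 + (b %/% 8 * 8 + 4)
    }
    keys <- lapply(keys, q)
    tab <- sort(table(unlist(keys)), decreasing = TRUE)
    pal_keys <- as.numeric(names(tab))
    if (length(pal_keys) > 256) {
      keep <- pal_keys[1:256]
      kr <- keep %/% 65536; kg <- (keep %/% 256) %% 256; kb <- keep %% 256
      remap <- function(k) {
        u <- sort(unique(k))
        nearest <- vapply(u, function(kk) {
          r <- kk %/% 65536; g <- (kk %/% 256) %% 256; b <- kk %% 256
          keep[which.min((r - kr)^2 + (g - kg)^2 + (b - kb)^2)]
        }, numeric(1))
        matrix(nearest[match(k, u)], nrow(k), ncol(k))
      }
      keys <- lapply(keys, remap)
      pal_keys <- keep
    }
    pal_keys <- sort(pal_keys)
  }
  palette <- cbind(pal_keys %/% 65536, (pal_keys %/% 256) %% 256,
                   pal_keys %% 256)
  idx <- lapply(keys, function(k)
    matrix(match(as.numeric(k), pal_keys) - 1L, nrow(k), ncol(k)))
  delay_cs <- max(1L, as.integer(round(spec$frame_duration_s * 100)))
  atomic_write(path, function(tmp)
    write_gif(idx, palette, delay_cs, tmp))
  invisible(path)
}

# Minimal GIF89a writer. `frames` are h x w 0-based palette-index matrices,
# `palette` an n x 3 matrix of 0..255. LZW uses literal codes with periodic
# clear codes, which every decoder accepts.
write_gif <- function(frames, palette, delay_cs, path) {
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  np <- nrow(palette)
  gs <- max(1L, ceiling(log2(np)))        # global color table size exponent-1
  slots <- 2L^gs
  if (slots < np) { gs <- gs + 1L; slots <- 2L^gs }
  pal <- rbind(palette, matrix(0L, slots - np, 3))

  u16 <- function(v) as.raw(c(v %% 256, v %/% 256))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("GIF89a"), con)
  writeBin(u16(w), con); writeBin(u16(h), con)
  writeBin(as.raw(c(bitwOr(0xF0, gs - 1L), 0, 0)), con)  # GCT, 8-bit res
  writeBin(as.raw(as.integer(t(pal))), con)
  # NETSCAPE looping extension (loop forever)
  writeBin(as.raw(c(0x21, 0xFF, 0x0B)), con)
  writeBin(charToRaw("NETSCAPE2.0"), con)
  writeBin(as.raw(c(0x03, 0x01, 0x00, 0x00, 0x00)), con)
  cs <- max(2L, gs)
  for (f in frames) {
    writeBin(as.raw(c(0x21, 0xF9, 0x04, 0x00)), con)     # GCE, no transparency
    writeBin(u16(delay_cs), con)
    writeBin(as.raw(c(0x00, 0x00)), con)
    writeBin(as.raw(0x2C), con)                          # image descriptor
    writeBin(u16(0), con); writeBin(u16(0), con)
    writeBin(u16(w), con); writeBin(u16(h), con)
    writeBin(as.raw(0x00), con)
    writeBin(as.raw(cs), con)
    bytes <- gif_lzw_literal(as.integer(t(f)), cs)       # row-major pixels
    i <- 1L
    while (i <= length(bytes)) {
      j <- min(i + 254L, length(bytes))
      writeBin(as.raw(j - i + 1L), con)
      writeBin(bytes[i:j], con)
      i <- j + 1L
    }
    writeBin(as.raw(0x00), con)                          # block terminator
  }
  writeBin(as.raw(0x3B), con)                            # trailer
  invisible(path)
}

# LZW stream of literal codes: a clear code is emitted before the decoder's
# growing table would force a wider code, so all codes stay cs+1 bits.
gif_lzw_literal <- function(pix, cs) {
  clear <- 2L^cs
  eoi <- clear + 1L
  W <- cs + 1L
  chunk <- 2L^cs - 3L
  n <- length(pix)
  starts <- seq(1L, n, by = chunk)
  codes <- unlist(lapply(starts, function(s)
    c(clear, pix[s:min(s + chunk - 1L, n)])), use.names = FALSE)
  codes <- c(codes, eoi)
  bits <- matrix(0L, nrow = W, ncol = length(codes))
  for (b in seq_len(W))
    bits[b, ] <- bitwAnd(bitwShiftR(codes, b - 1L), 1L)
  bv <- as.integer(bits)                  # LSB-first within each code
  pad <- (8L - length(bv) %% 8L) %% 8L
  if (pad) bv <- c(bv, integer(pad))
  as.raw(as.integer(2L^(0:7) %*% matrix(bv, nrow = 8L)))
}
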