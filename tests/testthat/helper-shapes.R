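# Geometric fixtures drawn in code.

drawDisk <- function(nr, nc, center, radius, value = 1) {
  rr <- outer(seq_len(nr) - center[1], rep(1, nc))
  cc <- outer(rep(1, nr), seq_len(nc) - center[2])
  (rr^2 + cc^2 <= radius^2) * value
}

addGaussianSpot <- function(img, center, sigma, amplitude) {
  rr <- outer(seq_len(nrow(img)) - center[1], rep(1, ncol(img)))
  cc <- outer(rep(1, nrow(img)), seq_len(ncol(img)) - center[2])
  img + amplitude * exp(-(rr^2 + cc^2) / (2 * sigma^2))
}

# minimal independent BMP writers (uncompressed), for the reader tests
writeBMP8 <- function(gray255, path) {
  w <- ncol(gray255); h <- nrow(gray255)
  rowBytes <- ((w + 3) %/% 4) * 4
  dataOffset <- 14 + 40 + 256 * 4
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x42, 0x4D)), con)
  writeBin(as.integer(dataOffset + rowBytes * h), con, size = 4,
           endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(dataOffset), con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(8L, con, size = 2, endian = "little")
  writeBin(rep(0L, 6), con, size = 4, endian = "little")
  pal <- as.vector(rbind(0:255, 0:255, 0:255, rep(0, 256))) # B,G,R,0
  writeBin(as.raw(pal), con)
  for (r in rev(seq_len(h))) {
    row <- as.integer(gray255[r, ])
    writeBin(as.raw(c(row, rep(0, rowBytes - w))), con)
  }
  invisible(path)
}

writeBMP24 <- function(rgb255, path) { # rows x cols x 3 (R,G,B)
  w <- dim(rgb255)[2]; h <- dim(rgb255)[1]
  rowBytes <- ((3 * w + 3) %/% 4) * 4
  dataOffset <- 14 + 40
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x42, 0x4D)), con)
  writeBin(as.integer(dataOffset + rowBytes * h), con, size = 4,
           endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(as.integer(dataOffset), con, size = 4, endian = "little")
  writeBin(40L, con, size = 4, endian = "little")
  writeBin(as.integer(w), con, size = 4, endian = "little")
  writeBin(as.integer(h), con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")
  writeBin(24L, con, size = 2, endian = "little")
  writeBin(rep(0L, 6), con, size = 4, endian = "little")
  for (r in rev(seq_len(h))) {
    px <- as.vector(rbind(rgb255[r, , 3], rgb255[r, , 2], rgb255[r, , 1]))
    writeBin(as.raw(c(as.integer(px), rep(0, rowBytes - 3 * w))), con)
  }
  invisible(path)
}
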