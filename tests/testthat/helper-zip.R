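# Minimal ZIP writer (stored entries, no compression) so the CLI's bundle
# expansion can be tested without a system zip tool. 32-bit ops are done on
# split 16-bit halves because R integers cannot hold unsigned 32-bit values.

xor32 <- function(a, b) {
  bitwXor(a %% 65536, b %% 65536) +
    bitwXor(a %/% 65536, b %/% 65536) * 65536
}

crc32_of <- function(bytes) {
  poly <- 0xEDB88320
  crc <- 4294967295
  for (b in as.integer(bytes)) {
    crc <- xor32(crc, b)
    for (k in 1:8) {
      odd <- crc %% 2
      crc <- (crc - odd) / 2
      if (odd) crc <- xor32(crc, poly)
    }
  }
  xor32(crc, 4294967295)
}

le_bytes <- function(x, n) {
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

write_stored_zip <- function(zipfile, paths) {
  con <- file(zipfile, "wb")
  on.exit(close(con))
  central <- list()
  offset <- 0
  for (p in paths) {
    data <- readBin(p, "raw", file.size(p))
    nm <- charToRaw(basename(p))
    crc <- crc32_of(data)
    header <- c(le_bytes(0x04034b50, 4), le_bytes(20, 2), le_bytes(0, 2),
                le_bytes(0, 2), le_bytes(0, 2), le_bytes(0x21, 2),
                le_bytes(crc, 4), le_bytes(length(data), 4),
                le_bytes(length(data), 4), le_bytes(length(nm), 2),
                le_bytes(0, 2))
    writeBin(c(header, nm, data), con)
    central[[length(central) + 1L]] <-
      c(le_bytes(0x02014b50, 4), le_bytes(20, 2), le_bytes(20, 2),
        le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 2), le_bytes(0x21, 2),
        le_bytes(crc, 4), le_bytes(length(data), 4), le_bytes(length(data), 4),
        le_bytes(length(nm), 2), le_bytes(0, 2), le_bytes(0, 2),
        le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 4), le_bytes(offset, 4), nm)
    offset <- offset + length(header) + length(nm) + length(data)
  }
  cd <- do.call(c, central)
  writeBin(cd, con)
  writeBin(c(le_bytes(0x06054b50, 4), le_bytes(0, 2), le_bytes(0, 2),
             le_bytes(length(paths), 2), le_bytes(length(paths), 2),
             le_bytes(length(cd), 4), le_bytes(offset, 4), le_bytes(0, 2)),
           con)
  zipfile
}
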