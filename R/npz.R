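# Minimal NPZ (ZIP of NumPy .npy members) reader/writer.
#
# No HDF5/NPZ binding ships with this R installation, and the on-disk cohort
# format must be portable to the Python ecosystem, so the container is written
# directly: .npy v1.0 members (float64/int64, Fortran order flagged in the
# header) inside a stored (uncompressed) ZIP. CRC32 is computed with a
# table-driven register, vectorized across 256 lockstep chunks for large
# payloads and spliced with GF(2) zero-advance operators. The reader
# additionally inflates deflate-compressed members so archives produced by
# numpy.savez_compressed load too.

# 32-bit values are carried as doubles (R integers cannot hold 0x80000000);
# XOR acts on 16-bit halves.
bx32 <- function(a, b) {
  bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
}

.crc_env <- new.env(parent = emptyenv())

crc_table <- function() {
  if (!is.null(.crc_env$tab)) return(.crc_env$tab)
  tab <- numeric(256)
  for (i in 0:255) {
    cr <- i
    for (k in 1:8) {
      cr <- if (cr %% 2) bx32(cr %/% 2, 3988292384) else cr %/% 2 # 0xEDB88320
    }
    tab[i + 1] <- cr
  }
  .crc_env$tab <- tab
  tab
}

# GF(2) linear-operator tools: a 32x32 bit matrix is 32 column words.
gf2_matvec <- function(cols, v) {
  r <- 0
  j <- 0L
  while (v > 0) {
    if (v %% 2) r <- bx32(r, cols[j + 1L])
    v <- v %/% 2
    j <- j + 1L
  }
  r
}

gf2_matmul <- function(a, b) vapply(b, function(col) gf2_matvec(a, col), numeric(1))

# operator advancing a (reflected) CRC register by one zero bit
gf2_zbit <- function() c(3988292384, 2^(0:30))

# operator for n zero bytes, by binary exponentiation
gf2_zeros_op <- function(n) {
  op <- Reduce(function(m, i) gf2_matmul(m, m), 1:3, accumulate = FALSE,
               init = gf2_zbit()) # Zbit^8
  acc <- NULL
  while (n > 0) {
    if (n %% 2) acc <- if (is.null(acc)) op else gf2_matmul(acc, op)
    n <- n %/% 2
    if (n > 0) op <- gf2_matmul(op, op)
  }
  if (is.null(acc)) vapply(0:31, function(j) 2^j, numeric(1)) else acc
}

# zero-initialized (unconditioned) CRC register after processing `ints`
crc_raw_linear <- function(ints, tab) {
  crc <- 0
  for (i in seq_along(ints)) {
    crc <- bx32(crc %/% 256, tab[bitwXor(crc %% 256, ints[i]) + 1L])
  }
  crc
}

crc32_num <- function(bytes) {
  tab <- crc_table()
  n <- length(bytes)
  ints <- as.integer(bytes)
  if (n < 8192L) {
    raw0 <- crc_raw_linear(ints, tab)
  } else {
    # process 256 chunks in lockstep (vectorized), then splice their
    # registers together with zero-byte advance operators
    K <- 256L
    m <- n %/% K
    rem <- ints[(K * m + 1L):n]
    if (K * m == n) rem <- integer(0)
    mat <- matrix(ints[seq_len(K * m)], nrow = K, byrow = TRUE)
    st <- numeric(K)
    for (j in seq_len(m)) {
      st <- bx32(st %/% 256, tab[bitwXor(st %% 256, mat[, j]) + 1L])
    }
    op <- gf2_zeros_op(m)
    acc <- 0
    for (k in seq_len(K)) acc <- bx32(gf2_matvec(op, acc), st[k])
    if (length(rem)) {
      opr <- gf2_zeros_op(length(rem))
      acc <- bx32(gf2_matvec(opr, acc), crc_raw_linear(rem, tab))
    }
    raw0 <- acc
  }
  # conditioning: init register 0xFFFFFFFF, final xor 0xFFFFFFFF
  init_part <- gf2_matvec(gf2_zeros_op(n), 4294967295)
  bx32(bx32(raw0, init_part), 4294967295)
}

crc32_raw <- function(bytes) u32_raw(crc32_num(bytes))

u16_raw <- function(x) as.raw(c(x %% 256, (x %/% 256) %% 256))

u32_raw <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256, (x %/% 16777216) %% 256))
}

raw_u32 <- function(b) sum(as.numeric(b) * c(1, 256, 65536, 16777216))
raw_u16 <- function(b) sum(as.numeric(b) * c(1, 256))

npy_bytes <- function(x) {
  storage.mode(x) <- "double"
  dm <- dim(x)
  if (is.null(dm)) dm <- length(x)
  shape <- paste0("(", paste0(dm, ",", collapse = " "), ")")
  shape <- sub(", \\)$", ")", shape)
  if (length(dm) == 1) shape <- paste0("(", dm, ",)")
  hdr <- paste0("{'descr': '<f8', 'fortran_order': True, 'shape': ", shape, ", }")
  pre_len <- 10L
  pad <- 64L - ((pre_len + nchar(hdr) + 1L) %% 64L)
  if (pad == 64L) pad <- 0L
  hdr <- paste0(hdr, strrep(" ", pad), "\n")
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
  writeBin(u16_raw(nchar(hdr)), con)
  writeBin(charToRaw(hdr), con)
  writeBin(as.numeric(x), con, size = 8L, endian = "little")
  rawConnectionValue(con)
}

npy_parse <- function(bytes) {
  if (!identical(bytes[1:6], c(as.raw(0x93), charToRaw("NUMPY"))))
    stop("not an npy member")
  major <- as.integer(bytes[7])
  if (major == 1L) {
    hlen <- raw_u16(bytes[9:10])
    hstart <- 11L
  } else {
    hlen <- raw_u32(bytes[9:12])
    hstart <- 13L
  }
  hdr <- rawToChar(bytes[hstart:(hstart + hlen - 1L)])
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", hdr)
  fortran <- grepl("'fortran_order':\\s*True", hdr)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", hdr)
  dm <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  dm <- dm[!is.na(dm)]
  data <- bytes[(hstart + hlen):length(bytes)]
  n <- if (length(dm)) prod(dm) else 1L
  v <- switch(descr,
    "<f8" = readBin(data, numeric(), n, size = 8L, endian = "little"),
    "<f4" = readBin(data, numeric(), n, size = 4L, endian = "little"),
    "<i8" = {
      lo <- readBin(data, integer(), 2L * n, size = 4L, endian = "little")
      low <- as.numeric(lo[seq(1L, 2L * n, 2L)])
      low[low < 0] <- low[low < 0] + 4294967296
      low + 4294967296 * as.numeric(lo[seq(2L, 2L * n, 2L)])
    },
    "<i4" = as.numeric(readBin(data, integer(), n, size = 4L, endian = "little")),
    stop("unsupported npy dtype: ", descr)
  )
  if (length(dm) <= 1L) return(v)
  if (fortran) array(v, dm) else aperm(array(v, rev(dm)), rev(seq_along(dm)))
}

#' Write a list of arrays to an NPZ archive
#' @param x named list of numeric vectors/arrays (and optionally raw vectors,
#'   stored verbatim under their own names)
#' @param path output file path
#' @noRd
npz_write <- function(x, path) {
  stopifnot(length(names(x)) == length(x))
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  entries <- list()
  pos <- 0L
  for (nm in names(x)) {
    payload <- if (is.raw(x[[nm]])) x[[nm]] else npy_bytes(x[[nm]])
    fname <- if (is.raw(x[[nm]])) nm else paste0(nm, ".npy")
    fn <- charToRaw(fname)
    crc <- crc32_raw(payload)
    lfh <- c(u32_raw(0x04034b50), u16_raw(20), u16_raw(0), u16_raw(0),
             u16_raw(0), u16_raw(0), crc, u32_raw(length(payload)),
             u32_raw(length(payload)), u16_raw(length(fn)), u16_raw(0), fn)
    writeBin(lfh, con)
    writeBin(payload, con)
    entries[[length(entries) + 1L]] <- list(fn = fn, crc = crc,
                                            size = length(payload), off = pos)
    pos <- pos + length(lfh) + length(payload)
  }
  cd_start <- pos
  cd_len <- 0L
  for (e in entries) {
    cde <- c(u32_raw(0x02014b50), u16_raw(20), u16_raw(20), u16_raw(0),
             u16_raw(0), u16_raw(0), u16_raw(0), e$crc, u32_raw(e$size),
             u32_raw(e$size), u16_raw(length(e$fn)), u16_raw(0), u16_raw(0),
             u16_raw(0), u16_raw(0), u32_raw(0), u32_raw(e$off), e$fn)
    writeBin(cde, con)
    cd_len <- cd_len + length(cde)
  }
  eocd <- c(u32_raw(0x06054b50), u16_raw(0), u16_raw(0),
            u16_raw(length(entries)), u16_raw(length(entries)),
            u32_raw(cd_len), u32_raw(cd_start), u16_raw(0))
  writeBin(eocd, con)
  invisible(path)
}

inflate_raw <- function(deflated, usize, crc_bytes) {
  # wrap a raw deflate stream in a gzip envelope (with the CRC recorded in the
  # ZIP central directory) so memDecompress can read it
  gz <- c(as.raw(c(0x1f, 0x8b, 0x08, 0, 0, 0, 0, 0, 0, 0xff)), deflated,
          crc_bytes, u32_raw(usize %% 4294967296))
  memDecompress(gz, type = "gzip")
}

#' Read an NPZ archive into a named list
#' @noRd
npz_read <- function(path) {
  bytes <- readBin(path, raw(), file.info(path)$size)
  n <- length(bytes)
  # locate end-of-central-directory record
  tail_start <- max(1L, n - 65557L)
  win <- bytes[tail_start:n]
  sig <- c(as.raw(0x50), as.raw(0x4b), as.raw(0x05), as.raw(0x06))
  hits <- which(win == sig[1])
  eocd <- NA_integer_
  for (h in rev(hits)) {
    if (h + 3L <= length(win) && identical(win[h:(h + 3L)], sig)) {
      eocd <- tail_start + h - 1L
      break
    }
  }
  if (is.na(eocd)) stop("not a ZIP/NPZ file: ", path)
  n_entries <- raw_u16(bytes[(eocd + 10L):(eocd + 11L)])
  cd_off <- raw_u32(bytes[(eocd + 16L):(eocd + 19L)])
  out <- list()
  p <- cd_off + 1L
  for (i in seq_len(n_entries)) {
    stopifnot(raw_u32(bytes[p:(p + 3L)]) == 0x02014b50)
    method <- raw_u16(bytes[(p + 10L):(p + 11L)])
    crc_b <- bytes[(p + 16L):(p + 19L)]
    csize <- raw_u32(bytes[(p + 20L):(p + 23L)])
    usize <- raw_u32(bytes[(p + 24L):(p + 27L)])
    fnlen <- raw_u16(bytes[(p + 28L):(p + 29L)])
    exlen <- raw_u16(bytes[(p + 30L):(p + 31L)])
    cmlen <- raw_u16(bytes[(p + 32L):(p + 33L)])
    lho <- raw_u32(bytes[(p + 42L):(p + 45L)])
    fname <- rawToChar(bytes[(p + 46L):(p + 45L + fnlen)])
    # local header gives the data offset (its own fnlen/extra may differ)
    lp <- lho + 1L
    lfnlen <- raw_u16(bytes[(lp + 26L):(lp + 27L)])
    lexlen <- raw_u16(bytes[(lp + 28L):(lp + 29L)])
    dstart <- lp + 30L + lfnlen + lexlen
    payload <- if (csize > 0) bytes[dstart:(dstart + csize - 1L)] else raw(0)
    if (method == 8L) payload <- inflate_raw(payload, usize, crc_b)
    else if (method != 0L) stop("unsupported ZIP compression method: ", method)
    key <- sub("\\.npy$", "", fname)
    out[[key]] <- if (grepl("\\.npy$", fname)) npy_parse(payload) else payload
    p <- p + 46L + fnlen + exlen + cmlen
  }
  out
}
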