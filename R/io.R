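#' Share files and trusted-initializer streams on disk
#'
#' One party's side of a shared tensor is persisted as a small binary file:
#' header = magic `"MPCSHR"`, a version byte, the ring width \eqn{\lambda},
#' the fractional and integer bit counts, then row and column counts as
#' 32-bit words; body = row-major \eqn{\lambda}-bit little-endian words. One
#' file per party per tensor, so an owner can mail each processor its share
#' and nothing else.
#'
#' @param share One party's share matrix/vector (pattern doubles).
#' @param path File path.
#' @param fmt An [fp_format()].
#' @return `write_share_file()` returns `path` invisibly;
#'   `read_share_file()` returns a list with `share` (matrix) and `fmt`.
#' @export
write_share_file <- function(share, path, fmt) {
  m <- if (is.null(dim(share))) matrix(share, ncol = 1) else share
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MPCSHR"), con)
  writeBin(as.raw(c(1L, fmt$lam, fmt$a, fmt$b)), con)
  writeBin(as.integer(c(nrow(m), ncol(m))), con, size = 4, endian = "little")
  writeBin(pack_words(as.numeric(t(m)), fmt$lam), con)
  invisible(path)
}

#' @rdname write_share_file
#' @export
read_share_file <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 6))
  if (magic != "MPCSHR") stop("not a share file: bad magic in ", path)
  hdr <- as.integer(readBin(con, "raw", 4))
  if (hdr[1] != 1L) stop("unsupported share file version ", hdr[1])
  lam <- hdr[2]; a <- hdr[3]; b <- hdr[4]
  dims <- readBin(con, "integer", 2, size = 4, endian = "little")
  words <- unpack_words(readBin(con, "raw", dims[1] * dims[2] * (lam / 8)), lam)
  share <- matrix(words, dims[1], dims[2], byrow = TRUE)
  list(share = share, fmt = fp_format(a, b, lam))
}

# pattern doubles -> little-endian lam-bit words as raw
pack_words <- function(x, lam) {
  full <- writeBin(x, raw(), size = 8, endian = "little")
  if (lam == 64) return(full)
  bytes <- lam / 8
  keep <- as.vector(outer(seq_len(bytes), (seq_along(x) - 1) * 8, `+`))
  full[keep]
}

unpack_words <- function(r, lam) {
  bytes <- lam / 8
  n <- length(r) / bytes
  if (lam < 64) {
    full <- raw(8 * n)
    idx <- as.vector(outer(seq_len(bytes), (seq_len(n) - 1) * 8, `+`))
    full[idx] <- r
    r <- full
  }
  readBin(r, "double", n, size = 8, endian = "little")
}

#' Persist and reload trusted-initializer streams
#'
#' Each party's stream is a file of typed records in consumption order
#' (tag byte + payload): tag 1 = matrix triple (three dims, then the party's
#' shares of U, V, W), tag 2 = a block of elementwise ring triples, tag 3 =
#' a block of \eqn{Z_2} triples (bytes), tag 4 = a block of masked bit pairs
#' (bit byte + ring word per pair).
#'
#' @param rand A `ti_randomness` object from [ti_gen()].
#' @param path_alice,path_bob Output stream files.
#' @param fmt An [fp_format()].
#' @return `write_ti_streams()` the paths invisibly; `read_ti_streams()` a
#'   reassembled `ti_randomness`.
#' @export
write_ti_streams <- function(rand, path_alice, path_bob, fmt) {
  lam <- fmt$lam
  for (side in c("alice", "bob")) {
    path <- if (side == "alice") path_alice else path_bob
    con <- file(path, "wb")
    writeBin(charToRaw("MPCTIS"), con)
    writeBin(as.raw(c(1L, lam)), con)
    for (tr in rand$mt) {
      writeBin(as.raw(1L), con)
      writeBin(as.integer(tr$dims), con, size = 4, endian = "little")
      writeBin(pack_words(as.numeric(t(tr$u[[side]])), lam), con)
      writeBin(pack_words(as.numeric(t(tr$v[[side]])), lam), con)
      writeBin(pack_words(as.numeric(t(tr$w[[side]])), lam), con)
    }
    sfx <- if (side == "alice") "A" else "B"
    net <- length(rand$et$uA)
    writeBin(as.raw(2L), con)
    writeBin(as.integer(net), con, size = 4, endian = "little")
    if (net > 0) for (nm in c("u", "v", "w"))
      writeBin(pack_words(rand$et[[paste0(nm, sfx)]], lam), con)
    nbt <- length(rand$bt$uA)
    writeBin(as.raw(3L), con)
    writeBin(as.integer(nbt), con, size = 4, endian = "little")
    if (nbt > 0) for (nm in c("u", "v", "w"))
      writeBin(as.raw(rand$bt[[paste0(nm, sfx)]]), con)
    nmb <- length(rand$mb$r2A)
    writeBin(as.raw(4L), con)
    writeBin(as.integer(nmb), con, size = 4, endian = "little")
    if (nmb > 0) {
      writeBin(as.raw(rand$mb[[paste0("r2", sfx)]]), con)
      writeBin(pack_words(rand$mb[[paste0("rR", sfx)]], lam), con)
    }
    close(con)
  }
  invisible(c(path_alice, path_bob))
}

#' @rdname write_ti_streams
#' @export
read_ti_streams <- function(path_alice, path_bob, fmt) {
  lam <- fmt$lam
  read_side <- function(path) {
    con <- file(path, "rb")
    on.exit(close(con))
    if (rawToChar(readBin(con, "raw", 6)) != "MPCTIS")
      stop("not a TI stream file: ", path)
    hdr <- as.integer(readBin(con, "raw", 2))
    if (hdr[2] != lam) stop("TI stream ring width ", hdr[2], " != format ", lam)
    out <- list(mt = list(), et = NULL, bt = NULL, mb = NULL)
    repeat {
      tag <- readBin(con, "raw", 1)
      if (length(tag) == 0) break
      tag <- as.integer(tag)
      if (tag == 1L) {
        d <- readBin(con, "integer", 3, size = 4, endian = "little")
        rd <- function(nr, nc) matrix(unpack_words(
          readBin(con, "raw", nr * nc * lam / 8), lam), nr, nc, byrow = TRUE)
        out$mt[[length(out$mt) + 1L]] <-
          list(dims = d, u = rd(d[1], d[2]), v = rd(d[2], d[3]), w = rd(d[1], d[3]))
      } else if (tag == 2L) {
        n <- readBin(con, "integer", 1, size = 4, endian = "little")
        out$et <- if (n > 0) lapply(1:3, function(i)
          unpack_words(readBin(con, "raw", n * lam / 8), lam)) else
          rep(list(numeric(0)), 3)
      } else if (tag == 3L) {
        n <- readBin(con, "integer", 1, size = 4, endian = "little")
        out$bt <- if (n > 0) lapply(1:3, function(i)
          as.numeric(readBin(con, "raw", n))) else rep(list(numeric(0)), 3)
      } else if (tag == 4L) {
        n <- readBin(con, "integer", 1, size = 4, endian = "little")
        out$mb <- if (n > 0) list(as.numeric(readBin(con, "raw", n)),
                                  unpack_words(readBin(con, "raw", n * lam / 8), lam)) else
          list(numeric(0), numeric(0))
      } else stop("unknown TI stream record tag ", tag)
    }
    out
  }
  A <- read_side(path_alice); B <- read_side(path_bob)
  r <- new.env(parent = emptyenv())
  class(r) <- "ti_randomness"
  r$mt <- purrr::map2(A$mt, B$mt, function(a, b) {
    list(dims = a$dims,
         u = st_new(a$u, b$u, lam), v = st_new(a$v, b$v, lam),
         w = st_new(a$w, b$w, lam))
  })
  r$mt_cursor <- 0L
  r$et <- list(uA = A$et[[1]], uB = B$et[[1]], vA = A$et[[2]], vB = B$et[[2]],
               wA = A$et[[3]], wB = B$et[[3]])
  r$et_cursor <- 0L
  r$bt <- list(uA = A$bt[[1]], uB = B$bt[[1]], vA = A$bt[[2]], vB = B$bt[[2]],
               wA = A$bt[[3]], wB = B$bt[[3]])
  r$bt_cursor <- 0L
  r$mb <- list(r2A = A$mb[[1]], r2B = B$mb[[1]], rRA = A$mb[[2]], rRB = B$mb[[2]])
  r$mb_cursor <- 0L
  r
}

#' Read a delimited training table
#'
#' Comma- or tab-separated text with a header row; all feature columns must
#' be numeric and the label column must be named `label` with 0/1 values.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_lr_data <- function(path) {
  first <- readLines(path, n = 1)
  sep <- if (grepl("\t", first)) "\t" else ","
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                                      check.names = FALSE))
}

#' Write revealed model weights as delimited text
#'
#' @param fit A fitted model (any trainer).
#' @param path Output path (tab-separated: term, weight).
#' @export
write_weights <- function(fit, path) {
  utils::write.table(tidy(fit), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
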