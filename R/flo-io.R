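# Middlebury .flo flow-field format: little-endian float32 magic 202021.25
# ("PIEH"), int32 width, int32 height, then row-major interleaved (u, v)
# float32 pairs.

FLO_MAGIC <- 202021.25

#' Write a flow field in Middlebury .flo format
#'
#' @param flow A [flow_field()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flo <- function(flow, path) {
  assert_flow(flow)
  h <- nrow(flow$u); w <- ncol(flow$u)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(FLO_MAGIC, con, size = 4L, endian = "little")
  writeBin(as.integer(c(w, h)), con, size = 4L, endian = "little")
  inter <- array(0, c(2L, w, h))
  inter[1L, , ] <- t(flow$u)
  inter[2L, , ] <- t(flow$v)
  writeBin(as.numeric(inter), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a Middlebury .flo flow field
#'
#' @param path Input path.
#' @return A [flow_field()].
#' @export
read_flo <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "numeric", n = 1L, size = 4L, endian = "little")
  if (abs(magic - FLO_MAGIC) > 1e-3)
    stop("not a .flo file (bad magic): ", path, call. = FALSE)
  wh <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  w <- wh[1L]; h <- wh[2L]
  dat <- readBin(con, "numeric", n = 2L * w * h, size = 4L, endian = "little")
  inter <- array(dat, c(2L, w, h))
  flow_field(u = t(inter[1L, , , drop = TRUE]),
             v = t(inter[2L, , , drop = TRUE]))
}
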