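# Image serialization uses binary NetPBM (P6 for RGB, P5 for masks):
# self-describing, dependency-free, readable by every image tool. No PNG
# writer is available without extra dependencies.

#' Write an RGB array as a binary PPM (P6) file
#'
#' @param pixels H x W x 3 integer array with values in `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(pixels, path) {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", dim(pixels)[2], dim(pixels)[1]),
            con, eos = NULL)
  # interleave row-major: channel fastest, then column, then row
  writeBin(as.raw(as.integer(aperm(pixels, c(3, 2, 1)))), con)
  invisible(path)
}

#' Read a binary PPM (P6) file
#'
#' @param path file path.
#' @return H x W x 3 integer array.
#' @export
read_ppm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_pnm_header(con, "P6")
  vals <- as.integer(readBin(con, "raw", hdr$w * hdr$h * 3))
  aperm(array(vals, dim = c(3, hdr$w, hdr$h)), c(3, 2, 1))
}

#' Write a binary mask as a PGM (P5) file (0 / 255)
#'
#' @param mask logical matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(mask, path) {
  stopifnot(is.matrix(mask))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n255\n", ncol(mask), nrow(mask)),
            con, eos = NULL)
  writeBin(as.raw(ifelse(t(mask), 255L, 0L)), con)
  invisible(path)
}

#' Read a PGM (P5) mask file
#'
#' @param path file path.
#' @return logical matrix (`TRUE` where the stored value exceeds 127).
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- read_pnm_header(con, "P5")
  vals <- as.integer(readBin(con, "raw", hdr$w * hdr$h))
  t(matrix(vals > 127, hdr$w, hdr$h))
}

read_pnm_header <- function(con, magic) {
  tok <- character(0)
  while (length(tok) < 4) {
    ch <- readChar(con, 1, useBytes = TRUE)
    if (length(ch) == 0) stop("truncated PNM header")
    if (ch == "#") {  # comment line
      repeat {
        ch <- readChar(con, 1, useBytes = TRUE)
        if (length(ch) == 0 || ch == "\n") break
      }
      next
    }
    if (grepl("^[[:space:]]$", ch)) {
      next
    }
    # accumulate a token
    word <- ch
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0 || grepl("^[[:space:]]$", ch)) break
      word <- paste0(word, ch)
    }
    tok <- c(tok, word)
  }
  if (tok[1] != magic) stop(sprintf("expected %s file, got %s",
                                    magic, tok[1]))
  list(w = as.integer(tok[2]), h = as.integer(tok[3]),
       maxval = as.integer(tok[4]))
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
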