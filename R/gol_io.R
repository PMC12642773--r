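#' Read and write cellular-automaton patterns
#'
#' Two plain-text formats are supported: run-length encoding (RLE, the common
#' interchange format: `b` = off, `o` = on, `$` = end of row, `!` = end of
#' pattern, with an optional `x = ..., y = ...` header and `#` comment lines)
#' and the `.cells` format (one text row per lattice row, `.` = off, `O` =
#' on, `!` comment lines).
#'
#' @param path File path.
#' @param origin Global `(row, col)` for the pattern's top-left corner.
#' @return `read_rle()`/`read_cells()` return a [gol_grid()].
#' @export
read_rle <- function(path, origin = c(1L, 1L)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  lines <- lines[!grepl("^\\s*x\\s*=", lines)]
  body <- paste(lines, collapse = "")
  body <- sub("!.*$", "", body)
  body <- gsub("\\s", "", body)
  cells <- list()
  r <- 0L; cc <- 0L
  count <- 0L
  for (ch in strsplit(body, "")[[1]]) {
    if (grepl("[0-9]", ch)) {
      count <- count * 10L + as.integer(ch)
    } else {
      n <- max(count, 1L)
      if (ch == "b") {
        cc <- cc + n
      } else if (ch == "o") {
        if (n > 0) cells <- c(cells, list(cbind(rep(r, n), cc + seq_len(n) - 1L)))
        cc <- cc + n
      } else if (ch == "$") {
        r <- r + n
        cc <- 0L
      } else {
        stop("unexpected RLE character: ", ch)
      }
      count <- 0L
    }
  }
  cells <- if (length(cells)) do.call(rbind, cells) else matrix(integer(0), ncol = 2)
  gol_grid(sweep(cells, 2, as.integer(origin), "+"))
}

#' @rdname read_rle
#' @param grid A `Grid` to serialize.
#' @param comment Optional comment line written to the header.
#' @export
write_rle <- function(grid, path, comment = NULL) {
  live <- live_cells(grid)
  if (nrow(live) == 0) {
    writeLines(c("#C empty", "x = 0, y = 0, rule = B3/S23", "!"), path)
    return(invisible(path))
  }
  r0 <- min(live[, 1]); c0 <- min(live[, 2])
  nr <- max(live[, 1]) - r0 + 1L
  nc <- max(live[, 2]) - c0 + 1L
  mat <- matrix(0L, nr, nc)
  mat[cbind(live[, 1] - r0 + 1L, live[, 2] - c0 + 1L)] <- 1L
  encode_run <- function(n, ch) if (n == 1) ch else paste0(n, ch)
  rows <- apply(mat, 1, function(row) {
    r <- rle(row)
    paste(mapply(encode_run, r$lengths, ifelse(r$values == 1L, "o", "b")),
          collapse = "")
  })
  # trailing dead runs in a row are redundant
  rows <- sub("(\\d*)b$", "", rows)
  header <- sprintf("x = %d, y = %d, rule = B3/S23", nc, nr)
  out <- c(if (!is.null(comment)) paste0("#C ", comment),
           header, paste0(paste(rows, collapse = "$"), "!"))
  writeLines(out, path)
  invisible(path)
}

#' @rdname read_rle
#' @export
read_cells <- function(path, origin = c(1L, 1L)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*!", lines)]
  cells <- list()
  for (i in seq_along(lines)) {
    on <- which(strsplit(lines[i], "")[[1]] %in% c("O", "*"))
    if (length(on)) cells <- c(cells, list(cbind(i - 1L, on - 1L)))
  }
  cells <- if (length(cells)) do.call(rbind, cells) else matrix(integer(0), ncol = 2)
  gol_grid(sweep(cells, 2, as.integer(origin), "+"))
}

#' @rdname read_rle
#' @export
write_cells <- function(grid, path, comment = NULL) {
  live <- live_cells(grid)
  if (nrow(live) == 0) {
    writeLines(c("! empty"), path)
    return(invisible(path))
  }
  r0 <- min(live[, 1]); c0 <- min(live[, 2])
  nr <- max(live[, 1]) - r0 + 1L
  nc <- max(live[, 2]) - c0 + 1L
  mat <- matrix(".", nr, nc)
  mat[cbind(live[, 1] - r0 + 1L, live[, 2] - c0 + 1L)] <- "O"
  out <- c(if (!is.null(comment)) paste0("! ", comment),
           apply(mat, 1, paste, collapse = ""))
  writeLines(out, path)
  invisible(path)
}
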