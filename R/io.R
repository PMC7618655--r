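#' Read a grayscale image
#'
#' Supported dialects: PGM "P2" (plain text) and "P5" (raw binary), 8- or
#' 16-bit. Intensities are rescaled to [0, 1] doubles (value / maxval).
#' PNG and DICOM are recognised by extension but not supported in this build
#' (no grayscale PNG/DICOM reader among the available R packages); they raise
#' an explicit error naming the dialect. Laterality is metadata carried by
#' manifests/configuration, never inferred from pixels.
#'
#' @param path image file path.
#' @return numeric matrix (rows = y, cols = x) in [0, 1] with attributes
#'   `maxval` and `path`.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("png", "dcm", "dicom")) {
    stop(sprintf("read_image: dialect '%s' is not supported in this build; use 8/16-bit PGM (P2/P5)", ext))
  }
  read_pgm(path)
}

#' Read a PGM image (P2 plain or P5 raw, 8/16-bit)
#'
#' @param path file path.
#' @return numeric matrix in [0, 1]; attribute `maxval` keeps the original
#'   bit depth (255 or 65535).
#' @export
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("read_pgm: unexpected end of file in header")
      if (ch == "#") {  # comment to end of line
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (length(ch) == 0L || ch == "\n") break
        }
        next
      }
      if (grepl("[ \t\r\n]", ch)) {
        if (length(tok)) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (!magic %in% c("P2", "P5")) {
    stop(sprintf("read_pgm: unsupported magic '%s' (need P2 or P5)", magic))
  }
  W <- as.integer(read_token()); H <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(W) || is.na(H) || is.na(maxval) || W < 1L || H < 1L ||
      !(maxval %in% c(255L, 65535L))) {
    stop("read_pgm: malformed header (need width, height, maxval in {255, 65535})")
  }
  n <- W * H
  if (magic == "P2") {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "[ \t\r\n]+")[[1]]))
    if (length(vals) < n || anyNA(vals[seq_len(n)])) {
      stop("read_pgm: pixel count mismatch or non-numeric pixel data")
    }
    vals <- vals[seq_len(n)]
  } else {
    bytes_per <- if (maxval > 255L) 2L else 1L
    raw_vals <- readBin(con, "integer", n = n, size = bytes_per,
                        signed = FALSE, endian = "big")
    if (length(raw_vals) < n) stop("read_pgm: truncated P5 pixel data")
    vals <- as.numeric(raw_vals)
  }
  img <- matrix(vals, nrow = H, ncol = W, byrow = TRUE) / maxval
  attr(img, "maxval") <- maxval
  attr(img, "path") <- path
  img
}

#' Write a PGM image
#'
#' @param img numeric matrix in [0, 1] (values are clamped).
#' @param path output path.
#' @param maxval 255 (8-bit) or 65535 (16-bit).
#' @param ascii write plain-text P2 instead of raw P5.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path, maxval = 255L, ascii = FALSE) {
  stopifnot(is.matrix(img), maxval %in% c(255L, 65535L))
  q <- round(pmin(pmax(img, 0), 1) * maxval)
  H <- nrow(q); W <- ncol(q)
  if (ascii) {
    con <- file(path, "wb")  # binary mode: unix line endings everywhere
    on.exit(close(con))
    writeChar(sprintf("P2\n%d %d\n%d\n", W, H, maxval), con, eos = NULL)
    rows <- apply(q, 1L, paste, collapse = " ")
    writeChar(paste0(paste(rows, collapse = "\n"), "\n"), con, eos = NULL)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n%d\n", W, H, maxval), con, eos = NULL)
    vals <- as.integer(t(q))
    writeBin(vals, con, size = if (maxval > 255L) 2L else 1L, endian = "big")
  }
  invisible(path)
}

#' Read a PTS landmark file
#'
#' Dialect: `version: 1`, `n_points: K`, `{`, K lines of `x y`, `}`.
#' Windows and Unix line endings are both accepted. Errors report the
#' offending line number.
#'
#' @param path file path.
#' @param schema optional [landmark_schema()]; when given, a full
#'   [landmark_set()] is returned and the point count is checked.
#' @return n x 2 matrix, or a `landmark_set` when `schema` is supplied.
#' @export
read_pts <- function(path, schema = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("read_pts: empty file: ", path)
  at <- function(i) trimws(lines[nonblank[i]])
  if (!grepl("^version:\\s*1$", at(1))) {
    stop(sprintf("read_pts: line %d: expected 'version: 1'", nonblank[1]))
  }
  m <- regmatches(at(2), regexec("^n_points:\\s*([0-9]+)$", at(2)))[[1]]
  if (length(m) < 2L) {
    stop(sprintf("read_pts: line %d: expected 'n_points: K'", nonblank[2]))
  }
  K <- as.integer(m[2])
  if (at(3) != "{") stop(sprintf("read_pts: line %d: expected '{'", nonblank[3]))
  if (length(nonblank) < 4L + K) {
    stop(sprintf("read_pts: line %d: expected %d point rows before '}'",
                 nonblank[length(nonblank)], K))
  }
  pts <- matrix(NA_real_, K, 2L)
  for (i in seq_len(K)) {
    row <- strsplit(at(3L + i), "[ \t]+")[[1]]
    vals <- suppressWarnings(as.numeric(row))
    if (length(vals) != 2L || anyNA(vals)) {
      stop(sprintf("read_pts: line %d: expected 'x y'", nonblank[3L + i]))
    }
    pts[i, ] <- vals
  }
  if (at(4L + K) != "}") {
    stop(sprintf("read_pts: line %d: expected '}' after %d points",
                 nonblank[4L + K], K))
  }
  colnames(pts) <- c("x", "y")
  if (is.null(schema)) pts else landmark_set(pts, schema)
}

#' Write a PTS landmark file
#'
#' Coordinates are written with 6 decimal places; a write/read round trip is
#' value-exact at that precision and preserves point order.
#'
#' @param l a [landmark_set()] or n x 2 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pts <- function(l, path) {
  pts <- if (inherits(l, "landmark_set")) l$points else as.matrix(l)
  con <- file(path, "wb")
  on.exit(close(con))
  body <- paste(sprintf("%.6f %.6f", pts[, 1], pts[, 2]), collapse = "\n")
  writeChar(sprintf("version: 1\nn_points: %d\n{\n%s\n}\n", nrow(pts), body),
            con, eos = NULL)
  invisible(path)
}

#' Write a landmark schema file
#'
#' Plain key-value dialect: `n_points: K`, one `role: i [j]` line per role
#' (1-based indices), and optional `curve_<name>: i j k ...` outline lines.
#'
#' @param schema a [landmark_schema()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(schema, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  out <- c(sprintf("n_points: %d", schema$n_points),
           vapply(names(schema$roles), function(r) {
             sprintf("%s: %s", r, paste(schema$roles[[r]], collapse = " "))
           }, ""),
           if (!is.null(schema$curves)) {
             vapply(names(schema$curves), function(cn) {
               sprintf("curve_%s: %s", cn,
                       paste(schema$curves[[cn]], collapse = " "))
             }, "")
           })
  writeChar(paste0(paste(out, collapse = "\n"), "\n"), con, eos = NULL)
  invisible(path)
}

#' Read a landmark schema file
#'
#' @param path file written by [write_schema()].
#' @return a [landmark_schema()].
#' @export
read_schema <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(trimws(lines))]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9_]+):\\s*(.*)$", lines))
  bad <- which(vapply(kv, length, 1L) < 3L)
  if (length(bad)) stop(sprintf("read_schema: malformed line %d", bad[1]))
  keys <- vapply(kv, `[`, "", 2L)
  vals <- vapply(kv, `[`, "", 3L)
  n_points <- as.integer(vals[keys == "n_points"][1])
  if (is.na(n_points)) stop("read_schema: missing n_points")
  is_curve <- startsWith(keys, "curve_")
  roles <- lapply(vals[keys != "n_points" & !is_curve],
                  function(v) as.integer(strsplit(trimws(v), "[ \t]+")[[1]]))
  names(roles) <- keys[keys != "n_points" & !is_curve]
  curves <- NULL
  if (any(is_curve)) {
    curves <- lapply(vals[is_curve],
                     function(v) as.integer(strsplit(trimws(v), "[ \t]+")[[1]]))
    names(curves) <- sub("^curve_", "", keys[is_curve])
  }
  landmark_schema(n_points, roles, curves)
}

#' Mirror a right-knee image/landmark pair into left-knee orientation
#'
#' The image is flipped about its vertical axis; landmark x-coordinates map
#' to `width - 1 - x` (0-based pixel-centre mirror) and the left/right
#' plateau-corner roles are swapped so role semantics stay anatomical.
#' Applying the flip twice is the identity.
#'
#' @param image grayscale matrix.
#' @param landmarks a [landmark_set()] (or NULL).
#' @return list with elements `image` and `landmarks`.
#' @export
flip_to_left <- function(image, landmarks = NULL) {
  W <- ncol(image)
  flipped <- image[, rev(seq_len(W)), drop = FALSE]
  attributes(flipped)$maxval <- attr(image, "maxval")
  lm <- landmarks
  if (!is.null(lm)) {
    pts <- lm$points
    pts[, 1] <- (W - 1) - pts[, 1]
    schema <- lm$schema
    swp <- schema$roles$plateau_corner_left
    schema$roles$plateau_corner_left <- schema$roles$plateau_corner_right
    schema$roles$plateau_corner_right <- swp
    lm <- landmark_set(pts, schema)
  }
  list(image = flipped, landmarks = lm)
}

#' Read a dataset manifest
#'
#' Comma-separated table with columns `id, image, pts, laterality` and
#' optionally `true_atfa` and `split`. Paths are resolved relative to the
#' manifest's directory. Ids must be unique and referenced files must exist.
#'
#' @param path manifest CSV path.
#' @param check_files verify referenced files exist (default TRUE).
#' @return data.frame with absolute `image`/`pts` paths.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  man <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "image", "pts", "laterality")
  miss <- setdiff(need, names(man))
  if (length(miss)) stop("read_manifest: missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(man$id)) stop("read_manifest: duplicate ids")
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  man$image <- resolve(man$image)
  man$pts <- resolve(man$pts)
  if (check_files) {
    for (col in c("image", "pts")) {
      missing_f <- !file.exists(man[[col]])
      if (any(missing_f)) {
        stop("read_manifest: missing ", col, " file(s): ",
             paste(head(man[[col]][missing_f], 3L), collapse = ", "))
      }
    }
  }
  man
}
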