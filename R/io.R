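# Image and ratings I/O.
#
# Images travel as NetPBM PGM/PPM (P2/P5 gray, P3/P6 color; 8- or 16-bit),
# which base R can read and write without external codecs, or as plain CSV
# matrices.  Color inputs are converted to luminance with Rec.709 weights.

#' Write a luminance matrix as a PGM image
#'
#' Binary (P5) grayscale NetPBM, 8- or 16-bit (big-endian).  Values are
#' clipped to `[0, 1]` and quantized to the full bit range, so a 16-bit
#' round trip is lossless to 1/65535.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @param bits 8 or 16 (default 16).
#' @return `path`, invisibly.
#' @export
write_pgm <- function(image, path, bits = 16L) {
  if (!bits %in% c(8L, 16L)) stop("bits must be 8 or 16")
  maxval <- 2L^bits - 1L
  q <- round(pmin(pmax(image, 0), 1) * maxval)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("P5\n%d %d\n%d", ncol(image), nrow(image), maxval), con)
  v <- as.integer(t(q))                 # row-major raster order
  if (bits == 8L) writeBin(as.raw(v), con)
  else writeBin(as.raw(rbind(v %/% 256L, v %% 256L)), con)
  invisible(path)
}

read_pnm <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  magic <- rawToChar(raw[1:2])
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported image format in ", path,
         " (need PGM/PPM: P2, P3, P5 or P6)")
  ascii <- magic %in% c("P2", "P3")
  channels <- if (magic %in% c("P3", "P6")) 3L else 1L
  # header: width, height, maxval as whitespace-separated tokens after the
  # magic, with optional '#' comments; scan byte-wise so binary pixel data
  # is never touched
  header_vals <- integer(0); pos <- 3L; tok <- ""
  in_comment <- FALSE
  while (length(header_vals) < 3L && pos <= length(raw)) {
    ch <- rawToChar(raw[pos]); pos <- pos + 1L
    if (in_comment) { if (ch == "\n") in_comment <- FALSE; next }
    if (ch == "#") { in_comment <- TRUE; next }
    if (grepl("[0-9]", ch)) tok <- paste0(tok, ch)
    else if (nzchar(tok)) { header_vals <- c(header_vals, as.integer(tok)); tok <- "" }
  }
  if (length(header_vals) < 3L) stop("truncated NetPBM header in ", path)
  w <- header_vals[1]; h <- header_vals[2]; maxval <- header_vals[3]
  n_px <- w * h * channels
  if (ascii) {
    txt <- gsub("#[^\n]*", " ", rawToChar(raw[3:length(raw)]))
    toks <- strsplit(trimws(txt), "[ \t\r\n]+")[[1]]
    if (length(toks) < n_px + 3L) stop("truncated pixel data in ", path)
    vals <- as.numeric(toks[3L + seq_len(n_px)])
  } else {
    body <- raw[pos:length(raw)]
    if (maxval > 255L) {
      if (length(body) < 2L * n_px) stop("truncated pixel data in ", path)
      m <- matrix(as.integer(body[seq_len(2L * n_px)]), nrow = 2L)
      vals <- m[1, ] * 256L + m[2, ]
    } else {
      if (length(body) < n_px) stop("truncated pixel data in ", path)
      vals <- as.integer(body[seq_len(n_px)])
    }
  }
  if (anyNA(vals)) stop("unparseable pixel data in ", path)
  list(values = vals, width = w, height = h, maxval = maxval,
       channels = channels)
}

#' Read an image as a luminance matrix
#'
#' Reads NetPBM images (`.pgm`, `.ppm`, `.pnm`; ASCII or binary, 8- or
#' 16-bit) or plain numeric CSV matrices, scales to `[0, 1]` by bit depth,
#' converts color to luminance with Rec.709 weights (0.2126, 0.7152,
#' 0.0722), and validates squareness and, when a config is supplied, the
#' dyadic size requirement.
#'
#' @param path Image path.
#' @param config Optional [pyramid_config()] to validate against.
#' @param linearize If `TRUE`, apply sRGB-to-linear conversion after
#'   scaling (for photographs; calibrated stimuli are assumed linear).
#' @return Luminance matrix in `[0, 1]`.
#' @export
read_image <- function(path, config = NULL, linearize = FALSE) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "tsv")) {
    img <- as.matrix(utils::read.csv(path, header = FALSE,
                                     sep = if (ext == "csv") "," else "\t"))
    storage.mode(img) <- "double"
    dimnames(img) <- NULL
  } else {
    p <- read_pnm(path)
    v <- p$values / p$maxval
    if (p$channels == 3L) {
      rgb <- matrix(v, ncol = 3L, byrow = TRUE)
      v <- rgb %*% c(0.2126, 0.7152, 0.0722)
    }
    img <- matrix(v, nrow = p$height, ncol = p$width, byrow = TRUE)
  }
  if (linearize) {
    img <- ifelse(img <= 0.04045, img / 12.92, ((img + 0.055) / 1.055)^2.4)
  }
  if (nrow(img) != ncol(img))
    stop(sprintf("image %s is not square (%d x %d)", path, nrow(img), ncol(img)))
  if (!is.null(config)) validate_image(img, config)
  img
}

#' Read behavioral ratings
#'
#' Reads the ratings CSV dialect — columns `image_id`, `observer_id`,
#' `task` (`texturality` or `similarity`), `response` in `{0, 1}` — and
#' pools responses into per-image, per-task proportions.  Duplicate rows
#' are distinct trials.  Alternatively a pre-aggregated table with columns
#' `image_id`, `task`, `proportion` and optionally `n_trials` is accepted.
#'
#' @param path CSV path.
#' @param min_trials Images with fewer pooled trials are flagged (default 4).
#' @return Data frame with `image_id`, `task`, `proportion`, `n_trials`,
#'   `flagged`; zero rows (with a warning) for an empty file.
#' @export
read_ratings <- function(path, min_trials = 4L) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  empty <- data.frame(image_id = character(0), task = character(0),
                      proportion = numeric(0), n_trials = integer(0),
                      flagged = logical(0))
  if (nrow(d) == 0L) {
    warning("ratings file is empty: ", path)
    return(empty)
  }
  if ("proportion" %in% names(d)) {
    if (any(d$proportion < 0 | d$proportion > 1, na.rm = TRUE))
      stop("proportion outside [0, 1] in ", path)
    out <- data.frame(image_id = as.character(d$image_id),
                      task = if ("task" %in% names(d)) d$task else "texturality",
                      proportion = d$proportion,
                      n_trials = if ("n_trials" %in% names(d))
                        as.integer(d$n_trials) else NA_integer_)
  } else {
    need <- c("image_id", "observer_id", "task", "response")
    if (!all(need %in% names(d)))
      stop("ratings file must have columns ", paste(need, collapse = ", "))
    bad_task <- which(!d$task %in% c("texturality", "similarity"))
    if (length(bad_task))
      stop("unknown task value at data row(s) ",
           paste(utils::head(bad_task, 5), collapse = ", "), " of ", path)
    bad_resp <- which(!d$response %in% c(0, 1))
    if (length(bad_resp))
      stop("response outside {0, 1} at data row(s) ",
           paste(utils::head(bad_resp, 5), collapse = ", "), " of ", path)
    agg <- stats::aggregate(response ~ image_id + task, data = d,
                            FUN = function(r) c(mean(r), length(r)))
    out <- data.frame(image_id = as.character(agg$image_id), task = agg$task,
                      proportion = agg$response[, 1],
                      n_trials = as.integer(agg$response[, 2]))
  }
  out$flagged <- !is.na(out$n_trials) & out$n_trials < min_trials
  out[order(out$task, out$image_id), , drop = FALSE]
}
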