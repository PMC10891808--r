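#' Read and write MOTChallenge CSV streams
#'
#' The MOTChallenge dialect is a headerless CSV with one detection or track
#' per row: `frame, id, bb_left, bb_top, bb_width, bb_height, conf, x, y, z`
#' (the last three unused, written as -1; `id` is -1 for raw detections).
#' Frames are 1-based. Internally boxes are half-open corners
#' `(x1, y1, x2, y2)`; the conversion `(left, top, width, height) <->`
#' corners is exact.
#'
#' `read_mot()` parses a file into a frame-ordered data frame;
#' `write_mot()` is its inverse, with deterministic row order (frame, then
#' id) and coordinates serialized to at most two decimals. A write/read
#' round trip is the identity on any valid stream at that precision.
#'
#' @param path file path.
#' @param kind `"detections"` (id column ignored, score kept) or `"tracks"`.
#' @return `read_mot()` returns a data frame with columns `frame, id, x1,
#'   y1, x2, y2, score`.
#' @export
read_mot <- function(path, kind = c("detections", "tracks")) {
  kind <- match.arg(kind)
  cols <- c("frame", "id", "x1", "y1", "x2", "y2", "score")
  if (file.size(path) == 0)
    return(stats::setNames(data.frame(integer(0), integer(0), numeric(0),
                                      numeric(0), numeric(0), numeric(0),
                                      numeric(0)), cols))
  raw <- utils::read.csv(path, header = FALSE, strip.white = TRUE)
  if (ncol(raw) < 7)
    stop(sprintf("malformed MOT file '%s': expected >= 7 columns, got %d",
                 path, ncol(raw)))
  bad <- which(!stats::complete.cases(raw[, 1:7]))
  if (length(bad))
    stop(sprintf("malformed row at line %d of '%s'", bad[1], path))
  nonpos <- which(raw[[5]] <= 0 | raw[[6]] <= 0)
  if (length(nonpos)) {
    warning(sprintf("%d row(s) with non-positive box size rejected in '%s'",
                    length(nonpos), path))
    raw <- raw[-nonpos, , drop = FALSE]
  }
  out <- data.frame(frame = as.integer(raw[[1]]),
                    id = as.integer(raw[[2]]),
                    x1 = raw[[3]], y1 = raw[[4]],
                    x2 = raw[[3]] + raw[[5]], y2 = raw[[4]] + raw[[6]],
                    score = raw[[7]])
  if (any(out$frame < 1)) stop(sprintf("malformed frame index in '%s'", path))
  out[order(out$frame, out$id), , drop = FALSE]
}

#' @rdname read_mot
#' @param stream a data frame with columns `frame, x1, y1, x2, y2` and
#'   optionally `id` (default -1) and `score` (default 1).
#' @export
write_mot <- function(stream, path) {
  if (nrow(stream) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  id <- if (is.null(stream$id)) rep(-1L, nrow(stream)) else stream$id
  score <- if (is.null(stream$score)) rep(1, nrow(stream)) else stream$score
  o <- order(stream$frame, id)
  lines <- sprintf("%d,%d,%s,%s,%s,%s,%s,-1,-1,-1",
                   as.integer(stream$frame[o]), as.integer(id[o]),
                   fmt2(stream$x1[o]), fmt2(stream$y1[o]),
                   fmt2(stream$x2[o] - stream$x1[o]),
                   fmt2(stream$y2[o] - stream$y1[o]), fmt2(score[o]))
  writeLines(lines, path)
  invisible(path)
}

# <= 2 decimals, no trailing zeros
fmt2 <- function(x) {
  s <- formatC(round(x, 2), format = "f", digits = 2)
  sub("\\.?0+$", "", s)
}

#' Write a simulated scenario to a directory
#'
#' Writes `gt.txt` and `det.txt` in MOTChallenge format plus `events.json`
#' into `dir`.
#'
#' @param scenario a `pen_scenario` from [simulate_scenario()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  stopifnot(inherits(scenario, "pen_scenario"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mot(scenario$gt, file.path(dir, "gt.txt"))
  write_mot(scenario$dets, file.path(dir, "det.txt"))
  jsonlite::write_json(scenario$events, file.path(dir, "events.json"),
                       dataframe = "rows", na = "null")
  invisible(dir)
}

#' Load tracker configuration from a YAML file
#'
#' Reads a config file with optional top-level keys `noise` (`th1`, `th2`),
#' `roi` (`x, y, w, h, mode`), and one section per tracker name whose
#' entries override that tracker's defaults. Precedence elsewhere in the
#' package is: explicit argument > config file > built-in default.
#'
#' @param path YAML file path.
#' @return a named list of configuration sections.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) list() else cfg
}
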