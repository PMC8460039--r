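# Praat TextGrid I/O (long "ooTextFile" format, UTF-8).

#' Read a Praat TextGrid into an annotation set
#'
#' Parses a long-format ("ooTextFile") TextGrid and converts one interval
#' tier into events.  Interval times (seconds) are mapped to 0-based
#' sample indices by rounding at `fs`.  Intervals with empty labels are
#' treated as unannotated and skipped.
#'
#' @param path TextGrid file.
#' @param fs target sampling rate (Hz).
#' @param tier name of the interval tier holding the labels
#'   (default "labels").
#' @return an `annotation_set` (no context columns filled).
#' @export
read_textgrid <- function(path, fs, tier = "labels") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  tiers <- parse_textgrid_tiers(lines)
  if (!tier %in% names(tiers))
    stop(sprintf("tier '%s' not found; available tiers: %s", tier,
                 paste(names(tiers), collapse = ", ")))
  iv <- tiers[[tier]]
  iv <- iv[nzchar(iv$text), , drop = FALSE]
  if (nrow(iv) > 1 && any(iv$xmin[-1] < iv$xmax[-nrow(iv)] - 1e-9))
    stop("overlapping intervals on tier '", tier, "'")
  ev <- data.frame(label = iv$text,
                   onset = round(iv$xmin * fs),
                   offset = round(iv$xmax * fs))
  annotation_set(ev, fs)
}

# returns named list of data.frames (xmin, xmax, text), one per interval tier
parse_textgrid_tiers <- function(lines) {
  num <- function(l) as.numeric(sub(".*=\\s*", "", l))
  str <- function(l) {
    m <- regmatches(l, regexpr('"(?:[^"]|"")*"', l))
    if (!length(m)) return("")
    gsub('""', '"', substr(m, 2, nchar(m) - 1))
  }
  tiers <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (grepl('class\\s*=\\s*"IntervalTier"', lines[i])) {
      name <- ""
      xmin <- xmax <- numeric(0)
      text <- character(0)
      i <- i + 1L
      while (i <= n && !grepl('class\\s*=', lines[i])) {
        l <- lines[i]
        if (grepl("^\\s*name\\s*=", l)) name <- str(l)
        if (grepl("^\\s*xmin\\s*=", l) && length(xmin) == length(text) + 1L) {
          # xmin lines inside an interval block alternate xmin/xmax/text;
          # handled below instead
        }
        if (grepl("^\\s*intervals\\s*\\[", l)) {
          x1 <- num(lines[i + 1L]); x2 <- num(lines[i + 2L])
          tx <- str(lines[i + 3L])
          xmin <- c(xmin, x1); xmax <- c(xmax, x2); text <- c(text, tx)
          i <- i + 3L
        }
        i <- i + 1L
      }
      tiers[[name]] <- data.frame(xmin = xmin, xmax = xmax, text = text,
                                  stringsAsFactors = FALSE)
    } else i <- i + 1L
  }
  tiers
}

#' Write an annotation set as a Praat TextGrid
#'
#' Emits a long-format ("ooTextFile") TextGrid with two interval tiers:
#' `"labels"` (every event's label) and `"context"` (a compact
#' `bout.motif` tag for contextualized vocal events, empty otherwise).
#' Unannotated stretches are written as empty-label intervals so the
#' tiers tile the full time range, as Praat requires.
#'
#' @param ann an `annotation_set`.
#' @param path output path.
#' @export
write_textgrid <- function(ann, path) {
  ev <- ann$events
  fs <- ann$fs
  xmax <- (max(ev$offset) + fs) / fs
  ctx <- ifelse(is.na(ev$bout), "",
                paste0("b", ev$bout,
                       ifelse(is.na(ev$motif), "", paste0(".m", ev$motif))))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('File type = "ooTextFile"')
  w('Object class = "TextGrid"')
  w("")
  w("xmin = 0 ")
  w("xmax = %.10g ", xmax)
  w("tiers? <exists> ")
  w("size = 2 ")
  w("item []: ")
  write_tier <- function(k, name, labels) {
    # tile [0, xmax] with empty fillers between events
    iv_x1 <- numeric(0); iv_x2 <- numeric(0); iv_t <- character(0)
    cur <- 0
    for (i in seq_len(nrow(ev))) {
      a <- ev$onset[i] / fs; b <- ev$offset[i] / fs
      if (a > cur + 1e-9) {
        iv_x1 <- c(iv_x1, cur); iv_x2 <- c(iv_x2, a); iv_t <- c(iv_t, "")
      }
      iv_x1 <- c(iv_x1, a); iv_x2 <- c(iv_x2, b); iv_t <- c(iv_t, labels[i])
      cur <- b
    }
    if (cur < xmax) {
      iv_x1 <- c(iv_x1, cur); iv_x2 <- c(iv_x2, xmax); iv_t <- c(iv_t, "")
    }
    w("    item [%d]:", k)
    w('        class = "IntervalTier" ')
    w('        name = "%s" ', name)
    w("        xmin = 0 ")
    w("        xmax = %.10g ", xmax)
    w("        intervals: size = %d ", length(iv_x1))
    for (i in seq_along(iv_x1)) {
      w("        intervals [%d]:", i)
      w("            xmin = %.10g ", iv_x1[i])
      w("            xmax = %.10g ", iv_x2[i])
      w('            text = "%s" ', gsub('"', '""', iv_t[i]))
    }
  }
  write_tier(1, "labels", ev$label)
  write_tier(2, "context", ctx)
  invisible(path)
}
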