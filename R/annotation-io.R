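EVENT_KINDS <- c("nucleus", "phrase_break", "sentence_break")

mark_to_kind <- function(mark) {
  ifelse(mark == "/", "phrase_break",
         ifelse(mark == "//", "sentence_break", "nucleus"))
}

kind_to_mark <- function(kind) {
  c(nucleus = "", phrase_break = "/", sentence_break = "//")[kind]
}

#' Construct an annotation sequence
#'
#' An annotation sequence holds the timestamped syllable-nucleus and
#' break events of one narrative recording by one annotator, possibly
#' spread over several audio parts. Nucleus events carry an intensity in
#' dB; break events (phrase `/` or sentence `//`) mark interruptions of
#' the speech rhythm and need not carry one.
#'
#' @param events data.frame with columns `part` (integer, >= 1), `time`
#'   (seconds within the part, >= 0), `kind` (one of `"nucleus"`,
#'   `"phrase_break"`, `"sentence_break"`), `intensity` (dB, `NA`
#'   allowed on break rows).
#' @param language_iso language code (3-letter ISO for corpus data;
#'   arbitrary codes are allowed for synthetic sequences).
#' @param annotator annotator initials.
#' @return An object of class `annotation_seq`.
#' @export
annotation_seq <- function(events, language_iso = "xxx", annotator = "syn") {
  if (nrow(events) == 0L) {
    events <- data.frame(part = integer(), time = numeric(),
                         kind = character(), intensity = numeric())
  }
  rownames(events) <- NULL
  events$part <- as.integer(events$part)
  events$time <- as.numeric(events$time)
  events$kind <- as.character(events$kind)
  events$intensity <- as.numeric(events$intensity)
  obj <- structure(list(language_iso = language_iso,
                        annotator = annotator,
                        events = events),
                   class = "annotation_seq")
  validate_annotation_seq(obj)
}

validate_annotation_seq <- function(x) {
  ev <- x$events
  if (nrow(ev) == 0L) return(x)
  if (!all(ev$kind %in% EVENT_KINDS))
    stop("unknown event kind(s): ",
         paste(setdiff(unique(ev$kind), EVENT_KINDS), collapse = ", "))
  if (any(ev$time < 0)) stop("negative event time")
  if (any(ev$part < 1L)) stop("part index must be >= 1")
  ord <- order(ev$part, ev$time)
  if (!identical(ord, seq_len(nrow(ev))))
    stop("events not sorted by (part, time)")
  for (p in unique(ev$part)) {
    tt <- ev$time[ev$part == p]
    if (any(diff(tt) <= 0))
      stop("times not strictly increasing within part ", p)
  }
  nuc <- ev$kind == "nucleus"
  if (any(nuc & !is.finite(ev$intensity)))
    stop("nucleus rows must carry an intensity")
  x
}

#' @export
print.annotation_seq <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<annotation_seq> %s/%s: %d events (%d nuclei, %d breaks) in %d part(s)\n",
              x$language_iso, x$annotator, nrow(ev),
              sum(ev$kind == "nucleus"), sum(ev$kind != "nucleus"),
              length(unique(ev$part))))
  invisible(x)
}

#' Number of nucleus events
#' @param seq an `annotation_seq`.
#' @return integer count.
#' @export
n_nuclei <- function(seq) sum(seq$events$kind == "nucleus")

split_fields <- function(lines) strsplit(lines, "\t", fixed = TRUE)

parse_num <- function(s, what, lineno, path) {
  v <- suppressWarnings(as.numeric(s))
  bad <- which(!is.na(s) & nzchar(s) & is.na(v))
  if (length(bad))
    stop(sprintf("%s: line %d: non-numeric %s field '%s'",
                 path, lineno[bad[1]], what, s[bad[1]]))
  v
}

read_tab_rows <- function(path, ncol_expected) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(list(fields = list(), lineno = integer()))
  fields <- split_fields(lines)
  nf <- lengths(fields)
  # a trailing empty intensity field gets dropped by strsplit; pad
  fields <- lapply(fields, function(f) c(f, rep("", ncol_expected - length(f))))
  if (any(nf > ncol_expected))
    stop(sprintf("%s: line %d: expected %d tab-separated columns, found %d",
                 path, lineno[which(nf > ncol_expected)[1]],
                 ncol_expected, max(nf)))
  # tolerate a header row (non-numeric 'time' in column 2)
  if (length(fields) &&
      is.na(suppressWarnings(as.numeric(fields[[1]][2]))) &&
      nzchar(fields[[1]][2])) {
    fields <- fields[-1]
    lineno <- lineno[-1]
  }
  list(fields = fields, lineno = lineno)
}

#' Read a tab-separated nucleus annotation file
#'
#' The `.out` dialect has 4 tab-separated columns per row: `part` (index
#' of the audio file within the narrative), `time` (seconds), `mark`
#' (empty for a nucleus, `/` for a phrase break, `//` for a sentence
#' break) and `intensity` (dB; may be empty on break rows). An optional
#' header line is tolerated.
#'
#' @param path file path.
#' @param language_iso,annotator metadata attached to the result.
#' @return An [annotation_seq()].
#' @export
read_out_file <- function(path, language_iso = "xxx", annotator = "unk") {
  if (!file.exists(path)) stop("no such file: ", path)
  rows <- read_tab_rows(path, 4L)
  if (!length(rows$fields))
    return(annotation_seq(data.frame(part = integer(), time = numeric(),
                                     kind = character(), intensity = numeric()),
                          language_iso, annotator))
  m <- do.call(rbind, rows$fields)
  ev <- data.frame(
    part = as.integer(parse_num(m[, 1], "part", rows$lineno, path)),
    time = parse_num(m[, 2], "time", rows$lineno, path),
    kind = mark_to_kind(m[, 3]),
    intensity = parse_num(m[, 4], "intensity", rows$lineno, path)
  )
  annotation_seq(ev, language_iso, annotator)
}

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else format(v, digits = 17, scientific = FALSE, trim = TRUE)
  }, character(1))
  out
}

#' Write a tab-separated nucleus annotation file
#'
#' Inverse of [read_out_file()]: writing then re-reading reproduces the
#' sequence field for field.
#'
#' @param seq an `annotation_seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_out_file <- function(seq, path) {
  ev <- seq$events
  lines <- sprintf("%d\t%s\t%s\t%s", ev$part, fmt_num(ev$time),
                   kind_to_mark(ev$kind), fmt_num(ev$intensity))
  writeLines(lines, path)
  invisible(path)
}

#' Read a concatenated multi-language annotation file
#'
#' The concatenated dialect adds two columns, `language` and
#' `annotator`, to the 4-column format. Rows are grouped into one
#' sequence per (language, annotator) pair, in order of first
#' appearance.
#'
#' @param path file path.
#' @return list of [annotation_seq()] objects.
#' @export
read_concatenated <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  rows <- read_tab_rows(path, 6L)
  if (!length(rows$fields)) return(list())
  m <- do.call(rbind, rows$fields)
  if (ncol(m) != 6L || any(!nzchar(m[, 5])))
    stop(path, ": expected 6 columns (part, time, mark, intensity, language, annotator)")
  key <- paste(m[, 5], m[, 6], sep = "\r")
  groups <- split(seq_len(nrow(m)), factor(key, levels = unique(key)))
  lapply(groups, function(idx) {
    ev <- data.frame(
      part = as.integer(parse_num(m[idx, 1], "part", rows$lineno[idx], path)),
      time = parse_num(m[idx, 2], "time", rows$lineno[idx], path),
      kind = mark_to_kind(m[idx, 3]),
      intensity = parse_num(m[idx, 4], "intensity", rows$lineno[idx], path)
    )
    annotation_seq(ev, m[idx[1], 5], m[idx[1], 6])
  })
}

#' Write several sequences as one concatenated file
#' @param seqs list of `annotation_seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_concatenated <- function(seqs, path) {
  lines <- unlist(lapply(seqs, function(s) {
    ev <- s$events
    sprintf("%d\t%s\t%s\t%s\t%s\t%s", ev$part, fmt_num(ev$time),
            kind_to_mark(ev$kind), fmt_num(ev$intensity),
            s$language_iso, s$annotator)
  }))
  writeLines(lines, path)
  invisible(path)
}

# ---- Praat TextGrid (point tiers) ------------------------------------------

tg_unquote <- function(s) {
  s <- sub('^\\s*"', "", s)
  s <- sub('"\\s*$', "", s)
  gsub('""', '"', s)
}

# Parse a TextGrid file (long or short text form) into a list of tiers:
# list(name=, class=, times=, marks=). Interval tiers are kept so we can
# name them in error messages, with items = intervals.
parse_textgrid <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  if (!length(lines) || !grepl("ooTextFile", lines[1]))
    stop(path, ": not a Praat text file (missing ooTextFile header)")
  if (!any(grepl("TextGrid", lines[2])))
    stop(path, ": not a TextGrid object")
  long <- any(grepl("^\\s*item\\s*\\[", lines))
  if (long) parse_textgrid_long(lines, path) else parse_textgrid_short(lines, path)
}

grab_val <- function(line) sub("^[^=]*=\\s*", "", line)

parse_textgrid_long <- function(lines, path) {
  tiers <- list()
  i <- 1L
  n <- length(lines)
  cur <- NULL
  while (i <= n) {
    ln <- lines[i]
    if (grepl("^\\s*item\\s*\\[\\s*[0-9]+\\s*\\]", ln)) {
      if (!is.null(cur)) tiers[[length(tiers) + 1L]] <- cur
      cur <- list(name = "", class = "", times = numeric(), marks = character())
    } else if (!is.null(cur)) {
      if (grepl("^\\s*class\\s*=", ln)) cur$class <- tg_unquote(grab_val(ln))
      else if (grepl("^\\s*name\\s*=", ln)) cur$name <- tg_unquote(grab_val(ln))
      else if (grepl("^\\s*(number|time)\\s*=", ln))
        cur$times <- c(cur$times, as.numeric(grab_val(ln)))
      else if (grepl("^\\s*(mark|text)\\s*=", ln))
        cur$marks <- c(cur$marks, tg_unquote(grab_val(ln)))
    }
    i <- i + 1L
  }
  if (!is.null(cur)) tiers[[length(tiers) + 1L]] <- cur
  tiers
}

parse_textgrid_short <- function(lines, path) {
  # positional short form: after the 7-line preamble, each tier is
  # "ClassName", "tier name", xmin, xmax, n, then n records
  vals <- lines[nzchar(trimws(lines))]
  i <- which(grepl("ooTextFile", vals))[1] + 1L  # object class line
  i <- i + 1L                                    # xmin
  i <- i + 2L                                    # skip xmin,xmax -> <exists>
  i <- i + 1L                                    # size
  ntier <- as.integer(trimws(vals[i]))
  i <- i + 1L
  tiers <- vector("list", ntier)
  for (t in seq_len(ntier)) {
    cls <- tg_unquote(vals[i]); nm <- tg_unquote(vals[i + 1L])
    np <- as.integer(trimws(vals[i + 4L]))
    i <- i + 5L
    if (cls == "TextTier") {
      times <- numeric(np); marks <- character(np)
      for (k in seq_len(np)) {
        times[k] <- as.numeric(trimws(vals[i]))
        marks[k] <- tg_unquote(vals[i + 1L])
        i <- i + 2L
      }
      tiers[[t]] <- list(name = nm, class = cls, times = times, marks = marks)
    } else {
      # interval tier: 3 values per interval; retain name only
      i <- i + 3L * np
      tiers[[t]] <- list(name = nm, class = cls,
                         times = numeric(), marks = character())
    }
  }
  tiers
}

#' Read syllable-nucleus annotations from a Praat TextGrid
#'
#' Reads a point tier (Praat class `TextTier`) from a TextGrid in long
#' or short text form. Points labelled `/` become phrase breaks, `//`
#' sentence breaks; any other label (typically the syllable number) is a
#' nucleus. Intensities are not stored in TextGrids, so the intensity
#' field is left `NA`; it can be filled from a `.out` file or by the
#' synthetic generator.
#'
#' @param path TextGrid path.
#' @param tier_name name of the point tier holding the annotations. The
#'   corpus files this format mirrors do not fix a tier name; the
#'   default `"nuclei"` matches what [write_textgrid()] emits.
#' @param part audio-part index to assign (one TextGrid annotates one
#'   audio file).
#' @param language_iso,annotator metadata attached to the result.
#' @return An [annotation_seq()] (nucleus intensities `NA`).
#' @export
read_textgrid <- function(path, tier_name = "nuclei", part = 1L,
                          language_iso = "xxx", annotator = "unk") {
  tiers <- parse_textgrid(path)
  names_avail <- vapply(tiers, `[[`, "", "name")
  hit <- which(names_avail == tier_name)
  if (!length(hit))
    stop(sprintf("%s: no tier named '%s'; available tiers: %s",
                 path, tier_name, paste(sQuote(names_avail), collapse = ", ")))
  tier <- tiers[[hit[1]]]
  if (tier$class != "TextTier")
    stop(sprintf("%s: tier '%s' is a %s; only point tiers (TextTier) are supported",
                 path, tier_name, tier$class))
  if (!length(tier$times))
    return(annotation_seq(data.frame(part = integer(), time = numeric(),
                                     kind = character(), intensity = numeric()),
                          language_iso, annotator))
  ord <- order(tier$times)
  ev <- data.frame(part = as.integer(part),
                   time = tier$times[ord],
                   kind = mark_to_kind(trimws(tier$marks[ord])),
                   intensity = NA_real_)
  # TextGrid nuclei carry no intensity; bypass the nucleus-intensity check
  obj <- structure(list(language_iso = language_iso, annotator = annotator,
                        events = ev), class = "annotation_seq")
  for (p in unique(ev$part)) {
    tt <- ev$time[ev$part == p]
    if (any(diff(tt) <= 0)) stop("times not strictly increasing within part ", p)
  }
  obj
}

#' Write an annotation sequence as a Praat TextGrid point tier
#'
#' Writes the long text form. Nuclei are labelled with their running
#' syllable number, breaks with `/` or `//`. Only a single part can be
#' written per TextGrid (one TextGrid annotates one audio file).
#'
#' @param seq an `annotation_seq` (single part).
#' @param path output path.
#' @param tier_name tier name to emit.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(seq, path, tier_name = "nuclei") {
  ev <- seq$events
  if (length(unique(ev$part)) > 1L)
    stop("a TextGrid holds one audio part; split the sequence first")
  xmax <- if (nrow(ev)) max(ev$time) + 1 else 1
  marks <- ifelse(ev$kind == "nucleus",
                  as.character(cumsum(ev$kind == "nucleus")),
                  kind_to_mark(ev$kind))
  out <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0",
    sprintf("xmax = %s", fmt_num(xmax)),
    "tiers? <exists>",
    "size = 1",
    "item []:",
    "    item [1]:",
    '        class = "TextTier"',
    sprintf('        name = "%s"', tier_name),
    "        xmin = 0",
    sprintf("        xmax = %s", fmt_num(xmax)),
    sprintf("        points: size = %d", nrow(ev))
  )
  if (nrow(ev)) {
    pts <- unlist(lapply(seq_len(nrow(ev)), function(k) {
      c(sprintf("        points [%d]:", k),
        sprintf("            number = %s", fmt_num(ev$time[k])),
        sprintf('            mark = "%s"', marks[k]))
    }))
    out <- c(out, pts)
  }
  writeLines(out, path)
  invisible(path)
}
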