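# PROSITE pattern parsing and scanning. Patterns are hyphen-separated
# elements: a residue letter, `x` (any residue), `[ABC]` (set), `{ABC}`
# (anything but the set), each optionally repeated `(n)` or `(n,m)`;
# `<` anchors the match to the N terminus, `>` to the C terminus; a
# trailing `.` is tolerated. The scanner is a direct backtracking matcher,
# independent of R's regex engine.

#' Parse a PROSITE pattern
#'
#' @param pattern PROSITE pattern text, e.g. `"C-x(2)-C-x(2)-C-x(3)-C"`.
#' @return object of class `prosite_pattern`: list of elements, each with
#'   `type` (`"any"`, `"set"`, `"notset"`), `residues`, `min`, `max`, plus
#'   attributes `anchor_start` / `anchor_end`. Round-trips through
#'   [format()] to canonical text.
#' @export
prosite_parse <- function(pattern) {
  txt <- sub("\\.$", "", trimws(pattern))
  if (!nzchar(txt)) stop("empty PROSITE pattern")
  anchor_start <- startsWith(txt, "<")
  if (anchor_start) txt <- substring(txt, 2)
  anchor_end <- endsWith(txt, ">")
  if (anchor_end) txt <- substring(txt, 1, nchar(txt) - 1)
  toks <- strsplit(txt, "-", fixed = TRUE)[[1]]
  if (!length(toks) || any(!nzchar(toks))) {
    stop("malformed PROSITE pattern near '", pattern, "'")
  }
  elems <- lapply(seq_along(toks), function(i) {
    tok <- toks[[i]]
    m <- regmatches(tok, regexec(
      "^(x|[A-Z]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(?:\\(([0-9]+)(?:,([0-9]+))?\\))?$",
      tok))[[1]]
    if (!length(m)) stop("malformed PROSITE token '", tok, "' at element ", i)
    core <- m[[2]]
    lo <- if (nzchar(m[[3]])) as.integer(m[[3]]) else 1L
    hi <- if (nzchar(m[[4]])) as.integer(m[[4]]) else lo
    if (lo < 1 || hi < lo) stop("invalid repeat count in token '", tok, "'")
    if (core == "x") {
      list(type = "any", residues = "", min = lo, max = hi)
    } else if (startsWith(core, "[")) {
      list(type = "set", residues = gsub("\\[|\\]", "", core), min = lo, max = hi)
    } else if (startsWith(core, "{")) {
      list(type = "notset", residues = gsub("[{}]", "", core), min = lo, max = hi)
    } else {
      list(type = "set", residues = core, min = lo, max = hi)
    }
  })
  structure(elems, class = "prosite_pattern",
            anchor_start = anchor_start, anchor_end = anchor_end)
}

#' @export
format.prosite_pattern <- function(x, ...) {
  core <- vapply(unclass(x), function(e) {
    base <- switch(e$type,
                   any = "x",
                   set = if (nchar(e$residues) == 1) e$residues
                         else paste0("[", e$residues, "]"),
                   notset = paste0("{", e$residues, "}"))
    if (e$min == 1 && e$max == 1) base
    else if (e$min == e$max) paste0(base, "(", e$min, ")")
    else paste0(base, "(", e$min, ",", e$max, ")")
  }, "")
  paste0(if (isTRUE(attr(x, "anchor_start"))) "<" else "",
         paste(core, collapse = "-"),
         if (isTRUE(attr(x, "anchor_end"))) ">" else "")
}

#' @export
print.prosite_pattern <- function(x, ...) {
  cat("PROSITE pattern:", format(x), "\n")
  invisible(x)
}

.elem_ok <- function(elem, ch) {
  switch(elem$type,
         any = TRUE,
         set = grepl(ch, elem$residues, fixed = TRUE),
         notset = !grepl(ch, elem$residues, fixed = TRUE))
}

#' Scan a protein for PROSITE pattern matches
#'
#' Finds every 0-based start position where the pattern matches; variable
#' repeats are explored exhaustively by backtracking and anchors are
#' respected. Overlapping matches at distinct starts are all reported.
#'
#' @param protein amino-acid string.
#' @param pattern a `prosite_pattern` (see [prosite_parse()]) or pattern text.
#' @return data.frame with columns `start` (0-based) and `end` (0-based
#'   half-open end of the shortest match at that start); zero rows when the
#'   pattern does not occur.
#' @export
prosite_scan <- function(protein, pattern) {
  if (is.character(pattern)) pattern <- prosite_parse(pattern)
  stopifnot(inherits(pattern, "prosite_pattern"))
  ch <- strsplit(toupper(protein), "")[[1]]
  n <- length(ch)
  elems <- unclass(pattern)
  ne <- length(elems)
  anchor_end <- isTRUE(attr(pattern, "anchor_end"))

  # returns smallest match end (1-based, exclusive) from pos at element k, or -1
  match_from <- function(pos, k) {
    if (k > ne) {
      if (anchor_end && pos != n + 1L) return(-1L)
      return(pos)
    }
    e <- elems[[k]]
    # consume e$min .. e$max residues satisfying the element
    upto <- min(e$max, n + 1L - pos)
    if (upto < e$min) return(-1L)
    ok <- 0L
    for (c0 in seq_len(upto)) {
      if (!.elem_ok(e, ch[pos + c0 - 1L])) break
      ok <- c0
    }
    if (ok < e$min) return(-1L)
    best <- -1L
    for (c0 in e$min:ok) {
      r <- match_from(pos + c0, k + 1L)
      if (r > 0L && (best < 0L || r < best)) best <- r
    }
    best
  }

  starts <- if (isTRUE(attr(pattern, "anchor_start"))) 1L else seq_len(max(n, 0L))
  hits <- lapply(starts, function(p) {
    e <- match_from(p, 1L)
    if (e > 0L) c(p - 1L, e - 1L) else NULL
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  data.frame(start = hits[, 1], end = hits[, 2])
}
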